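test_that("matrix entries follow the post-breeding census convention", {
  A <- leslie_matrix(q = c(0.5, 1), m = c(0, 4), sex_ratio = 0.5)
  expect_equal(unclass(A), matrix(c(1, 0.5, 0, 0), 2, 2),
               ignore_attr = TRUE)
  B <- leslie_matrix(q = rep(0.1, 5), m = rep(0, 5))
  expect_true(all(B[1, ] == 0))
  expect_error(leslie_matrix(c(0.5, 1), c(0, 4, 1)), "equal length")
  expect_error(leslie_matrix(c(0.5, 1.4), c(0, 4)), "\\[0, 1\\]")
})

test_that("the survival subdiagonal reproduces the l-ratios", {
  q <- c(0.3, 0.1, 0.15, 0.2, 1)
  A <- leslie_matrix(q, rep(0.2, 5))
  l <- cumulative_survival(q)
  P <- A[cbind(2:5, 1:4)]
  expect_equal(P, l[-1] / l[-5])
})

test_that("projection iterates the matrix recurrence", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  traj <- leslie_project(A, c(1, 0), years = 4)
  expect_equal(traj[, 1], c(1, 0, 1, 0, 1), ignore_attr = TRUE)
  expect_equal(traj[, 2], c(0, 1, 0, 1, 0), ignore_attr = TRUE)
  expect_error(leslie_project(A, c(1, 0, 0)), "match")
  expect_error(leslie_project(A, c(-1, 0)), "non-negative")
})

test_that("long-run growth of the projection converges to lambda", {
  q <- c(0.2, 0.1, 0.1, 0.15, 0.2, 0.3, 1)
  m <- c(0, 0, 0.4, 0.6, 0.6, 0.5, 0.3)
  A <- leslie_matrix(q, m)
  st <- eigen_analysis(A)
  traj <- leslie_project(A, rep(1, 7), years = 500)
  ratio <- sum(traj[501, ]) / sum(traj[500, ])
  expect_equal(ratio, st$lambda, tolerance = 1e-6)
})

test_that("eigen-analysis solves the textbook two-age example", {
  A <- matrix(c(0, 0.5, 2, 0), 2, 2)
  st <- eigen_analysis(A)
  expect_equal(st$lambda, 1)
  expect_equal(st$R0, 1)
  expect_equal(st$generation_time, 1)
})

test_that("elasticities sum to one and lambda solves Euler-Lotka", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 20
    q <- c(runif(n - 1, 0.02, 0.3), 1)
    m <- c(rep(0, 5), runif(n - 5, 0, 0.6))
    A <- leslie_matrix(q, m)
    st <- eigen_analysis(A)
    expect_equal(sum(st$elasticity), 1, tolerance = 1e-9)
    expect_equal(st$lambda, euler_lotka_lambda(unclass(A)),
                 tolerance = 1e-10)
    expect_true(all(st$stable_age >= -1e-12))
    expect_equal(sum(st$stable_age), 1, tolerance = 1e-9)
    expect_equal(st$repro_value[1], 1)
  }
})

test_that("a stable-age start grows exactly geometrically", {
  q <- c(0.2, 0.1, 0.12, 0.2, 0.4, 1)
  m <- c(0, 0.1, 0.5, 0.6, 0.5, 0.2)
  A <- leslie_matrix(q, m)
  st <- eigen_analysis(A)
  traj <- leslie_project(A, st$stable_age, years = 50)
  for (t in c(10, 25, 50))
    expect_equal(traj[t + 1, ], st$lambda^t * st$stable_age,
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("increasing any vital rate never decreases lambda", {
  q <- c(0.2, 0.1, 0.12, 0.2, 0.4, 1)
  m <- c(0, 0.1, 0.5, 0.6, 0.5, 0.2)
  A <- unclass(leslie_matrix(q, m))
  lam0 <- eigen_analysis(A)$lambda
  set.seed(2)
  nz <- which(A > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    Ap <- A
    Ap[nz[k, 1], nz[k, 2]] <- Ap[nz[k, 1], nz[k, 2]] * 1.05
    expect_gte(eigen_analysis(Ap)$lambda, lam0 - 1e-12)
  }
})

test_that("bycatch mortality depresses the growth rate", {
  sc <- scenario_spec()
  tr <- scenario_truth(sc)
  q_tot <- tr$q
  f_nat <- siler_age_distribution(sc$params, sc$max_age)
  S_nat <- rev(cumsum(rev(f_nat)))
  q_nat <- pmin(f_nat / S_nat, 1); q_nat[length(q_nat)] <- 1
  m <- default_maternity(sc$max_age)
  lam_nat <- eigen_analysis(leslie_matrix(q_nat, m))$lambda
  lam_tot <- eigen_analysis(leslie_matrix(q_tot, m))$lambda
  expect_gte(lam_nat, lam_tot)
})

test_that("unreachable sterile trailing classes are trimmed, not fatal", {
  # no survival into the last class and zero fertility there
  q <- c(0.2, 0.3, 1, 0)
  m <- c(0, 0.8, 0.4, 0)
  A <- leslie_matrix(q, m)
  st <- eigen_analysis(A)
  expect_length(st$stable_age, 4)
  expect_equal(st$stable_age[4], 0)
  expect_gt(st$lambda, 0)
})
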