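# Settings used by the quick pipeline checks: a small pool keeps each fit
# around a second while leaving the algorithm structure intact.
quick_fit <- function(sample, seed, draws = 1500, ...) {
  fit_ahp(sample, ahp_priors(draws = draws), seed = seed, ...)
}

test_that("importance weights normalise and the resample comes from the pool", {
  smp <- simulate_ahp(600, ahp_gen(), max_age = 25, seed = 21)
  post <- quick_fit(smp, seed = 21)
  expect_equal(sum(post$weights), 1, tolerance = 1e-12)
  expect_true(all(post$weights >= 0))
  key <- apply(post$samples, 1, paste, collapse = "\r")
  pool_key <- apply(post$pool, 1, paste, collapse = "\r")
  expect_true(all(key %in% pool_key))
  # diagnostics report the stopping criterion at every stage
  expect_true(all(c("unique_fraction", "pool_size") %in%
                    names(post$diagnostics)))
  expect_true(post$iterations <= 10)
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  smp <- simulate_ahp(400, ahp_gen(), max_age = 22, seed = 5)
  a <- quick_fit(smp, seed = 99)
  b <- quick_fit(smp, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$weights, b$weights)
  c <- quick_fit(smp, seed = 100)
  expect_false(identical(a$samples, c$samples))
})

test_that("a single-row resample is degenerate but legal", {
  smp <- simulate_ahp(400, ahp_gen(), max_age = 22, seed = 5)
  post <- fit_ahp(smp, ahp_priors(draws = 800), n_resample = 1, seed = 2)
  expect_equal(nrow(post$samples), 1)
  expect_s3_class(post, "ahp_posterior")
})

test_that("optimisation never loses likelihood relative to the prior pool", {
  smp <- simulate_ahp(500, ahp_gen(), max_age = 25, seed = 13)
  spec <- ahp_priors(draws = 1000)
  post <- fit_ahp(smp, spec, seed = 13)
  dat <- deaths_at_age(smp)
  prior_ll <- apply(draw_priors(spec, seed = 13), 1,
                    function(p) ahp_loglik(p, dat))
  expect_gte(max(post$loglik), max(prior_ll))
})

test_that("impossible priors are reported", {
  smp <- simulate_ahp(200, ahp_gen(), max_age = 20, seed = 1)
  lo <- c(A = 0.95, B = 0, C = 0, D = 0.9, E = 0, F = 1, G = 0.5,
          H = 1, I = 0.9)
  hi <- lo + 1e-3
  hi["A"] <- 0.99
  expect_error(fit_ahp(smp, ahp_priors(lo, hi, draws = 100), seed = 1),
               "priors incompatible")
})

test_that("posterior quantiles behave at the degenerate edges", {
  smp <- simulate_ahp(400, ahp_gen(), max_age = 22, seed = 5)
  post <- quick_fit(smp, seed = 7)
  # identical rows: all three quantiles coincide
  clone <- post
  clone$samples <- post$samples[rep(1, 50), ]
  pr <- predict_ahp(clone, 1:20)
  expect_equal(pr$lower, pr$median)
  expect_equal(pr$upper, pr$median)
  # zero-width level: quantiles collapse onto the median
  pr0 <- predict_ahp(post, 1:20, level = 0)
  expect_equal(pr0$lower, pr0$median)
  expect_equal(pr0$upper, pr0$median)
  empty <- post
  empty$samples <- post$samples[0, , drop = FALSE]
  expect_error(predict_ahp(empty, 1:20), "empty posterior")
})

test_that("credible bands shrink as the sample grows", {
  big <- simulate_ahp(3000, ahp_gen(), max_age = 29, seed = 50)
  small <- simulate_ahp(300, ahp_gen(), max_age = 29, seed = 50)
  post_b <- fit_ahp(big, ahp_priors(draws = 3000), seed = 50)
  post_s <- fit_ahp(small, ahp_priors(draws = 3000), seed = 50)
  wb <- predict_ahp(post_b, 0:25)
  ws <- predict_ahp(post_s, 0:25)
  width <- function(pr) mean(pr$upper[pr$component == "total"] -
                               pr$lower[pr$component == "total"])
  expect_lt(width(wb), width(ws))
})

test_that("IMIS posterior means match dense grid integration on a reduced model", {
  truth <- ahp_params(A = 0.15, B = 0.5, C = 0.8, D = 0.05, E = 3, F = 3,
                      G = 0.004, H = 1.12, I = 0.01)
  smp <- simulate_ahp(3000, truth, max_age = 25, seed = 5)
  lo <- c(A = 0.05, B = 0.5, C = 0.8, D = 0.05, E = 3, F = 3,
          G = 0.001, H = 1.05, I = 0.01)
  hi <- c(A = 0.30, B = 0.5, C = 0.8, D = 0.05, E = 3, F = 3,
          G = 0.012, H = 1.20, I = 0.01)
  post <- fit_ahp(smp, ahp_priors(lo, hi, draws = 3000), seed = 3)
  imis_mean <- colMeans(post$samples)[c("A", "G", "H")]

  # oracle: posterior mean by quadrature over a 60^3 grid of the free box
  n <- 60
  grid <- expand.grid(A = seq(lo["A"], hi["A"], length.out = n),
                      G = seq(lo["G"], hi["G"], length.out = n),
                      H = seq(lo["H"], hi["H"], length.out = n))
  dat <- deaths_at_age(smp)
  dat <- dat[-nrow(dat), ]              # open-ended terminal class
  x <- dat$x; M <- dat$M; S <- dat$S
  hump <- 0.01 + 0.05 * exp(-3 * log((x + 0.5) / 3)^2)
  llv <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gh <- grid$G[i] * grid$H[i]^x
    q <- grid$A[i]^((x + 0.5)^0.8) + hump + gh / (1 + gh)
    llv[i] <- if (any(q <= 0 | q >= 1)) -Inf
              else sum(M * log(q) + (S - M) * log(1 - q))
  }
  w <- exp(llv - max(llv)); w <- w / sum(w)
  grid_mean <- c(A = sum(w * grid$A), G = sum(w * grid$G),
                 H = sum(w * grid$H))
  expect_true(all(abs(imis_mean - grid_mean) / grid_mean <= 0.05))
})

test_that("with the hump priors collapsed the aHP agrees with the Siler fit", {
  pstar <- siler_params(0.25, 0.6, 0.01, 0.002, 0.18)
  smp <- simulate_natural(1500, pstar, max_age = 30, seed = 5)
  lo <- c(A = 0.001, B = 0, C = 0, D = 0, E = 1, F = 3, G = 1e-6,
          H = 1, I = 0)
  hi <- c(A = 0.5, B = 2, C = 3, D = 1e-6, E = 1, F = 3, G = 0.1,
          H = 1.5, I = 1e-6)
  post <- fit_ahp(smp, ahp_priors(lo, hi, draws = 4000), seed = 5)
  sfit <- fit_siler(smp, max_age = 30)
  ages <- 0:28
  q_s <- 1 - siler_survivorship(sfit$par, ages + 1) /
    siler_survivorship(sfit$par, ages)
  tot <- predict_ahp(post, ages)
  tot <- tot[tot$component == "total", ]
  inside <- q_s >= tot$lower & q_s <= tot$upper
  expect_gte(mean(inside), 0.9)
})
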