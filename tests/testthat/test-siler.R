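test_that("survivorship matches closed forms and boundary cases", {
  expect_equal(siler_survivorship(c(0, 1, 0.1, 0, 1), 10), exp(-1))
  expect_equal(siler_survivorship(siler_ref(), 0), 1)
  expect_error(siler_survivorship(siler_ref(), -1), "negative age")
  # removable singularities at b1 = 0 / b3 = 0
  expect_equal(siler_survivorship(c(0.2, 0, 0, 0, 0), 3), exp(-0.6))
  expect_equal(siler_survivorship(c(0, 1, 0, 0.1, 0), 2), exp(-0.2))
})

test_that("survivorship equals the quadrature of the hazard", {
  p <- siler_ref()
  x <- seq(0, 30, by = 1.5)
  expect_equal(siler_survivorship(p, x), quad_survivorship(unclass(p), x),
               tolerance = 1e-8)
})

test_that("hazard decomposes into monotone components that sum to the total", {
  p <- siler_ref()
  h <- siler_hazard(p, 0:30)
  expect_equal(h$total[1], 0.26)
  expect_equal(h$total, h$juvenile + h$constant + h$senescent,
               tolerance = 1e-12)
  expect_true(all(diff(h$juvenile) <= 0))
  expect_true(all(diff(h$senescent) >= 0))
  expect_true(all(h$total >= 0))
  z <- siler_hazard(c(0, 1, 0, 0, 1), 0:10)
  expect_true(all(z$total == 0))
})

test_that("log-survivorship slope reproduces the hazard", {
  p <- siler_ref()
  x <- seq(0.5, 25, by = 0.5)
  h <- 1e-4
  slope <- -(log(siler_survivorship(p, x + h)) -
               log(siler_survivorship(p, x - h))) / (2 * h)
  expect_equal(slope, siler_hazard(p, x)$total, tolerance = 1e-6)
})

test_that("discrete age-at-death distribution is a proper pmf", {
  f <- siler_age_distribution(c(0, 1, 0.1, 0, 1), 2)
  expect_equal(f, c(1 - exp(-0.1), exp(-0.1) - exp(-0.2), exp(-0.2)))
  for (p in list(siler_ref(), siler_gen())) {
    f <- siler_age_distribution(p, 40)
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("simulated deaths follow the generating age distribution", {
  p <- siler_gen()
  f <- siler_age_distribution(p, 30)
  smp <- simulate_natural(1e6, p, max_age = 30, seed = 99)
  counts <- tabulate(floor(as.numeric(smp)) + 1L, nbins = 31)
  expect_gt(suppressWarnings(chisq.test(counts, p = f)$p.value), 0.001)
})

test_that("the likelihood is locally maximal at the generating parameters", {
  p <- siler_gen()
  smp <- simulate_natural(20000, p, max_age = 30, seed = 31)
  counts <- tabulate(floor(as.numeric(smp)) + 1L, nbins = 31)
  nll <- function(par) {
    f <- siler_age_distribution(par, 30)
    -sum(counts[f > 0] * log(f[f > 0]))
  }
  base <- nll(p)
  set.seed(8)
  worse <- replicate(100, nll(unclass(p) * exp(rnorm(5, 0, 0.25))))
  expect_true(all(base <= worse))
})

test_that("Siler fit recovers the generating hazard from a large sample", {
  pstar <- siler_gen()
  smp <- simulate_natural(5000, pstar, max_age = 30, seed = 42)
  fit <- fit_siler(smp, max_age = 30)
  mu_true <- siler_hazard(pstar, 0:25)$total
  mu_fit <- siler_hazard(fit$par, 0:25)$total
  expect_true(all(abs(mu_fit - mu_true) / mu_true <= 0.20))
})

test_that("removing thinned young classes corrects the juvenile bias", {
  pstar <- siler_gen()
  smp <- simulate_natural(5000, pstar, max_age = 30, seed = 42)
  thinned <- thin_young(smp, retention = c(0.5, 0.5), seed = 7)
  f0 <- fit_siler(thinned, rm = 0, max_age = 30)
  f2 <- fit_siler(thinned, rm = 2, max_age = 30)
  q_true <- 1 - siler_survivorship(pstar, 1:2) / siler_survivorship(pstar, 0:1)
  q_of <- function(f)
    1 - siler_survivorship(f$par, 1:2) / siler_survivorship(f$par, 0:1)
  expect_lt(sum(abs(q_of(f2) - q_true)), sum(abs(q_of(f0) - q_true)))
})

test_that("fit is invariant to duplicating every record", {
  smp <- simulate_natural(400, siler_ref(), max_age = 25, seed = 3)
  f1 <- fit_siler(smp, max_age = 25)
  f2 <- fit_siler(c(as.numeric(smp), as.numeric(smp)), max_age = 25)
  expect_equal(unclass(f1$par), unclass(f2$par), tolerance = 1e-5)
  expect_equal(f2$objective, 2 * f1$objective, tolerance = 1e-8)
})

test_that("degenerate samples are rejected", {
  expect_error(fit_siler(rep(3, 50)), "single age class|at least two")
  expect_error(fit_siler(numeric(0)), "no ages")
  expect_error(fit_siler(c(0, 0, 1, 1), rm = 2), "all ages removed")
})

test_that("least-squares objective gives a comparable hazard", {
  pstar <- siler_gen()
  smp <- simulate_natural(5000, pstar, max_age = 30, seed = 42)
  fit <- fit_siler(smp, max_age = 30, objective = "leastsquares")
  mu_true <- siler_hazard(pstar, 0:20)$total
  mu_fit <- siler_hazard(fit$par, 0:20)$total
  expect_true(all(abs(mu_fit - mu_true) / mu_true <= 0.30))
})

test_that("prediction covers all ages including removed classes", {
  smp <- simulate_natural(800, siler_ref(), max_age = 25, seed = 12)
  fit <- fit_siler(smp, rm = 2, max_age = 25)
  sched <- predict(fit)
  expect_equal(sched$age, 0:25)
  expect_true(all(is.finite(sched$total)))
  expect_true(all(sched$qx >= 0 & sched$qx <= 1))
})
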