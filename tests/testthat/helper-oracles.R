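# Shared fixtures and independent oracles used across the suite.

# reference Siler parameterisations
siler_ref <- function() siler_params(0.2, 0.5, 0.05, 0.01, 0.2)
siler_gen <- function() siler_params(0.3, 0.6, 0.02, 0.005, 0.25)

# survivorship by numerical quadrature of the hazard (independent of the
# closed-form product used by the implementation)
quad_survivorship <- function(p, x) {
  mu <- function(s) p[1] * exp(-p[2] * s) + p[3] + p[4] * exp(p[5] * s)
  vapply(x, function(xi) {
    if (xi == 0) return(1)
    exp(-stats::integrate(mu, 0, xi, rel.tol = 1e-12,
                          abs.tol = 1e-14)$value)
  }, numeric(1))
}

# unique positive root of the Euler-Lotka equation
# sum_x lambda^-(x+1) l(x) F_x = 1, solved by bisection
euler_lotka_lambda <- function(A, tol = 1e-12) {
  n <- nrow(A)
  Fx <- A[1, ]
  P <- A[cbind(2:n, 1:(n - 1))]
  l <- cumprod(c(1, P))
  g <- function(lam) sum(lam^(-(seq_len(n))) * l * Fx) - 1
  lo <- 1e-6
  hi <- 5
  while (g(hi) > 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# a well-specified aHP generator used in recovery/coverage checks
ahp_gen <- function() ahp_params(A = 0.12, B = 0.8, C = 0.9, D = 0.08,
                                 E = 2.5, F = 3, G = 0.002, H = 1.15,
                                 I = 0.02)

# small deaths-at-age table whose last class still has survivors, so the
# likelihood uses every row
toy_deaths <- function() data.frame(x = 0:4, M = c(30, 12, 8, 5, 9),
                                    S = c(100, 70, 58, 50, 45))
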