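#' Uniform prior specification for the aHP parameters
#'
#' Per-parameter lower and upper bounds of independent uniform priors, plus
#' the size of the initial prior pool.  A parameter whose bounds coincide is
#' held fixed at that value (a point-mass prior), which is how reduced
#' models are expressed.  The defaults are deliberately wide boxes suited to
#' small cetaceans; real analyses should set bounds from biological
#' knowledge.
#'
#' @param lower,upper named or positional numeric vectors of length 9
#'   (order A, B, C, D, E, F, G, H, I); `lower <= upper` elementwise.
#' @param draws size of the initial prior pool (default 5000).
#' @param seed optional seed stored with the spec.
#' @return an object of class `prior_spec`.
#' @export
ahp_priors <- function(lower = c(A = 0.001, B = 0, C = 0, D = 0, E = 0,
                                 F = 0.5, G = 1e-06, H = 1, I = 0),
                       upper = c(A = 0.5, B = 2, C = 3, D = 0.5, E = 10,
                                 F = 15, G = 0.1, H = 1.5, I = 0.5),
                       draws = 5000, seed = NULL) {
  nm <- ahp_parameter_names()
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 9L || length(upper) != 9L)
    stop("need 9 lower and 9 upper bounds")
  if (anyNA(lower) || anyNA(upper)) stop("bounds must be finite")
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  if (draws < 1) stop("draws must be >= 1")
  names(lower) <- names(upper) <- nm
  structure(list(lower = lower, upper = upper, draws = as.integer(draws),
                 seed = seed, free = which(lower < upper)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Uniform aHP priors (", x$draws, " draws; ",
      length(x$free), " free parameters)\n", sep = "")
  print(rbind(lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Draw from the prior
#'
#' Independent uniform draws within the bounds; fixed parameters are
#' repeated at their point value.  Reproducible given a seed.
#'
#' @param spec a [ahp_priors] object.
#' @param n number of draws (default `spec$draws`).
#' @param seed seed (default `spec$seed`).
#' @return `n x 9` matrix with parameter-name columns.
#' @export
draw_priors <- function(spec, n = spec$draws, seed = spec$seed) {
  stopifnot(inherits(spec, "prior_spec"))
  X <- matrix(rep(spec$lower, each = n), n, 9L,
              dimnames = list(NULL, names(spec$lower)))
  draw <- function() {
    for (j in spec$free)
      X[, j] <<- stats::runif(n, spec$lower[j], spec$upper[j])
  }
  if (is.null(seed)) draw() else with_substream(seed, "priors", draw())
  X
}

# log prior density over the free dimensions (uniform box; -Inf outside)
log_prior <- function(X, spec) {
  free <- spec$free
  lp <- rep(-sum(log(spec$upper[free] - spec$lower[free])), nrow(X))
  for (j in free)
    lp[X[, j] < spec$lower[j] | X[, j] > spec$upper[j]] <- -Inf
  lp
}

# multivariate normal log density for rows of X (free-dim coordinates)
dmvnorm_log <- function(X, mean, sigma) {
  d <- length(mean)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(sigma + diag(1e-8, d))
  z <- backsolve(ch, t(X) - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}


logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# covariance of the `k` pool points nearest to `center` (about the center,
# not the sample mean), in free coordinates, inflated x1.2.  When importance
# weights are supplied the deviations are weight-averaged (shrunk towards
# the uniform 1/n as in the standard IMIS recipe), which stretches the
# component along whatever posterior ridge the neighbourhood traces.
neighbour_cov <- function(pool_free, center, k, scale_width, w = NULL) {
  n <- nrow(pool_free)
  z <- sweep(pool_free, 2, center) / rep(scale_width, each = n)
  dist2 <- rowSums(z^2)
  idx <- order(dist2)[seq_len(min(k, n))]
  dev <- sweep(pool_free[idx, , drop = FALSE], 2, center)
  wt <- if (is.null(w)) rep(1, length(idx)) else (w[idx] + 1 / n) / 2
  wt <- wt / sum(wt)
  sg <- 1.2 * crossprod(dev * sqrt(wt))
  sg + diag(1e-10 + 1e-6 * scale_width^2, ncol(pool_free))
}

# covariance at a local optimum: inverse of the negative numerical Hessian
# of the log likelihood over the free coordinates; NULL when not positive
# definite (caller falls back to the neighbourhood covariance)
hessian_cov <- function(fn, center, width, cap = NULL) {
  d <- length(center)
  h <- pmax(1e-3 * width, 1e-8)
  f0 <- fn(center)
  for (tries in 1:4) {
    ok <- TRUE
    H <- matrix(0, d, d)
    for (i in seq_len(d)) {
      ei <- replace(numeric(d), i, h[i])
      fp <- fn(center + ei); fm <- fn(center - ei)
      if (!is.finite(fp) || !is.finite(fm)) { ok <- FALSE; break }
      H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
      for (j in seq_len(i - 1L)) {
        ej <- replace(numeric(d), j, h[j])
        fpp <- fn(center + ei + ej); fpm <- fn(center + ei - ej)
        fmp <- fn(center - ei + ej); fmm <- fn(center - ei - ej)
        if (!all(is.finite(c(fpp, fpm, fmp, fmm)))) { ok <- FALSE; break }
        H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
      }
      if (!ok) break
    }
    if (ok) break
    h <- h / 10
  }
  if (!ok) return(NULL)
  sg <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(sg)) return(NULL)
  sg <- (sg + t(sg)) / 2
  if (!is.null(cap)) {
    # bound the principal scales: flat likelihood ridges would otherwise
    # blow the cloud up far beyond the support that matters
    ev <- eigen(sg, symmetric = TRUE)
    vals <- pmin(pmax(ev$values, 1e-8), cap)
    sg <- ev$vectors %*% (vals * t(ev$vectors))
    sg <- (sg + t(sg)) / 2
  }
  if (inherits(tryCatch(chol(sg), error = function(e) e), "error"))
    return(NULL)
  sg
}

# expected fraction of unique points in a K-resample given normalised weights
expected_unique_fraction <- function(w, K) {
  sum(1 - (1 - w)^K) / K
}

#' Fit the adapted Heligman-Pollard model by Bayesian melding with IMIS
#'
#' Posterior inference for the nine aHP parameters from an age-structured
#' stranding sample.  The likelihood is binomial per age class (deaths given
#' numbers at risk, the at-risk counts taken from the cumulative survival of
#' the observed cohort); the prior is the uniform box of `priors`; their
#' logarithmic pooling is explored by Incremental Mixture Importance
#' Sampling:
#'
#' 1. an initial pool is drawn from the prior and weighted by likelihood;
#' 2. *optimizer stage*: local derivative-free (Nelder-Mead, with one
#'    restart) maximisation of the log posterior is started from the
#'    `n_opt` highest-likelihood points, spaced so that consecutive starts
#'    never share a nearest-neighbour ball; each run whose optimum beats
#'    the best prior-pool likelihood seeds a Gaussian cloud whose
#'    covariance is the inverse numerical Hessian at the optimum
#'    (eigenvalues capped, inflated x1.2), falling back to the
#'    neighbourhood covariance when the Hessian is not positive definite;
#' 3. *IMIS stage*: up to `n_imis` times, a multivariate-normal mixture
#'    component is centred at the current highest-weight point, with the
#'    importance-weighted covariance of its `pool/n_opt` nearest
#'    neighbours (inflated x1.2); importance weights are recomputed
#'    against the full mixture envelope `prior x likelihood / g(x)`;
#' 4. the procedure stops early once the expected fraction of unique points
#'    in an `n_resample`-draw equals or exceeds `1 - 1/e` (weights
#'    reasonably uniform), and
#' 5. `n_resample` parameter vectors are drawn from the pool with
#'    replacement, proportional to weight.
#'
#' Internally the sampler works in logit-transformed box coordinates, where
#' the uniform prior is a product of standard logistic densities: mixture
#' clouds can never leave the support and parameters spanning orders of
#' magnitude (such as `G`) are much closer to Gaussian.  The run is
#' deterministic given `seed` (all stages draw from named substreams of
#' it).
#'
#' @param sample an [age_sample] or numeric ages at death.
#' @param priors a [ahp_priors] specification.
#' @param n_imis maximum number of IMIS iterations (default 10).
#' @param n_opt number of optimizer starts (default 10).
#' @param n_resample rows in the final resample (default 500).
#' @param uf_target stopping threshold on the expected unique fraction of
#'   an `n_resample`-draw (default `1 - 1/e`, i.e. importance weights
#'   reasonably uniform).
#' @param seed master seed.
#' @param hump_offset hump-term age offset used in the likelihood
#'   (class midpoint 0.5 by default, so age class 0 is defined).
#' @param verbose print per-iteration diagnostics.
#' @return an object of class `ahp_posterior`: list with `samples`
#'   (`n_resample x 9` matrix), `weights` (normalised importance weights of
#'   the pre-resample pool), `pool`, `loglik`, `unique_fraction`,
#'   `iterations`, `diagnostics` (per-stage data frame), `data`, `priors`,
#'   `hump_offset`, `seed`.
#' @references The stopping rule and mixture construction follow the
#'   standard IMIS recipe for Bayesian melding of deterministic demographic
#'   models.
#' @export
fit_ahp <- function(sample, priors = ahp_priors(), n_imis = 10, n_opt = 10,
                    n_resample = 500, uf_target = 1 - exp(-1), seed = 1,
                    hump_offset = 0.5, verbose = FALSE) {
  if (!length(sample)) stop("no ages")
  data <- deaths_at_age(sample)
  spec <- priors
  free <- spec$free
  d <- length(free)
  if (d == 0L) stop("all parameters fixed: nothing to estimate")
  width <- spec$upper[free] - spec$lower[free]
  N0 <- spec$draws
  B <- max(ceiling(N0 / n_opt), 10L)
  K_near <- B

  # IMIS runs in logit-box coordinates u = logit((x - lower)/width): the
  # uniform box prior becomes a product of standard logistic densities,
  # Gaussian mixture clouds can never leave the support, and strongly
  # skewed parameters (e.g. G spanning several orders of magnitude) are
  # far closer to Gaussian there.
  eps <- 1e-12
  to_u <- function(X) {
    U <- X
    for (j in seq_len(d))
      U[, j] <- stats::qlogis(pmin(pmax((X[, j] - spec$lower[free[j]]) /
                                          width[j], eps), 1 - eps))
    U
  }
  expand <- function(U) {
    X <- matrix(rep(spec$lower, each = nrow(U)), nrow(U), 9L,
                dimnames = list(NULL, names(spec$lower)))
    for (j in seq_len(d))
      X[, free[j]] <- spec$lower[free[j]] + width[j] * stats::plogis(U[, j])
    X
  }
  loglik_rows <- function(X)
    apply(X, 1L, function(p) ahp_loglik(p, data, hump_offset))

  pool <- draw_priors(spec, n = N0, seed = seed)
  pool_u <- to_u(pool[, free, drop = FALSE])
  ll <- loglik_rows(pool)
  if (all(!is.finite(ll))) stop("priors incompatible with data")
  max_prior_ll <- max(ll)

  centers <- list()   # mixture components (mean, sigma) in u coordinates
  sigmas <- list()
  comp_n <- integer(0)   # points drawn from each component
  ll_u <- function(u) {
    U <- matrix(u, 1L)
    ahp_loglik(expand(U)[1L, ], data, hump_offset)
  }

  # --- optimizer stage -------------------------------------------------
  # starts are spaced out: after picking the highest-likelihood candidate,
  # its K_near nearest pool points are excluded from later candidacy, so
  # the local searches probe distinct regions of a ridged posterior
  ord <- order(-ll, seq_along(ll))
  avail <- rep(TRUE, nrow(pool_u))
  starts <- integer(0)
  for (k in seq_len(min(n_opt, sum(is.finite(ll))))) {
    cand <- ord[avail[ord] & is.finite(ll[ord])]
    if (!length(cand)) break
    i <- cand[1L]
    starts <- c(starts, i)
    z <- sweep(pool_u, 2, pool_u[i, ])
    avail[order(rowSums(z^2))[seq_len(min(K_near, nrow(pool_u)))]] <- FALSE
    avail[i] <- FALSE
  }
  opt_results <- with_substream(seed, "optimizer", lapply(starts, function(i) {
    o <- stats::optim(pool_u[i, ], function(u) -ll_u(u),
                      method = "Nelder-Mead",
                      control = list(maxit = 1000))
    # restart once from the incumbent: a fresh simplex escapes the
    # premature shrinkage Nelder-Mead is prone to in nine dimensions
    o <- stats::optim(o$par, function(u) -ll_u(u),
                      method = "Nelder-Mead",
                      control = list(maxit = 1000))
    list(u = o$par, ll = -o$value)
  }))
  kept <- Filter(function(o) is.finite(o$ll) && o$ll > max_prior_ll,
                 opt_results)
  if (verbose)
    message(sprintf("optimizer stage: %d/%d runs beat the prior maximum",
                    length(kept), length(opt_results)))
  add_cloud <- function(center_u, cloud_seed_name, sigma = NULL, w = NULL) {
    sg <- if (!is.null(sigma)) sigma else
      neighbour_cov(pool_u, center_u, K_near, rep(1, d), w = w)
    Z <- with_substream(seed, cloud_seed_name, {
      z <- MASS::mvrnorm(B, mu = center_u, Sigma = sg)
      if (d == 1L || B == 1L) matrix(z, ncol = d) else z
    })
    centers[[length(centers) + 1L]] <<- center_u
    sigmas[[length(sigmas) + 1L]] <<- sg
    comp_n <<- c(comp_n, B)
    pool_u <<- rbind(pool_u, Z)
    Xnew <- expand(Z)
    pool <<- rbind(pool, Xnew)
    ll <<- c(ll, loglik_rows(Xnew))
  }
  for (k in seq_along(kept)) {
    sg <- hessian_cov(ll_u, kept[[k]]$u, rep(1, d), cap = 9)
    add_cloud(kept[[k]]$u, paste0("cloud-opt-", k), sigma = sg)
  }

  # --- importance weights against the mixture envelope -----------------
  log_prior_u <- function(U) rowSums(stats::dlogis(U, log = TRUE))
  weights_now <- function() {
    lp <- log_prior_u(pool_u)
    if (!length(centers)) {
      lw <- lp + ll - lp     # prior-only pool: weights proportional to L
    } else {
      n_comp <- length(centers)
      lg_comp <- vapply(seq_len(n_comp), function(k)
        dmvnorm_log(pool_u, centers[[k]], sigmas[[k]]),
        numeric(nrow(pool_u)))
      if (nrow(pool_u) == 1L) lg_comp <- matrix(lg_comp, 1L)
      # g(u) = (N0 * prior + sum_k n_k phi_k) / (N0 + sum_k n_k)
      lg <- apply(cbind(log(N0) + lp,
                        sweep(lg_comp, 2, log(comp_n), "+")),
                  1L, logsumexp) - log(N0 + sum(comp_n))
      lw <- lp + ll - lg
    }
    lw[!is.finite(lw)] <- -Inf
    w <- exp(lw - logsumexp(lw))
    w / sum(w)
  }

  diagnostics <- data.frame()
  w <- weights_now()
  uf <- expected_unique_fraction(w, n_resample)
  diagnostics <- rbind(diagnostics,
                       data.frame(stage = "optimizer", iteration = 0L,
                                  pool_size = nrow(pool),
                                  unique_fraction = uf, max_weight = max(w)))
  target_uf <- uf_target
  iter <- 0L
  while (uf < target_uf && iter < n_imis) {
    iter <- iter + 1L
    best <- order(-w, seq_along(w))[1L]
    add_cloud(pool_u[best, ], paste0("cloud-imis-", iter), w = w)
    w <- weights_now()
    uf <- expected_unique_fraction(w, n_resample)
    diagnostics <- rbind(diagnostics,
                         data.frame(stage = "imis", iteration = iter,
                                    pool_size = nrow(pool),
                                    unique_fraction = uf,
                                    max_weight = max(w)))
    if (verbose)
      message(sprintf("IMIS %2d: pool %d, unique fraction %.3f",
                      iter, nrow(pool), uf))
  }

  idx <- with_substream(seed, "resample",
                        sample.int(nrow(pool), n_resample, replace = TRUE,
                                   prob = w))
  structure(list(samples = pool[idx, , drop = FALSE], weights = w,
                 pool = pool, loglik = ll, unique_fraction = uf,
                 iterations = iter, diagnostics = diagnostics,
                 data = data, priors = spec, hump_offset = hump_offset,
                 seed = seed,
                 settings = list(n_imis = n_imis, n_opt = n_opt,
                                 n_resample = n_resample)),
            class = "ahp_posterior")
}

#' @export
print.ahp_posterior <- function(x, ...) {
  cat("aHP posterior (Bayesian melding with IMIS)\n")
  cat(sprintf("  resample: %d rows; pool: %d; IMIS iterations: %d\n",
              nrow(x$samples), nrow(x$pool), x$iterations))
  cat(sprintf("  expected unique fraction: %.3f (stop threshold %.3f)\n",
              x$unique_fraction, 1 - exp(-1)))
  cat("  posterior medians:\n")
  print(round(apply(x$samples, 2, stats::median), 5))
  invisible(x)
}

#' Posterior mortality schedules with credible intervals
#'
#' Pointwise posterior quantiles (`(1-level)/2`, median, `1-(1-level)/2`)
#' of the natural, anthropogenic and total mortality-at-age across the
#' resampled aHP parameter vectors.
#'
#' @param post an `ahp_posterior` from [fit_ahp].
#' @param ages ages at which to evaluate.
#' @param level credible level in `(0, 1]` (default 0.90).
#' @param hump_offset defaults to the offset used in fitting.
#' @return data frame with columns `age`, `component`
#'   (`natural` / `anthropogenic` / `total`), `lower`, `median`, `upper`.
#' @export
predict_ahp <- function(post, ages, level = 0.90, hump_offset = NULL) {
  stopifnot(inherits(post, "ahp_posterior"))
  if (!nrow(post$samples)) stop("empty posterior")
  if (level < 0 || level >= 1) stop("level must lie in [0, 1)")
  if (is.null(hump_offset)) hump_offset <- post$hump_offset
  x <- as.numeric(ages)
  K <- nrow(post$samples)
  nat <- ant <- matrix(0, K, length(x))
  for (i in seq_len(K)) {
    cm <- ahp_components(as_ahp_params(post$samples[i, ]), x, hump_offset)
    nat[i, ] <- cm$juvenile + cm$adult
    ant[i, ] <- cm$hump
  }
  tot <- nat + ant
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  one <- function(m, name) {
    qs <- apply(m, 2, stats::quantile, probs = probs, names = FALSE)
    data.frame(age = x, component = name, lower = qs[1, ],
               median = qs[2, ], upper = qs[3, ])
  }
  out <- rbind(one(nat, "natural"), one(ant, "anthropogenic"),
               one(tot, "total"))
  rownames(out) <- NULL
  out
}

#' @export
predict.ahp_posterior <- function(object, ages, level = 0.90, ...) {
  predict_ahp(object, ages, level = level)
}
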