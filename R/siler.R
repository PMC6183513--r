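#' Siler competing-risk mortality parameters
#'
#' The five-parameter Siler model describes the hazard of long-lived mammals
#' as three competing risks: an exponentially declining juvenile risk, a
#' constant risk affecting all ages and an exponentially increasing senescent
#' risk,
#' \deqn{\mu(x) = a_1 e^{-b_1 x} + a_2 + a_3 e^{b_3 x}.}
#'
#' @param a1 juvenile hazard scale (1/yr).
#' @param b1 juvenile decline rate (1/yr).
#' @param a2 constant hazard (1/yr).
#' @param a3 senescent hazard scale (1/yr).
#' @param b3 senescent increase rate (1/yr).
#' @return a named numeric vector of class `siler_params`.
#' @export
siler_params <- function(a1, b1, a2, a3, b3) {
  p <- c(a1 = a1, b1 = b1, a2 = a2, a3 = a3, b3 = b3)
  if (anyNA(p) || any(!is.finite(p))) stop("Siler parameters must be finite")
  if (any(p < 0)) stop("Siler parameters must be non-negative")
  class(p) <- c("siler_params", "numeric")
  p
}

as_siler_params <- function(p) {
  if (inherits(p, "siler_params")) return(p)
  p <- unname(as.numeric(p))
  if (length(p) != 5L) stop("expected 5 Siler parameters")
  siler_params(p[1], p[2], p[3], p[4], p[5])
}

#' Siler survivorship
#'
#' Survivorship as the product of the three competing risks,
#' `l(x) = l_j(x) l_c(x) l_s(x)` with
#' `l_j = exp((-a1/b1)(1 - exp(-b1 x)))`, `l_c = exp(-a2 x)` and
#' `l_s = exp((a3/b3)(1 - exp(b3 x)))`.  Removable singularities at
#' `b1 = 0` or `b3 = 0` are evaluated in the limit (`exp(-a x)`).
#'
#' @param p Siler parameters ([siler_params] or a length-5 vector).
#' @param ages non-negative ages (years).
#' @return survivorship values in `(0, 1]`, `l(0) = 1`.
#' @export
siler_survivorship <- function(p, ages) {
  p <- as_siler_params(p)
  x <- as.numeric(ages)
  if (any(x < 0)) stop("negative age")
  lj <- if (p["b1"] > 0) exp((-p["a1"] / p["b1"]) * (1 - exp(-p["b1"] * x)))
        else exp(-p["a1"] * x)
  lc <- exp(-p["a2"] * x)
  ls <- if (p["b3"] > 0) exp((p["a3"] / p["b3"]) * (1 - exp(p["b3"] * x)))
        else exp(-p["a3"] * x)
  unname(lj * lc * ls)
}

#' Siler hazard and its components
#'
#' @param p Siler parameters.
#' @param ages non-negative ages (years).
#' @return a `data.frame` (class `mortality_schedule`, kind `"hazard"`) with
#'   columns `age`, `juvenile`, `constant`, `senescent`, `total`; the total
#'   is the sum of the components at every age.
#' @export
siler_hazard <- function(p, ages) {
  p <- as_siler_params(p)
  x <- as.numeric(ages)
  if (any(x < 0)) stop("negative age")
  out <- data.frame(
    age       = x,
    juvenile  = unname(p["a1"] * exp(-p["b1"] * x)),
    constant  = rep(unname(p["a2"]), length(x)),
    senescent = unname(p["a3"] * exp(p["b3"] * x))
  )
  out$total <- out$juvenile + out$constant + out$senescent
  structure(out, kind = "hazard",
            class = c("mortality_schedule", "data.frame"))
}

#' Discrete age-at-death distribution implied by a Siler model
#'
#' Probability that death occurs in age class `x`, `f(x) = l(x) - l(x+1)`
#' for `x = 0..max_age-1`, with the survivorship beyond `max_age` collected
#' into a terminal mass `f(max_age) = l(max_age)`.  Sums to 1 exactly.
#'
#' @param p Siler parameters.
#' @param max_age oldest age class (>= 1).
#' @return numeric vector of length `max_age + 1`.
#' @export
siler_age_distribution <- function(p, max_age) {
  if (max_age < 1) stop("max_age must be >= 1")
  l <- siler_survivorship(p, 0:max_age)
  c(l[-length(l)] - l[-1L], l[length(l)])
}

# negative multinomial log-likelihood of observed age-class counts, with the
# first `rm` classes excluded and the distribution renormalised over the rest
siler_nll <- function(logp, counts, rm) {
  p <- exp(logp)
  if (any(!is.finite(p))) return(1e10)
  f <- siler_age_distribution(p, length(counts) - 1L)
  keep <- seq_along(counts) > rm
  f <- f[keep] / sum(f[keep])
  if (any(f <= 0 & counts[keep] > 0)) return(1e10)
  ll <- sum(counts[keep][f > 0] * log(f[f > 0]))
  if (!is.finite(ll)) return(1e10) else -ll
}

# least-squares on log hazard: model q(x) vs observed life-table q(x)
siler_lsq <- function(logp, counts, rm) {
  p <- exp(logp)
  if (any(!is.finite(p))) return(1e10)
  x <- seq_along(counts) - 1L
  S <- rev(cumsum(rev(counts)))
  keep <- x >= rm & counts > 0 & S > 0
  q_obs <- counts[keep] / S[keep]
  q_mod <- siler_qx(p, x[keep])
  ok <- is.finite(q_mod)            # survivorship can underflow at old ages
  q_obs <- q_obs[ok]; q_mod <- q_mod[ok]
  if (!length(q_mod) || any(q_mod <= 0)) return(1e10)
  v <- sum((log(pmin(q_obs, 1 - 1e-12)) - log(pmin(q_mod, 1 - 1e-12)))^2)
  if (!is.finite(v)) 1e10 else v
}

# death probability q(x) = 1 - l(x+1)/l(x) implied by the Siler hazard
siler_qx <- function(p, ages) {
  1 - siler_survivorship(p, ages + 1) / siler_survivorship(p, ages)
}

#' Fit a Siler model to ages at death
#'
#' Maximises the multinomial likelihood of the observed age-class
#' frequencies under the discrete age-at-death distribution implied by the
#' Siler survivorship (deaths data are a census of ages at death).  A
#' least-squares alternative on log death probabilities is available via
#' `objective = "leastsquares"`.  Parameters are optimised on the log scale
#' (unconstrained Nelder-Mead, positivity by construction) with seeded
#' jittered restarts.
#'
#' Stranding samples commonly under-represent the youngest animals (faster
#' decomposition, predation, lower detection).  `rm` excludes the leading
#' `rm` age classes from the objective — the model is fitted to the
#' remaining "unbiased" ages — while predictions (e.g. [predict.siler_fit])
#' remain available for all ages including the removed ones.
#'
#' @param sample an [age_sample] or numeric ages at death.
#' @param rm number of leading age classes to exclude from the fit.
#' @param init optional initial [siler_params]; default
#'   `(0.1, 0.5, 0.05, 0.01, 0.1)`.
#' @param max_age oldest age class of the discretisation; defaults to the
#'   maximum observed age.
#' @param objective `"multinomial"` (default) or `"leastsquares"`.
#' @param restarts number of jittered Nelder-Mead restarts.
#' @param seed integer seed for the restart jitter.
#' @return an object of class `siler_fit`: list with `par`
#'   ([siler_params]), `objective`, `rm`, `max_age`, `counts`,
#'   `convergence`.
#' @examples
#' p <- siler_params(0.3, 0.6, 0.02, 0.005, 0.25)
#' ages <- simulate_natural(n = 500, params = p, max_age = 30, seed = 1)
#' fit <- fit_siler(ages)
#' fit$par
#' @export
fit_siler <- function(sample, rm = 0, init = NULL, max_age = NULL,
                      objective = c("multinomial", "leastsquares"),
                      restarts = 10, seed = 1) {
  objective <- match.arg(objective)
  ages <- floor(as.numeric(sample))
  if (!length(ages)) stop("no ages")
  if (any(ages < 0)) stop("invalid age")
  if (is.null(max_age)) max_age <- max(ages)
  if (max_age < 1) stop("need at least two age classes")
  counts <- tabulate(ages + 1L, nbins = max_age + 1L)
  if (rm >= sum(counts > 0) || rm > max_age) stop("all ages removed")
  if (sum(counts[(rm + 1L):length(counts)]) == 0) stop("all ages removed")
  if (sum(counts > 0) < 2L) stop("degenerate sample: single age class")
  if (is.null(init)) init <- siler_params(0.1, 0.5, 0.05, 0.01, 0.1)
  init <- as_siler_params(init)
  fn <- if (objective == "multinomial") siler_nll else siler_lsq
  starts <- list(log(pmax(unclass(init), 1e-8)))
  if (restarts > 0) {
    jit <- with_substream(seed, "siler-restarts",
      replicate(restarts, starts[[1L]] + stats::rnorm(5, 0, 0.7),
                simplify = FALSE))
    starts <- c(starts, jit)
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, fn, counts = counts, rm = rm,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    # polish from the incumbent optimum
    o <- stats::optim(o$par, fn, counts = counts, rm = rm,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value >= 1e10)
    stop("Siler fit failed to find a finite objective")
  structure(list(par = as_siler_params(exp(best$par)),
                 objective = best$value, objective_type = objective,
                 rm = rm, max_age = max_age, counts = counts,
                 convergence = best$convergence),
            class = "siler_fit")
}

#' Predicted mortality schedule from a fitted Siler model
#'
#' @param object a `siler_fit`.
#' @param ages ages at which to predict (default `0:max_age` of the fit,
#'   including any classes removed from the objective).
#' @param ... unused.
#' @return a `mortality_schedule` data frame with hazard components
#'   (`juvenile`, `constant`, `senescent`, `total`) and the implied death
#'   probability `qx`.
#' @export
predict.siler_fit <- function(object, ages = NULL, ...) {
  if (is.null(ages)) ages <- 0:object$max_age
  sched <- siler_hazard(object$par, ages)
  sched$qx <- siler_qx(object$par, ages)
  sched
}

#' @export
print.siler_fit <- function(x, ...) {
  cat("Siler competing-risk mortality fit (", x$objective_type,
      " objective)\n", sep = "")
  print(round(unclass(x$par), 5))
  cat("objective:", format(x$objective), " removed leading classes:",
      x$rm, "\n")
  invisible(x)
}
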