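#' Synthetic stranding scenarios with known ground truth
#'
#' A scenario bundles everything needed to emulate an age-structured
#' stranding record: a Siler natural-mortality generator, the number of
#' natural strandings, a bycatch block (count, mean age, spread of a
#' truncated normal with mode before maturity), optional per-age retention
#' probabilities mimicking under-representation of the youngest carcasses,
#' and the oldest age class.  Defaults emulate a coastal bottlenose-dolphin
#' stranding record of 220 aged natural deaths plus 80 bycaught animals
#' centred at age 3.
#'
#' @param params natural-mortality generator ([siler_params]).
#' @param n_natural number of natural strandings.
#' @param n_bycatch number of bycaught animals.
#' @param bycatch_mean,bycatch_sd mean age (yr) and spread of the bycatch
#'   hump (`sd > 0`).
#' @param retention optional vector of per-age retention probabilities in
#'   `[0, 1]` (index 1 = age 0); ages beyond its length are fully retained.
#' @param max_age oldest age class.
#' @param seed master seed for all draws.
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(params = siler_params(0.25, 0.6, 0.01, 0.002, 0.18),
                          n_natural = 220, n_bycatch = 80,
                          bycatch_mean = 3, bycatch_sd = 1.5,
                          retention = NULL, max_age = 30, seed = 1) {
  if (n_natural < 0 || n_bycatch < 0) stop("counts must be non-negative")
  if (bycatch_sd <= 0) stop("bycatch_sd must be positive")
  if (!is.null(retention) && (any(retention < 0) || any(retention > 1)))
    stop("retention probabilities must lie in [0, 1]")
  if (max_age < 1) stop("max_age must be >= 1")
  structure(list(params = as_siler_params(params),
                 n_natural = n_natural, n_bycatch = n_bycatch,
                 bycatch_mean = bycatch_mean, bycatch_sd = bycatch_sd,
                 retention = retention, max_age = max_age, seed = seed),
            class = "scenario_spec")
}

#' Simulate natural strandings from a Siler age-at-death distribution
#'
#' Ages are drawn (seeded multinomial sampling) from the discrete
#' age-at-death distribution implied by the Siler survivorship.
#'
#' @param n number of deaths.
#' @param params generating [siler_params].
#' @param max_age oldest age class.
#' @param seed seed.
#' @return an [age_sample] with cause `"natural"`.
#' @export
simulate_natural <- function(n, params, max_age, seed = NULL) {
  if (n == 0) return(age_sample(numeric(0)))
  f <- siler_age_distribution(params, max_age)
  ages <- with_substream(seed, "simulate-natural",
                         sample(0:max_age, n, replace = TRUE, prob = f))
  age_sample(ages, cause = "natural")
}

#' Simulate bycaught animals with a normal age hump
#'
#' Ages are a truncated normal on `[0, max_age]` (inverse-CDF sampling)
#' rounded to integer age classes, matching the resolution of ages read
#' from tooth growth layers.
#'
#' @param n number of bycaught animals.
#' @param mean_age,sd hump centre (yr) and spread.
#' @param max_age oldest age class.
#' @param seed seed.
#' @return an [age_sample] with cause `"anthropogenic"`.
#' @export
simulate_bycatch <- function(n, mean_age = 3, sd = 1.5, max_age = 30,
                             seed = NULL) {
  if (n == 0) return(age_sample(numeric(0)))
  if (sd <= 0) stop("sd must be positive")
  plo <- stats::pnorm(0, mean_age, sd)
  phi <- stats::pnorm(max_age, mean_age, sd)
  u <- with_substream(seed, "simulate-bycatch", stats::runif(n, plo, phi))
  ages <- pmin(pmax(round(stats::qnorm(u, mean_age, sd)), 0), max_age)
  age_sample(ages, cause = "anthropogenic")
}

#' Thin young age classes to mimic carcass under-representation
#'
#' Each record of age `x` is kept independently with probability
#' `retention[x + 1]`; ages beyond the retention vector are always kept.
#'
#' @param sample an [age_sample].
#' @param retention per-age retention probabilities (index 1 = age 0).
#' @param seed seed.
#' @return the thinned [age_sample].
#' @export
thin_young <- function(sample, retention, seed = NULL) {
  if (any(retention < 0) || any(retention > 1))
    stop("retention probabilities must lie in [0, 1]")
  ages <- floor(as.numeric(sample))
  p <- ifelse(ages + 1L <= length(retention), retention[pmin(ages + 1L,
              length(retention))], 1)
  keep <- with_substream(seed, "thin-young",
                         stats::runif(length(ages)) < p)
  cause <- attr(sample, "cause")
  age_sample(as.numeric(sample)[keep],
             cause = if (!is.null(cause)) cause[keep] else NULL)
}

#' Simulate a full stranding scenario
#'
#' Natural deaths from the Siler generator plus a normally distributed
#' bycatch hump, optionally thinned at young ages.  Cause labels are
#' carried in the output for diagnostics but are not used by any estimator.
#'
#' @param spec a [scenario_spec].
#' @return an [age_sample] combining both causes.
#' @export
simulate_strandings <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  nat <- simulate_natural(spec$n_natural, spec$params, spec$max_age,
                          seed = spec$seed)
  by <- simulate_bycatch(spec$n_bycatch, spec$bycatch_mean, spec$bycatch_sd,
                         spec$max_age, seed = spec$seed)
  ages <- c(as.numeric(nat), as.numeric(by))
  cause <- c(rep("natural", length(nat)), rep("anthropogenic", length(by)))
  out <- age_sample(ages, cause = cause)
  if (!is.null(spec$retention))
    out <- thin_young(out, spec$retention, seed = spec$seed)
  out
}

#' True mortality schedule of a simulated scenario
#'
#' The exact death probability `q(x)` implied by the natural + bycatch
#' mixture a scenario generates (expected class frequencies, not a
#' realisation), for use as ground truth in recovery checks.  Thinning is
#' a sampling artefact and is deliberately not reflected: it biases the
#' observed record, not the underlying mortality.
#'
#' @param spec a [scenario_spec].
#' @return data frame with columns `age`, `f` (mixture age-at-death pmf)
#'   and `q` (true death probability).
#' @export
scenario_truth <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  x <- 0:spec$max_age
  f_nat <- siler_age_distribution(spec$params, spec$max_age)
  n_tot <- spec$n_natural + spec$n_bycatch
  if (spec$n_bycatch > 0) {
    breaks <- c(stats::pnorm(seq(-0.5, spec$max_age - 0.5),
                             spec$bycatch_mean, spec$bycatch_sd),
                stats::pnorm(spec$max_age, spec$bycatch_mean,
                             spec$bycatch_sd))
    lo <- stats::pnorm(0, spec$bycatch_mean, spec$bycatch_sd)
    f_by <- pmax(diff(pmax(breaks, lo)), 0)
    f_by <- f_by / sum(f_by)
  } else f_by <- rep(0, length(x))
  f <- (spec$n_natural * f_nat + spec$n_bycatch * f_by) / n_tot
  S <- rev(cumsum(rev(f)))
  q <- ifelse(S > 0, f / S, 1)
  q[length(q)] <- 1
  data.frame(age = x, f = f, q = q)
}
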