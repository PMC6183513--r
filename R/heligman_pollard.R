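#' Adapted Heligman-Pollard (aHP) parameters
#'
#' The classical Heligman-Pollard model expresses the probability of dying
#' at age `x` as three additive components: a rapidly declining infant
#' curve `A^((x+B)^C)`, a lognormal "accident hump"
#' `D exp(-E (ln(x/F))^2)` and a logistic adult rise `G H^x / (1 + G H^x)`.
#' The adapted model adds a ninth parameter `I` that lifts the hump's
#' baseline, so that accident (here: bycatch) mortality need not vanish at
#' age 0.
#'
#' @param A infant-mortality level (probability scale, `< 1`).
#' @param B age shift of the infant decline (yr).
#' @param C rate of decline of infant mortality.
#' @param D hump severity.
#' @param E hump spread (inverse-width of the lognormal bump).
#' @param F hump location (yr, `> 0`).
#' @param G base level of adult mortality.
#' @param H rate of increase of adult mortality (typically `>= 1`).
#' @param I hump baseline offset (probability).
#' @return named numeric vector of class `ahp_params`.
#' @export
ahp_params <- function(A, B, C, D, E, F, G, H, I) {
  p <- c(A = A, B = B, C = C, D = D, E = E, F = F, G = G, H = H, I = I)
  if (anyNA(p) || any(!is.finite(p))) stop("aHP parameters must be finite")
  if (any(p[c("A", "B", "C", "D", "E", "G", "I")] < 0))
    stop("aHP parameters A, B, C, D, E, G, I must be non-negative")
  if (p["A"] >= 1) stop("A must be < 1")
  if (p["F"] <= 0) stop("F must be > 0")
  if (p["H"] < 0) stop("H must be non-negative")
  class(p) <- c("ahp_params", "numeric")
  p
}

#' Names of the free parameters of the mortality curves
#'
#' The adapted Heligman-Pollard model has nine free parameters, the
#' unadapted Heligman-Pollard eight, the Siler model five.
#'
#' @return character vector of parameter names.
#' @export
ahp_parameter_names <- function() c("A", "B", "C", "D", "E", "F", "G", "H", "I")

#' @rdname ahp_parameter_names
#' @export
hp_parameter_names <- function() c("A", "B", "C", "D", "E", "F", "G", "H")

#' @rdname ahp_parameter_names
#' @export
siler_parameter_names <- function() c("a1", "b1", "a2", "a3", "b3")

as_ahp_params <- function(p) {
  if (inherits(p, "ahp_params")) return(p)
  p <- as.numeric(p)
  if (length(p) != 9L) stop("expected 9 aHP parameters")
  do.call(ahp_params, as.list(p))
}

# raw component evaluation; hump evaluated at `x + hump_offset`
ahp_components <- function(p, x, hump_offset = 0) {
  xh <- x + hump_offset
  if (any(xh <= 0) && (p["D"] > 0 || p["I"] > 0))
    stop("hump term needs positive ages; use a positive hump offset for age 0")
  juvenile <- unname(p["A"]^((x + p["B"])^p["C"]))
  hump <- if (p["D"] > 0 || p["I"] > 0)
    unname(p["I"] + p["D"] * exp(-p["E"] * log(xh / p["F"])^2))
  else rep(0, length(x))
  gh <- unname(p["G"] * p["H"]^x)
  adult <- gh / (1 + gh)
  list(juvenile = juvenile, hump = hump, adult = adult)
}

#' Death probability under the adapted Heligman-Pollard model
#'
#' Evaluates `q(x) = A^((x+B)^C) + [I + D exp(-E (ln(x/F))^2)] +
#' G H^x / (1 + G H^x)`.  During fitting and class-level prediction the
#' hump term is evaluated at the class midpoint `x + 0.5` (see
#' `hump_offset`) so that the logarithm is defined at age class 0 — the
#' point of the `I` parameter is precisely that bycatch at age 0 need not
#' be zero.
#'
#' @param p [ahp_params] or length-9 vector.
#' @param ages ages (years); must be positive where the hump term is active
#'   unless `hump_offset > 0`.
#' @param hump_offset added to the age inside the hump term only (default 0:
#'   evaluate at the ages given, so the hump component equals `I + D`
#'   exactly at `x = F`).
#' @return a `mortality_schedule` data frame (kind `"probability"`) with
#'   columns `age`, `juvenile`, `hump`, `adult`, `total`.  Components are
#'   reported unclamped; `total` is their sum clamped to `[0, 1]`.  An
#'   unclamped total above 1 flags an invalid parameter vector; direct
#'   calls raise an error.
#' @export
ahp_qx <- function(p, ages, hump_offset = 0) {
  p <- as_ahp_params(p)
  x <- as.numeric(ages)
  if (any(x < 0)) stop("negative age")
  cm <- ahp_components(p, x, hump_offset)
  total <- cm$juvenile + cm$hump + cm$adult
  if (any(total > 1))
    stop("invalid aHP parameters: q(x) > 1 at age ",
         x[which(total > 1)[1L]])
  out <- data.frame(age = x, juvenile = cm$juvenile, hump = cm$hump,
                    adult = cm$adult, total = pmin(pmax(total, 0), 1))
  structure(out, kind = "probability",
            class = c("mortality_schedule", "data.frame"))
}

#' Death probability under the unadapted eight-parameter model
#'
#' The classical Heligman-Pollard curve: identical to [ahp_qx] with the
#' hump baseline `I` fixed at 0.
#'
#' @inheritParams ahp_qx
#' @param p length-8 vector (A..H).
#' @return as [ahp_qx].
#' @export
hp_qx <- function(p, ages, hump_offset = 0) {
  p <- as.numeric(p)
  if (length(p) != 8L) stop("expected 8 HP parameters")
  ahp_qx(c(p, 0), ages, hump_offset)
}

#' Decompose aHP mortality into natural and anthropogenic parts
#'
#' Natural mortality is the sum of the infant and adult terms; the
#' anthropogenic (bycatch) component is the accident hump including its
#' baseline offset.  With a posterior sample, the pointwise posterior
#' median of each component is returned.
#'
#' @param p an [ahp_params] vector or an `ahp_posterior` (see [fit_ahp]).
#' @param ages ages at which to evaluate.
#' @param hump_offset see [ahp_qx]; posterior objects default to the offset
#'   used in fitting.
#' @return data frame with columns `age`, `natural`, `anthropogenic`,
#'   `total` (their sum).
#' @export
ahp_decompose <- function(p, ages, hump_offset = NULL) {
  if (inherits(p, "ahp_posterior")) {
    if (is.null(hump_offset)) hump_offset <- p$hump_offset
    draws <- p$samples
    nat <- ant <- matrix(0, nrow(draws), length(ages))
    for (i in seq_len(nrow(draws))) {
      cm <- ahp_components(as_ahp_params(draws[i, ]), as.numeric(ages),
                           hump_offset)
      nat[i, ] <- cm$juvenile + cm$adult
      ant[i, ] <- cm$hump
    }
    natural <- apply(nat, 2, stats::median)
    anthropogenic <- apply(ant, 2, stats::median)
  } else {
    if (is.null(hump_offset)) hump_offset <- 0
    cm <- ahp_components(as_ahp_params(p), as.numeric(ages), hump_offset)
    natural <- cm$juvenile + cm$adult
    anthropogenic <- cm$hump
  }
  data.frame(age = as.numeric(ages), natural = natural,
             anthropogenic = anthropogenic,
             total = natural + anthropogenic)
}

#' Deaths and numbers at risk per age class
#'
#' The data object of the aHP likelihood: for every age class `x`, the
#' observed deaths `M(x)` and the number at risk `S(x)` obtained from the
#' cumulative survival of the observed cohort (everyone dying at age `>= x`
#' was at risk at `x`).
#'
#' @param sample an [age_sample] or numeric ages at death.
#' @return data frame with columns `x`, `M`, `S`.
#' @export
deaths_at_age <- function(sample) {
  lt <- life_table(sample)
  n <- rev(cumsum(rev(lt$N)))
  data.frame(x = lt$x, M = lt$N, S = n)
}

#' Binomial log-likelihood of an aHP parameter vector
#'
#' Deaths given numbers at risk per age class, binomial with the model
#' `q(x)`: `sum_x [M(x) ln q(x) + (S(x) - M(x)) ln(1 - q(x))]` (binomial
#' coefficients dropped).  Parameter vectors whose `q(x)` leaves `(0, 1)`
#' at any required age score `-Inf` rather than raising, so the fitter can
#' discard them.
#'
#' When the table is cohort-closed (everyone still at risk at the oldest
#' class dies there, `M = S`), that terminal class is open-ended — the
#' model probability of eventual death is 1 regardless of the parameters —
#' so it carries no information about the one-year `q` and is excluded
#' from the sum.  Tables whose last class has survivors are used in full.
#'
#' @param p [ahp_params] or length-9 vector.
#' @param data a data frame from [deaths_at_age].
#' @param hump_offset hump-term age offset; class-midpoint 0.5 by default.
#' @return log-likelihood (scalar, possibly `-Inf`).
#' @export
ahp_loglik <- function(p, data, hump_offset = 0.5) {
  p <- try(as_ahp_params(p), silent = TRUE)
  if (inherits(p, "try-error")) return(-Inf)
  n <- nrow(data)
  if (n > 1L && data$M[n] == data$S[n]) data <- data[-n, , drop = FALSE]
  cm <- try(ahp_components(p, data$x, hump_offset), silent = TRUE)
  if (inherits(cm, "try-error")) return(-Inf)
  q <- cm$juvenile + cm$hump + cm$adult
  if (any(!is.finite(q)) || any(q <= 0 | q >= 1)) return(-Inf)
  sum(data$M * log(q) + (data$S - data$M) * log(1 - q))
}
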