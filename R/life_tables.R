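#' Cohort life table from ages at death
#'
#' Builds a regular cohort life table from a sample of ages at death.  Ages
#' are binned to integer classes by truncation (ages from growth-layer counts
#' are reported in whole years) spanning 0 to the oldest observed age.
#'
#' Columns, for age class `x`:
#' \describe{
#'   \item{N}{observed deaths in the class}
#'   \item{S}{number alive at the start of the class, scaled to the radix}
#'   \item{l}{survivorship proportion, `l(0) = 1`}
#'   \item{d}{proportion dying in the class, `d(x) = l(x) - l(x+1)`}
#'   \item{q}{probability of death in `[x, x+1)`; 1 at the oldest class}
#'   \item{e}{remaining life expectancy (years), with person-years
#'     `L(x) = (l(x) + l(x+1))/2` (deaths at mid-interval)}
#' }
#' The radix is cosmetic: it scales `S` only.
#'
#' @param sample an [age_sample] or numeric vector of ages at death.
#' @param radix notional starting cohort size (default 1000).
#' @return a `data.frame` of class `life_table`.
#' @examples
#' life_table(c(0, 0, 1, 2, 2, 5))
#' @export
life_table <- function(sample, radix = 1000) {
  ages <- as.numeric(sample)
  if (!length(ages)) stop("no ages")
  if (any(ages < 0)) stop("invalid age: ages must be non-negative")
  if (radix <= 0) stop("radix must be positive")
  x <- 0:max(floor(ages))
  N <- tabulate(floor(ages) + 1L, nbins = length(x))
  life_table_from_counts(x, N, radix)
}

# shared column arithmetic given deaths-per-class counts (or proportions)
life_table_from_counts <- function(x, N, radix) {
  S <- rev(cumsum(rev(N)))
  l <- S / S[1L]
  q <- ifelse(S > 0, N / S, 1)
  q[length(q)] <- 1
  l_next <- c(l[-1L], 0)
  d <- l - l_next
  L <- (l + l_next) / 2
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)
  out <- data.frame(x = x, N = N, S = radix * l, l = l, d = d, q = q, e = e)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Life table from a death-probability schedule
#'
#' Builds the life table implied by a `q(x)` schedule (e.g. from a fitted
#' Siler or Heligman-Pollard model) rather than from observed deaths.  The
#' survivorship recursion is `l(0) = 1`, `l(x+1) = l(x)(1 - q(x))`; a
#' terminal class with `q = 1` is appended when the schedule does not end in
#' 1, so that the cohort closes.
#'
#' @param q vector of death probabilities over ages `0..omega`, each in
#'   `[0, 1]`.
#' @param radix notional starting cohort size.
#' @return a `data.frame` of class `life_table`; `N` holds the expected
#'   deaths per class at the radix.
#' @export
life_table_from_qx <- function(q, radix = 1000) {
  q <- as.numeric(q)
  if (!length(q)) stop("no ages")
  if (anyNA(q) || any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (q[length(q)] < 1) q <- c(q, 1)
  l <- cumulative_survival(q)
  d <- l - c(l[-1L], 0)
  out <- life_table_from_counts(seq_along(q) - 1L, d, radix)
  out$N <- radix * d
  out
}

#' Cumulative survival from a death-probability schedule
#'
#' The bare survivorship recursion `l(0) = 1`, `l(x+1) = l(x)(1 - q(x))`,
#' exposed for Leslie-matrix construction.
#'
#' @param q death probabilities over ages `0..omega`.
#' @return survivorship `l(x)` for `x = 0..omega` (same length as `q`).
#' @examples
#' cumulative_survival(rep(0.1, 3))  # 1, 0.9, 0.81
#' @export
cumulative_survival <- function(q) {
  q <- as.numeric(q)
  if (!length(q)) stop("no ages")
  if (anyNA(q) || any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  cumprod(c(1, 1 - q[-length(q)]))
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat("Cohort life table over ages 0-", max(x$x), " (", sum(x$N),
      " deaths)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write a life table to CSV
#' @param lt a `life_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
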