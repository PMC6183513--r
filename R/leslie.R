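#' Build a Leslie projection matrix
#'
#' Constructs the female-based projection matrix from a death-probability
#' schedule and a maternity schedule.  The top row holds fertilities
#' (female offspring per female per year), the subdiagonal the survival
#' probabilities; all other entries are zero.
#'
#' The fertility convention is a post-breeding birth-pulse census: calves
#' are born at the end of a time unit to mothers counted at the end of the
#' previous interval, so `F_i = P_i * sex_ratio * m[i+1]` with
#' `P_i = 1 - q(i)`, and the last-class fertility is 0.  Only female
#' offspring are counted (`sex_ratio` is the proportion of female births).
#'
#' @param q death probabilities per age class, each in `[0, 1]`.
#' @param m maternity schedule (calves per female per year), same length.
#' @param sex_ratio proportion of births that are female (default 0.5).
#' @return an `(omega+1) x (omega+1)` matrix of class `leslie_matrix`.
#' @examples
#' leslie_matrix(q = c(0.5, 1), m = c(0, 4))   # [[1, 0], [0.5, 0]]
#' @export
leslie_matrix <- function(q, m, sex_ratio = 0.5) {
  q <- as.numeric(q); m <- as.numeric(m)
  if (length(q) != length(m)) stop("q and m must have equal length")
  if (anyNA(q) || any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (anyNA(m) || any(m < 0)) stop("m must be non-negative")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]")
  n <- length(q)
  P <- 1 - q
  A <- matrix(0, n, n)
  if (n > 1) {
    A[cbind(2:n, 1:(n - 1))] <- P[1:(n - 1)]
    A[1, 1:(n - 1)] <- P[1:(n - 1)] * sex_ratio * m[2:n]
  }
  dimnames(A) <- list(paste0("age", 0:(n - 1)), paste0("age", 0:(n - 1)))
  class(A) <- c("leslie_matrix", "matrix", "array")
  A
}

#' @export
print.leslie_matrix <- function(x, digits = 4, ...) {
  cat("Leslie projection matrix (", nrow(x), " age classes)\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Project a population with a Leslie matrix
#'
#' Iterates `N(t+1) = A N(t)` from an initial abundance-by-age vector.  The
#' default 100-year horizon is a commonly used long-term window; other
#' criteria (e.g. three generation times) can be passed instead.
#'
#' @param A a [leslie_matrix] (or any square non-negative matrix).
#' @param n0 non-negative initial abundance by age, length `nrow(A)`.
#' @param years number of annual steps (default 100).
#' @return a `(years+1) x (omega+1)` trajectory matrix; row 1 is `n0`,
#'   rownames give the year.
#' @export
leslie_project <- function(A, n0, years = 100) {
  A <- unclass(A)
  n0 <- as.numeric(n0)
  if (length(n0) != nrow(A)) stop("n0 length must match matrix order")
  if (any(n0 < 0)) stop("n0 must be non-negative")
  out <- matrix(0, years + 1L, nrow(A))
  out[1L, ] <- n0
  for (t in seq_len(years)) out[t + 1L, ] <- A %*% out[t, ]
  dimnames(out) <- list(year = 0:years, colnames(A))
  out
}

# drop trailing age classes that are both unreachable (zero survival into
# them) and sterile; they make the matrix reducible without affecting the
# dominant root
trim_leslie <- function(A) {
  n <- nrow(A)
  keep <- n
  while (keep > 1L && A[1L, keep] == 0 && A[keep, keep - 1L] == 0)
    keep <- keep - 1L
  keep
}

#' Demographic eigen-analysis of a Leslie matrix
#'
#' Computes the population parameters implied by a projection matrix:
#' the annual multiplicative growth `lambda` (dominant eigenvalue, Perron
#' root) and `r = ln(lambda)`; the stable age distribution (right
#' eigenvector, normalised to sum to 1); age-specific reproductive values
#' (left eigenvector, scaled so the age-0 value is 1); sensitivity
#' (`s_ij = v_i w_j / <v, w>`) and elasticity (`e_ij = a_ij s_ij / lambda`)
#' matrices; the net production `R0 = sum_x l(x) F_x` (female calves per
#' average female lifetime, `l` from cumulative survival with `l(0) = 1`);
#' and the generation time `T = ln(R0)/ln(lambda)`, falling back to the
#' cohort formula `sum_x x l(x) F_x / R0` when `lambda = 1`.
#'
#' Trailing age classes with zero fertility that no individual can reach
#' are trimmed before the eigen-decomposition (they make the matrix
#' reducible); the reported vectors are padded back with zeros.
#'
#' @param A a [leslie_matrix].
#' @return an object of class `demographic_stats`: list with `lambda`, `r`,
#'   `stable_age`, `repro_value`, `sensitivity`, `elasticity`, `R0`,
#'   `generation_time`.
#' @export
eigen_analysis <- function(A) {
  A0 <- unclass(A)
  n0 <- nrow(A0)
  keep <- trim_leslie(A0)
  A <- A0[seq_len(keep), seq_len(keep), drop = FALSE]
  ev <- eigen(A)
  mod <- Mod(ev$values)
  cand <- which(mod >= max(mod) * (1 - 1e-9))
  i <- cand[which.max(Re(ev$values[cand]))]
  lambda <- ev$values[i]
  if (abs(Im(lambda)) > 1e-9 * max(1, Mod(lambda)))
    stop("no Perron root: dominant eigenvalue is complex")
  lambda <- Re(lambda)
  if (lambda < 0) stop("no Perron root: dominant eigenvalue negative")
  Fx <- A[1L, ]
  P <- if (keep > 1L) c(A[cbind(2:keep, 1:(keep - 1L))]) else numeric(0)
  l <- cumprod(c(1, P))
  R0 <- sum(l * Fx)
  if (lambda <= .Machine$double.eps) {
    # sterile population: nilpotent projection, everything dies out
    pad <- function(x) c(x, rep(0, n0 - keep))
    return(structure(list(lambda = 0, r = -Inf,
                          stable_age = rep(NA_real_, n0),
                          repro_value = rep(NA_real_, n0),
                          sensitivity = matrix(NA_real_, n0, n0),
                          elasticity = matrix(NA_real_, n0, n0),
                          R0 = R0, generation_time = NA_real_),
                     class = "demographic_stats"))
  }
  w <- Re(ev$vectors[, i])
  if (sum(w) < 0) w <- -w
  w <- w / sum(w)
  evl <- eigen(t(A))
  il <- which.min(Mod(evl$values - lambda))
  v <- Re(evl$vectors[, il])
  if (v[1L] != 0) v <- v / v[1L] else v <- v / max(abs(v))
  vw <- sum(v * w)
  sens <- outer(v, w) / vw
  elas <- (A / lambda) * sens
  Tg <- if (abs(lambda - 1) > 1e-9 && R0 > 0) log(R0) / log(lambda)
        else if (R0 > 0) sum((0:(keep - 1L)) * l * Fx) / R0
        else NA_real_
  pad <- function(x) c(x, rep(0, n0 - keep))
  padm <- function(M) {
    out <- matrix(0, n0, n0)
    out[seq_len(keep), seq_len(keep)] <- M
    out
  }
  structure(list(lambda = lambda, r = log(lambda),
                 stable_age = pad(w), repro_value = pad(v),
                 sensitivity = padm(sens), elasticity = padm(elas),
                 R0 = R0, generation_time = Tg),
            class = "demographic_stats")
}

#' @export
print.demographic_stats <- function(x, ...) {
  cat("Demographic parameters\n")
  cat(sprintf("  lambda (annual growth): %.6f  (r = %+.6f)\n",
              x$lambda, x$r))
  cat(sprintf("  net production R0:      %.6f female calves/female\n", x$R0))
  cat(sprintf("  generation time:        %.3f yr\n", x$generation_time))
  invisible(x)
}
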