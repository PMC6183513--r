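#' Observed ages at death from stranded animals
#'
#' An `age_sample` is the raw abstraction of a stranding record: one
#' non-negative age at death per animal, optionally labelled with a cause of
#' death (`"natural"`, `"anthropogenic"` or `"unknown"`).  Cause labels are
#' carried for diagnostics only; none of the estimators uses them (the point
#' of the method is to work without cause-resolved data).
#'
#' @param ages numeric vector of non-negative, finite ages at death (years).
#' @param cause optional character vector of per-record cause flags, recycled
#'   if length 1.
#' @return an object of class `age_sample`: the numeric age vector with an
#'   optional `cause` attribute.
#' @examples
#' age_sample(c(0, 1, 1, 4, 12))
#' @export
age_sample <- function(ages, cause = NULL) {
  ages <- as.numeric(ages)
  if (anyNA(ages) || any(!is.finite(ages))) stop("ages must be finite")
  if (any(ages < 0)) stop("invalid age: ages must be non-negative")
  if (!is.null(cause)) {
    cause <- as.character(cause)
    if (length(cause) == 1L) cause <- rep(cause, length(ages))
    if (length(cause) != length(ages))
      stop("cause must have one entry per age")
    bad <- setdiff(unique(cause), c("natural", "anthropogenic", "unknown"))
    if (length(bad))
      stop("unknown cause label(s): ", paste(bad, collapse = ", "))
    attr(ages, "cause") <- cause
  }
  class(ages) <- c("age_sample", class(ages))
  ages
}

#' @export
print.age_sample <- function(x, ...) {
  cat("Ages at death:", length(x), "records,",
      "range", min(x), "-", max(x), "years\n")
  cs <- attr(x, "cause")
  if (!is.null(cs)) print(table(cause = cs))
  invisible(x)
}

#' Read an age-at-death table from CSV
#'
#' The file must have a header with an `age` column; optional `frequency`
#' (default 1) and `cause` columns are honoured.  Frequencies are expanded
#' into individual records.
#'
#' @param path path to a comma-separated, UTF-8, '.'-decimal CSV file.
#' @return an [age_sample].
#' @export
read_age_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"age" %in% names(tab)) stop("missing column: age")
  if (nrow(tab) == 0L) stop("no ages")
  age <- suppressWarnings(as.numeric(tab$age))
  if (anyNA(age))
    stop("non-numeric age at row ", which(is.na(age))[1L])
  freq <- if ("frequency" %in% names(tab)) {
    f <- suppressWarnings(as.numeric(tab$frequency))
    if (anyNA(f) || any(f < 0))
      stop("invalid frequency at row ",
           which(is.na(f) | f < 0)[1L])
    f
  } else rep(1, nrow(tab))
  idx <- rep(seq_len(nrow(tab)), times = round(freq))
  if (!length(idx)) stop("no ages")
  cause <- if ("cause" %in% names(tab)) tab$cause[idx] else NULL
  age_sample(age[idx], cause = cause)
}

#' Write an age sample to CSV as one row per age class
#'
#' @param sample an [age_sample].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_age_table <- function(sample, path) {
  cause <- attr(sample, "cause")
  if (is.null(cause)) {
    tab <- as.data.frame(table(age = floor(as.numeric(sample))),
                         stringsAsFactors = FALSE)
    names(tab) <- c("age", "frequency")
  } else {
    tab <- as.data.frame(table(age = floor(as.numeric(sample)), cause = cause),
                         stringsAsFactors = FALSE)
    names(tab) <- c("age", "cause", "frequency")
    tab <- tab[tab$frequency > 0, , drop = FALSE]
  }
  tab$age <- as.numeric(tab$age)
  tab <- tab[order(tab$age), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
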