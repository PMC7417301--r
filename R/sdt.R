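# Signal-detection-theory evaluation of a binary classification result.
# "Elite" is the signal class: a hit is an elite athlete classified elite
# (sensitivity), a correct rejection is a novice classified novice
# (specificity).

#' Confusion rates for an elite/novice classification
#'
#' @param predictions Predicted labels (`"elite"` / `"novice"`).
#' @param labels True labels; both classes must be present.
#' @return A list: `hit`, `miss`, `fa`, `cr` (rates in \[0, 1\] with
#'   `hit + miss = 1` and `fa + cr = 1`), `n_elite`, `n_novice`.
#' @export
confusion_rates <- function(predictions, labels) {
  pred <- as.character(predictions)
  truth <- as.character(labels)
  stopifnot(length(pred) == length(truth))
  n_elite <- sum(truth == "elite")
  n_novice <- sum(truth == "novice")
  if (n_elite == 0L || n_novice == 0L)
    stop("both classes must be present in the true labels")
  hit <- sum(pred == "elite" & truth == "elite") / n_elite
  fa <- sum(pred == "elite" & truth == "novice") / n_novice
  list(hit = hit, miss = 1 - hit, fa = fa, cr = 1 - fa,
       n_elite = n_elite, n_novice = n_novice)
}

# extreme rates make the z-transform infinite; the standard log-linear
# correction replaces 0 with 1/(2N) and 1 with 1 - 1/(2N) of the relevant
# class count, and the result is flagged, never silent
.correct_rate <- function(rate, n) {
  if (rate <= 0) 1 / (2 * n) else if (rate >= 1) 1 - 1 / (2 * n) else rate
}

.check_rate <- function(rate, what) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop(what, " must be a rate in [0, 1]")
}

.z_rates <- function(hit, fa, n_elite, n_novice, correction) {
  .check_rate(hit, "hit"); .check_rate(fa, "fa")
  corrected <- FALSE
  if (hit %in% c(0, 1) || fa %in% c(0, 1)) {
    if (!correction)
      stop("hit/fa rate of exactly 0 or 1; enable the extreme-rate ",
           "correction or provide interior rates")
    if ((hit %in% c(0, 1) && is.null(n_elite)) ||
        (fa %in% c(0, 1) && is.null(n_novice)))
      stop("class counts are required to correct extreme rates")
    hit <- .correct_rate(hit, n_elite)
    fa <- .correct_rate(fa, n_novice)
    corrected <- TRUE
  }
  list(zh = qnorm(hit), zf = qnorm(fa), corrected = corrected)
}

#' Sensitivity index d-prime
#'
#' `z(hit) - z(fa)` with `z` the inverse standard-normal CDF: the distance
#' between the elite and novice decision-variable distributions in standard
#' deviation units. 0 is chance; larger is more separable.
#'
#' @param hit,fa Hit and false-alarm rates in \[0, 1\].
#' @param n_elite,n_novice Class counts, needed only when a rate is exactly
#'   0 or 1 and the correction kicks in.
#' @param correction Apply the 1/(2N) extreme-rate correction (default
#'   TRUE).
#' @return d-prime (numeric scalar).
#' @export
d_prime <- function(hit, fa, n_elite = NULL, n_novice = NULL,
                    correction = TRUE) {
  z <- .z_rates(hit, fa, n_elite, n_novice, correction)
  z$zh - z$zf
}

#' Response criterion C
#'
#' `-(z(hit) + z(fa)) / 2`. Negative values mean a liberal strategy (the
#' framework over-calls elite), positive values a conservative one; 0 is
#' the ideal observer.
#'
#' @inheritParams d_prime
#' @return Criterion C (numeric scalar).
#' @export
criterion_c <- function(hit, fa, n_elite = NULL, n_novice = NULL,
                        correction = TRUE) {
  z <- .z_rates(hit, fa, n_elite, n_novice, correction)
  -(z$zh + z$zf) / 2
}

#' Full signal-detection summary of a classification result
#'
#' @param predictions Predicted labels, or a `cv_result` (in which case
#'   `labels` is taken from it).
#' @param labels True labels.
#' @param correction Apply the extreme-rate correction (default TRUE).
#' @return An object of class `sdt_metrics`: `hit`, `miss`, `fa`, `cr`,
#'   `d_prime`, `c`, `n_elite`, `n_novice`, `corrected`.
#' @export
sdt_metrics <- function(predictions, labels = NULL, correction = TRUE) {
  if (inherits(predictions, "cv_result")) {
    labels <- predictions$labels
    predictions <- predictions$predictions
  }
  r <- confusion_rates(predictions, labels)
  z <- .z_rates(r$hit, r$fa, r$n_elite, r$n_novice, correction)
  structure(list(hit = r$hit, miss = r$miss, fa = r$fa, cr = r$cr,
                 d_prime = z$zh - z$zf, c = -(z$zh + z$zf) / 2,
                 n_elite = r$n_elite, n_novice = r$n_novice,
                 corrected = z$corrected),
            class = "sdt_metrics")
}

#' @exportS3Method base::print
print.sdt_metrics <- function(x, ...) {
  cat(sprintf(paste0("<sdt_metrics> hit %.2f miss %.2f FA %.2f CR %.2f | ",
                     "d' = %.2f, C = %.2f%s\n"),
              x$hit, x$miss, x$fa, x$cr, x$d_prime, x$c,
              if (x$corrected) " (extreme-rate corrected)" else ""))
  invisible(x)
}
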