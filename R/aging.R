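#' Kaplan-Meier survival curve of a worm cohort
#'
#' Product-limit estimate of the fraction of worms alive by day, computed
#' with the `survival` package. With no censoring this equals the simple
#' fraction-alive-by-day recount. The curve starts at 1.0 and is
#' non-increasing.
#'
#' @param records Data frame with columns `worm_id`, `death_day` (integer
#'   >= 1) and optionally `censored` (logical; censored worms contribute
#'   observation time but no death).
#' @return A `survival_curve`: list with `days` (ordered observed days)
#'   and `fraction_alive`.
#' @export
survival_curve <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no survival records")
  if (!all(c("worm_id", "death_day") %in% names(records)))
    stop("records need worm_id and death_day columns")
  if (any(records$death_day < 1)) stop("death_day must be >= 1")
  cens <- if ("censored" %in% names(records)) records$censored else
    rep(FALSE, nrow(records))
  fit <- survival::survfit(
    survival::Surv(records$death_day, !cens) ~ 1)
  structure(list(days = as.integer(fit$time), fraction_alive = fit$surv,
                 n = nrow(records)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve over %d worms, days %d..%d\n", x$n,
              min(x$days), max(x$days)))
  print(data.frame(day = x$days, fraction_alive = round(x$fraction_alive, 4)))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$days, c(1, x$fraction_alive)),
                 do.points = FALSE, xlab = "day", ylab = "fraction alive",
                 main = "cohort survival", ylim = c(0, 1), ...)
  invisible(x)
}

#' Elderly age threshold from a survival curve
#'
#' The chronological age separating elderly from non-elderly worms: the
#' smallest observed day at which cohort survival has fallen to at most
#' `fraction` (default the 20% survival threshold).
#'
#' @param curve A [survival_curve()].
#' @param fraction Survival fraction defining old age, default 0.20.
#' @return The threshold day (integer).
#' @export
elderly_age_threshold <- function(curve, fraction = 0.20) {
  stopifnot(inherits(curve, "survival_curve"))
  hit <- which(curve$fraction_alive <= fraction)
  if (length(hit) == 0L)
    stop(sprintf(paste("survival never falls to %.0f%%; cannot derive an",
                       "elderly threshold (min observed survival %.1f%%)"),
                 100 * fraction, 100 * min(curve$fraction_alive)))
  as.integer(curve$days[hit[1]])
}

#' Label worms as elderly
#'
#' A worm observation counts as elderly when its chronological age is at
#' or beyond the survival-derived threshold (inclusive).
#'
#' @param age_days Numeric age(s) in days.
#' @param threshold Threshold day from [elderly_age_threshold()].
#' @return Logical vector.
#' @export
label_elderly <- function(age_days, threshold) {
  age_days >= threshold
}

#' Healthy Aging Index report
#'
#' Joins per-observation predicted biological ages (the HAI) with
#' chronological ages, reporting both the HAI itself and its deviation
#' from chronological age, plus the elderly flag at the survival-derived
#' threshold. Rows must be matched: both inputs carry `worm_id` and must
#' agree row by row.
#'
#' @param predictions Data frame with `worm_id` and `predicted_age_days`.
#' @param chronological_ages Data frame with `worm_id` and `age_days`,
#'   same row order.
#' @param threshold Elderly threshold day.
#' @return A `hai_report` data frame with columns `worm_id`, `hai`,
#'   `chronological_age`, `deviation` (`hai - chronological_age`) and
#'   `elderly_by_threshold`.
#' @export
hai_report <- function(predictions, chronological_ages, threshold) {
  if (nrow(predictions) != nrow(chronological_ages))
    stop("predictions and ages differ in length")
  if (!identical(as.character(predictions$worm_id),
                 as.character(chronological_ages$worm_id)))
    stop("worm ids do not match between predictions and ages")
  out <- data.frame(
    worm_id = predictions$worm_id,
    hai = predictions$predicted_age_days,
    chronological_age = chronological_ages$age_days,
    stringsAsFactors = FALSE)
  out$deviation <- out$hai - out$chronological_age
  out$elderly_by_threshold <- label_elderly(out$chronological_age, threshold)
  class(out) <- c("hai_report", "data.frame")
  out
}

#' @export
summary.hai_report <- function(object, ...) {
  cat(sprintf("HAI report: %d observations, %d worms\n", nrow(object),
              length(unique(object$worm_id))))
  cat(sprintf("  mean HAI %.2f d, mean deviation %+.2f d, %.0f%% elderly\n",
              mean(object$hai), mean(object$deviation),
              100 * mean(object$elderly_by_threshold)))
  invisible(object)
}
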