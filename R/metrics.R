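#' Proportion of detected errors
#'
#' An error counts as "detected" when the observer's post-choice confidence
#' in it falls below 0.5 — i.e. the observer believes the unchosen option
#' was more likely correct. The first-order model can never detect an error
#' (its confidence is bounded below by 0.5); the postdecisional and
#' second-order models can.
#'
#' @param trials A `trial_table` with at least one error trial.
#' @return Fraction of error trials with `z_post < 0.5`.
#' @export
error_detection_rate <- function(trials) {
  err <- !trials$correct
  if (!any(err))
    stop("error-detection rate undefined: no error trials", call. = FALSE)
  mean(trials$z_post[err] < 0.5)
}

#' Calibration curve: accuracy conditional on stated confidence
#'
#' Bins trials by post-choice confidence into `n_levels` equal-width levels
#' on `[0, 1]` and reports, per level, the mean stated confidence and the
#' achieved proportion correct. A correctly specified Bayesian observer
#' (beliefs equal to the generative parameters) is calibrated: the curve
#' lies on the identity line up to binomial noise. Mismatched belief
#' hyperparameters bend it into systematic over- or underconfidence.
#'
#' @param trials A `trial_table`.
#' @param n_levels Number of equal-width confidence levels (>= 2).
#' @return A data frame with one row per level: `level`, `lower`, `upper`,
#'   `mean_confidence`, `prop_correct`, `count`. Empty levels have count 0
#'   and `NA` accuracy.
#' @export
calibration_curve <- function(trials, n_levels = 10L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("`n_levels` must be at least 2", call. = FALSE)
  br <- seq(0, 1, length.out = n_levels + 1)
  lev <- findInterval(trials$z_post, br, rightmost.closed = TRUE)
  lev <- pmin(pmax(lev, 1L), n_levels)
  out <- data.frame(
    level = seq_len(n_levels),
    lower = br[-(n_levels + 1)],
    upper = br[-1],
    mean_confidence = NA_real_,
    prop_correct = NA_real_,
    count = 0L
  )
  agg_n <- tabulate(lev, n_levels)
  out$count <- agg_n
  occ <- agg_n > 0
  out$mean_confidence[occ] <-
    vapply(which(occ), function(l) mean(trials$z_post[lev == l]), numeric(1))
  out$prop_correct[occ] <-
    vapply(which(occ), function(l) mean(trials$correct[lev == l]), numeric(1))
  out
}

#' Metacognitive bias and sensitivity summaries
#'
#' Bias is the overall mean confidence; sensitivity is the difference in
#' mean confidence between correct and error trials. These are the
#' summaries contrasted between choose-rate (rate after acting) and
#' rate-choose (rate before acting) designs.
#'
#' @param trials A `trial_table`.
#' @param column Which confidence column to summarize, `"z_post"` or
#'   `"z_pre"`.
#' @return Named numeric vector `c(bias, sensitivity)`; sensitivity is `NA`
#'   if only one accuracy class is present.
#' @export
bias_and_sensitivity <- function(trials, column = c("z_post", "z_pre")) {
  column <- match.arg(column)
  z <- trials[[column]]
  bias <- mean(z)
  sens <- if (any(trials$correct) && any(!trials$correct))
    mean(z[trials$correct]) - mean(z[!trials$correct])
  else NA_real_
  c(bias = bias, sensitivity = sens)
}
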