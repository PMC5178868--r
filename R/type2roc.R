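#' Type 2 ROC: confidence as a classifier of one's own accuracy
#'
#' Sweeping a criterion across the rating scale, plots the probability of
#' high confidence given a correct response (type 2 hit rate) against the
#' probability of high confidence given an error (type 2 false-alarm rate).
#' The area under the curve (trapezoid rule) summarizes metacognitive
#' sensitivity: 0.5 is chance, 1 perfect discrimination of one's own errors.
#' The area is invariant to any strictly monotone transform of confidence.
#'
#' @param trials A `trial_table` containing at least one correct and one
#'   error trial, with `z_post` on every record.
#' @param scheme A [rating_scheme()] controlling the criterion grid.
#' @return An object of class `"type2_roc"`: list with `hit_rates`,
#'   `fa_rates` (each including the (0,0) and (1,1) endpoints) and `area`.
#' @examples
#' tt <- simulate_trials(gen_params(rho = 0.6), n = 2000,
#'                       belief = belief_params("second_order", rho = 0.6),
#'                       seed = 1)
#' type2_roc(tt)$area
#' @export
type2_roc <- function(trials, scheme = rating_scheme(10)) {
  if (all(trials$correct) || all(!trials$correct))
    stop("type 2 ROC undefined: need both correct and error trials",
         call. = FALSE)
  miss <- which(is.na(trials$z_post))
  if (length(miss))
    stop("records missing z_post at rows: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  edges <- resolve_edges(scheme, trials$z_post)
  rating <- bin_ratings(trials$z_post, edges)
  k <- scheme$n_bins
  zc <- rating[trials$correct]
  ze <- rating[!trials$correct]
  # criterion "rating >= r" for r = K..2, plus fixed endpoints
  hr <- vapply(k:2, function(r) mean(zc >= r), numeric(1))
  fa <- vapply(k:2, function(r) mean(ze >= r), numeric(1))
  hr <- c(0, hr, 1)
  fa <- c(0, fa, 1)
  area <- sum(diff(fa) * (utils::head(hr, -1) + utils::tail(hr, -1)) / 2)
  structure(list(hit_rates = hr, fa_rates = fa, area = area,
                 n_correct = length(zc), n_error = length(ze)),
            class = "type2_roc")
}

#' @export
print.type2_roc <- function(x, ...) {
  cat(sprintf("Type 2 ROC: area = %.4f (%d correct, %d error trials)\n",
              x$area, x$n_correct, x$n_error))
  invisible(x)
}

#' @export
plot.type2_roc <- function(x, ...) {
  plot(x$fa_rates, x$hit_rates, type = "b", pch = 16,
       xlab = "P(high confidence | error)",
       ylab = "P(high confidence | correct)",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
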