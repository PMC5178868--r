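#' Rating scheme: discretization of continuous confidence
#'
#' Confidence in these models is a continuous probability in `[0, 1]`; ROC
#' and meta-d' analyses need ordered rating categories. A scheme either
#' fixes the cut points (`edges`) or asks for per-dataset empirical
#' quantiles (`method = "quantile"`, the default, which avoids the empty
#' rating cells that break the meta-d' likelihood).
#'
#' @param n_bins Number of rating categories, at least 2.
#' @param edges Optional strictly increasing interior cut points in `(0, 1)`
#'   of length `n_bins - 1`; overrides `method`.
#' @param method `"quantile"` (edges from the data at binning time) or
#'   `"equal"` (equal-width bins on `[0, 1]`).
#' @return An object of class `"rating_scheme"`.
#' @examples
#' rating_scheme(4)                       # quantile bins
#' rating_scheme(4, method = "equal")     # fixed-width bins
#' @export
rating_scheme <- function(n_bins = 4L, edges = NULL,
                          method = c("quantile", "equal")) {
  method <- match.arg(method)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be at least 2", call. = FALSE)
  if (!is.null(edges)) {
    if (length(edges) != n_bins - 1L)
      stop("`edges` must have length n_bins - 1", call. = FALSE)
    if (any(edges <= 0 | edges >= 1) || is.unsorted(edges, strictly = TRUE))
      stop("`edges` must be strictly increasing and inside (0, 1)",
           call. = FALSE)
    method <- "fixed"
  }
  structure(list(n_bins = n_bins, edges = edges, method = method),
            class = "rating_scheme")
}

resolve_edges <- function(scheme, z) {
  k <- scheme$n_bins
  if (!is.null(scheme$edges)) return(scheme$edges)
  if (scheme$method == "equal") return(seq(0, 1, length.out = k + 1)[-c(1, k + 1)])
  e <- unname(stats::quantile(z, probs = seq_len(k - 1) / k, type = 7))
  # Degenerate data can collapse quantiles; nudge into a valid partition.
  e <- pmin(pmax(e, 1e-9), 1 - 1e-9)
  if (is.unsorted(e, strictly = TRUE))
    e <- cummax(e + seq_along(e) * 1e-12)
  e
}

# Bin confidence into ratings 1..K: half-open [edge_i, edge_{i+1}),
# last bin closed at 1.
bin_ratings <- function(z, edges) {
  findInterval(z, c(0, edges, 1 + 1e-9), rightmost.closed = FALSE)
}

#' Rating counts by stimulus, response and confidence rating
#'
#' Cross-tabulates a trial table into the 2 (stimulus) x 2 (response) x K
#' (rating) counts that type 2 SDT analyses consume. Bin membership uses
#' half-open intervals `[edge_i, edge_{i+1})` with the top bin closed at 1.
#'
#' @param trials A `trial_table` with `z_post` on every record.
#' @param scheme A [rating_scheme()].
#' @return An object of class `"rating_counts"`: a list with `tab` (a
#'   `2 x 2 x K` array indexed by stimulus in `{-1, +1}`, response in
#'   `{-1, +1}` and rating `1..K`), the `edges` used and `n_bins`.
#' @export
discretize_confidence <- function(trials, scheme = rating_scheme(4)) {
  stopifnot(inherits(scheme, "rating_scheme"))
  miss <- which(is.na(trials$z_post))
  if (length(miss))
    stop("records missing z_post at rows: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) ", ..." else "", call. = FALSE)
  edges <- resolve_edges(scheme, trials$z_post)
  rating <- bin_ratings(trials$z_post, edges)
  k <- scheme$n_bins
  tab <- array(0L, dim = c(2, 2, k),
               dimnames = list(stimulus = c("-1", "1"),
                               response = c("-1", "1"),
                               rating = as.character(seq_len(k))))
  tab[] <- as.integer(table(factor(trials$d, c(-1, 1)),
                            factor(trials$a, c(-1, 1)),
                            factor(rating, seq_len(k))))
  structure(list(tab = tab, edges = edges, n_bins = k),
            class = "rating_counts")
}

#' @export
print.rating_counts <- function(x, ...) {
  cat(sprintf("Rating counts: %d trials, %d rating bins\n",
              sum(x$tab), x$n_bins))
  cat("  edges:", paste(signif(x$edges, 4), collapse = ", "), "\n")
  print(x$tab, ...)
  invisible(x)
}

#' @export
as.data.frame.rating_counts <- function(x, ...) {
  g <- expand.grid(stimulus = c(-1L, 1L), response = c(-1L, 1L),
                   rating = seq_len(x$n_bins))
  g$count <- as.vector(x$tab)
  g[order(g$stimulus, g$response, g$rating), c("stimulus", "response",
                                               "rating", "count")]
}
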