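#' Maximum-likelihood meta-d' fit
#'
#' Expresses metacognitive sensitivity in units of type 1 d' by fitting an
#' equal-variance Gaussian SDT model to the response-conditional rating
#' distributions (Maniscalco & Lau's meta-d'). The type 1 performance of the
#' hypothetical metacognitively-ideal observer is `meta_d`, its type 1
#' criterion is held at the empirically estimated *relative* criterion
#' (`c' = c / d'`, so the meta-level criterion is `meta_d * c'`), and the
#' `2 * (K - 1)` type 2 criteria are free, parameterized as ordered offsets
#' from the type 1 criterion. The likelihood is the multinomial probability
#' of each rating conditional on stimulus and response; only the type 2
#' structure is fit, so `meta_d = d'` for an observer whose confidence uses
#' exactly the evidence driving choice (ratio `meta_d / d' = 1`), values
#' below 1 indicate hypo- and above 1 hyper-metacognitive sensitivity.
#'
#' Every cell is padded with `1 / (2K)` before likelihood evaluation, which
#' regularizes empty ratings without noticeably biasing large samples.
#'
#' @param x A `"rating_counts"` object (see [discretize_confidence()]) or a
#'   `trial_table`.
#' @param padding Count added to every stimulus-response-rating cell;
#'   default `1 / (2 * n_bins)`.
#' @param ... Passed between methods; for the trial-table method, `scheme`
#'   (a [rating_scheme()], default 4 quantile bins).
#' @return An object of class `"metad_fit"` with components `d_prime`,
#'   `c` (type 1 criterion), `meta_d`, `meta_c`, `type2_criteria` (ordered),
#'   `nll`, `ratio` (`meta_d / d_prime`, `NA` when `d_prime` is 0),
#'   `se_meta_d`, `n`, `convergence`.
#' @examples
#' tt <- simulate_trials(gen_params(), n = 2000,
#'                       belief = belief_params("first_order"), seed = 1)
#' fit <- fit_meta_d(tt)
#' coef(fit)["ratio"]  # ~1 for a first-order (ideal) observer
#' @export
fit_meta_d <- function(x, ...) UseMethod("fit_meta_d")

#' @rdname fit_meta_d
#' @export
fit_meta_d.trial_table <- function(x, padding = NULL,
                                   scheme = rating_scheme(4), ...) {
  fit_meta_d(discretize_confidence(x, scheme), padding = padding)
}

#' @rdname fit_meta_d
#' @export
fit_meta_d.rating_counts <- function(x, padding = NULL, ...) {
  k <- x$n_bins
  if (is.null(padding)) padding <- 1 / (2 * k)
  tab <- x$tab + padding
  if (all(x$tab == 0))
    stop("degenerate data: all rating cells are zero", call. = FALSE)

  # Type 1 SDT from padded counts: HR = P(a=+1 | d=+1), FA = P(a=+1 | d=-1)
  n_s2 <- sum(tab["1", , ]); n_s1 <- sum(tab["-1", , ])
  hr <- sum(tab["1", "1", ]) / n_s2
  fa <- sum(tab["-1", "1", ]) / n_s1
  d_prime <- stats::qnorm(hr) - stats::qnorm(fa)
  c1 <- -(stats::qnorm(hr) + stats::qnorm(fa)) / 2
  cprime <- if (abs(d_prime) > 1e-8) c1 / d_prime else 0

  # counts n[stim, resp, rating]
  nll_fun <- function(par) {
    meta_d <- par[1]
    t1c <- cprime * meta_d
    up <- t1c + cumsum(exp(par[2:k]))              # criteria above, resp +1
    lo <- t1c - cumsum(exp(par[(k + 1):(2 * k - 1)]))  # below, resp -1
    nll <- 0
    for (s in 1:2) {
      mu <- c(-1, 1)[s] * meta_d / 2
      # response +1: bins (t1c, up1), (up1, up2), ..., (up_{K-1}, Inf)
      bounds_u <- c(t1c, up, Inf)
      p_u <- diff(stats::pnorm(bounds_u - mu))
      p_u <- p_u / sum(p_u)
      # response -1: ratings 1..K at bins (lo1, t1c), ..., (-Inf, lo_{K-1})
      bounds_l <- c(t1c, lo, -Inf)
      p_l <- -diff(stats::pnorm(bounds_l - mu))
      p_l <- p_l / sum(p_l)
      nll <- nll - sum(tab[s, 2, ] * log(pmax(p_u, 1e-300))) -
        sum(tab[s, 1, ] * log(pmax(p_l, 1e-300)))
    }
    nll
  }

  # start: meta_d at d', criteria spread from pooled conditional quantiles
  start_off <- function(p_ge) {
    # p_ge: observed P(rating >= r | response) for r = 2..K
    q <- stats::qnorm(pmin(pmax(p_ge, 1e-4), 1 - 1e-4))
    inc <- diff(c(0, -q))           # distances from criterion, increasing
    log(pmax(inc, 0.05))
  }
  cnt_u <- apply(tab[, 2, , drop = FALSE], 3, sum)
  cnt_l <- apply(tab[, 1, , drop = FALSE], 3, sum)
  p_ge_u <- rev(cumsum(rev(cnt_u)))[-1] / sum(cnt_u)
  p_ge_l <- rev(cumsum(rev(cnt_l)))[-1] / sum(cnt_l)
  par0 <- c(d_prime, start_off(p_ge_u), start_off(p_ge_l))

  opt <- stats::optim(par0, nll_fun, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0)
    stop(sprintf("meta-d' optimizer failed to converge (code %d): %s",
                 opt$convergence, opt$message %||% ""), call. = FALSE)
  meta_d <- opt$par[1]
  t1c <- cprime * meta_d
  up <- t1c + cumsum(exp(opt$par[2:k]))
  lo <- t1c - cumsum(exp(opt$par[(k + 1):(2 * k - 1)]))
  se <- tryCatch({
    v <- diag(solve(opt$hessian))[1]
    if (is.finite(v) && v > 0) sqrt(v) else NA_real_
  }, error = function(e) NA_real_)

  structure(list(
    d_prime = unname(d_prime), c = unname(c1), meta_d = unname(meta_d),
    meta_c = unname(t1c),
    type2_criteria = unname(c(rev(lo), t1c, up)), nll = unname(opt$value),
    ratio = if (abs(d_prime) > 1e-8) unname(meta_d / d_prime) else NA_real_,
    se_meta_d = unname(se), n = sum(x$tab), n_bins = k,
    convergence = opt$convergence
  ), class = "metad_fit")
}

#' @export
print.metad_fit <- function(x, ...) {
  cat("Meta-d' fit (response-conditional ML, equal-variance SDT)\n")
  cat(sprintf("  d' = %.4f   c = %.4f   meta-d' = %.4f   meta-d'/d' = %s\n",
              x$d_prime, x$c, x$meta_d,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio)))
  cat(sprintf("  nll = %.2f on %d trials, %d rating bins\n",
              x$nll, x$n, x$n_bins))
  invisible(x)
}

#' @export
summary.metad_fit <- function(object, ...) {
  print(object)
  cat("  type 2 criteria (ordered):",
      paste(sprintf("%.3f", object$type2_criteria), collapse = ", "), "\n")
  cat(sprintf("  SE(meta-d') = %s\n",
              if (is.na(object$se_meta_d)) "NA"
              else sprintf("%.4f", object$se_meta_d)))
  invisible(object)
}

#' @export
coef.metad_fit <- function(object, ...) {
  c(d_prime = object$d_prime, c = object$c, meta_d = object$meta_d,
    ratio = object$ratio)
}

#' @export
logLik.metad_fit <- function(object, ...) {
  val <- -object$nll
  attr(val, "df") <- 1 + 2 * (object$n_bins - 1)
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}
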