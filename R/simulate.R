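#' Draw paired internal samples from the generative model
#'
#' Samples `n` pairs `(x_act, x_conf)` conditional on a world state: each is
#' a draw from the bivariate Gaussian with mean `(d*theta, d*theta)`,
#' standard deviations `(sigma_act, sigma_conf)` and correlation `rho`.
#'
#' @param params A [gen_params()] object (with a scalar `theta`).
#' @param d World state, `-1` or `+1`.
#' @param n Number of pairs, at least 1.
#' @param seed Integer seed; the draw is reproducible given it.
#' @return A data frame with columns `x_act` and `x_conf`.
#' @examples
#' s <- sample_internal_states(gen_params(rho = 0.6), d = 1, n = 5, seed = 1)
#' @export
sample_internal_states <- function(params, d, n, seed) {
  stopifnot(inherits(params, "gen_params"))
  if (!d %in% c(-1, 1)) stop("`d` must be -1 or +1", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1", call. = FALSE)
  theta <- params$theta
  if (inherits(theta, "theta_prior"))
    stop("`params$theta` must be a fixed value here", call. = FALSE)
  set.seed(child_seed(seed, 1L))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  mu <- d * theta
  data.frame(
    x_act  = mu + params$sigma_act * z1,
    x_conf = mu + params$sigma_conf *
      (params$rho * z1 + sqrt(1 - params$rho^2) * z2)
  )
}

#' Decision rule
#'
#' The observer responds "right" (`+1`) when the decision variable exceeds
#' zero and "left" (`-1`) otherwise; a sample of exactly zero maps to `-1`.
#'
#' @param x_act Finite numeric vector of decision-variable samples.
#' @return Integer vector of actions in `{-1, +1}`.
#' @examples
#' decide(c(0.05, 0, -2.3))
#' @export
decide <- function(x_act) {
  if (any(!is.finite(x_act))) stop("`x_act` must be finite", call. = FALSE)
  ifelse(x_act > 0, 1L, -1L)
}

#' Simulate a table of decision + confidence trials
#'
#' On each trial the world state `d` is drawn equiprobably from `{-1, +1}`
#' (flat prior), the stimulus strength from `theta` (fixed value or
#' [theta_prior()] schedule), internal states from the bivariate generative
#' model, the action from [decide()], and confidence from the observer model
#' in `belief`. The generative coupling follows the observer model class:
#' first-order sets `x_conf = x_act`; postdecisional adds an extra
#' independent evidence sample `x_new ~ N(d*theta, sigma_act^2)` so that
#' `x_conf = x_act + x_new`; second-order draws the correlated pair.
#'
#' Both post-choice confidence (`z_post`, conditioned on the overt action)
#' and pre-choice confidence (`z_pre`, rating the covert `sign(x_conf)`
#' response; see [prechoice_confidence()]) are recorded.
#'
#' @param params A [gen_params()] object; its `theta` (or the `theta`
#'   argument, which overrides it) is the per-trial stimulus schedule.
#' @param n Number of trials.
#' @param belief A [belief_params()] object; its `model` selects the
#'   confidence computation and the generative coupling. A `NULL`
#'   `belief$theta` inherits the simulation schedule (a fixed value stays
#'   fixed; a schedule prior is marginalized over).
#' @param theta Optional override of the stimulus schedule.
#' @param seed Integer root seed; stages (world state = 1, stimulus = 2,
#'   internal noise = 3) use child seeds derived from it.
#' @return A `trial_table`: a data frame with columns
#'   `trial, d, theta, x_act, x_conf, x_new, a, z_pre, z_post, correct`.
#' @examples
#' tt <- simulate_trials(gen_params(rho = 0.6), n = 100,
#'                       belief = belief_params("second_order", rho = 0.6),
#'                       seed = 42)
#' mean(tt$correct)
#' @export
simulate_trials <- function(params, n, belief, theta = NULL, seed = 1L) {
  stopifnot(inherits(params, "gen_params"), inherits(belief, "belief_params"))
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1", call. = FALSE)
  n <- as.integer(n)
  schedule <- if (is.null(theta)) params$theta else theta
  if (inherits(schedule, "theta_prior") && length(schedule$values) == 0L)
    stop("empty theta schedule", call. = FALSE)

  set.seed(child_seed(seed, 1L))
  d <- sample(c(-1L, 1L), n, replace = TRUE)

  set.seed(child_seed(seed, 2L))
  th <- if (inherits(schedule, "theta_prior")) {
    sample(schedule$values, n, replace = TRUE, prob = schedule$weights)
  } else rep(schedule, n)

  set.seed(child_seed(seed, 3L))
  z1 <- stats::rnorm(n)
  mu <- d * th
  x_act <- mu + params$sigma_act * z1
  x_new <- rep(NA_real_, n)
  if (belief$model == "first_order") {
    x_conf <- x_act
  } else if (belief$model == "postdecisional") {
    x_new <- mu + params$sigma_act * stats::rnorm(n)
    x_conf <- x_act + x_new
  } else {
    z2 <- stats::rnorm(n)
    x_conf <- mu + params$sigma_conf *
      (params$rho * z1 + sqrt(1 - params$rho^2) * z2)
  }

  a <- decide(x_act)

  # The observer's theta: explicit beliefs win; otherwise inherit schedule.
  btheta <- if (!is.null(belief$theta)) belief$theta else schedule
  z_post <- confidence(x_conf, a, belief, theta = btheta)
  z_pre <- prechoice_confidence(x_conf, belief, theta = btheta)

  tt <- data.frame(
    trial = seq_len(n), d = d, theta = th, x_act = x_act, x_conf = x_conf,
    x_new = x_new, a = a, z_pre = z_pre, z_post = z_post,
    correct = a == d
  )
  class(tt) <- c("trial_table", "data.frame")
  attr(tt, "model") <- belief$model
  tt
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials%s\n", nrow(x),
              if (!is.null(attr(x, "model")))
                sprintf(" [%s model]", attr(x, "model")) else ""))
  cat(sprintf("  proportion correct = %.4f, mean confidence = %.4f\n",
              mean(x$correct), mean(x$z_post)))
  err <- !x$correct
  if (any(err))
    cat(sprintf("  detected errors (z_post < 0.5 | error) = %.4f\n",
                mean(x$z_post[err] < 0.5)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more trials\n")
  invisible(x)
}

#' @export
summary.trial_table <- function(object, ...) {
  out <- list(
    n = nrow(object),
    model = attr(object, "model"),
    prop_correct = mean(object$correct),
    mean_confidence = mean(object$z_post),
    bias_sensitivity = bias_and_sensitivity(object),
    error_detection = if (any(!object$correct))
      error_detection_rate(object) else NA_real_
  )
  class(out) <- "summary.trial_table"
  out
}

#' @export
print.summary.trial_table <- function(x, ...) {
  cat(sprintf("Trial table summary (%d trials, %s model)\n", x$n,
              x$model %||% "unknown"))
  cat(sprintf("  proportion correct   %.4f\n", x$prop_correct))
  cat(sprintf("  mean confidence      %.4f\n", x$mean_confidence))
  cat(sprintf("  sensitivity (dz)     %.4f\n", x$bias_sensitivity[["sensitivity"]]))
  cat(sprintf("  error-detection rate %s\n",
              if (is.na(x$error_detection)) "n/a (no errors)"
              else sprintf("%.4f", x$error_detection)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
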