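#' Generative parameters of the internal-evidence process
#'
#' The decision variable `X_act` and the confidence variable `X_conf` are
#' modelled as one draw per trial from a bivariate Gaussian with mean
#' `(d*theta, d*theta)` (`d` the world state, `theta` the stimulus strength)
#' and covariance
#' \deqn{\Sigma = \begin{pmatrix} \sigma_{act}^2 & \rho\sigma_{act}\sigma_{conf} \\
#'   \rho\sigma_{act}\sigma_{conf} & \sigma_{conf}^2 \end{pmatrix}.}
#' `sigma_act` controls task performance, `sigma_conf` the fidelity of the
#' evidence available to the confidence judgement, and `rho` their coupling.
#'
#' @param sigma_act Positive standard deviation of the decision variable.
#' @param sigma_conf Positive standard deviation of the confidence variable.
#' @param rho Correlation between the two variables, in `[-1, 1]`.
#' @param theta Stimulus strength in `[0, 1]`; scales the sample mean.
#'   May also be a [theta_prior()] when used as a simulation schedule.
#' @return An object of class `"gen_params"`.
#' @examples
#' gen_params(sigma_act = 1, sigma_conf = 1, rho = 0.6, theta = 1)
#' @export
gen_params <- function(sigma_act = 1, sigma_conf = 1, rho = 0, theta = 1) {
  check_sigma(sigma_act, "sigma_act")
  check_sigma(sigma_conf, "sigma_conf")
  check_rho(rho)
  if (!inherits(theta, "theta_prior")) check_theta(theta)
  structure(
    list(sigma_act = sigma_act, sigma_conf = sigma_conf, rho = rho,
         theta = theta),
    class = "gen_params"
  )
}

#' Observer's belief (hyper)parameters
#'
#' The parameters the observer assumes when inverting the generative model to
#' compute confidence. They have the same fields as [gen_params()] but need
#' not equal the true generative values: mismatches produce systematic over-
#' or underconfidence. `model` selects which confidence computation the
#' observer applies.
#'
#' @param model One of `"first_order"`, `"postdecisional"`, `"second_order"`.
#'   First-order: confidence from the same variable that drives the choice
#'   (never below 0.5). Postdecisional: the decision sample plus one extra
#'   independent evidence sample. Second-order: infer the likely decision
#'   variable from `X_conf`, the observed action and the assumed covariance.
#' @param theta Believed stimulus strength: a scalar, a [theta_prior()] to
#'   marginalize over, or `NULL` to inherit the simulation's schedule.
#' @inheritParams gen_params
#' @return An object of class `"belief_params"`.
#' @export
belief_params <- function(model = c("second_order", "first_order", "postdecisional"),
                          sigma_act = 1, sigma_conf = 1, rho = 0,
                          theta = NULL) {
  model <- match.arg(model)
  check_sigma(sigma_act, "sigma_act")
  check_sigma(sigma_conf, "sigma_conf")
  check_rho(rho)
  if (!is.null(theta) && !inherits(theta, "theta_prior")) check_theta(theta)
  structure(
    list(model = model, sigma_act = sigma_act, sigma_conf = sigma_conf,
         rho = rho, theta = theta),
    class = "belief_params"
  )
}

#' Discrete prior over stimulus strength
#'
#' When the observer does not know the trial's stimulus strength, confidence
#' marginalizes the evidence likelihood over a discrete prior on `theta`.
#' The same object doubles as a per-trial sampling schedule in
#' [simulate_trials()].
#'
#' @param values Strictly increasing stimulus strengths in `[0, 1]`.
#' @param weights Nonnegative weights summing to 1; defaults to uniform.
#' @return An object of class `"theta_prior"`.
#' @examples
#' theta_prior(seq(0, 1, length.out = 20))
#' @export
theta_prior <- function(values, weights = NULL) {
  if (length(values) < 1L || any(!is.finite(values)))
    stop("`values` must be a non-empty vector of finite stimulus strengths",
         call. = FALSE)
  if (any(values < 0 | values > 1))
    stop("theta values must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE))
    stop("theta values must be strictly increasing", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(values), length(values))
  if (length(weights) != length(values) || any(weights < 0))
    stop("`weights` must be nonnegative and match `values` in length",
         call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("`weights` must sum to 1 (tolerance 1e-12)", call. = FALSE)
  structure(list(values = as.numeric(values), weights = as.numeric(weights)),
            class = "theta_prior")
}

#' @export
print.gen_params <- function(x, ...) {
  cat("Generative parameters (bivariate-Gaussian evidence)\n")
  cat(sprintf("  sigma_act = %g, sigma_conf = %g, rho = %g\n",
              x$sigma_act, x$sigma_conf, x$rho))
  cat("  theta:", format_theta(x$theta), "\n")
  invisible(x)
}

#' @export
print.belief_params <- function(x, ...) {
  cat(sprintf("Belief parameters [%s model]\n", x$model))
  cat(sprintf("  sigma_act = %g, sigma_conf = %g, rho = %g\n",
              x$sigma_act, x$sigma_conf, x$rho))
  cat("  theta:",
      if (is.null(x$theta)) "(inherit simulation schedule)"
      else format_theta(x$theta), "\n")
  invisible(x)
}

#' @export
print.theta_prior <- function(x, ...) {
  cat(sprintf("Discrete prior over stimulus strength (%d support points)\n",
              length(x$values)))
  cat("  values: ", paste(signif(utils::head(x$values, 6), 4), collapse = ", "),
      if (length(x$values) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

format_theta <- function(theta) {
  if (inherits(theta, "theta_prior"))
    sprintf("prior over %d values in [%g, %g]", length(theta$values),
            min(theta$values), max(theta$values))
  else sprintf("%g (fixed)", theta)
}

check_sigma <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(TRUE)
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < -1 || rho > 1)
    stop("`rho` must be a single number in [-1, 1]", call. = FALSE)
  invisible(TRUE)
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0 || theta > 1)
    stop("`theta` must be a single number in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

# Resolve a theta argument to (values, weights) for marginalization.
theta_support <- function(theta) {
  if (inherits(theta, "theta_prior"))
    list(values = theta$values, weights = theta$weights)
  else
    list(values = theta, weights = 1)
}
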