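#' Confidence posteriors of the three observer models
#'
#' Confidence is the posterior probability that the taken action matched the
#' world state, `z = P(a = d | evidence, beliefs)`, with a flat prior on
#' `d` in `{-1, +1}`. The three models differ in what "evidence" is:
#'
#' * **first-order** — the confidence variable is the decision variable
#'   itself (`X_conf = X_act`, likelihood `N(d*theta, sigma_act^2)`). Since
#'   the action is the sign of the same sample, confidence never falls below
#'   0.5: the model cannot see itself in error.
#' * **postdecisional** — the confidence variable is the decision sample plus
#'   one extra independent sample, `X_conf = X_act + X_new`, with likelihood
#'   `N(2*d*theta, 2*sigma_act^2)`. When the summed evidence contradicts the
#'   action, confidence drops below 0.5 (error detection).
#' * **second-order** — the observer treats the decision system as a coupled
#'   actor: given `X_conf` it infers the likely decision variable (via the
#'   assumed covariance) and conditions on the observed action,
#'   `z = P(a = d | X_conf, a, Sigma)`. For each `d` the posterior weight is
#'   the Gaussian likelihood `N(X_conf; d*theta, sigma_conf^2)` times
#'   `P(a | X_conf, d) = Phi(a * mu_c / sigma_c)` with conditional mean
#'   `mu_c = d*theta + rho*(sigma_act/sigma_conf)*(X_conf - d*theta)` and
#'   conditional SD `sigma_c = sigma_act*sqrt(1 - rho^2)`. With `rho = 1`
#'   and `sigma_act = sigma_conf` this reduces exactly to the first-order
#'   model; the degenerate `sigma_c = 0` case is handled as the analytic
#'   step-function limit, never a division by zero.
#'
#' When the observer does not know the trial's stimulus strength, likelihoods
#' are mixed over a [theta_prior()] before normalizing. All computation is in
#' log space with log-sum-exp normalization, so extreme samples (|x_conf|
#' many SDs out) do not underflow.
#'
#' @param x_conf Numeric vector of confidence-variable values.
#' @param a Action(s) in `{-1, +1}`; scalar or vector matching `x_conf`.
#' @param belief A [belief_params()] object supplying the assumed parameters.
#' @param theta Believed stimulus strength (scalar or [theta_prior()]);
#'   defaults to `belief$theta`.
#' @return Numeric vector of confidence values in `[0, 1]`.
#' @examples
#' b <- belief_params("second_order", sigma_act = 1, sigma_conf = 1, rho = 0.6)
#' second_order_confidence(0, a = 1, b, theta = 1)  # ~0.69 despite x_conf = 0
#' first_order_confidence(1, a = 1, belief_params("first_order"), theta = 1)
#' @name confidence_models
NULL

#' Evaluate confidence under the model selected by `belief`
#'
#' Dispatches to [first_order_confidence()], [postdecisional_confidence()] or
#' [second_order_confidence()] according to `belief$model`.
#'
#' @inheritParams confidence_models
#' @return Numeric vector of confidence values in `[0, 1]`.
#' @export
confidence <- function(x_conf, a, belief, theta = NULL) {
  switch(belief$model,
    first_order    = first_order_confidence(x_conf, a, belief, theta),
    postdecisional = postdecisional_confidence(x_conf, a, belief, theta),
    second_order   = second_order_confidence(x_conf, a, belief, theta)
  )
}

#' @rdname confidence_models
#' @export
first_order_confidence <- function(x_conf, a, belief, theta = NULL) {
  q <- check_query(x_conf, a, belief, theta)
  posterior_z(q, function(x, a, d, th)
    stats::dnorm(x, d * th, belief$sigma_act, log = TRUE))
}

#' @rdname confidence_models
#' @export
postdecisional_confidence <- function(x_conf, a, belief, theta = NULL) {
  q <- check_query(x_conf, a, belief, theta)
  # x_conf is the sum of two independent N(d*theta, sigma^2) samples
  posterior_z(q, function(x, a, d, th)
    stats::dnorm(x, 2 * d * th, sqrt(2) * belief$sigma_act, log = TRUE))
}

#' @rdname confidence_models
#' @export
second_order_confidence <- function(x_conf, a, belief, theta = NULL) {
  q <- check_query(x_conf, a, belief, theta)
  sa <- belief$sigma_act; sc <- belief$sigma_conf; rho <- belief$rho
  s_c <- sa * sqrt(max(0, 1 - rho^2))
  posterior_z(q, function(x, a, d, th) {
    mu <- d * th
    mu_c <- mu + rho * (sa / sc) * (x - mu)
    stats::dnorm(x, mu, sc, log = TRUE) + log_phi(a * mu_c, s_c)
  })
}

#' Pre-choice confidence
#'
#' Confidence elicited before the overt action (the rate-choose design):
#' the observer frames the response consistent with the confidence evidence
#' — the covert choice `sign(x_conf)` — and evaluates the model's posterior
#' that this response matches the world state. The overt action (driven by
#' `x_act`, which the rater cannot see) plays no role.
#'
#' In the first-order model the overt action *is* `sign(x_conf)`, so
#' pre- and post-choice confidence coincide trial by trial. In the
#' second-order model they dissociate exactly on the trials where the
#' decision and confidence variables disagree: post-choice ratings there
#' condition on an action at odds with `x_conf` and drop below 0.5, while
#' pre-choice ratings stay on the `x_conf`-consistent side. Averaged over
#' trials this yields the two signatures of action-informed confidence:
#' post-choice bias (mean confidence) is lower, and post-choice
#' sensitivity (correct-error separation) is higher, than pre-choice.
#'
#' @inheritParams confidence_models
#' @return Numeric vector of confidence values in `[0, 1]`; at least 0.5
#'   whenever `rho * sigma_act / sigma_conf <= 1` (everywhere, for the
#'   first-order and postdecisional models).
#' @export
prechoice_confidence <- function(x_conf, belief, theta = NULL) {
  a_hyp <- ifelse(x_conf >= 0, 1, -1)
  confidence(x_conf, a_hyp, belief, theta)
}

#' Monte-Carlo oracle for the second-order confidence posterior
#'
#' Brute-force check of the closed form: simulate trials from the true
#' generative process, keep those whose confidence variable lands within
#' `window` of `x_conf_target` and whose action equals `a`, and return the
#' fraction correct among them. As `window -> 0` and `n -> Inf` this
#' converges to `second_order_confidence(x_conf_target, a, ...)` when the
#' observer's beliefs equal the generative parameters. The oracle never
#' touches the closed-form code path: it only samples, applies the decision
#' rule and counts.
#'
#' @param params A [gen_params()] object with scalar `theta`.
#' @param x_conf_target Confidence-variable value at which to estimate.
#' @param window Half-width of the selection window (> 0).
#' @param a Conditioning action, `-1` or `+1`.
#' @param n Number of simulated trials (>= 1e5).
#' @param seed Integer seed.
#' @return A list with `estimate`, `se` (binomial standard error) and
#'   `n_selected`.
#' @export
mc_oracle_confidence <- function(params, x_conf_target, window, a,
                                 n = 1e6, seed = 1L) {
  stopifnot(inherits(params, "gen_params"))
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  if (n < 1e5) stop("`n` must be at least 1e5", call. = FALSE)
  if (!a %in% c(-1, 1)) stop("`a` must be -1 or +1", call. = FALSE)
  theta <- params$theta
  if (inherits(theta, "theta_prior"))
    stop("oracle requires a fixed theta", call. = FALSE)
  set.seed(child_seed(seed, 1L))
  n <- as.integer(n)
  d <- sample(c(-1L, 1L), n, replace = TRUE)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  mu <- d * theta
  x_act <- mu + params$sigma_act * z1
  x_conf <- mu + params$sigma_conf *
    (params$rho * z1 + sqrt(1 - params$rho^2) * z2)
  act <- ifelse(x_act > 0, 1L, -1L)
  sel <- abs(x_conf - x_conf_target) < window & act == a
  k <- sum(sel)
  if (k < 100)
    stop(sprintf("only %d trials selected; increase `n` or `window`", k),
         call. = FALSE)
  p <- mean(d[sel] == a)
  list(estimate = p, se = sqrt(p * (1 - p) / k), n_selected = k)
}

# ---- internals ------------------------------------------------------------

check_query <- function(x_conf, a, belief, theta) {
  if (!inherits(belief, "belief_params"))
    stop("`belief` must be a belief_params object", call. = FALSE)
  if (any(!is.finite(x_conf)))
    stop("`x_conf` must be finite", call. = FALSE)
  if (missing(a) || is.null(a) || any(is.na(a)))
    stop("an action is required; use prechoice_confidence() otherwise",
         call. = FALSE)
  if (!all(a %in% c(-1, 1)))
    stop("`a` must be -1 or +1", call. = FALSE)
  th <- theta %||% belief$theta
  if (is.null(th))
    stop("no believed theta available: supply `theta`", call. = FALSE)
  if (!inherits(th, "theta_prior") && length(th) != 1L)
    stop("`theta` must be a single value or a theta_prior", call. = FALSE)
  sup <- theta_support(th)
  n <- max(length(x_conf), length(a))
  list(x = rep_len(as.numeric(x_conf), n), a = rep_len(as.numeric(a), n),
       values = sup$values, weights = sup$weights)
}

# z = P(d = a | ...) from a per-component log-likelihood loglik(x, a, d, th),
# mixing over the theta support in log space (running log-sum-exp keeps
# memory at O(n) regardless of the prior's size).
posterior_z <- function(q, loglik) {
  mix_log <- function(d) {
    acc <- rep(-Inf, length(q$x))
    for (j in seq_along(q$values)) {
      comp <- log(q$weights[j]) + loglik(q$x, q$a, d, q$values[j])
      acc <- logaddexp(acc, comp)
    }
    acc
  }
  l_same <- mix_log(q$a)
  l_other <- mix_log(-q$a)
  stats::plogis(l_same - l_other)
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  out[a == -Inf & b == -Inf] <- -Inf
  out
}

# log Phi(m / s), with the analytic s -> 0 limit (step function in m).
# The zero branch uses a finite floor rather than -Inf so that when every
# mixture component is suppressed (action conditioned on a measure-zero
# event) the factors cancel in the posterior ratio instead of giving 0/0.
log_phi <- function(m, s) {
  if (s > 0) return(stats::pnorm(m / s, log.p = TRUE))
  ifelse(m > 0, 0, ifelse(m == 0, log(0.5), -700))
}
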