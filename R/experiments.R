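#' Simulation experiments
#'
#' Each experiment is a pure function from parameters + seed to tidy tables,
#' reproducing one of the framework's qualitative phenomena: the X-pattern,
#' the detected-error surface, action effects on confidence, type 2 ROC
#' sweeps, the meta-d'/d' sweep, and hyperparameter-driven miscalibration.
#' Re-running with the same arguments yields identical tables.
#'
#' @name experiments
NULL

#' Experiment specification
#'
#' A validated container for a config-driven experiment run, as consumed by
#' [run_experiment()] and the command-line `experiment` subcommand. Fields
#' other than `experiment_id`, `n_trials` and `seed` are passed through to
#' the experiment function.
#'
#' @param experiment_id One of `"x_pattern"`, `"error_surface"`,
#'   `"action_effect"`, `"roc_sweep"`, `"metad_sweep"`, `"miscalibration"`.
#' @param n_trials Trials per condition (>= 1000).
#' @param seed Integer root seed.
#' @param ... Experiment-specific overrides (grids, parameters).
#' @return An object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(experiment_id, n_trials = 1e5, seed = 1L, ...) {
  ids <- c("x_pattern", "error_surface", "action_effect", "roc_sweep",
           "metad_sweep", "miscalibration")
  if (!experiment_id %in% ids)
    stop("unknown experiment_id; must be one of: ",
         paste(ids, collapse = ", "), call. = FALSE)
  if (n_trials < 1000)
    stop("`n_trials` must be at least 1000 for stochastic experiments",
         call. = FALSE)
  structure(list(experiment_id = experiment_id, n_trials = n_trials,
                 seed = seed, args = list(...)),
            class = "experiment_spec")
}

#' Run an experiment from its specification
#'
#' @param spec An [experiment_spec()] (or a plain list with the same
#'   fields, e.g. parsed from a YAML config).
#' @return The experiment's result tables (a named list of data frames).
#' @export
run_experiment <- function(spec) {
  if (!inherits(spec, "experiment_spec"))
    spec <- do.call(experiment_spec, c(
      spec[c("experiment_id", "n_trials", "seed")][
        !vapply(spec[c("experiment_id", "n_trials", "seed")], is.null,
                logical(1))],
      spec$args %||% spec[setdiff(names(spec),
                                  c("experiment_id", "n_trials", "seed"))]))
  fn <- switch(spec$experiment_id,
    x_pattern      = run_x_pattern,
    error_surface  = run_error_surface,
    action_effect  = run_action_effect,
    roc_sweep      = run_roc_sweep,
    metad_sweep    = run_metad_sweep,
    miscalibration = run_miscalibration)
  do.call(fn, c(list(n = spec$n_trials, seed = spec$seed), spec$args))
}

#' X-pattern: confidence vs stimulus strength and vs internal state
#'
#' Simulates all three observer models on *shared* internal samples drawn
#' over a grid of stimulus strengths, with the observer marginalizing over a
#' uniform prior on that grid (the subject does not know the trial's theta).
#' Mean confidence is tabulated (a) against objective stimulus strength,
#' split by accuracy — every model shows the behavioral X-pattern: rising
#' with theta on correct trials, falling on errors — and (b) against the
#' internal confidence variable in equal-count bins, where the first-order
#' model stays monotone in |x_conf| but the postdecisional and second-order
#' models split by accuracy.
#'
#' @param n Trials (shared across models).
#' @param seed Integer seed.
#' @param sigma_act,sigma_conf,rho Generative (= believed) parameters of the
#'   second-order model; the first-order and postdecisional models use
#'   `sigma_act`.
#' @param theta_grid Stimulus-strength grid; also the observer's prior
#'   support. A maximum below 0.5 triggers a warning (error-branch means
#'   become unstable without high-strength trials).
#' @param state_bins Number of equal-count bins of `x_conf` for the
#'   internal-state table.
#' @return List of data frames `by_theta` (model, theta, correct,
#'   mean_confidence, n) and `by_state` (model, bin, x_conf_mean, correct,
#'   mean_confidence, n).
#' @export
run_x_pattern <- function(n = 1e5, seed = 1L, sigma_act = 1, sigma_conf = 1,
                          rho = 0.6,
                          theta_grid = seq(0, 1, length.out = 20),
                          state_bins = 25L) {
  if (max(theta_grid) < 0.5)
    warning("theta grid has no high-strength points (max < 0.5); ",
            "error-branch means will be noisy")
  prior <- theta_prior(theta_grid)
  n <- as.integer(n)

  set.seed(child_seed(seed, 1L))
  d <- sample(c(-1L, 1L), n, replace = TRUE)
  set.seed(child_seed(seed, 2L))
  th <- sample(prior$values, n, replace = TRUE, prob = prior$weights)
  set.seed(child_seed(seed, 3L))
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z3 <- stats::rnorm(n)

  mu <- d * th
  x_act <- mu + sigma_act * z1
  a <- decide(x_act)
  correct <- a == d

  xc <- list(
    first_order    = x_act,
    postdecisional = x_act + (mu + sigma_act * z3),
    second_order   = mu + sigma_conf * (rho * z1 + sqrt(1 - rho^2) * z2)
  )
  beliefs <- list(
    first_order    = belief_params("first_order", sigma_act),
    postdecisional = belief_params("postdecisional", sigma_act),
    second_order   = belief_params("second_order", sigma_act, sigma_conf, rho)
  )

  by_theta <- list(); by_state <- list()
  for (m in names(xc)) {
    z <- confidence(xc[[m]], a, beliefs[[m]], theta = prior)
    agg <- stats::aggregate(z, list(theta = th, correct = correct), mean)
    cnt <- stats::aggregate(z, list(theta = th, correct = correct), length)
    by_theta[[m]] <- data.frame(model = m, theta = agg$theta,
                                correct = agg$correct,
                                mean_confidence = agg$x, n = cnt$x)
    qs <- stats::quantile(xc[[m]], probs = seq(0, 1, length.out = state_bins + 1))
    bin <- cut(xc[[m]], breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
    ag2 <- stats::aggregate(cbind(conf = z, x = xc[[m]]),
                            list(bin = bin, correct = correct), mean)
    cn2 <- stats::aggregate(z, list(bin = bin, correct = correct), length)
    by_state[[m]] <- data.frame(model = m, bin = ag2$bin,
                                x_conf_mean = ag2$x, correct = ag2$correct,
                                mean_confidence = ag2$conf, n = cn2$x)
  }
  list(by_theta = do.call(rbind, by_theta),
       by_state = do.call(rbind, by_state))
}

#' Detected-error surface over (sigma_conf, rho)
#'
#' At fixed task performance (`sigma_act = 1`, `theta = 1`, ~84% correct),
#' simulates the second-order model over a grid of confidence-noise and
#' coupling values and records the fraction of errors with confidence below
#' 0.5. Detection is highest at low `sigma_conf` and vanishes as `rho`
#' approaches 1 (the first-order limit).
#'
#' @param n Trials per grid cell.
#' @param seed Integer seed.
#' @param sigma_conf_grid,rho_grid Grid values (`rho` in `[0, 1)`).
#' @param sigma_act,theta Fixed performance parameters.
#' @return Data frame `(sigma_conf, rho, error_detection_rate, n_errors)`.
#' @export
run_error_surface <- function(n = 1e4, seed = 1L,
                              sigma_conf_grid = seq(0.25, 2.5, length.out = 10),
                              rho_grid = seq(0, 0.95, length.out = 10),
                              sigma_act = 1, theta = 1) {
  stopifnot(all(sigma_conf_grid > 0), all(rho_grid >= 0), all(rho_grid < 1))
  grid <- expand.grid(sigma_conf = sigma_conf_grid, rho = rho_grid)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- grid$sigma_conf[i]; r <- grid$rho[i]
    tt <- simulate_trials(
      gen_params(sigma_act, sc, r, theta), n = n,
      belief = belief_params("second_order", sigma_act, sc, r),
      seed = child_seed(seed, i))
    ne <- sum(!tt$correct)
    data.frame(sigma_conf = sc, rho = r,
               error_detection_rate = if (ne > 0) error_detection_rate(tt)
                                      else NA_real_,
               n_errors = ne)
  })
  do.call(rbind, out)
}

#' Action effects on confidence: choose-rate vs rate-choose
#'
#' On identical simulated trials, contrasts confidence rated after the
#' action (`z_post`, choose-rate) with confidence rated before it (`z_pre`,
#' rate-choose). For the second-order model the action is informative, so
#' post-choice ratings have lower mean (bias) and larger correct-error
#' separation (sensitivity); for the first-order control the two are
#' identical trial by trial.
#'
#' @param n Trials per parameter setting.
#' @param seed Integer seed.
#' @param sigma_act,theta Fixed parameters.
#' @param sigma_conf_grid Sweep of `sigma_conf` at `rho = rho_fixed`.
#' @param rho_grid Sweep of `rho` at `sigma_conf = sigma_conf_fixed`.
#' @param rho_fixed,sigma_conf_fixed Constants for the two sweeps.
#' @return Data frame with one row per (sweep, value, model, condition):
#'   columns `sweep`, `value`, `model`, `condition` (`choose_rate` /
#'   `rate_choose`), `bias`, `sensitivity`.
#' @export
run_action_effect <- function(n = 1e5, seed = 1L, sigma_act = 1, theta = 1,
                              sigma_conf_grid = c(0.75, 1, 1.5, 2),
                              rho_grid = c(0, 0.2, 0.4, 0.6, 0.8),
                              rho_fixed = 0.6, sigma_conf_fixed = 1) {
  settings <- rbind(
    data.frame(sweep = "sigma_conf", value = sigma_conf_grid,
               sigma_conf = sigma_conf_grid, rho = rho_fixed,
               model = "second_order"),
    data.frame(sweep = "rho", value = rho_grid,
               sigma_conf = sigma_conf_fixed, rho = rho_grid,
               model = "second_order"),
    data.frame(sweep = "first_order_control", value = NA_real_,
               sigma_conf = sigma_conf_fixed, rho = rho_fixed,
               model = "first_order")
  )
  out <- lapply(seq_len(nrow(settings)), function(i) {
    s <- settings[i, ]
    tt <- simulate_trials(
      gen_params(sigma_act, s$sigma_conf, s$rho, theta), n = n,
      belief = belief_params(s$model, sigma_act, s$sigma_conf, s$rho),
      seed = child_seed(seed, i))
    post <- bias_and_sensitivity(tt, "z_post")
    pre <- bias_and_sensitivity(tt, "z_pre")
    data.frame(sweep = s$sweep, value = s$value, model = s$model,
               condition = c("choose_rate", "rate_choose"),
               bias = c(post[["bias"]], pre[["bias"]]),
               sensitivity = c(post[["sensitivity"]], pre[["sensitivity"]]))
  })
  do.call(rbind, out)
}

#' Type 2 ROC area sweeps
#'
#' Sweeps `sigma_conf` (at fixed `rho`) and `rho` (at fixed `sigma_conf`)
#' with task performance held constant, recording the type 2 ROC area of
#' the second-order model at each setting. Area falls as either parameter
#' rises: noisier confidence evidence, or tighter coupling to the decision
#' variable, both erode the model's view of its own errors.
#'
#' @param n Trials per setting.
#' @param seed Integer seed.
#' @param sigma_conf_grid,rho_grid Sweep values.
#' @param rho_fixed,sigma_conf_fixed Constants for the two sweeps.
#' @param sigma_act,theta Fixed performance parameters.
#' @param scheme [rating_scheme()] for the ROC criteria.
#' @return Data frame `(sweep, value, area, n_correct, n_error)`.
#' @export
run_roc_sweep <- function(n = 1e5, seed = 1L,
                          sigma_conf_grid = c(0.5, 0.75, 1, 1.5, 2),
                          rho_grid = c(0, 0.25, 0.5, 0.75, 0.95),
                          rho_fixed = 0.5, sigma_conf_fixed = 1,
                          sigma_act = 1, theta = 1,
                          scheme = rating_scheme(10)) {
  settings <- rbind(
    data.frame(sweep = "sigma_conf", value = sigma_conf_grid,
               sigma_conf = sigma_conf_grid, rho = rho_fixed),
    data.frame(sweep = "rho", value = rho_grid,
               sigma_conf = sigma_conf_fixed, rho = rho_grid)
  )
  out <- lapply(seq_len(nrow(settings)), function(i) {
    s <- settings[i, ]
    tt <- simulate_trials(
      gen_params(sigma_act, s$sigma_conf, s$rho, theta), n = n,
      belief = belief_params("second_order", sigma_act, s$sigma_conf, s$rho),
      seed = child_seed(seed, i))
    roc <- type2_roc(tt, scheme)
    data.frame(sweep = s$sweep, value = s$value, area = roc$area,
               n_correct = roc$n_correct, n_error = roc$n_error)
  })
  do.call(rbind, out)
}

#' meta-d'/d' sweep over (sigma_act, sigma_conf) at rho = 0.5
#'
#' Simulates one dataset per point of a deterministic grid over
#' `(sigma_act, sigma_conf)`, fits meta-d' to each, and records the ratio
#' and the detected-error fraction. Hyper-metacognitive sensitivity
#' (`meta-d' > d'`) concentrates where `sigma_conf / sigma_act < 1`, and the
#' log-ratio associates positively with error detection.
#'
#' @param n Trials per dataset.
#' @param seed Integer seed.
#' @param sigma_grid Grid values used for both `sigma_act` and `sigma_conf`.
#' @param rho Coupling, fixed at 0.5.
#' @param theta Stimulus strength.
#' @param scheme [rating_scheme()] for the meta-d' fit.
#' @return Data frame `(sigma_act, sigma_conf, d_prime, meta_d, ratio,
#'   error_detection_rate, fit_ok)`; failed fits carry `fit_ok = FALSE` and
#'   `NA` estimates.
#' @export
run_metad_sweep <- function(n = 1e4, seed = 1L,
                            sigma_grid = seq(0.25, 3, length.out = 20),
                            rho = 0.5, theta = 1,
                            scheme = rating_scheme(4)) {
  grid <- expand.grid(sigma_act = sigma_grid, sigma_conf = sigma_grid)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sa <- grid$sigma_act[i]; sc <- grid$sigma_conf[i]
    tt <- simulate_trials(
      gen_params(sa, sc, rho, theta), n = n,
      belief = belief_params("second_order", sa, sc, rho),
      seed = child_seed(seed, i))
    ne <- sum(!tt$correct)
    edr <- if (ne > 0) error_detection_rate(tt) else NA_real_
    fit <- tryCatch(fit_meta_d(tt, scheme = scheme), error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(sigma_act = sa, sigma_conf = sc, d_prime = NA_real_,
                 meta_d = NA_real_, ratio = NA_real_,
                 error_detection_rate = edr, fit_ok = FALSE)
    } else {
      data.frame(sigma_act = sa, sigma_conf = sc, d_prime = fit$d_prime,
                 meta_d = fit$meta_d, ratio = fit$ratio,
                 error_detection_rate = edr, fit_ok = TRUE)
    }
  })
  res <- do.call(rbind, out)
  attr(res, "n_failed") <- sum(!res$fit_ok)
  res
}

#' Miscalibration from mismatched belief hyperparameters
#'
#' Generative parameters are fixed (`sigma_act = 1.5`, `sigma_conf = 1`,
#' `rho = 0.6`); one believed parameter at a time is varied while the others
#' stay at their true values, and the calibration curve (accuracy at 10
#' confidence levels) is computed. Matched beliefs give the identity line;
#' each mismatch bends it in a characteristic direction (e.g. believing
#' `sigma_act` smaller than it is produces overconfidence).
#'
#' @param n Trials per belief setting.
#' @param seed Integer seed.
#' @param gen True generative parameters ([gen_params()]).
#' @param belief_sigma_act,belief_sigma_conf,belief_rho Believed values to
#'   sweep, one panel per parameter.
#' @param n_levels Confidence levels for the calibration curve.
#' @return Data frame `(panel, believed_value, level, mean_confidence,
#'   prop_correct, count)`. The matched setting appears in every panel.
#' @export
run_miscalibration <- function(n = 1e5, seed = 1L,
                               gen = gen_params(1.5, 1, 0.6, 1),
                               belief_sigma_act = c(1, 1.25, 1.5, 1.75, 2),
                               belief_sigma_conf = c(0.5, 0.75, 1, 1.5, 2),
                               belief_rho = c(0.2, 0.4, 0.6, 0.8, 0.95),
                               n_levels = 10L) {
  panels <- list(sigma_act = belief_sigma_act,
                 sigma_conf = belief_sigma_conf,
                 rho = belief_rho)
  # one shared set of internal states; only the observer's beliefs vary
  matched <- belief_params("second_order", gen$sigma_act, gen$sigma_conf,
                           gen$rho)
  tt <- simulate_trials(gen, n = n, belief = matched, seed = seed)
  out <- list(); i <- 0L
  for (p in names(panels)) {
    for (v in panels[[p]]) {
      i <- i + 1L
      b <- list(sigma_act = gen$sigma_act, sigma_conf = gen$sigma_conf,
                rho = gen$rho)
      b[[p]] <- v
      belief <- belief_params("second_order", b$sigma_act, b$sigma_conf,
                              b$rho)
      tt$z_post <- confidence(tt$x_conf, tt$a, belief, theta = gen$theta)
      cc <- calibration_curve(tt, n_levels)
      out[[i]] <- data.frame(panel = p, believed_value = v,
                             level = cc$level,
                             mean_confidence = cc$mean_confidence,
                             prop_correct = cc$prop_correct,
                             count = cc$count)
    }
  }
  do.call(rbind, out)
}
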