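# Frozen expected values are closed forms of the Gaussian posterior
# arithmetic: logistic likelihood ratios for the shared-variable models and
# the Phi-weighted mixture for the second-order model.

test_that("first-order confidence matches the logistic closed form", {
  b <- belief_params("first_order", sigma_act = 1)
  expect_equal(first_order_confidence(0, -1, b, theta = 1), 0.5)
  expect_equal(first_order_confidence(1, 1, b, theta = 1), 0.88079708,
               tolerance = 1e-8)
  # sign symmetry of the generative model
  expect_equal(first_order_confidence(-1, -1, b, theta = 1), 0.88079708,
               tolerance = 1e-8)
  # general sigma: z = logistic(2 a theta x / sigma^2)
  b2 <- belief_params("first_order", sigma_act = 0.7)
  expect_equal(first_order_confidence(0.3, 1, b2, theta = 0.6),
               plogis(2 * 0.6 * 0.3 / 0.49), tolerance = 1e-10)
})

test_that("postdecisional confidence uses the summed-evidence likelihood", {
  b <- belief_params("postdecisional", sigma_act = 1)
  expect_equal(postdecisional_confidence(0, 1, b, theta = 1), 0.5)
  # an error-detection case: summed evidence contradicts the action
  expect_equal(postdecisional_confidence(-2, 1, b, theta = 1), 0.01798621,
               tolerance = 1e-8)
  expect_equal(postdecisional_confidence(2, 1, b, theta = 1), 0.98201379,
               tolerance = 1e-8)
})

test_that("second-order confidence matches the conditional-Gaussian form", {
  # equivocal evidence but informative action: z = Phi(0.5) ~ 0.69
  expect_equal(second_order_confidence(0, 1, canonical_so(), theta = 1),
               0.69146246, tolerance = 1e-8)
  # rho = 0: the action term alone discriminates, z = Phi(1)
  b0 <- belief_params("second_order", 1, 1, 0)
  expect_equal(second_order_confidence(0, 1, b0, theta = 1), 0.84134475,
               tolerance = 1e-8)
  # reduction limit equals the first-order value
  br <- belief_params("second_order", 1, 1, 1)
  expect_equal(second_order_confidence(1, 1, br, theta = 1), 0.88079708,
               tolerance = 1e-8)
})

test_that("second-order model nests the first-order model at rho = 1", {
  br <- belief_params("second_order", 1, 1, 1)
  bf <- belief_params("first_order", 1)
  for (th in c(0.25, 0.5, 1)) {
    x <- seq(-4, 4, length.out = 41)
    a <- ifelse(x > 0, 1, -1)  # actions the first-order observer would take
    expect_equal(second_order_confidence(x, a, br, theta = th),
                 first_order_confidence(x, a, bf, theta = th),
                 tolerance = 1e-8)
  }
})

test_that("degenerate |rho| = 1 with unequal SDs uses the analytic limit", {
  b <- belief_params("second_order", 1, 2, 1)
  x <- c(-3, -0.5, 0.5, 3)
  z <- second_order_confidence(x, ifelse(x > 0, 1, -1), b, theta = 1)
  expect_true(all(is.finite(z)))
  expect_true(all(z >= 0 & z <= 1))
  # x = 0 with the tie-handling limit stays defined
  z0 <- second_order_confidence(0, 1, b, theta = 1)
  expect_true(is.finite(z0) && z0 >= 0 && z0 <= 1)
})

test_that("confidence outputs respect range, complement and mirror laws", {
  x <- seq(-5, 5, length.out = 21)
  cfgs <- list(
    belief_params("first_order", 0.8),
    belief_params("postdecisional", 1.2),
    belief_params("second_order", 1, 0.6, 0.4),
    belief_params("second_order", 1.5, 1, 0.8)
  )
  for (b in cfgs) for (th in c(0.3, 1)) {
    zp <- confidence(x, 1, b, theta = th)
    zm <- confidence(x, -1, b, theta = th)
    expect_true(all(zp >= 0 & zp <= 1))
    # mirror symmetry: z(x, a) == z(-x, -a)
    expect_equal(zp, confidence(-x, -1, b, theta = th), tolerance = 1e-10)
    if (b$model != "second_order") {
      # the action adds nothing in these models: posteriors are complements
      expect_equal(zp + zm, rep(1, length(x)), tolerance = 1e-10)
    } else {
      # across actions the sum departs from 1 by the action-information
      # shift, whose sign is that of (1 - rho * sigma_act / sigma_conf)
      shift_sign <- sign(1 - b$rho * b$sigma_act / b$sigma_conf)
      expect_true(all(shift_sign * (zp + zm - 1) >= -1e-10))
    }
  }
  # second-order complement does hold in the first-order reduction limit
  br <- belief_params("second_order", 1, 1, 1)
  x <- seq(-3, 3, length.out = 13)
  expect_equal(second_order_confidence(x, 1, br, theta = 1) +
                 second_order_confidence(x, -1, br, theta = 1),
               rep(1, 13), tolerance = 1e-10)
})

test_that("confidence is nondecreasing in x_conf for a = +1", {
  x <- seq(-6, 6, length.out = 201)
  for (b in list(belief_params("first_order", 1),
                 belief_params("postdecisional", 1),
                 canonical_so(),
                 belief_params("second_order", 2, 0.5, 0.3))) {
    z <- confidence(x, 1, b, theta = 1)
    expect_true(all(diff(z) >= -1e-12), info = b$model)
  }
})

test_that("first-order confidence never falls below one half", {
  b <- belief_params("first_order", 1)
  x <- seq(-5, 5, length.out = 10001)
  z <- first_order_confidence(x, decide(x), b, theta = 1)
  expect_true(all(z >= 0.5))
  expect_equal(min(z), 0.5)
  expect_equal(x[which.min(z)], 0)
})

test_that("marginalizing over theta matches an explicit mixture", {
  pr <- theta_prior(c(0.2, 0.6, 1), c(0.2, 0.3, 0.5))
  b <- belief_params("first_order", 1)
  x <- c(-1.3, 0.4, 2.2)
  # independent mixture arithmetic in plain probability space
  lik <- function(x, d) sapply(seq_along(pr$values), function(j)
    pr$weights[j] * dnorm(x, d * pr$values[j], 1))
  manual <- vapply(x, function(xi)
    sum(lik(xi, 1)) / (sum(lik(xi, 1)) + sum(lik(xi, -1))), numeric(1))
  expect_equal(first_order_confidence(x, 1, b, theta = pr), manual,
               tolerance = 1e-12)

  so <- canonical_so()
  man2 <- vapply(x, function(xi) {
    comp <- function(d) sum(sapply(seq_along(pr$values), function(j) {
      th <- pr$values[j]
      mu_c <- d * th + 0.6 * (xi - d * th)
      pr$weights[j] * dnorm(xi, d * th, 1) * pnorm(mu_c / 0.8)
    }))
    comp(1) / (comp(1) + comp(-1))
  }, numeric(1))
  expect_equal(second_order_confidence(x, 1, so, theta = pr), man2,
               tolerance = 1e-12)
})

test_that("extreme samples do not underflow the log-space posterior", {
  for (b in list(belief_params("first_order", 1),
                 belief_params("postdecisional", 1), canonical_so())) {
    z <- confidence(c(-40, 40), c(1, 1), b, theta = 1)
    expect_true(all(is.finite(z)))
    expect_equal(z[2], 1, tolerance = 1e-12)
    expect_lt(z[1], 1e-8)  # sure of an error (or its floor for first-order)
  }
})

test_that("pre-choice confidence rates the covert x_conf-consistent choice", {
  so <- canonical_so()
  # equals the post-choice posterior evaluated at the covert response
  x <- seq(-4, 4, length.out = 81)
  expect_equal(prechoice_confidence(x, so, theta = 1),
               second_order_confidence(x, ifelse(x >= 0, 1, -1), so,
                                       theta = 1), tolerance = 1e-12)
  # at equivocal evidence the covert action still lifts confidence
  expect_equal(prechoice_confidence(0, so, theta = 1), 0.69146246,
               tolerance = 1e-8)
  # bounded below by 0.5 whenever rho * sigma_act / sigma_conf <= 1
  expect_true(all(prechoice_confidence(x, so, theta = 1) >= 0.5))
  bf <- belief_params("first_order", 1)
  expect_equal(prechoice_confidence(c(0, 1), bf, theta = 1),
               c(0.5, 0.88079708), tolerance = 1e-8)
  # first-order model: pre- and post-choice confidence coincide trial by trial
  tt <- simulate_trials(canonical_gen(), n = 2000,
                        belief = belief_params("first_order", 1), seed = 21)
  expect_equal(tt$z_pre, tt$z_post, tolerance = 1e-12)
})

test_that("action modulation at equivocal evidence follows the covariance", {
  # at x_conf = 0 the action lifts confidence above 0.5 ...
  z0 <- function(sc, rho) second_order_confidence(
    0, 1, belief_params("second_order", 1, sc, rho), theta = 1)
  sweep_sc <- vapply(c(0.5, 1, 2, 3), z0, numeric(1), rho = 0.4)
  expect_true(all(sweep_sc > 0.5))
  expect_true(all(diff(sweep_sc) > 0))     # noisier x_conf: action counts more
  sweep_rho <- vapply(c(0, 0.3, 0.6, 0.9, 0.99), z0, numeric(1), sc = 1)
  expect_true(all(diff(sweep_rho) < 0))    # tighter coupling: action redundant
  expect_equal(z0(1, 0.999), 0.5, tolerance = 0.02)
})

test_that("confidence query validation catches bad inputs", {
  expect_error(first_order_confidence(NaN, 1, belief_params("first_order")),
               "finite")
  expect_error(first_order_confidence(1, 0, belief_params("first_order")),
               "-1 or \\+1")
  expect_error(first_order_confidence(1, NULL, belief_params("first_order")),
               "action")
  expect_error(second_order_confidence(1, 1, canonical_so(), theta = NULL),
               "theta")
})

test_that("Monte-Carlo oracle agrees with the closed form", {
  p <- canonical_gen()
  o <- mc_oracle_confidence(p, 0, window = 0.05, a = 1, n = 1e6, seed = 2)
  expect_lt(abs(o$estimate - 0.69146246), 3 * o$se)
  # reduction limit
  p1 <- gen_params(1, 1, 1, 1)
  o1 <- mc_oracle_confidence(p1, 1, window = 0.05, a = 1, n = 2e5, seed = 3)
  expect_lt(abs(o1$estimate - 0.88079708), 3 * o1$se)
  # no signal anywhere
  p0 <- gen_params(1, 1, 0, 0)
  o0 <- mc_oracle_confidence(p0, 0.3, window = 0.1, a = 1, n = 2e5, seed = 4)
  expect_lt(abs(o0$estimate - 0.5), 3 * o0$se)
  expect_error(mc_oracle_confidence(p, 12, window = 0.01, a = 1, n = 1e5,
                                    seed = 5), "selected")
  expect_error(mc_oracle_confidence(p, 0, window = 0.05, a = 1, n = 10,
                                    seed = 5), "1e\\+05|at least")
})
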