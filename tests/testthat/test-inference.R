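test_that("Savage-Dickey estimates match the closed-form conjugate oracle", {
  set.seed(201)
  for (m in c(0, 0.5, 1, 2)) {
    for (s in c(0.3, 0.5, 1)) {
      draws <- rnorm(20000, m, s)
      want <- dnorm(0, 0, 2) / dnorm(0, m, s)
      got <- as.numeric(savage_dickey_bf(draws, prior_scale = 2))
      expect_lt(abs(got / want - 1), 0.10)
    }
  }
  # posterior equal to prior: BF10 = 1 within estimator tolerance
  draws <- rnorm(50000, 0, 2)
  expect_lt(abs(as.numeric(savage_dickey_bf(draws, 2)) - 1), 0.05)
  # shrinking information: a null-centred posterior slightly narrower than
  # the prior gives BF10 just below 1, approaching 1 as the posterior
  # widens back to the prior
  bfs <- sapply(c(1.2, 1.6, 1.9, 1.99), function(s) {
    as.numeric(savage_dickey_bf(rnorm(50000, 0, s), 2))
  })
  expect_true(all(bfs < 1.05))
  expect_true(all(diff(bfs) > 0))
  expect_gt(bfs[4], 0.95)
  # estimator metadata is recorded
  k <- savage_dickey_bf(rnorm(2000), 2, method = "kernel")
  expect_identical(attr(k, "method"), "kernel")
  expect_true(is.finite(attr(k, "bandwidth")))
})

test_that("pd and ROPE equal direct counting oracles exactly", {
  expect_equal(probability_of_direction(c(-1, -2, -0.5)), 1)
  expect_equal(probability_of_direction(c(-1, 2, 3, 4)), 0.75)
  expect_equal(rope_fraction(c(-0.05, 0.05, 0.5)), 2 / 3)
  expect_equal(rope_fraction(c(-2, -2, -2)), 0)
  set.seed(202)
  for (i in 1:20) {
    d <- rnorm(500, rnorm(1), runif(1, 0.1, 2))
    med <- median(d)
    count_pd <- if (med >= 0) sum(d >= 0) else sum(d <= 0)
    expect_identical(probability_of_direction(d), count_pd / length(d))
    r <- sort(runif(2, -1, 1))
    expect_identical(rope_fraction(d, r),
                     sum(d >= r[1] & d <= r[2]) / length(d))
  }
  # symmetric sample: pd near its 0.5 floor
  expect_lt(probability_of_direction(rnorm(100000)), 0.52)
  # Normal(0, 0.05) inside the default ROPE: ~Phi(2) - Phi(-2)
  expect_equal(rope_fraction(rnorm(100000, 0, 0.05)),
               pnorm(2) - pnorm(-2), tolerance = 0.01)
})

test_that("the Gibbs sampler recovers generating fixed effects", {
  dat <- make_regression_data(n_subjects = 10, n_per = 80, seed = 203)
  fit <- fit_awareness_model(dat, "van_amp", "detection_only",
                             chains = 2, iter = 800, warmup = 400,
                             seed = 204)
  expect_true(fit$converged)
  ci <- confint(fit)
  truth <- c(0.5, -2, -3)
  expect_true(all(truth >= ci[, 1] & truth <= ci[, 2]))
  # reproducibility: identical seed, identical draws
  fit2 <- fit_awareness_model(dat, "van_amp", "detection_only",
                              chains = 2, iter = 800, warmup = 400,
                              seed = 204)
  expect_identical(fit$draws, fit2$draws)
  # summary carries the exact BF identity and ordered intervals
  sm <- summary(fit)
  expect_equal(sm$bf01, 1 / sm$bf10)
  expect_true(all(sm$ci_low < sm$ci_high))
  expect_true(all(sm$pd >= 0.5 & sm$pd <= 1))
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  dat <- make_regression_data(n_subjects = 6, n_per = 40, seed = 205)
  fit <- fit_awareness_model(dat, "van_amp", "detection_only",
                             chains = 2, iter = 2000, warmup = 500,
                             seed = 206)
  model_str <- "
  model {
    for (i in 1:N) { y[i] ~ dt(inprod(X[i,], bsub[subj[i],]), tau_e, nu) }
    for (s in 1:S) { for (k in 1:K) { bsub[s,k] ~ dnorm(beta[k], tau_u[k]) } }
    for (k in 1:K) {
      beta[k] ~ dnorm(0, 0.25)
      sd_u[k] ~ dt(0, pow(2.5, -2), 2) T(0,)
      tau_u[k] <- pow(sd_u[k], -2)
    }
    sigma ~ dt(0, pow(10, -2), 2) T(0,)
    tau_e <- pow(sigma, -2)
    nu ~ dgamma(2, 0.1) T(1,)
  }"
  X <- cbind(1, dat$aware, dat$opacity_centered)
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = dat$van_amp, X = X, subj = dat$subject_id,
                N = nrow(dat), S = max(dat$subject_id), K = 3),
    inits = list(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
                 list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2)),
    n.chains = 2, n.adapt = 500, quiet = TRUE)
  update(jm, 1000)
  sm <- rjags::coda.samples(jm, "beta", n.iter = 4000)
  jags_mean <- summary(sm)$statistics[, "Mean"]
  jags_sd <- summary(sm)$statistics[, "SD"]
  ours <- unname(coef(fit))
  # agreement within a fraction of the posterior SD
  expect_true(all(abs(ours - jags_mean) < 0.35 * jags_sd))
})

test_that("full-model and detection-only awareness effects agree", {
  set.seed(207)
  ds <- generate_dataset(n_subjects = 6, n_trials = 120,
                         erp = erp_gen_params(noise_sd = 25), seed = 208)
  sel <- select_trials(ds$trials, selection_config(min_trials_per_cell = 5))
  full <- fit_awareness_model(sel$van, "van_amp", "full_interaction",
                              chains = 2, iter = 600, warmup = 300,
                              seed = 209)
  det <- fit_awareness_model(sel$van, "van_amp", "detection_only",
                             chains = 2, iter = 600, warmup = 300,
                             seed = 209)
  eff_full <- awareness_effects(full)$detect
  eff_det <- awareness_effects(det)$detect
  pooled_sd <- sqrt(sd(eff_full)^2 + sd(eff_det)^2)
  expect_lt(abs(mean(eff_full) - mean(eff_det)), 2 * pooled_sd)
})

test_that("degenerate inputs error or flag, never crash", {
  dat <- make_regression_data(n_subjects = 1, n_per = 30, seed = 210)
  expect_error(fit_awareness_model(dat, "van_amp", "detection_only"),
               "two subjects")
  expect_error(fit_awareness_model(dat[0, ], "van_amp"), "empty")
  expect_error(fit_awareness_model(make_regression_data(seed = 211),
                                   "missing_col"), "not found")
})

test_that("null data give CIs covering zero for the awareness terms", {
  dat <- make_regression_data(n_subjects = 8, n_per = 60,
                              beta = c(0, 0, 0), subject_sd = 0.3,
                              seed = 212)
  fit <- fit_awareness_model(dat, "van_amp", "detection_only",
                             chains = 2, iter = 600, warmup = 300,
                             seed = 213)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= 0 & ci[, 2] >= 0))
})

test_that("model methods expose the standard fitted-model interface", {
  dat <- make_regression_data(n_subjects = 6, n_per = 40, seed = 214)
  fit <- fit_awareness_model(dat, "van_amp", "detection_only",
                             chains = 2, iter = 400, warmup = 200,
                             seed = 215)
  expect_named(coef(fit), c("(Intercept)", "awareness", "opacity"))
  expect_equal(length(fitted(fit)), nrow(dat))
  expect_equal(residuals(fit), dat$van_amp - fitted(fit))
  pr <- predict(fit, data.frame(aware = c(0, 1), opacity_centered = 0))
  expect_equal(dim(pr), c(2L, 3L))
  # the aware-unaware contrast in predictions equals the coefficient
  expect_equal(unname(pr[2, "mean"] - pr[1, "mean"]),
               unname(coef(fit)["awareness"]))
  expect_output(print(fit), "awareness_fit")
  expect_output(print(summary(fit)), "Robust Bayesian")
})
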