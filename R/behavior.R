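#' Bayesian logistic mixed model of orientation-report accuracy
#'
#' Fits trial-level correctness with a Bernoulli-logit mixed model with
#' subject-level random coefficients, mirroring the amplitude models:
#' \code{"detection_only"} regresses correctness on awareness within the
#' detection threshold, \code{"full_interaction"} adds the threshold dummy
#' and its interaction with awareness. Fixed effects (log-odds) get
#' Normal(0, \code{prior_scale}) priors. Sampling is delegated to JAGS
#' (\pkg{rjags}), the package's posterior-sampling engine for this
#' non-conjugate likelihood.
#'
#' @param trials Analysis trial table (catch trials are dropped if present).
#' @param formula \code{"detection_only"} or \code{"full_interaction"}.
#' @param prior_scale SD of the normal prior on intercept and slopes.
#' @param chains,iter,warmup MCMC settings.
#' @param seed Integer seed.
#' @return An object of class \code{behavior_fit}: posterior draws of the
#'   fixed effects, estimated condition-wise proportions correct,
#'   Savage-Dickey BF10 for the awareness effect, convergence diagnostics,
#'   and a \code{separation} flag when the outcome is degenerate (all
#'   correct or all incorrect), in which case no sampling is attempted.
#' @export
fit_behavior_model <- function(trials,
                               formula = c("detection_only",
                                           "full_interaction"),
                               prior_scale = 2, chains = 2, iter = 1000,
                               warmup = 500, seed = 1) {
  formula <- match.arg(formula)
  trials <- trials[trials$staircase != "catch", , drop = FALSE]
  if (formula == "detection_only") {
    trials <- trials[trials$staircase == "detect", , drop = FALSE]
  }
  if (nrow(trials) == 0) stop("empty analysis set", call. = FALSE)
  y <- trials$correct
  if (is.null(y) || anyNA(y)) stop("correctness column missing or NA",
                                   call. = FALSE)
  if (length(unique(y)) < 2) {
    return(structure(list(separation = TRUE, converged = FALSE,
                          formula = formula, n_obs = length(y),
                          observed = mean(y)),
                     class = "behavior_fit"))
  }
  X <- if (formula == "detection_only") {
    cbind("(Intercept)" = 1, awareness = trials$aware)
  } else {
    cbind("(Intercept)" = 1, threshold = trials$threshold_dummy,
          awareness = trials$aware,
          "threshold:awareness" = trials$threshold_dummy * trials$aware)
  }
  subj <- match(trials$subject_id, sort(unique(trials$subject_id)))
  model_str <- "
  model {
    for (i in 1:N) {
      y[i] ~ dbern(p[i])
      logit(p[i]) <- inprod(X[i,], bsub[subj[i],])
    }
    for (s in 1:S) {
      for (k in 1:K) { bsub[s,k] ~ dnorm(beta[k], tau_u[k]) }
    }
    for (k in 1:K) {
      beta[k] ~ dnorm(0, prec_b)
      sd_u[k] ~ dt(0, 0.16, 3) T(0,)
      tau_u[k] <- pow(sd_u[k], -2)
    }
  }"
  dat <- list(y = y, X = X, subj = subj, N = length(y), S = max(subj),
              K = ncol(X), prec_b = 1 / prior_scale^2)
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + (ch - 1L) * 1009L)
  })
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = chains,
                          n.adapt = max(100, warmup %/% 2), quiet = TRUE)
  update(jm, warmup)
  sm <- rjags::coda.samples(jm, "beta", n.iter = iter)
  draws <- do.call(rbind, lapply(sm, as.matrix))
  colnames(draws) <- colnames(X)
  gd <- try(coda::gelman.diag(sm, multivariate = FALSE)$psrf[, 1],
            silent = TRUE)
  rhat <- if (inherits(gd, "try-error")) rep(NA_real_, ncol(X)) else
    stats::setNames(gd, colnames(X))
  converged <- all(is.finite(rhat)) && max(rhat) < 1.1
  props <- if (formula == "detection_only") {
    c(detect_unaware = mean(stats::plogis(draws[, 1])),
      detect_aware = mean(stats::plogis(draws[, 1] + draws[, 2])))
  } else {
    c(identify_unaware = mean(stats::plogis(draws[, 1])),
      identify_aware = mean(stats::plogis(draws[, 1] + draws[, 3])),
      detect_unaware = mean(stats::plogis(draws[, 1] + draws[, 2])),
      detect_aware = mean(stats::plogis(rowSums(draws))))
  }
  bf <- savage_dickey_bf(draws[, "awareness"], prior_scale)
  structure(list(draws = draws, proportions = props,
                 bf10_awareness = as.numeric(bf),
                 bf01_awareness = 1 / as.numeric(bf),
                 rhat = rhat, converged = converged, separation = FALSE,
                 formula = formula, prior_scale = prior_scale,
                 n_obs = length(y), n_subjects = max(subj), seed = seed),
            class = "behavior_fit")
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat(sprintf("Bayesian logistic mixed model of correctness (%s)\n",
              x$formula))
  if (isTRUE(x$separation)) {
    cat(sprintf("  degenerate outcome (observed proportion %.3f): separation flagged, not sampled\n",
                x$observed))
    return(invisible(x))
  }
  cat("  estimated proportions correct:\n")
  print(round(x$proportions, 3))
  cat(sprintf("  awareness effect: BF10 = %.3g (%s)\n",
              x$bf10_awareness, bf_label(x$bf10_awareness)))
  if (!x$converged) cat("  ** convergence flagged **\n")
  invisible(x)
}
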