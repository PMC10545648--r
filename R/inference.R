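#' Fit a robust Bayesian hierarchical regression of trial amplitudes
#'
#' Trial-level mean amplitudes are modelled with a Student-t likelihood
#' (robust to residual outliers) and subject-level random coefficients:
#' \deqn{y_i = x_i' \beta + x_i' u_{s(i)} + e_i, \quad e_i \sim t_\nu(0, \sigma)}
#' Two model formulas are available. \code{"detection_only"} uses detection
#' trials only with predictors \code{1 + awareness + opacity}, where
#' \code{awareness} is dummy coded 0 = unaware, 1 = aware and \code{opacity}
#' is the block-centered opacity. \code{"full_interaction"} uses both
#' thresholds with \code{1 + threshold*awareness + threshold*opacity}
#' (threshold dummy coded 0 = identification, 1 = detection), so the
#' \code{awareness} coefficient is the identification awareness effect and
#' the \code{threshold:awareness} interaction is the change of that effect
#' from identification to detection. All predictors enter un-standardized.
#'
#' Fixed effects get independent Normal(0, \code{prior_scale}) priors.
#' Random effects are independent across coefficients with half-t(2) priors
#' on their SDs; the residual scale has a half-t(2) prior and the Student-t
#' degrees of freedom a Gamma(2, 0.1) prior truncated at 1. Sampling uses a
#' blocked Gibbs sampler on the normal scale-mixture representation of the
#' Student-t (all conditionals conjugate; the degrees of freedom are drawn
#' from a discretized grid). Identical seeds give identical draws.
#'
#' @param data Analysis trial table (one of the data frames returned by
#'   \code{\link{select_trials}}), with columns \code{subject_id},
#'   \code{aware}, \code{threshold_dummy}, \code{opacity_centered},
#'   \code{orientation}, and the outcome.
#' @param outcome Column name of the outcome, e.g. \code{"van_amp"} or
#'   \code{"lp_amp"}.
#' @param formula One of \code{"full_interaction"}, \code{"detection_only"}.
#' @param include_orientation Add grating orientation (right = 1) as an
#'   additional fixed and random predictor.
#' @param prior_scale SD of the zero-mean normal prior on intercept and
#'   slopes (default 2).
#' @param likelihood \code{"student_t"} (default) or \code{"gaussian"}.
#' @param chains,iter,warmup MCMC settings: number of chains, kept iterations
#'   per chain, and discarded warmup iterations per chain.
#' @param seed Integer seed.
#' @param rope Region of practical equivalence used by \code{summary}, in
#'   outcome units (default \code{c(-0.1, 0.1)} microvolts).
#' @return An object of class \code{awareness_fit} with posterior draws of
#'   the fixed effects (\code{$draws}, iterations x coefficients, chains
#'   stacked), auxiliary draws (\code{$sigma}, \code{$nu}, \code{$sd_u}),
#'   convergence diagnostics (\code{$rhat}, \code{$ess}, \code{$converged})
#'   and the model description.
#' @examples
#' \donttest{
#' ds <- generate_dataset(n_subjects = 4, n_trials = 80, seed = 2)
#' sel <- select_trials(ds$trials, selection_config(min_trials_per_cell = 5))
#' fit <- fit_awareness_model(sel$van, "van_amp", chains = 2, iter = 300,
#'                            warmup = 150, seed = 9)
#' summary(fit)
#' }
#' @export
fit_awareness_model <- function(data, outcome = "van_amp",
                                formula = c("full_interaction",
                                            "detection_only"),
                                include_orientation = FALSE,
                                prior_scale = 2,
                                likelihood = c("student_t", "gaussian"),
                                chains = 2, iter = 1000, warmup = 500,
                                seed = 1, rope = c(-0.1, 0.1)) {
  formula <- match.arg(formula)
  likelihood <- match.arg(likelihood)
  if (formula == "detection_only") {
    data <- data[data$staircase == "detect", , drop = FALSE]
  }
  if (nrow(data) == 0) stop("empty analysis set", call. = FALSE)
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found",
                       call. = FALSE)
  X <- if (formula == "detection_only") {
    cbind("(Intercept)" = 1, awareness = data$aware,
          opacity = data$opacity_centered)
  } else {
    cbind("(Intercept)" = 1, threshold = data$threshold_dummy,
          awareness = data$aware, opacity = data$opacity_centered,
          "threshold:awareness" = data$threshold_dummy * data$aware,
          "threshold:opacity" = data$threshold_dummy * data$opacity_centered)
  }
  if (include_orientation) {
    X <- cbind(X, orientation = as.integer(data$orientation == "right"))
  }
  subj <- match(data$subject_id, sort(unique(data$subject_id)))
  n_subj <- max(subj)
  if (n_subj < 2) {
    stop("at least two subjects are required to fit the hierarchical model",
         call. = FALSE)
  }
  res <- gibbs_robust_lmm(y, X, subj, prior_scale = prior_scale,
                          student_t = likelihood == "student_t",
                          chains = chains, iter = iter, warmup = warmup,
                          seed = seed)
  rhat <- diag_rhat(res$beta_chains)
  ess <- diag_ess(res$beta_chains)
  converged <- all(is.finite(rhat)) && max(rhat) < 1.1
  if (!converged) {
    warning("sampler did not converge (max Rhat = ",
            round(max(rhat), 3), "); treat results with caution",
            call. = FALSE)
  }
  structure(list(draws = res$beta, draws_by_chain = res$beta_chains,
                 sigma = res$sigma, nu = res$nu, sd_u = res$sd_u,
                 rhat = rhat, ess = ess, converged = converged,
                 outcome = outcome, formula = formula,
                 include_orientation = include_orientation,
                 likelihood = likelihood, prior_scale = prior_scale,
                 rope = rope, n_obs = length(y), n_subjects = n_subj,
                 chains = chains, iter = iter, warmup = warmup, seed = seed,
                 y = y, X = X, subj = subj,
                 u_mean = res$u_mean),
            class = "awareness_fit")
}

# Blocked Gibbs sampler for the Student-t hierarchical linear model.
# Scale-mixture form: e_i | lambda_i ~ N(0, sigma^2 / lambda_i),
# lambda_i ~ Gamma(nu/2, nu/2). Conjugate updates for beta (normal), the
# per-subject coefficients u_s (normal), sigma^2 and the random-effect
# variances (inverse-gamma via the Huang-Wand half-t augmentation), and the
# mixing weights (gamma). nu is drawn from its discretized full conditional.
gibbs_robust_lmm <- function(y, X, subj, prior_scale = 2, student_t = TRUE,
                             chains = 2, iter = 1000, warmup = 500, seed = 1,
                             A_u = 2.5, A_e = 10,
                             nu_grid = c(seq(1, 30, by = 1),
                                         seq(32, 100, by = 4))) {
  N <- length(y); K <- ncol(X); S <- max(subj)
  idx <- split(seq_len(N), subj)
  Xs <- lapply(idx, function(ii) X[ii, , drop = FALSE])
  half_t_df <- 2
  beta_ch <- vector("list", chains)
  sigma_ch <- vector("list", chains)
  nu_ch <- vector("list", chains)
  sdu_ch <- vector("list", chains)
  u_acc <- matrix(0, S, K)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + (ch - 1L) * 1009L)
    beta <- rep(0, K); u <- matrix(0, S, K)
    sigma2 <- stats::var(y); tau2 <- rep(1, K)
    lam <- rep(1, N); nu <- 30; a_e <- 1; a_u <- rep(1, K)
    keep_b <- matrix(NA_real_, iter, K,
                     dimnames = list(NULL, colnames(X)))
    keep_s <- numeric(iter); keep_n <- numeric(iter)
    keep_t <- matrix(NA_real_, iter, K)
    for (it in seq_len(iter + warmup)) {
      fit_u <- rowSums(X * u[subj, , drop = FALSE])
      w <- lam / sigma2
      Xw <- X * w
      A <- crossprod(Xw, X) + diag(1 / prior_scale^2, K)
      b <- crossprod(Xw, y - fit_u)
      ch_A <- chol(A)
      beta <- drop(backsolve(ch_A, backsolve(ch_A, b, transpose = TRUE)) +
                     backsolve(ch_A, stats::rnorm(K)))
      fit_b <- drop(X %*% beta)
      for (s in seq_len(S)) {
        ii <- idx[[s]]
        Xi <- Xs[[s]]
        Ai <- crossprod(Xi * w[ii], Xi) + diag(1 / tau2, K)
        bi <- crossprod(Xi * w[ii], y[ii] - fit_b[ii])
        ch_i <- chol(Ai)
        u[s, ] <- drop(backsolve(ch_i, backsolve(ch_i, bi, transpose = TRUE)) +
                         backsolve(ch_i, stats::rnorm(K)))
      }
      # interweaving translation move: shift mass between beta and the
      # subject effects (likelihood-invariant; exact Gibbs step on the
      # reparameterized space), which decorrelates the hyper-means
      prec_d <- 1 / prior_scale^2 + S / tau2
      mean_d <- (-beta / prior_scale^2 + colSums(u) / tau2) / prec_d
      delta <- stats::rnorm(K, mean_d, sqrt(1 / prec_d))
      beta <- beta + delta
      u <- sweep(u, 2, delta)
      fit_b <- drop(X %*% beta)
      r <- y - fit_b - rowSums(X * u[subj, , drop = FALSE])
      sigma2 <- 1 / stats::rgamma(1, (half_t_df + N) / 2,
                                  half_t_df / a_e + sum(lam * r^2) / 2)
      a_e <- 1 / stats::rgamma(1, (half_t_df + 1) / 2,
                               half_t_df / sigma2 + 1 / A_e^2)
      tau2 <- 1 / stats::rgamma(K, (half_t_df + S) / 2,
                                half_t_df / a_u + colSums(u^2) / 2)
      a_u <- 1 / stats::rgamma(K, (half_t_df + 1) / 2,
                               half_t_df / tau2 + 1 / A_u^2)
      if (student_t) {
        lam <- stats::rgamma(N, (nu + 1) / 2, (nu + r^2 / sigma2) / 2)
        s1 <- sum(log(lam)); s2 <- sum(lam)
        lp <- N * ((nu_grid / 2) * log(nu_grid / 2) - lgamma(nu_grid / 2)) +
          (nu_grid / 2 - 1) * s1 - (nu_grid / 2) * s2 +
          stats::dgamma(nu_grid, 2, 0.1, log = TRUE)
        lp <- lp - max(lp)
        nu <- sample(nu_grid, 1, prob = exp(lp))
      }
      if (it > warmup) {
        j <- it - warmup
        keep_b[j, ] <- beta
        keep_s[j] <- sqrt(sigma2)
        keep_n[j] <- if (student_t) nu else Inf
        keep_t[j, ] <- sqrt(tau2)
        u_acc <- u_acc + u / (iter * chains)
      }
    }
    beta_ch[[ch]] <- keep_b
    sigma_ch[[ch]] <- keep_s
    nu_ch[[ch]] <- keep_n
    sdu_ch[[ch]] <- keep_t
  }
  list(beta = do.call(rbind, beta_ch), beta_chains = beta_ch,
       sigma = unlist(sigma_ch), nu = unlist(nu_ch),
       sd_u = do.call(rbind, sdu_ch), u_mean = u_acc)
}

# Split-chain potential scale reduction factor per coefficient.
diag_rhat <- function(beta_chains) {
  splits <- unlist(lapply(beta_chains, function(m) {
    h <- floor(nrow(m) / 2)
    list(m[seq_len(h), , drop = FALSE],
         m[(h + 1):(2 * h), , drop = FALSE])
  }), recursive = FALSE)
  K <- ncol(beta_chains[[1]])
  out <- vapply(seq_len(K), function(k) {
    draws <- vapply(splits, function(m) m[, k], numeric(nrow(splits[[1]])))
    n <- nrow(draws); m <- ncol(draws)
    mu <- colMeans(draws)
    B <- n * stats::var(mu)
    W <- mean(apply(draws, 2, stats::var))
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  names(out) <- colnames(beta_chains[[1]])
  out
}

diag_ess <- function(beta_chains) {
  ml <- coda::mcmc.list(lapply(beta_chains, coda::mcmc))
  out <- coda::effectiveSize(ml)
  names(out) <- colnames(beta_chains[[1]])
  out
}

#' Savage-Dickey Bayes factor for a point null at zero
#'
#' BF10 is the prior density at zero divided by the posterior density at
#' zero. The prior is Normal(0, \code{prior_scale}) and evaluated in closed
#' form. The posterior density at zero is estimated from the draws either by
#' a moment-matched normal (default; accurate for the near-Gaussian fixed-
#' effect posteriors of the hierarchical linear model, and stable when zero
#' lies far in the tail) or by a kernel density with Sheather-Jones
#' bandwidth. The estimator and its bandwidth are recorded as attributes.
#'
#' @param draws Numeric vector of posterior draws (>= 1000 recommended).
#' @param prior_scale SD of the zero-mean normal prior.
#' @param method \code{"normal"} or \code{"kernel"}.
#' @return BF10, with attributes \code{method}, \code{bandwidth} (kernel
#'   method), and \code{lower_bound = TRUE} when the posterior density at
#'   zero underflows so only a lower bound on BF10 can be reported.
#' @examples
#' set.seed(1)
#' savage_dickey_bf(rnorm(5000, 2, 0.5), prior_scale = 2)  # ~745
#' @export
savage_dickey_bf <- function(draws, prior_scale = 2,
                             method = c("normal", "kernel")) {
  method <- match.arg(method)
  prior0 <- stats::dnorm(0, 0, prior_scale)
  bw <- NA_real_
  post0 <- if (method == "normal") {
    stats::dnorm(0, mean(draws), stats::sd(draws))
  } else {
    d <- stats::density(draws, bw = "SJ")
    bw <- d$bw
    stats::approx(d$x, d$y, xout = 0, yleft = 0, yright = 0)$y
  }
  floor_dens <- .Machine$double.xmin * 1e50
  lower <- !is.finite(post0) || post0 < floor_dens
  bf <- prior0 / max(post0, floor_dens)
  structure(bf, method = method, bandwidth = bw, lower_bound = lower)
}

#' Probability of direction
#'
#' Fraction of the posterior draws sharing the sign of the posterior median;
#' draws exactly at zero are counted with the median's side.
#'
#' @param draws Numeric vector of posterior draws.
#' @return A proportion in [0.5, 1].
#' @export
probability_of_direction <- function(draws) {
  stopifnot(length(draws) >= 1)
  if (stats::median(draws) >= 0) mean(draws >= 0) else mean(draws <= 0)
}

#' Fraction of the posterior inside a region of practical equivalence
#'
#' @param draws Numeric vector of posterior draws.
#' @param rope Two ordered bounds of the (closed) equivalence region,
#'   default -0.1 to +0.1 microvolts.
#' @return A proportion in [0, 1], computed on the full posterior.
#' @export
rope_fraction <- function(draws, rope = c(-0.1, 0.1)) {
  stopifnot(length(rope) == 2, rope[1] <= rope[2])
  mean(draws >= rope[1] & draws <= rope[2])
}

# Verbal evidence label for a Bayes factor (annotation only).
bf_label <- function(bf) {
  b <- max(bf, 1 / bf)
  strength <- if (b >= 100) "extreme" else if (b >= 10) "strong" else
    if (b >= 3) "moderate" else "ambiguous"
  direction <- if (bf >= 1) "for" else "against"
  paste(strength, "evidence", direction, "an effect")
}

#' Summarize posterior fixed effects
#'
#' One row per fixed effect with posterior mean, equal-tailed 95\% credible
#' interval, Savage-Dickey BF10 and BF01, probability of direction, ROPE
#' fraction, split-Rhat and effective sample size.
#'
#' @param object An \code{\link{fit_awareness_model}} fit.
#' @param prob Credible-interval mass (default 0.95).
#' @param bf_method Density estimator for the Savage-Dickey ratio.
#' @param ... Unused.
#' @return A data frame of class \code{summary.awareness_fit}.
#' @export
summary.awareness_fit <- function(object, prob = 0.95,
                                  bf_method = c("normal", "kernel"), ...) {
  bf_method <- match.arg(bf_method)
  a <- (1 - prob) / 2
  out <- do.call(rbind, lapply(colnames(object$draws), function(nm) {
    d <- object$draws[, nm]
    bf <- savage_dickey_bf(d, object$prior_scale, bf_method)
    data.frame(term = nm, mean = mean(d),
               ci_low = unname(stats::quantile(d, a)),
               ci_high = unname(stats::quantile(d, 1 - a)),
               bf10 = as.numeric(bf), bf01 = 1 / as.numeric(bf),
               pd = probability_of_direction(d),
               rope = rope_fraction(d, object$rope),
               rhat = unname(object$rhat[nm]),
               ess = unname(object$ess[nm]))
  }))
  rownames(out) <- NULL
  attr(out, "outcome") <- object$outcome
  attr(out, "formula") <- object$formula
  attr(out, "converged") <- object$converged
  class(out) <- c("summary.awareness_fit", "data.frame")
  out
}

#' @export
print.summary.awareness_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Robust Bayesian hierarchical model of %s (%s)\n",
              attr(x, "outcome"), attr(x, "formula")))
  if (!isTRUE(attr(x, "converged"))) cat("  ** convergence flagged **\n")
  df <- as.data.frame(x)
  df$bf10 <- signif(df$bf10, 3)
  df$bf01 <- signif(df$bf01, 3)
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
print.awareness_fit <- function(x, ...) {
  cat(sprintf("awareness_fit: %s ~ %s | %d trials, %d subjects, %s likelihood\n",
              x$outcome, x$formula, x$n_obs, x$n_subjects, x$likelihood))
  cat(sprintf("  %d chains x %d iterations (+%d warmup), max Rhat %.3f%s\n",
              x$chains, x$iter, x$warmup, max(x$rhat),
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.awareness_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' @export
confint.awareness_fit <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  q <- t(apply(object$draws, 2, stats::quantile, probs = c(a, 1 - a)))
  if (!missing(parm)) q <- q[parm, , drop = FALSE]
  q
}

#' @export
fitted.awareness_fit <- function(object, ...) {
  beta <- colMeans(object$draws)
  drop(object$X %*% beta) +
    rowSums(object$X * object$u_mean[object$subj, , drop = FALSE])
}

#' @export
residuals.awareness_fit <- function(object, ...) {
  object$y - fitted(object)
}

#' Posterior predictions for new predictor values
#'
#' Population-level predictions (random effects set to zero) for a new data
#' frame with the model's predictor columns.
#'
#' @param object An \code{awareness_fit}.
#' @param newdata Data frame with \code{aware}, \code{opacity_centered} and,
#'   for the full model, \code{threshold_dummy} (plus \code{orientation}
#'   when the fit includes it).
#' @param ... Unused.
#' @return A matrix with posterior mean and 95\% CI per row of newdata.
#' @export
predict.awareness_fit <- function(object, newdata, ...) {
  X <- if (object$formula == "detection_only") {
    cbind(1, newdata$aware, newdata$opacity_centered)
  } else {
    cbind(1, newdata$threshold_dummy, newdata$aware,
          newdata$opacity_centered,
          newdata$threshold_dummy * newdata$aware,
          newdata$threshold_dummy * newdata$opacity_centered)
  }
  if (object$include_orientation) {
    X <- cbind(X, as.integer(newdata$orientation == "right"))
  }
  lin <- X %*% t(object$draws)
  t(apply(lin, 1, function(d) {
    c(mean = mean(d), ci_low = unname(stats::quantile(d, 0.025)),
      ci_high = unname(stats::quantile(d, 0.975)))
  }))
}

#' @export
plot.awareness_fit <- function(x, ...) {
  K <- ncol(x$draws)
  op <- graphics::par(mfrow = c(ceiling(K / 2), 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in colnames(x$draws)) {
    d <- stats::density(x$draws[, nm])
    plot(d, main = nm, xlab = "coefficient", ...)
    graphics::abline(v = 0, lty = 2)
  }
  invisible(x)
}

#' Awareness effects implied by a fitted model
#'
#' Combines posterior draws into the three reported effects. For the full
#' model: the identification awareness effect (the \code{awareness}
#' coefficient), the detection awareness effect (\code{awareness} plus
#' \code{threshold:awareness}), and their difference (the interaction). For
#' the detection-only model, only the detection effect is available.
#'
#' @param fit An \code{\link{fit_awareness_model}} object.
#' @return A list of named draw vectors: \code{detect}, and for the full
#'   model also \code{identify} and \code{interaction}.
#' @export
awareness_effects <- function(fit) {
  d <- fit$draws
  if (fit$formula == "detection_only") {
    list(detect = d[, "awareness"])
  } else {
    list(detect = d[, "awareness"] + d[, "threshold:awareness"],
         identify = d[, "awareness"],
         interaction = d[, "threshold:awareness"])
  }
}
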