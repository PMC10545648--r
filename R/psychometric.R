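#' Fit a probit psychometric function to staircase data
#'
#' Maximum-likelihood binomial regression of the aware/unaware response on
#' opacity with a probit link: P(aware | x) = Phi((x - mu) / sigma), with
#' mu = -intercept/slope and sigma = 1/slope. The fit is declared
#' non-converged (rather than raising an error) on one-sided data, complete
#' separation, a non-positive slope, or non-finite estimates, mirroring the
#' repeat-the-staircase behaviour such data call for in practice.
#'
#' @param opacity Numeric vector of presented opacities.
#' @param aware 0/1 vector of awareness responses.
#' @return An object of class \code{probit_fit}: \code{mu}, \code{sigma},
#'   their standard errors (delta method), \code{converged}, \code{n}, and
#'   the slope sign flag \code{increasing}.
#' @examples
#' set.seed(1)
#' x <- runif(400, 2, 8)
#' y <- rbinom(400, 1, pnorm((x - 5) / 1))
#' fit_probit(x, y)
#' @export
fit_probit <- function(opacity, aware) {
  stopifnot(length(opacity) == length(aware))
  ok <- is.finite(opacity) & !is.na(aware)
  opacity <- opacity[ok]; aware <- as.integer(aware[ok])
  n <- length(opacity)
  bad <- function() structure(list(mu = NA_real_, sigma = NA_real_,
                                   se_mu = NA_real_, se_sigma = NA_real_,
                                   converged = FALSE, increasing = NA,
                                   n = n),
                              class = "probit_fit")
  if (n < 3 || length(unique(opacity)) < 2 || length(unique(aware)) < 2) {
    return(bad())
  }
  fit <- suppressWarnings(
    stats::glm(aware ~ opacity, family = stats::binomial(link = "probit")))
  co <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  slope <- co[["opacity"]]
  if (!all(is.finite(co)) || slope == 0) return(bad())
  mu <- -co[[1]] / slope
  sigma <- 1 / slope
  V <- stats::vcov(fit)
  # delta method for mu = -b0/b1 and sigma = 1/b1
  g_mu <- c(-1 / slope, co[[1]] / slope^2)
  se_mu <- suppressWarnings(sqrt(drop(t(g_mu) %*% V %*% g_mu)))
  se_sigma <- se[2] / slope^2
  # separation shows up as diverging coefficients / exploding SEs; the point
  # estimate (by symmetry often still reasonable) is kept, but flagged
  separated <- !fit$converged || !all(is.finite(se)) ||
    abs(slope) > 1e3 || se[2] > 1e2 * max(abs(slope), 1e-12)
  structure(list(mu = mu, sigma = sigma, se_mu = se_mu,
                 se_sigma = se_sigma,
                 converged = !separated && is.finite(mu) && slope > 0,
                 increasing = slope > 0, n = n),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Probit psychometric fit: NOT converged (n = %d)\n", x$n))
  } else {
    cat(sprintf("Probit psychometric fit (n = %d): mu = %.3f (SE %.3f), sigma = %.3f (SE %.3f)\n",
                x$n, x$mu, x$se_mu, x$sigma, x$se_sigma))
  }
  invisible(x)
}

#' Predicted probability of an aware response
#'
#' @param object A converged \code{\link{fit_probit}} fit.
#' @param newdata Numeric vector of opacities (or a data frame with an
#'   \code{opacity} column).
#' @param ... Unused.
#' @return P(aware) at the given opacities.
#' @export
predict.probit_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$opacity else newdata
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  stats::pnorm((x - object$mu) / object$sigma)
}
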