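#' Logistic regression by iteratively re-weighted least squares
#'
#' Maximum-likelihood logistic regression fitted by IRLS with step-halving,
#' written against the deviance DEV = -2 ln L(theta).  The design matrix is
#' taken as-is (callers include the intercept column); rank deficiency is an
#' error naming the collinear columns, and apparent complete separation is
#' flagged rather than silently returned.
#'
#' @param design Numeric matrix including the intercept column.
#' @param y Binary 0/1 response vector.
#' @param tol Convergence tolerance on the deviance change, default 1e-10.
#' @param max_iter Maximum IRLS iterations, default 100.
#' @return List with \code{coefficients}, \code{deviance}, \code{fitted},
#'   \code{vcov} (inverse observed information), \code{converged},
#'   \code{iterations} and \code{flags} (character vector, possibly empty).
#' @export
fit_logistic_irls <- function(design, y, tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(design)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("fit_logistic_irls: y must be 0/1")
  if (nrow(X) != length(y)) stop("fit_logistic_irls: dimension mismatch")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- qx$pivot[(qx$rank + 1L):ncol(X)]
    nm <- colnames(X)
    nm <- if (is.null(nm)) paste0("col", dropped) else nm[dropped]
    stop("fit_logistic_irls: design is rank-deficient; collinear column(s): ",
         paste(nm, collapse = ", "))
  }
  beta <- rep(0, ncol(X))
  dev <- logistic_deviance(X, beta, y)
  converged <- FALSE
  flags <- character(0)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    dev_new <- logistic_deviance(X, beta_new, y)
    # step-halving: the full IRLS step may overshoot far from the optimum
    halvings <- 0L
    while (!is.finite(dev_new) || dev_new > dev + 1e-12) {
      if (halvings >= 30L) break
      beta_new <- (beta + beta_new) / 2
      dev_new <- logistic_deviance(X, beta_new, y)
      halvings <- halvings + 1L
    }
    delta <- abs(dev - dev_new)
    beta <- beta_new
    dev <- dev_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  if (!converged) {
    flags <- c(flags, "not_converged")
    if (max(abs(eta)) > 25)
      flags <- c(flags, "possible_separation")
    warning("IRLS did not converge in ", max_iter, " iterations",
            if ("possible_separation" %in% flags)
              " (possible complete separation; coefficients capped)" else "")
  } else if (max(abs(eta)) > 25 && dev < 1e-6) {
    flags <- c(flags, "possible_separation")
  }
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_,
    ncol(X), ncol(X)))
  list(coefficients = unname(beta), deviance = dev, fitted = mu,
       vcov = vc, converged = converged, iterations = iter, flags = flags)
}

# DEV = -2 sum[y*eta - ln(1 + e^eta)], overflow-safe
logistic_deviance <- function(X, beta, y) {
  eta <- drop(X %*% beta)
  -2 * sum(y * eta - log1pexp(eta))
}

log1pexp <- function(x) {
  out <- x
  lo <- x <= 30
  out[lo] <- log1p(exp(x[lo]))
  out
}

#' Likelihood-ratio test between nested logistic models
#'
#' Upper-tail chi-square probability of the deviance difference.
#'
#' @param dev_small Deviance of the smaller (nested) model.
#' @param dev_big Deviance of the larger model; must not exceed
#'   \code{dev_small} beyond numerical tolerance.
#' @param df Degrees of freedom (number of extra parameters), >= 1.
#' @return P-value.
#' @export
deviance_test <- function(dev_small, dev_big, df) {
  stopifnot(df >= 1)
  diff <- dev_small - dev_big
  if (diff < -1e-6)
    stop("deviance_test: larger model has higher deviance (", dev_big,
         " > ", dev_small, "); models are not nested or a fit failed")
  stats::pchisq(max(diff, 0), df = df, lower.tail = FALSE)
}
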