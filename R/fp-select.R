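#' @title Fractional-polynomial logistic aggregation model
#' @description Internal representation: per-covariate transforms (form,
#'   powers, positivity shift, overflow-guard scale), optional interaction
#'   pairs, coefficients and the cycle-by-cycle selection trace.
#' @name fp_logistic_model
NULL

new_transform <- function(form = "linear", powers = numeric(0),
                          shift = 0, scale = 1, xmin = NA_real_) {
  list(form = form, powers = powers, shift = shift, scale = scale,
       xmin = xmin)
}

basis_width <- function(tr) {
  switch(tr$form, omitted = 0L, linear = 1L, FP1 = 1L, FP2 = 2L)
}

variable_basis <- function(xs, tr) {
  switch(tr$form,
         omitted = NULL,
         linear = cbind(xs),
         FP1 = fp_basis(xs, tr$powers),
         FP2 = fp_basis(xs, tr$powers))
}

build_design <- function(Xs, transforms, interactions = list()) {
  cols <- list(`(Intercept)` = rep(1, length(Xs[[1L]])))
  first_col <- vector("list", length(Xs))
  for (j in seq_along(Xs)) {
    b <- variable_basis(Xs[[j]], transforms[[j]])
    if (is.null(b)) next
    first_col[[j]] <- b[, 1L]
    nm <- paste0("d", j, ".", seq_len(ncol(b)))
    for (c_ in seq_len(ncol(b))) cols[[nm[c_]]] <- b[, c_]
  }
  for (pr in interactions) {
    i <- pr[1L]; j <- pr[2L]
    if (is.null(first_col[[i]]) || is.null(first_col[[j]]))
      stop("interaction (", i, ",", j, ") references an omitted variable")
    cols[[paste0("d", i, ":d", j)]] <- first_col[[i]] * first_col[[j]]
  }
  do.call(cbind, cols)
}

fit_fp_model <- function(Xs, y, transforms, interactions = list(),
                         quiet = TRUE) {
  X <- build_design(Xs, transforms, interactions)
  f <- function() fit_logistic_irls(X, y)
  res <- tryCatch(if (quiet) suppressWarnings(f()) else f(),
                  error = function(e) NULL)
  if (is.null(res))
    return(list(deviance = Inf, coefficients = NULL, ok = FALSE))
  res$ok <- TRUE
  res$colnames <- colnames(X)
  res
}

#' Select a variable's fractional-polynomial form by the closed test
#'
#' With every other covariate held at its current transform, evaluates the
#' null (variable omitted), the straight line, the best first-degree
#' polynomial over the 8 candidate powers and the best second-degree
#' polynomial over the 36 power pairs, then applies the closed test at
#' level alpha: FP2 vs null on 4 df (not significant: omit), FP2 vs linear
#' on 3 df (not significant: keep linear), FP2 vs best FP1 on 2 df
#' (significant: FP2, else FP1).
#'
#' @param Xs List of shifted, scaled covariate vectors.
#' @param y Binary response.
#' @param transforms Current transform list (one per covariate).
#' @param j Index of the variable to re-select.
#' @param alpha Test level, default 0.05.
#' @param interactions Interaction pairs kept fixed during the scan.
#' @return List with \code{transform} (the chosen one) and \code{trace}
#'   (data frame: form, powers, deviance of the four candidate rows).
#' @export
select_fp_for_variable <- function(Xs, y, transforms, j, alpha = 0.05,
                                   interactions = list()) {
  tr_with <- function(form, powers = numeric(0)) {
    t2 <- transforms
    t2[[j]] <- modifyList(transforms[[j]],
                          list(form = form, powers = powers))
    t2
  }
  dev_of <- function(form, powers = numeric(0)) {
    fit_fp_model(Xs, y, tr_with(form, powers), interactions)$deviance
  }
  dev_null <- dev_of("omitted")
  dev_linear <- dev_of("linear")
  fp1 <- vapply(FP_POWERS, function(p) dev_of("FP1", p), numeric(1))
  best1 <- which.min(fp1)
  pairs <- fp2_power_pairs()
  fp2 <- vapply(seq_len(nrow(pairs)), function(i)
    dev_of("FP2", c(pairs$p[i], pairs$q[i])), numeric(1))
  best2 <- which.min(fp2)
  p2 <- c(pairs$p[best2], pairs$q[best2])

  choice <-
    if (deviance_test(dev_null, fp2[best2], 4) >= alpha) {
      list(form = "omitted", powers = numeric(0))
    } else if (deviance_test(dev_linear, fp2[best2], 3) >= alpha) {
      list(form = "linear", powers = numeric(0))
    } else if (deviance_test(fp1[best1], fp2[best2], 2) < alpha) {
      list(form = "FP2", powers = p2)
    } else {
      list(form = "FP1", powers = FP_POWERS[best1])
    }
  trace <- data.frame(
    form = c("omitted", "linear", "FP1", "FP2"),
    p = c(NA, 1, FP_POWERS[best1], p2[1L]),
    q = c(NA, NA, NA, p2[2L]),
    deviance = c(dev_null, dev_linear, fp1[best1], fp2[best2]))
  list(transform = modifyList(transforms[[j]], choice), trace = trace)
}

#' Multivariable fractional-polynomial cycles
#'
#' Fits the aggregating logistic regression over the signed-distance
#' covariates, re-selecting every covariate's fractional-polynomial form in
#' cycles until a full cycle changes nothing (or \code{max_cycles} is
#' reached).  Variables are processed in order of increasing p-value of
#' their uni-variate linear fits.  Every covariate is first shifted to
#' strictly positive values and, when its spread is extreme, rescaled by a
#' power of ten.
#'
#' @param d Numeric N x m covariate matrix (m = 3 for the three SVMs).
#' @param y Binary 0/1 response vector.
#' @param alpha Closed-test level, default 0.05.
#' @param max_cycles Cycle cap, default 5.
#' @param interaction_screen Run \code{\link{screen_interactions}} after the
#'   main-effects model converges (default FALSE).
#' @return An object of class \code{fp_logistic_model}.
#' @export
run_mfp_cycles <- function(d, y, alpha = 0.05, max_cycles = 5L,
                           interaction_screen = FALSE) {
  d <- as.matrix(d)
  m <- ncol(d)
  y <- as.numeric(y)
  stopifnot(nrow(d) == length(y), all(y %in% c(0, 1)), m >= 1L)
  var_names <- if (is.null(colnames(d))) paste0("d", seq_len(m)) else colnames(d)

  transforms <- vector("list", m)
  Xs <- vector("list", m)
  for (j in seq_len(m)) {
    sp <- shift_to_positive(d[, j])
    sc <- fp_scale_factor(sp$x)
    xs <- sp$x / sc
    Xs[[j]] <- xs
    transforms[[j]] <- new_transform(form = "linear", shift = sp$shift,
                                     scale = sc, xmin = min(xs))
  }

  # uni-variate screening orders the processing of variables
  ones <- cbind(rep(1, length(y)))
  dev0 <- suppressWarnings(fit_logistic_irls(ones, y))$deviance
  uni_p <- vapply(seq_len(m), function(j) {
    fit <- suppressWarnings(fit_logistic_irls(cbind(1, Xs[[j]]), y))
    deviance_test(dev0, fit$deviance, 1)
  }, numeric(1))
  ord <- order(uni_p)

  trace <- NULL
  cycle_deviance <- numeric(0)
  cycles_run <- 0L
  form_converged <- FALSE
  for (cyc in seq_len(max_cycles)) {
    cycles_run <- cyc
    changed <- FALSE
    for (j in ord) {
      sel <- select_fp_for_variable(Xs, y, transforms, j, alpha)
      if (!identical(sel$transform$form, transforms[[j]]$form) ||
          !identical(sel$transform$powers, transforms[[j]]$powers))
        changed <- TRUE
      transforms[[j]] <- sel$transform
      trace <- rbind(trace, cbind(cycle = cyc, variable = var_names[j],
                                  sel$trace))
    }
    cycle_deviance <- c(cycle_deviance,
                        fit_fp_model(Xs, y, transforms)$deviance)
    if (!changed) { form_converged <- TRUE; break }
  }
  if (!form_converged)
    warning("run_mfp_cycles: transforms still changing after ", max_cycles,
            " cycles; returning the last state")

  final <- fit_fp_model(Xs, y, transforms, quiet = FALSE)
  model <- structure(
    list(transforms = transforms, var_names = var_names,
         interactions = list(), coefficients = final$coefficients,
         coef_names = final$colnames, deviance = final$deviance,
         vcov = final$vcov, alpha = alpha, cycles_run = cycles_run,
         form_converged = form_converged, trace = trace,
         cycle_deviance = cycle_deviance, uni_p = uni_p, n = length(y)),
    class = "fp_logistic_model")
  if (interaction_screen) model <- screen_interactions(model, d, y, alpha)
  model
}

shifted_scaled <- function(model, d, clamp = TRUE) {
  d <- as.matrix(d)
  if (ncol(d) != length(model$transforms))
    stop("expected ", length(model$transforms), " covariates, got ", ncol(d))
  lapply(seq_len(ncol(d)), function(j) {
    tr <- model$transforms[[j]]
    xs <- (d[, j] + tr$shift) / tr$scale
    if (clamp && tr$form %in% c("FP1", "FP2")) {
      bad <- xs <= 0
      if (any(bad)) {
        warning("covariate ", model$var_names[j], ": ", sum(bad),
                " value(s) non-positive after the stored shift; clamped to ",
                "the training minimum")
        xs[bad] <- tr$xmin
      }
    }
    xs
  })
}

#' Screen pairwise interactions of the aggregated covariates
#'
#' Adds, one at a time, the product of each pair of (transformed,
#' first-basis-column) covariates to the main-effects model and keeps pairs
#' significant by a 1-df likelihood-ratio test.  The model with all kept
#' interactions is then refit and each interaction re-checked by both Wald
#' and LR tests in the joint model; non-significant ones are dropped once.
#'
#' @param model A fitted \code{fp_logistic_model} (main effects).
#' @param d The training covariate matrix.
#' @param y The training response.
#' @param alpha Test level, default 0.05.
#' @return The updated \code{fp_logistic_model}.
#' @export
screen_interactions <- function(model, d, y, alpha = 0.05) {
  Xs <- shifted_scaled(model, d, clamp = FALSE)
  y <- as.numeric(y)
  active <- which(vapply(model$transforms, function(t) t$form != "omitted",
                         TRUE))
  if (length(active) < 2L) return(model)
  prs <- utils::combn(active, 2L, simplify = FALSE)
  dev_main <- fit_fp_model(Xs, y, model$transforms)$deviance
  kept <- Filter(function(pr) {
    dev1 <- fit_fp_model(Xs, y, model$transforms, list(pr))$deviance
    deviance_test(dev_main, dev1, 1) < alpha
  }, prs)
  if (length(kept)) {
    joint <- fit_fp_model(Xs, y, model$transforms, kept)
    keep2 <- vapply(seq_along(kept), function(i) {
      without <- fit_fp_model(Xs, y, model$transforms, kept[-i])$deviance
      lr_p <- deviance_test(without, joint$deviance, 1)
      col <- match(paste0("d", kept[[i]][1], ":d", kept[[i]][2]),
                   joint$colnames)
      z <- joint$coefficients[col] / sqrt(joint$vcov[col, col])
      wald_p <- 2 * stats::pnorm(-abs(z))
      lr_p < alpha && wald_p < alpha
    }, TRUE)
    kept <- kept[keep2]
  }
  final <- fit_fp_model(Xs, y, model$transforms, kept, quiet = FALSE)
  model$interactions <- kept
  model$coefficients <- final$coefficients
  model$coef_names <- final$colnames
  model$deviance <- final$deviance
  model$vcov <- final$vcov
  model
}

#' Predict beta-turn probabilities from an FP logistic model
#'
#' Applies the stored per-covariate shifts and scales to new signed
#' distances, clamps values that fall non-positive under a log or
#' fractional power to the training minimum (with a warning), and returns
#' the inverse-logit of the linear predictor.
#'
#' @param object A \code{fp_logistic_model}.
#' @param newdata Numeric N x m matrix of signed distances.
#' @param type \code{"response"} (probabilities, default) or \code{"link"}.
#' @param ... Unused.
#' @return Numeric vector; probabilities are strictly inside (0, 1).
#' @export
predict.fp_logistic_model <- function(object, newdata,
                                      type = c("response", "link"), ...) {
  type <- match.arg(type)
  Xs <- shifted_scaled(object, newdata)
  X <- build_design(Xs, object$transforms, object$interactions)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.fp_logistic_model <- function(x, ...) {
  cat("Fractional-polynomial logistic model (", x$n, " examples, ",
      x$cycles_run, " cycle(s)", if (!x$form_converged) ", not settled",
      ")\n", sep = "")
  for (j in seq_along(x$transforms)) {
    tr <- x$transforms[[j]]
    cat("  ", x$var_names[j], ": ", tr$form,
        if (length(tr$powers)) paste0(" (", paste(tr$powers, collapse = ", "),
                                      ")"),
        "  [shift ", signif(tr$shift, 4), ", scale ", tr$scale, "]\n",
        sep = "")
  }
  if (length(x$interactions))
    cat("  interactions:",
        paste(vapply(x$interactions, function(p)
          paste0(x$var_names[p[1]], ":", x$var_names[p[2]]), ""),
          collapse = ", "), "\n")
  cat("  deviance:", format(x$deviance, digits = 10), "\n")
  invisible(x)
}

#' Per-cycle selection trace in tabular form
#'
#' One row per candidate form evaluated while each variable was processed:
#' cycle, variable, form, powers and model deviance.  \code{write_fp_trace}
#' writes it as TSV.
#'
#' @param model A \code{fp_logistic_model}.
#' @return Data frame.
#' @export
fp_trace_table <- function(model) model$trace

#' @rdname fp_trace_table
#' @param path Output TSV path.
#' @export
write_fp_trace <- function(model, path) {
  utils::write.table(fp_trace_table(model), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
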