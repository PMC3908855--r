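#' Partition negative examples with k-means
#'
#' The non-turn class is split into \code{k} clusters in the encoded feature
#' space ("original variables": the features are already in [0, 1], so no
#' further standardization is applied).  A seeded multi-restart
#' (\code{nstart = 10}) Hartigan-Wong k-means is used, so the partition is
#' deterministic given the seed.
#'
#' @param features Numeric matrix of the negative examples only.
#' @param k Number of clusters, default 3.
#' @param seed Integer seed.
#' @param nstart Number of random restarts, default 10.
#' @return A \code{cluster_partition}: list with \code{k}, \code{centers}
#'   (k x F), \code{assignment} (cluster index per row), \code{sizes},
#'   \code{seed}.
#' @export
cluster_negatives <- function(features, k = 3L, seed = 1L, nstart = 10L) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("cluster_negatives: no negative examples")
  k <- as.integer(k)
  n_distinct <- nrow(unique(features))
  if (n_distinct < k)
    stop("cluster_negatives: only ", n_distinct,
         " distinct negative examples but k = ", k)
  set.seed(seed)
  km <- if (k == 1L) {
    ctr <- matrix(colMeans(features), nrow = 1L)
    list(centers = ctr, cluster = rep(1L, nrow(features)),
         size = nrow(features))
  } else {
    stats::kmeans(features, centers = k, nstart = nstart, iter.max = 100L)
  }
  if (any(km$size == 0L))
    stop("cluster_negatives: k-means produced an empty cluster; ",
         "try a smaller k")
  structure(
    list(k = k, centers = unname(km$centers),
         assignment = as.integer(km$cluster),
         sizes = as.integer(km$size), seed = as.integer(seed)),
    class = "cluster_partition")
}

#' Build the balanced sub-training sets
#'
#' Merges all positive examples with each negative cluster.  When the
#' negatives split roughly evenly across k = 3 clusters of a 1:3
#' positive:negative dataset, each subset is approximately class-balanced.
#'
#' @param dataset An \code{encoded_dataset} with labels.
#' @param partition A \code{\link{cluster_negatives}} partition of exactly
#'   this dataset's negative examples (in dataset row order).
#' @return List of k subsets, each a list with \code{features} and
#'   \code{labels}.
#' @export
build_subtraining_sets <- function(dataset, partition) {
  stopifnot(inherits(dataset, "encoded_dataset"),
            inherits(partition, "cluster_partition"))
  if (is.null(dataset$labels)) stop("dataset has no labels")
  neg_idx <- which(dataset$labels == 0L)
  pos_idx <- which(dataset$labels == 1L)
  if (length(partition$assignment) != length(neg_idx))
    stop("partition covers ", length(partition$assignment),
         " negatives but the dataset has ", length(neg_idx))
  lapply(seq_len(partition$k), function(j) {
    rows <- c(pos_idx, neg_idx[partition$assignment == j])
    list(features = dataset$features[rows, , drop = FALSE],
         labels = dataset$labels[rows])
  })
}

#' SVM hyper-parameter grid
#'
#' Defaults to the canonical LIBSVM grid, C in 2^(-5, -3, ..., 15) and
#' gamma in 2^(-15, -13, ..., 3).  Tests and quick runs use
#' \code{coarse = TRUE}, a 2 x 2 sub-grid.
#'
#' @param cost Vector of candidate C values.
#' @param gamma Vector of candidate RBF gamma values.
#' @param coarse If TRUE, return the small default grid for fast runs.
#' @return List with \code{cost} and \code{gamma} vectors.
#' @export
svm_grid <- function(cost = 2^seq(-5, 15, by = 2),
                     gamma = 2^seq(-15, 3, by = 2),
                     coarse = FALSE) {
  if (coarse) {
    cost <- 2^c(0, 5)
    gamma <- 2^c(-7, -3)
  }
  stopifnot(all(cost > 0), all(gamma > 0))
  list(cost = sort(unique(cost)), gamma = sort(unique(gamma)))
}

tune_rbf_svm <- function(features, labels, grid, seed, inner_folds = 5L) {
  y <- factor(ifelse(labels == 1L, "1", "-1"), levels = c("1", "-1"))
  if (nlevels(droplevels(y)) < 2L)
    stop("SVM training subset contains a single class")
  n <- length(y)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(inner_folds), n))
  combos <- expand.grid(gamma = grid$gamma, cost = grid$cost,
                        KEEP.OUT.ATTRS = FALSE)
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    hits <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      m <- e1071::svm(features[tr, , drop = FALSE], y[tr],
                      kernel = "radial", cost = combos$cost[i],
                      gamma = combos$gamma[i], scale = FALSE)
      hits <- hits + sum(predict(m, features[!tr, , drop = FALSE]) == y[!tr])
    }
    hits / n
  }, numeric(1))
  # ties broken toward the smallest C, then the smallest gamma
  ord <- order(-acc, combos$cost, combos$gamma)
  best <- combos[ord[1L], ]
  model <- e1071::svm(features, y, kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = FALSE)
  # e1071 signs decision values toward whichever label LIBSVM saw first;
  # record a flip so that positive always means beta-turn
  dv <- attr(predict(model, features[1L, , drop = FALSE],
                     decision.values = TRUE), "decision.values")
  flip <- if (colnames(dv)[1L] == "1/-1") 1 else -1
  list(model = model, cost = best$cost, gamma = best$gamma,
       cv_accuracy = acc[ord[1L]], flip = flip,
       n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
       w_norm = svm_w_norm(model))
}

# ||w|| in the kernel-induced space: sqrt(a' K a) with a the signed dual
# coefficients over the support vectors
svm_w_norm <- function(model) {
  a <- as.numeric(model$coefs)
  sv <- as.matrix(model$SV)
  d2 <- as.matrix(stats::dist(sv))^2
  K <- exp(-model$gamma * d2)
  sqrt(max(drop(t(a) %*% K %*% a), .Machine$double.eps))
}

#' Train the three localized SVMs
#'
#' For each cluster-versus-positives subset independently, (C, gamma) is
#' chosen by seeded internal cross-validated accuracy over the grid (ties
#' resolved toward the smallest C, then the smallest gamma) and the final
#' model is refit on the whole subset with the chosen pair.
#'
#' @param subsets List of subsets from \code{\link{build_subtraining_sets}}.
#' @param grid Grid from \code{\link{svm_grid}}.
#' @param seed Integer seed for the internal CV shuffles.
#' @param inner_folds Internal CV fold count, default 5.
#' @param partition Optional \code{cluster_partition} stored alongside the
#'   models.
#' @return A \code{local_svm_ensemble}: the trained models, per-model tuning
#'   metadata and the cluster partition.
#' @export
train_local_svms <- function(subsets, grid = svm_grid(coarse = TRUE),
                             seed = 1L, inner_folds = 5L, partition = NULL) {
  fits <- lapply(seq_along(subsets), function(j) {
    s <- subsets[[j]]
    tune_rbf_svm(s$features, s$labels, grid, seed = seed + j, inner_folds)
  })
  structure(
    list(models = lapply(fits, `[[`, "model"),
         flips = vapply(fits, `[[`, numeric(1), "flip"),
         w_norms = vapply(fits, `[[`, numeric(1), "w_norm"),
         tuning = do.call(rbind, lapply(fits, function(f)
           data.frame(cost = f$cost, gamma = f$gamma,
                      cv_accuracy = f$cv_accuracy,
                      n_pos = f$n_pos, n_neg = f$n_neg))),
         partition = partition,
         n_features = ncol(subsets[[1L]]$features),
         grid = grid, seed = as.integer(seed)),
    class = "local_svm_ensemble")
}

#' Train one SVM on the pooled (un-clustered) data
#'
#' The baseline the clustered ensemble is designed to beat: a single RBF
#' SVM tuned on the full imbalanced training set.
#'
#' @inheritParams train_local_svms
#' @param dataset An \code{encoded_dataset} with labels.
#' @return List with the fitted model, tuning metadata and a
#'   \code{decision_values(features)} closure (positive = beta-turn).
#' @export
train_pooled_svm <- function(dataset, grid = svm_grid(coarse = TRUE),
                             seed = 1L, inner_folds = 5L) {
  fit <- tune_rbf_svm(dataset$features, dataset$labels, grid,
                      seed = seed, inner_folds = inner_folds)
  fit$decision_values <- function(features) {
    dv <- attr(predict(fit$model, as.matrix(features),
                       decision.values = TRUE), "decision.values")
    fit$flip * as.numeric(dv[, 1L])
  }
  fit
}

#' Cross-fitted signed distances for the aggregation stage
#'
#' Decision values of the localized SVMs on their own training residues are
#' optimistic (every positive sits in every subset), and a logistic
#' regression fit on them learns distorted weights.  For fitting the
#' aggregating model, the distance matrix is therefore cross-fitted in the
#' stacking convention: residues are split into K seeded folds, and each
#' fold's distances come from SVMs retrained without that fold, using the
#' (C, gamma) already tuned on the full subsets.  The cluster partition and
#' the final prediction-time SVMs are untouched.
#'
#' @param dataset The training \code{encoded_dataset} (with labels).
#' @param ensemble The \code{local_svm_ensemble} trained on all of it.
#' @param n_folds Number of cross-fit folds, default 3.
#' @param seed Integer seed for the fold split.
#' @param normalize Divide by each fold-model's kernel-space ||w||.
#' @return Numeric N x k matrix of out-of-fold signed distances.
#' @export
crossfit_distances <- function(dataset, ensemble, n_folds = 3L, seed = 1L,
                               normalize = FALSE) {
  stopifnot(inherits(dataset, "encoded_dataset"),
            inherits(ensemble, "local_svm_ensemble"))
  part <- ensemble$partition
  if (is.null(part)) stop("ensemble carries no cluster partition")
  N <- nrow(dataset$features)
  pos_idx <- which(dataset$labels == 1L)
  neg_idx <- which(dataset$labels == 0L)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), N))
  d <- matrix(NA_real_, N, part$k)
  for (f in seq_len(n_folds)) {
    hold <- fold == f
    for (j in seq_len(part$k)) {
      rows <- c(pos_idx, neg_idx[part$assignment == j])
      rows <- rows[!hold[rows]]
      ylab <- factor(ifelse(dataset$labels[rows] == 1L, "1", "-1"),
                     levels = c("1", "-1"))
      if (nlevels(droplevels(ylab)) < 2L)
        stop("crossfit_distances: a cross-fit subset lost a class; ",
             "use fewer folds")
      m <- e1071::svm(dataset$features[rows, , drop = FALSE], ylab,
                      kernel = "radial",
                      cost = ensemble$tuning$cost[j],
                      gamma = ensemble$tuning$gamma[j], scale = FALSE)
      dv <- attr(predict(m, dataset$features[hold, , drop = FALSE],
                         decision.values = TRUE), "decision.values")
      v <- as.numeric(dv[, 1L]) * (if (colnames(dv)[1L] == "1/-1") 1 else -1)
      if (normalize) v <- v / svm_w_norm(m)
      d[hold, j] <- v
    }
  }
  d
}

#' Signed decision values of the three localized SVMs
#'
#' Every example passes through all three models; column j holds model j's
#' decision value (kernel expansion over its support vectors plus bias),
#' signed so that positive means the beta-turn side.  With
#' \code{normalize = TRUE} each column is divided by that model's
#' kernel-space ||w||, turning decision values into geometric margins.
#'
#' @param ensemble A \code{local_svm_ensemble}.
#' @param features Numeric matrix, N x F with F as at training.
#' @param normalize Divide by the kernel-space norm of w (default FALSE:
#'   raw decision values).
#' @return Numeric N x 3 matrix of signed distances.
#' @export
signed_distances <- function(ensemble, features, normalize = FALSE) {
  stopifnot(inherits(ensemble, "local_svm_ensemble"))
  features <- as.matrix(features)
  if (ncol(features) != ensemble$n_features)
    stop("feature width ", ncol(features), " does not match the ensemble's ",
         ensemble$n_features)
  d <- vapply(seq_along(ensemble$models), function(j) {
    dv <- attr(predict(ensemble$models[[j]], features,
                       decision.values = TRUE), "decision.values")
    v <- ensemble$flips[j] * as.numeric(dv[, 1L])
    if (normalize) v / ensemble$w_norms[j] else v
  }, numeric(nrow(features)))
  matrix(d, nrow = nrow(features), ncol = length(ensemble$models))
}
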