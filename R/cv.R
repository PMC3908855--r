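#' Assign proteins to cross-validation folds
#'
#' Protein-level folds: all residues of a chain stay together, fold sizes
#' differ by at most one protein, and a seeded greedy pass balances each
#' fold's beta-turn residue count toward the global fraction (approximate
#' stratification; exact per-fold 25% is impossible with whole chains).
#'
#' @param proteins List of \code{\link{protein_record}} objects.
#' @param n_folds Number of folds, default 7.
#' @param seed Integer seed.
#' @return Integer vector of fold indices (1..n_folds), one per protein, in
#'   input order; names are protein ids.
#' @export
make_protein_folds <- function(proteins, n_folds = 7L, seed = 1L) {
  n <- length(proteins)
  n_folds <- as.integer(n_folds)
  if (n < n_folds)
    stop("make_protein_folds: ", n, " proteins but ", n_folds, " folds")
  capacity <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0L) capacity[seq_len(extra)] <- capacity[seq_len(extra)] + 1L
  pos <- vapply(proteins, function(p)
    if (is.null(p$labels)) 0L else sum(p$labels), integer(1))
  set.seed(seed)
  perm <- sample.int(n)
  ord <- perm[order(-pos[perm])]   # big-positive chains placed first
  fold <- integer(n)
  fold_n <- integer(n_folds)
  fold_pos <- numeric(n_folds)
  for (i in ord) {
    open <- which(fold_n < capacity)
    pick <- open[order(fold_pos[open], fold_n[open], open)][1L]
    fold[i] <- pick
    fold_n[pick] <- fold_n[pick] + 1L
    fold_pos[pick] <- fold_pos[pick] + pos[i]
  }
  names(fold) <- vapply(proteins, `[[`, character(1), "id")
  attr(fold, "seed") <- as.integer(seed)
  fold
}

#' Protein-level cross-validation of the full pipeline
#'
#' For each fold the entire method - negative-class clustering, the three
#' localized SVMs with their grid search, and fractional-polynomial
#' logistic-regression selection - is fit on the remaining folds only, and
#' the held-out fold is predicted.  Per-fold measures, their unweighted
#' mean (the headline numbers) and pooled-count measures are all reported.
#'
#' @param proteins Labeled \code{\link{protein_record}} list.
#' @param config A \code{\link{hsvmlr_config}}.
#' @param loo Leave-one-protein-out instead of \code{config$n_folds} folds
#'   (default FALSE).
#' @return A \code{metrics_report}: list with \code{per_fold} (data frame),
#'   \code{mean} (averaged row), \code{pooled} (metrics from pooled
#'   counts), \code{pooled_counts}, \code{roc}, \code{auc} (pooled),
#'   \code{folds}, \code{config}.
#' @export
cross_validate <- function(proteins, config, loo = FALSE) {
  stopifnot(inherits(config, "hsvmlr_config"))
  if (any(vapply(proteins, function(p) is.null(p$labels), TRUE)))
    stop("cross_validate: all proteins must carry labels")
  n_folds <- if (loo) length(proteins) else config$n_folds
  folds <- make_protein_folds(proteins, n_folds, seed = config$seed + 7000L)
  per_fold <- NULL
  all_prob <- numeric(0)
  all_true <- integer(0)
  pooled <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in seq_len(n_folds)) {
    train_p <- proteins[folds != f]
    test_p <- proteins[folds == f]
    if (sum(vapply(train_p, function(p) sum(p$labels), integer(1))) == 0L)
      stop("cross_validate: training folds for fold ", f, " lack positives")
    bundle <- hsvmlr_train(train_p, config, stage_seed = config$seed + f)
    pred <- predict(bundle, test_p)
    y_true <- unlist(lapply(test_p, `[[`, "labels"), use.names = FALSE)
    cc <- confusion_counts(y_true, pred$label)
    met <- compute_metrics(cc)
    auc_f <- if (length(unique(y_true)) == 2L)
      roc_auc(y_true, pred$prob)$auc else NA_real_
    per_fold <- rbind(per_fold, data.frame(
      fold = f, n_proteins = length(test_p), n_residues = length(y_true),
      Qtotal = met$Qtotal, Qpredicted = met$Qpredicted,
      Qobserved = met$Qobserved, MCC = met$MCC, AUC = auc_f))
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
    all_prob <- c(all_prob, pred$prob)
    all_true <- c(all_true, y_true)
  }
  mean_row <- colMeans(per_fold[, c("Qtotal", "Qpredicted", "Qobserved",
                                    "MCC", "AUC")], na.rm = TRUE)
  roc_pooled <- roc_auc(all_true, all_prob)
  structure(
    list(per_fold = per_fold, mean = as.list(mean_row),
         pooled = compute_metrics(pooled), pooled_counts = pooled,
         roc = roc_pooled$roc, auc = roc_pooled$auc, folds = folds,
         config = config),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Cross-validated beta-turn prediction (", nrow(x$per_fold),
      " folds)\n", sep = "")
  print(x$per_fold, row.names = FALSE, digits = 4)
  cat("fold-averaged: Qtotal ", round(x$mean$Qtotal, 2),
      "  Qpredicted ", round(x$mean$Qpredicted, 2),
      "  Qobserved ", round(x$mean$Qobserved, 2),
      "  MCC ", round(x$mean$MCC, 4),
      "  AUC ", round(x$mean$AUC, 4), "\n", sep = "")
  cat("pooled:        Qtotal ", round(x$pooled$Qtotal, 2),
      "  MCC ", round(x$pooled$MCC, 4),
      "  AUC ", round(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Emits \code{metrics.tsv} (per-fold rows plus the averaged row),
#' \code{metrics.json} and \code{roc.tsv} under \code{dir}.
#'
#' @param report A \code{metrics_report}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$per_fold
  avg <- data.frame(fold = NA, n_proteins = sum(tab$n_proteins),
                    n_residues = sum(tab$n_residues),
                    Qtotal = report$mean$Qtotal,
                    Qpredicted = report$mean$Qpredicted,
                    Qobserved = report$mean$Qobserved,
                    MCC = report$mean$MCC, AUC = report$mean$AUC)
  utils::write.table(rbind(tab, avg), file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(per_fold = tab, mean = report$mean,
         pooled = report$pooled[c("Qtotal", "Qpredicted", "Qobserved", "MCC")],
         pooled_counts = report$pooled_counts, auc_pooled = report$auc),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(report$roc, file.path(dir, "roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
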