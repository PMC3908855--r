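#' Run configuration for the hybrid predictor
#'
#' Collects every tunable of the pipeline in one validated object; it is
#' stored inside every model bundle and report so runs are reproducible
#' from the artifact alone.
#'
#' @param feature_mode One of \code{FEATURE_MODES}, default
#'   \code{"pssm_window_pss_window"} (the best-performing organization).
#' @param window Odd sliding-window size, default 7.
#' @param k Number of negative clusters / localized SVMs, default 3.
#' @param grid SVM (C, gamma) grid from \code{\link{svm_grid}}; the coarse
#'   grid by default.
#' @param fp_alpha Closed-test and interaction-screen level, default 0.05.
#' @param interaction_screen Screen pairwise interactions after the
#'   main-effects MFP model (default FALSE).
#' @param threshold Probability threshold for the turn/non-turn call,
#'   default 0.5.
#' @param n_folds Cross-validation folds, default 7.
#' @param inner_folds Internal CV folds of the SVM grid search, default 5.
#' @param normalize_distances Divide decision values by each model's
#'   kernel-space ||w|| (default FALSE: raw decision values).
#' @param lr_distances How the aggregating regression's training distances
#'   are computed: \code{"crossfit"} (default; out-of-fold decision values,
#'   see \code{\link{crossfit_distances}}) or \code{"insample"} (decision
#'   values of the final SVMs on their own training data).
#' @param crossfit_folds Folds for the cross-fitted distances, default 3.
#' @param seed Root seed; every stage derives its own stream from it.
#' @return A \code{hsvmlr_config} list.
#' @export
hsvmlr_config <- function(feature_mode = "pssm_window_pss_window",
                          window = 7L, k = 3L,
                          grid = svm_grid(coarse = TRUE),
                          fp_alpha = 0.05, interaction_screen = FALSE,
                          threshold = 0.5, n_folds = 7L, inner_folds = 5L,
                          normalize_distances = FALSE,
                          lr_distances = c("crossfit", "insample"),
                          crossfit_folds = 3L, seed = 1L) {
  lr_distances <- match.arg(lr_distances)
  feature_mode <- match.arg(feature_mode, FEATURE_MODES)
  window <- as.integer(window)
  stopifnot(window >= 3L, window %% 2L == 1L, k >= 1L,
            fp_alpha > 0, fp_alpha < 1, threshold > 0, threshold < 1,
            n_folds >= 2L, inner_folds >= 2L)
  structure(list(feature_mode = feature_mode, window = window,
                 k = as.integer(k), grid = grid, fp_alpha = fp_alpha,
                 interaction_screen = isTRUE(interaction_screen),
                 threshold = threshold, n_folds = as.integer(n_folds),
                 inner_folds = as.integer(inner_folds),
                 normalize_distances = isTRUE(normalize_distances),
                 lr_distances = lr_distances,
                 crossfit_folds = as.integer(crossfit_folds),
                 seed = as.integer(seed)),
            class = "hsvmlr_config")
}

#' Train the full hybrid model
#'
#' Encodes the proteins, partitions the non-turn residues into k clusters,
#' trains one localized RBF SVM per cluster-versus-turns subset, computes
#' every training example's three signed decision values, and selects and
#' fits the fractional-polynomial logistic regression that aggregates them.
#'
#' @param proteins Labeled \code{\link{protein_record}} list.
#' @param config A \code{\link{hsvmlr_config}}.
#' @param stage_seed Optional seed override for this call (used by
#'   cross-validation to give each fold its own stream); defaults to
#'   \code{config$seed}.
#' @return A \code{hsvmlr_model} bundle: cluster partition, the three SVMs,
#'   the FP-LR model, the config and the selection trace.
#' @export
hsvmlr_train <- function(proteins, config = hsvmlr_config(),
                         stage_seed = NULL) {
  stopifnot(inherits(config, "hsvmlr_config"))
  seed <- if (is.null(stage_seed)) config$seed else as.integer(stage_seed)
  ds <- encode_dataset(proteins, window = config$window,
                       mode = config$feature_mode)
  if (is.null(ds$labels)) stop("hsvmlr_train: proteins carry no labels")
  if (sum(ds$labels == 1L) == 0L) stop("hsvmlr_train: no positive examples")
  neg <- ds$features[ds$labels == 0L, , drop = FALSE]
  part <- cluster_negatives(neg, k = config$k, seed = seed + 101L)
  subsets <- build_subtraining_sets(ds, part)
  ensemble <- train_local_svms(subsets, grid = config$grid,
                               seed = seed + 202L,
                               inner_folds = config$inner_folds,
                               partition = part)
  d <- if (config$lr_distances == "crossfit")
    crossfit_distances(ds, ensemble, n_folds = config$crossfit_folds,
                       seed = seed + 303L,
                       normalize = config$normalize_distances)
  else
    signed_distances(ensemble, ds$features,
                     normalize = config$normalize_distances)
  fp <- run_mfp_cycles(d, ds$labels, alpha = config$fp_alpha,
                       interaction_screen = config$interaction_screen)
  structure(list(ensemble = ensemble, fp_model = fp, config = config,
                 seed = seed, n_train = nrow(ds$features),
                 feature_mode = config$feature_mode,
                 window = config$window),
            class = "hsvmlr_model")
}

#' Predict beta-turn probabilities for new proteins
#'
#' Each residue passes through all three localized SVMs; the aggregating
#' logistic regression turns the three signed distances into a turn
#' probability, thresholded into a 0/1 call.
#'
#' @param object A \code{hsvmlr_model}.
#' @param proteins List of \code{\link{protein_record}} objects (labels
#'   not required).
#' @param ... Unused.
#' @return Data frame with one row per residue: \code{protein_id},
#'   \code{position} (1-based), \code{prob}, \code{label}.
#' @export
predict.hsvmlr_model <- function(object, proteins, ...) {
  ds <- encode_dataset(proteins, window = object$window,
                       mode = object$feature_mode)
  d <- signed_distances(object$ensemble, ds$features,
                        normalize = object$config$normalize_distances)
  prob <- predict(object$fp_model, d)
  pos <- unlist(lapply(proteins, function(p)
    seq_len(nchar(p$sequence))), use.names = FALSE)
  data.frame(protein_id = ds$protein_ids, position = pos, prob = prob,
             label = as.integer(prob >= object$config$threshold))
}

#' @export
print.hsvmlr_model <- function(x, ...) {
  cat("Hybrid SVM + FP-logistic beta-turn model\n")
  cat("  trained on ", x$n_train, " residues (mode ", x$feature_mode,
      ", window ", x$window, ")\n", sep = "")
  cat("  localized SVMs (C, gamma, inner-CV accuracy):\n")
  t <- x$ensemble$tuning
  for (j in seq_len(nrow(t)))
    cat(sprintf("    model %d: C=%g gamma=%g acc=%.3f (%d pos / %d neg)\n",
                j, t$cost[j], t$gamma[j], t$cv_accuracy[j], t$n_pos[j],
                t$n_neg[j]))
  print(x$fp_model)
  invisible(x)
}

#' Save / load a model bundle directory
#'
#' The bundle directory holds the serialized model plus a JSON snapshot of
#' the config and tuning metadata for inspection; the format is versioned.
#'
#' @param model A \code{hsvmlr_model}.
#' @param dir Bundle directory (created if needed).
#' @return \code{dir} (or, for load, the model), invisibly.
#' @export
save_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "hsvmlr_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(format_version = 1L,
         config = unclass(model$config)[setdiff(names(model$config), "grid")],
         grid = model$config$grid, seed = model$seed,
         tuning = model$ensemble$tuning,
         fp_transforms = lapply(model$fp_model$transforms, function(t)
           list(form = t$form, powers = t$powers, shift = t$shift,
                scale = t$scale))),
    file.path(dir, "bundle.json"), auto_unbox = TRUE, digits = NA)
  write_fp_trace(model$fp_model, file.path(dir, "fp_trace.tsv"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @param dir Bundle directory written by \code{save_model_bundle}.
#' @export
load_model_bundle <- function(dir) {
  f <- file.path(dir, "model.rds")
  if (!file.exists(f)) stop("no model.rds under ", dir)
  readRDS(f)
}

#' Train, predict and evaluate from manifest files
#'
#' Thin orchestration entry points over the package functions; these back
#' the command-line interface.
#'
#' @param manifest Path to a manifest TSV (see \code{\link{read_manifest}}).
#' @param config A \code{\link{hsvmlr_config}}.
#' @param out Output directory (train/evaluate) or TSV path (predict).
#' @return See each stage's value.
#' @export
hsvmlr_train_manifest <- function(manifest, config, out) {
  model <- hsvmlr_train(read_manifest(manifest), config)
  save_model_bundle(model, out)
  invisible(model)
}

#' @rdname hsvmlr_train_manifest
#' @param bundle Model bundle directory.
#' @export
hsvmlr_predict_manifest <- function(bundle, manifest, out) {
  model <- load_model_bundle(bundle)
  pred <- predict(model, read_manifest(manifest))
  utils::write.table(pred, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pred)
}

#' @rdname hsvmlr_train_manifest
#' @export
hsvmlr_evaluate_manifest <- function(manifest, config, out) {
  report <- cross_validate(read_manifest(manifest), config)
  write_metrics_report(report, out)
  invisible(report)
}
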