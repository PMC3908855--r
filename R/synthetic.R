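AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Configuration of the synthetic dataset generator
#'
#' The generator emulates the statistical structure the predictor assumes:
#' roughly one beta-turn residue in four (the 1:3 imbalance of globular
#' proteins), and a non-turn class made of three distinct subpopulations so
#' that the k-means partition is meaningful.  Pseudo-PSSM rows are drawn
#' from class-conditional Gaussians; secondary-structure and shape symbols
#' from class-conditional categorical distributions (turns are mostly coil).
#'
#' @param n_proteins Number of chains, default 60.
#' @param length_range Integer min/max chain length, default c(50, 200).
#' @param pos_fraction Target beta-turn residue fraction, default 0.25.
#' @param n_subpop Number of negative subpopulations, default 3.
#' @param separation Per-coordinate SD of the turn-class mean profile's
#'   offset from the centre of the non-turn subpopulations, on the raw
#'   log-odds scale; default 0.35 (calibrated so the task difficulty is in
#'   the range real beta-turn predictors face); 0 removes the class signal
#'   entirely, including the annotation-string contrast.
#' @param subpop_separation Per-coordinate SD of the three non-turn
#'   subpopulation mean profiles, default 1: the negative class is
#'   strongly multi-modal, the premise of the clustered model.
#' @param noise_sd Within-class residue noise SD, default 1.
#' @param turn_runs Plant contiguous 4-residue turn segments instead of
#'   i.i.d. labels (beta-turns span four residues), default FALSE.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_proteins = 60L, length_range = c(50L, 200L),
                             pos_fraction = 0.25, n_subpop = 3L,
                             separation = 0.35, subpop_separation = 1,
                             noise_sd = 1, turn_runs = FALSE, seed = 1L) {
  stopifnot(n_proteins >= 1L, length_range[1] >= 1L,
            length_range[2] >= length_range[1],
            pos_fraction > 0, pos_fraction < 1,
            n_subpop >= 1L, separation >= 0, subpop_separation >= 0,
            noise_sd > 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 pos_fraction = pos_fraction,
                 n_subpop = as.integer(n_subpop),
                 separation = separation,
                 subpop_separation = subpop_separation,
                 noise_sd = noise_sd,
                 turn_runs = isTRUE(turn_runs), seed = as.integer(seed)),
            class = "synthetic_config")
}

# class-conditional symbol tables: turns live almost entirely in coil
PSS_PROBS <- list(pos = c(H = 0.05, E = 0.05, C = 0.90),
                  neg = c(H = 0.40, E = 0.35, C = 0.25))
SHAPE_PROBS <- list(
  pos = c(S = 0.30, R = 0.02, U = 0.05, V = 0.10, K = 0.10, A = 0.03,
          T = 0.30, G = 0.05, N = 0.05),
  neg = c(S = 0.05, R = 0.30, U = 0.15, V = 0.10, K = 0.05, A = 0.25,
          T = 0.03, G = 0.02, N = 0.05))

#' Simulate a labeled synthetic protein dataset
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List of \code{\link{protein_record}} objects with labels.  Each
#'   record carries the latent negative-subpopulation index per residue
#'   (NA for turns) in \code{attr(record, "subpop")}, for generator tests.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$length_range[2] < 7L)
    stop("simulate_dataset: maximum chain length below the window size")
  set.seed(config$seed)
  # mean profiles on the raw log-odds scale: the non-turn class is a
  # mixture of n_subpop well-separated modes, and the turn class sits at a
  # moderate offset from their centre (turns overlap every negative mode)
  mu_neg <- replicate(config$n_subpop,
                      stats::rnorm(20, 0, config$subpop_separation))
  mu_pos <- rowMeans(mu_neg) + stats::rnorm(20, 0, config$separation)
  # separation 0 means no class signal at all: the annotation-string
  # emissions collapse to the negative tables as well
  pss_pos <- if (config$separation == 0) PSS_PROBS$neg else PSS_PROBS$pos
  shp_pos <- if (config$separation == 0) SHAPE_PROBS$neg else SHAPE_PROBS$pos
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 config$n_proteins, replace = TRUE)
  lapply(seq_len(config$n_proteins), function(i) {
    L <- lens[i]
    labels <- if (config$turn_runs) {
      lab <- integer(L)
      n_runs <- max(1L, round(L * config$pos_fraction / 4))
      starts <- sample(seq_len(max(L - 3L, 1L)), n_runs, replace = TRUE)
      for (s in starts) lab[s:min(s + 3L, L)] <- 1L
      lab
    } else {
      stats::rbinom(L, 1L, config$pos_fraction)
    }
    subpop <- ifelse(labels == 1L, NA_integer_,
                     sample.int(config$n_subpop, L, replace = TRUE))
    mu <- t(vapply(seq_len(L), function(r)
      if (labels[r] == 1L) mu_pos else mu_neg[, subpop[r]], numeric(20)))
    pssm <- round(mu + matrix(stats::rnorm(L * 20, 0, config$noise_sd),
                              L, 20), 3)
    pss_chars <- character(L)
    pss_chars[labels == 1L] <- sample(names(pss_pos), sum(labels),
                                      replace = TRUE, prob = pss_pos)
    pss_chars[labels == 0L] <- sample(names(PSS_PROBS$neg), L - sum(labels),
                                      replace = TRUE, prob = PSS_PROBS$neg)
    shp_chars <- character(L)
    shp_chars[labels == 1L] <- sample(names(shp_pos), sum(labels),
                                      replace = TRUE, prob = shp_pos)
    shp_chars[labels == 0L] <- sample(names(SHAPE_PROBS$neg), L - sum(labels),
                                      replace = TRUE, prob = SHAPE_PROBS$neg)
    rec <- protein_record(
      id = sprintf("syn%03d", i),
      sequence = paste(sample(AA_LETTERS, L, replace = TRUE), collapse = ""),
      pssm = pssm,
      pss = paste(pss_chars, collapse = ""),
      shape = paste(shp_chars, collapse = ""),
      labels = labels)
    attr(rec, "subpop") <- subpop
    rec
  })
}

#' Write a PSI-BLAST-style ASCII profile
#'
#' @param scores Numeric L x 20 matrix of raw scores.
#' @param residues Character vector of L residue letters.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pssm_ascii <- function(scores, residues, path) {
  stopifnot(ncol(scores) == 20L, nrow(scores) == length(residues))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("            ", paste(sprintf("%7s", AA_LETTERS),
                                            collapse = ""))), con)
  for (i in seq_len(nrow(scores)))
    writeLines(sprintf("%5d %s %s", i, residues[i],
                       paste(sprintf("%7.3f", scores[i, ]), collapse = "")),
               con)
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1347     0.3160"), con)
  invisible(path)
}

#' Write a protein dataset in the manifest layout the readers accept
#'
#' One FASTA, PSSM, PSS and (when present) shape and labels file per
#' protein, plus a \code{manifest.tsv} tying them together.
#'
#' @param proteins List of \code{\link{protein_record}} objects.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file.
#' @export
write_dataset <- function(proteins, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(proteins, function(p) {
    fa <- paste0(p$id, ".fasta")
    writeLines(c(paste0(">", p$id), p$sequence), file.path(dir, fa))
    pf <- paste0(p$id, ".pssm")
    write_pssm_ascii(p$pssm, strsplit(p$sequence, "")[[1]],
                     file.path(dir, pf))
    ps <- paste0(p$id, ".pss")
    writeLines(p$pss, file.path(dir, ps))
    sh <- ""
    if (!is.null(p$shape)) {
      sh <- paste0(p$id, ".shape")
      writeLines(p$shape, file.path(dir, sh))
    }
    lb <- ""
    if (!is.null(p$labels)) {
      lb <- paste0(p$id, ".labels")
      writeLines(paste(p$labels, collapse = ""), file.path(dir, lb))
    }
    data.frame(id = p$id, fasta = fa, pssm = pf, pss = ps, shape = sh,
               labels = lb)
  })
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  man
}

#' Simulate a univariate fractional-polynomial regression fixture
#'
#' Draws y ~ Bernoulli(plogis(beta0 + basis(x) beta)) with the FP basis of
#' \code{\link{fp_basis}}; used to test power-recovery of the closed-test
#' selection.
#'
#' @param n Sample size.
#' @param powers FP powers (length 1 or 2) from \code{FP_POWERS}.
#' @param beta Coefficients: intercept first, then one per basis column.
#' @param x_dist Function of n returning strictly positive draws; default
#'   Uniform(0.5, 5).
#' @param seed Integer seed.
#' @return List with \code{x}, \code{y} and the generating \code{prob}.
#' @export
simulate_fp_data <- function(n, powers, beta,
                             x_dist = function(n) stats::runif(n, 0.5, 5),
                             seed = 1L) {
  set.seed(seed)
  x <- x_dist(n)
  if (any(x <= 0)) stop("simulate_fp_data: x must be strictly positive")
  B <- fp_basis(x, powers)
  if (length(beta) != ncol(B) + 1L)
    stop("simulate_fp_data: beta must have ", ncol(B) + 1L, " entries")
  prob <- stats::plogis(beta[1L] + drop(B %*% beta[-1L]))
  list(x = x, y = stats::rbinom(n, 1L, prob), prob = prob)
}
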