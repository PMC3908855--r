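#' Read a FASTA file
#'
#' Minimal strict FASTA reader.  The predictor only needs plain single-record
#' (or small multi-record) sequence files, but malformed input must be
#' reported with the offending line number, so parsing is done line by line.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-cased sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) stop("FASTA parse error in '", path, "': file is empty")
  if (!startsWith(lines[1], ">"))
    stop("FASTA parse error in '", path, "' at line 1: expected '>' header, got '",
         substr(lines[1], 1, 30), "'")
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      id <- strsplit(trimws(sub("^>", "", ln)), "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id))
        stop("FASTA parse error in '", path, "' at line ", i, ": empty header")
      ids <- c(ids, id)
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      seqs[cur] <- paste0(seqs[cur], gsub("\\s", "", ln))
    }
  }
  if (any(!nzchar(seqs))) {
    bad <- ids[which(!nzchar(seqs))[1]]
    stop("FASTA parse error in '", path, "': record '", bad, "' has no sequence")
  }
  stats::setNames(toupper(seqs), ids)
}

#' Read a PSI-BLAST ASCII profile (PSSM)
#'
#' Parses the ASCII matrix PSI-BLAST writes with \code{-out_ascii_pssm}:
#' header lines, then one row per residue carrying the position index, the
#' residue letter and the first block of 20 log-odds substitution scores.
#' Only that first score block is kept; the percentage block and trailing
#' statistics lines are ignored.
#'
#' @param path Path to the profile file.
#' @return A list with \code{scores} (numeric L x 20 matrix of raw scores)
#'   and \code{residues} (character vector of the L residue letters).
#' @export
read_pssm_ascii <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  row_re <- "^\\s*[0-9]+\\s+[A-Za-z]\\s"
  data_idx <- grep(row_re, lines)
  if (length(data_idx) == 0L)
    stop("PSSM parse error in '", path, "': no profile rows found")
  scores <- matrix(NA_real_, nrow = length(data_idx), ncol = 20L)
  residues <- character(length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 22L)
      stop("PSSM parse error in '", path, "' at line ", i,
           ": expected 20 scores after the position and residue, got ",
           length(tok) - 2L)
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals))
      stop("PSSM parse error in '", path, "' at line ", i,
           ": non-numeric score in the first 20-column block")
    scores[k, ] <- vals
    residues[k] <- toupper(tok[2])
  }
  pos <- as.integer(sub("^\\s*([0-9]+).*", "\\1", lines[data_idx]))
  if (!identical(pos, seq_along(pos)))
    stop("PSSM parse error in '", path, "': position indices are not 1..L")
  list(scores = scores, residues = residues)
}

#' Sigmoid-scale a raw PSSM
#'
#' Applies the elementwise logistic transform f(x) = 1 / (1 + exp(-x)) so
#' every substitution score lands strictly in (0, 1).
#'
#' @param raw Numeric matrix (or vector) of finite raw scores.
#' @return Object of the same shape with values strictly in (0, 1); scores
#'   extreme enough to saturate double precision are nudged to the nearest
#'   representable value inside the open interval.
#' @export
scale_pssm <- function(raw) {
  if (!all(is.finite(raw))) stop("scale_pssm: input contains non-finite values")
  out <- stats::plogis(raw)
  out[out >= 1] <- 1 - 2^-53
  out[out <= 0] <- 2^-1074
  out
}

PSS_ALPHABET <- c("H", "E", "C")
SHAPE_ALPHABET <- c("S", "R", "U", "V", "K", "A", "T", "G", "N")

#' One-hot encode a secondary-structure state
#'
#' Helix, strand and coil map to (1,0,0), (0,1,0) and (0,0,1).
#'
#' @param state One of "H", "E", "C".
#' @param pos Optional residue position, used only in error messages.
#' @return Binary numeric 3-vector named H, E, C.
#' @export
encode_pss <- function(state, pos = NA) {
  one_hot(state, PSS_ALPHABET, "secondary structure", pos)
}

#' One-hot encode a shape-string state
#'
#' The eight torsion-region symbols S, R, U, V, K, A, T, G plus N
#' (undefined) map to the canonical one-hot vectors in that fixed order.
#'
#' @param state One of S, R, U, V, K, A, T, G, N.
#' @param pos Optional residue position, used only in error messages.
#' @return Binary numeric 9-vector.
#' @export
encode_shape <- function(state, pos = NA) {
  one_hot(state, SHAPE_ALPHABET, "shape string", pos)
}

one_hot <- function(state, alphabet, what, pos) {
  j <- match(state, alphabet)
  if (is.na(j))
    stop("encoding error: unknown ", what, " symbol '", state, "'",
         if (!is.na(pos)) paste0(" at position ", pos) else "")
  stats::setNames(as.numeric(seq_along(alphabet) == j), alphabet)
}

one_hot_matrix <- function(states, alphabet, what) {
  chars <- strsplit(states, "", fixed = TRUE)[[1]]
  j <- match(chars, alphabet)
  if (anyNA(j)) {
    bad <- which(is.na(j))[1]
    stop("encoding error: unknown ", what, " symbol '", chars[bad],
         "' at position ", bad)
  }
  m <- matrix(0, nrow = length(j), ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  m[cbind(seq_along(j), j)] <- 1
  m
}

FEATURE_MODES <- c("pssm_window_pss_window", "pssm_window_central_pss",
                   "pssm_pss_shape_window")

#' Per-residue feature width of a mode (before windowing)
#' @keywords internal
mode_width <- function(mode) {
  switch(mode,
         pssm_window_pss_window = 23L,
         pssm_window_central_pss = 20L,   # window over PSSM only
         pssm_pss_shape_window = 32L,
         stop("unknown feature mode: ", mode))
}

#' Number of features produced by a mode and window size
#' @param mode Feature mode.
#' @param window Odd window size.
#' @return Integer feature count.
#' @export
feature_count <- function(mode, window = 7L) {
  n <- as.integer(window) * mode_width(mode)
  if (mode == "pssm_window_central_pss") n <- n + 3L
  n
}

#' Slide a window over one protein's encoded features
#'
#' Builds one fixed-length example per residue by concatenating the
#' per-residue encodings of the window centred on it; the prediction target
#' is always the central residue.  Windows overhanging the chain ends are
#' padded with all-zero vectors, which are distinguishable from real data
#' because sigmoid-scaled scores are strictly positive.
#'
#' Modes: \code{pssm_window_pss_window} windows the scaled PSSM and the
#' 3-bit PSS jointly (width 7 x 23 = 161); \code{pssm_window_central_pss}
#' windows the PSSM only and appends the central residue's PSS bits
#' (7 x 20 + 3 = 143); \code{pssm_pss_shape_window} adds the 9-bit shape
#' encoding inside the window (7 x 32 = 224).
#'
#' @param protein A \code{\link{protein_record}}.
#' @param window Odd integer window size, default 7.
#' @param mode One of \code{FEATURE_MODES}.
#' @param pssm_scaled Optional pre-scaled PSSM; defaults to
#'   \code{scale_pssm(protein$pssm)}.
#' @return List with \code{features} (L x F matrix), \code{labels}
#'   (or NULL) and \code{protein_ids}.
#' @export
build_windows <- function(protein, window = 7L,
                          mode = "pssm_window_pss_window",
                          pssm_scaled = NULL) {
  stopifnot(inherits(protein, "protein_record"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3, got ", window)
  mode <- match.arg(mode, FEATURE_MODES)
  if (mode == "pssm_pss_shape_window" && is.null(protein$shape))
    stop("protein '", protein$id, "': mode '", mode,
         "' requires a shape string but none is present")
  if (is.null(pssm_scaled)) pssm_scaled <- scale_pssm(protein$pssm)
  if (any(pssm_scaled < 0 | pssm_scaled > 1))
    stop("scaled PSSM values must lie in [0, 1]")
  L <- nchar(protein$sequence)
  pss_m <- one_hot_matrix(protein$pss, PSS_ALPHABET, "secondary structure")
  enc <- switch(mode,
    pssm_window_pss_window = cbind(pssm_scaled, pss_m),
    pssm_window_central_pss = pssm_scaled,
    pssm_pss_shape_window = cbind(
      pssm_scaled, pss_m,
      one_hot_matrix(protein$shape, SHAPE_ALPHABET, "shape string")))
  w <- ncol(enc)
  h <- (window - 1L) %/% 2L
  padded <- rbind(matrix(0, h, w), enc, matrix(0, h, w))
  feats <- matrix(0, nrow = L, ncol = window * w)
  for (k in seq_len(window)) {
    feats[, ((k - 1L) * w + 1L):(k * w)] <- padded[k:(k + L - 1L), , drop = FALSE]
  }
  if (mode == "pssm_window_central_pss") feats <- cbind(feats, pss_m)
  colnames(feats) <- NULL
  list(features = feats,
       labels = protein$labels,
       protein_ids = rep(protein$id, L))
}

#' Encode a set of proteins into a windowed per-residue dataset
#'
#' @param proteins List of \code{\link{protein_record}} objects.
#' @param window Odd window size, default 7.
#' @param mode Feature mode, see \code{\link{build_windows}}.
#' @return An \code{encoded_dataset}: list with \code{features} (N x F),
#'   \code{labels} (length-N 0/1 vector or NULL), \code{protein_ids}
#'   (length N), \code{feature_mode} and \code{window}.
#' @export
encode_dataset <- function(proteins, window = 7L,
                           mode = "pssm_window_pss_window") {
  stopifnot(length(proteins) > 0L)
  parts <- lapply(proteins, build_windows, window = window, mode = mode)
  labels <- lapply(parts, `[[`, "labels")
  have_labels <- !vapply(labels, is.null, logical(1))
  if (any(have_labels) && !all(have_labels))
    stop("encode_dataset: some proteins have labels and some do not")
  structure(
    list(features = do.call(rbind, lapply(parts, `[[`, "features")),
         labels = if (all(have_labels)) unlist(labels, use.names = FALSE) else NULL,
         protein_ids = unlist(lapply(parts, `[[`, "protein_ids"), use.names = FALSE),
         feature_mode = mode,
         window = as.integer(window)),
    class = "encoded_dataset")
}

read_state_file <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(what, " file '", path, "' is empty")
  if (any(grepl("\t", lines, fixed = TRUE))) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2L)
      stop(what, " file '", path, "': 2-column TSV expected")
    ord <- order(as.integer(tab[[1]]))
    paste(tab[[2]][ord], collapse = "")
  } else {
    paste(gsub("\\s", "", lines), collapse = "")
  }
}

read_labels_file <- function(path) {
  s <- read_state_file(path, "labels")
  v <- as.integer(strsplit(s, "", fixed = TRUE)[[1]])
  if (anyNA(v) || !all(v %in% c(0L, 1L)))
    stop("labels file '", path, "' must contain only 0/1 characters")
  v
}

#' Read a dataset manifest
#'
#' The manifest is a TSV with header columns \code{id}, \code{fasta},
#' \code{pssm}, \code{pss} and optionally \code{shape} and \code{labels}
#' (empty cells allowed); one row per protein chain.  Relative paths are
#' resolved against the manifest's own directory.  Residue letters in each
#' PSSM are validated against the FASTA sequence.
#'
#' @param path Manifest path.
#' @return List of \code{\link{protein_record}} objects, in manifest order.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "")
  req <- c("id", "fasta", "pssm", "pss")
  miss <- setdiff(req, names(man))
  if (length(miss))
    stop("manifest '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    seqs <- read_fasta(resolve(row$fasta))
    sq <- if (row$id %in% names(seqs)) seqs[[row$id]] else seqs[[1]]
    prof <- read_pssm_ascii(resolve(row$pssm))
    if (!identical(prof$residues, strsplit(sq, "", fixed = TRUE)[[1]]))
      stop("protein '", row$id, "': PSSM residue letters disagree with ",
           "the FASTA sequence")
    shape <- NULL
    if (!is.null(man$shape) && !is.na(row$shape) && nzchar(row$shape))
      shape <- read_state_file(resolve(row$shape), "shape")
    labels <- NULL
    if (!is.null(man$labels) && !is.na(row$labels) && nzchar(row$labels))
      labels <- read_labels_file(resolve(row$labels))
    protein_record(id = row$id, sequence = sq, pssm = prof$scores,
                   pss = read_state_file(resolve(row$pss), "pss"),
                   shape = shape, labels = labels)
  })
}
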