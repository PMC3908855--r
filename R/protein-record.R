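#' Construct a per-chain protein record
#'
#' Bundles everything the predictor needs for one protein chain: the amino
#' acid sequence, the raw (unscaled) L x 20 PSSM, the 3-state predicted
#' secondary structure string, an optional 9-state shape string and optional
#' per-residue binary beta-turn labels.  All per-residue annotations must
#' have length L = nchar(sequence).
#'
#' @param id Character scalar identifier.
#' @param sequence Amino-acid sequence (upper-case one-letter codes; X, B, Z
#'   are tolerated since no feature is derived from residue identity).
#' @param pssm Numeric matrix, L rows x 20 columns of raw substitution
#'   scores (log-odds scale, before sigmoid scaling).
#' @param pss Character scalar of length-L over \{H, E, C\}.
#' @param shape Optional character scalar of length L over
#'   \{S, R, U, V, K, A, T, G, N\}.
#' @param labels Optional integer vector of length L with values in \{0, 1\};
#'   1 marks a beta-turn residue.
#' @return An object of class \code{protein_record}.
#' @export
protein_record <- function(id, sequence, pssm, pss, shape = NULL, labels = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 1L) stop("protein '", id, "': empty sequence")
  pssm <- as.matrix(pssm)
  if (ncol(pssm) != 20L)
    stop("protein '", id, "': PSSM must have exactly 20 columns, got ", ncol(pssm))
  if (nrow(pssm) != L)
    stop("protein '", id, "': PSSM has ", nrow(pssm), " rows but sequence length is ", L)
  if (!all(is.finite(pssm)))
    stop("protein '", id, "': PSSM contains non-finite values")
  check_state_string(pss, L, c("H", "E", "C"), "pss", id)
  if (!is.null(shape))
    check_state_string(shape, L, c("S", "R", "U", "V", "K", "A", "T", "G", "N"),
                       "shape", id)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != L)
      stop("protein '", id, "': labels length ", length(labels),
           " != sequence length ", L)
    if (!all(labels %in% c(0L, 1L)))
      stop("protein '", id, "': labels must be 0/1")
  }
  structure(
    list(id = id, sequence = sequence, pssm = unname(pssm), pss = pss,
         shape = shape, labels = labels),
    class = "protein_record"
  )
}

check_state_string <- function(x, L, alphabet, what, id) {
  if (!is.character(x) || length(x) != 1L)
    stop("protein '", id, "': ", what, " must be a single string")
  if (nchar(x) != L)
    stop("protein '", id, "': ", what, " has length ", nchar(x),
         " but sequence length is ", L)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad))
    stop("protein '", id, "': invalid ", what, " symbol '", chars[bad[1]],
         "' at position ", bad[1])
  invisible(TRUE)
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": L=", nchar(x$sequence),
      if (!is.null(x$shape)) ", shape" else "",
      if (!is.null(x$labels)) paste0(", ", sum(x$labels), " turn residues") else "",
      "\n", sep = "")
  invisible(x)
}
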