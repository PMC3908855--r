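#' Candidate fractional-polynomial powers
#'
#' The conventional candidate set: -2, -1, -0.5, 0, 0.5, 1, 2, 3, where
#' power 0 denotes the natural logarithm and power 1 the untransformed
#' (straight-line) variable.
#' @export
FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Shift a covariate to strictly positive values
#'
#' Signed SVM decision values contain non-positive values, which rule out
#' logarithms and negative powers.  If the minimum is already positive no
#' shift is applied; otherwise the variable is shifted by
#' \code{-min(x) + delta} where delta is the smallest gap between adjacent
#' distinct ordered values (the standard fractional-polynomial convention).
#'
#' @param x Non-constant numeric vector.
#' @return List with \code{x} (shifted values, all > 0) and \code{shift}.
#' @export
shift_to_positive <- function(x) {
  if (!all(is.finite(x))) stop("shift_to_positive: non-finite values")
  ux <- sort(unique(x))
  if (length(ux) < 2L)
    stop("shift_to_positive: constant vector; no transform is meaningful")
  shift <- if (ux[1L] > 0) 0 else -ux[1L] + min(diff(ux))
  list(x = x + shift, shift = shift)
}

# Divisor 10^round(log10(IQR)) when the shifted variable's IQR leaves
# [0.01, 100]; keeps powers +-2 and 3 away from overflow.
fp_scale_factor <- function(x_shifted) {
  iqr <- stats::IQR(x_shifted)
  if (iqr > 100 || (iqr < 0.01 && iqr > 0)) 10^round(log10(iqr)) else 1
}

pow_col <- function(x, p) if (p == 0) log(x) else x^p

#' Fractional-polynomial basis columns
#'
#' FP1 with power p gives the single column x^p (x^0 is ln x).  FP2 with
#' distinct powers (p, q) gives x^p and x^q; with the repeated power
#' (p, p) it gives the mathematical-limit pair x^p and x^p * ln(x).
#'
#' @param x Strictly positive numeric vector.
#' @param powers Numeric vector of length 1 (FP1) or 2 (FP2), values from
#'   \code{FP_POWERS}.
#' @return Numeric matrix with one column per basis term.
#' @export
fp_basis <- function(x, powers) {
  if (any(x <= 0)) stop("fp_basis: x must be strictly positive")
  powers <- as.numeric(powers)
  if (!length(powers) %in% 1:2 ||
      !all(vapply(powers, function(p) any(abs(p - FP_POWERS) < 1e-9), TRUE)))
    stop("fp_basis: powers must be 1 or 2 values from {",
         paste(FP_POWERS, collapse = ", "), "}")
  if (length(powers) == 1L) {
    m <- cbind(pow_col(x, powers))
  } else if (powers[1L] != powers[2L]) {
    m <- cbind(pow_col(x, powers[1L]), pow_col(x, powers[2L]))
  } else {
    b <- pow_col(x, powers[1L])
    m <- cbind(b, b * log(x))
  }
  colnames(m) <- paste0("p", seq_len(ncol(m)))
  m
}

# All FP2 power pairs: combinations with repetition, 8 choose 2 + 8 = 36
fp2_power_pairs <- function() {
  pairs <- expand.grid(p = FP_POWERS, q = FP_POWERS)
  pairs[pairs$p <= pairs$q, , drop = FALSE]
}
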