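# Mass-isotopomer distributions (MIDs) and elementary operations on them.

#' Construct a mass-isotopomer distribution
#'
#' An MID is a vector of fractional abundances of the m+0 ... m+n mass
#' isotopologues of a metabolite. Fractions must be non-negative and sum to
#' one (within `tol`).
#'
#' @param fractions Numeric vector of length `n_carbons + 1`, ordered
#'   m+0 first.
#' @param metabolite Optional metabolite id the MID belongs to.
#' @param provenance One of `"simulated"`, `"raw-normalized"`,
#'   `"corrected"`.
#' @param tol Tolerance on the sum-to-one constraint.
#' @return A numeric vector of class `"mid"` with attributes `metabolite`
#'   and `provenance`. The vector is renormalized to sum exactly to one.
#' @export
mid <- function(fractions, metabolite = NA_character_,
                provenance = c("simulated", "raw-normalized", "corrected"),
                tol = 1e-6) {
  provenance <- match.arg(provenance)
  fractions <- as.numeric(fractions)
  if (length(fractions) < 1L || anyNA(fractions)) {
    stop("MID fractions must be a non-empty numeric vector without NAs")
  }
  if (any(fractions < -1e-12)) {
    stop("MID fractions must be non-negative")
  }
  fractions[fractions < 0] <- 0
  s <- sum(fractions)
  if (abs(s - 1) > tol) {
    stop(sprintf("MID fractions sum to %.8f, not 1 (tolerance %g)", s, tol))
  }
  structure(fractions / s, class = "mid",
            metabolite = metabolite, provenance = provenance)
}

#' @export
print.mid <- function(x, ...) {
  met <- attr(x, "metabolite")
  lab <- if (is.na(met)) "MID" else paste0("MID of ", met)
  cat(lab, " (", attr(x, "provenance"), "):\n", sep = "")
  v <- as.numeric(x)
  names(v) <- paste0("m+", seq_along(v) - 1L)
  print(round(v, 6))
  invisible(x)
}

as_mid_vector <- function(x) {
  v <- as.numeric(x)
  if (any(v < -1e-9) || abs(sum(v) - 1) > 1e-6) {
    stop("not a normalized MID (entries >= 0 summing to 1)")
  }
  v[v < 0] <- 0
  v / sum(v)
}

#' Convolve two mass-isotopomer distributions
#'
#' The MID of a molecule assembled from two independent moieties is the
#' Cauchy product (discrete convolution) of the moiety MIDs.
#'
#' @param a,b Normalized MIDs (numeric vectors or `mid` objects).
#' @return Numeric vector of length `length(a) + length(b) - 1`, summing
#'   to one.
#' @export
convolve_mids <- function(a, b) {
  a <- as_mid_vector(a)
  b <- as_mid_vector(b)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out / sum(out)
}

#' Normalize raw isotopologue intensities to an MID
#'
#' Measured per-isotopologue intensities are converted to fractional
#' abundances by dividing by their total, i.e. each species is expressed
#' relative to the sum of labeled and unlabeled forms in the sample.
#'
#' @param intensities Non-negative numeric vector of raw intensities,
#'   m+0 first.
#' @param metabolite Optional metabolite id.
#' @return An object of class `"mid"` with provenance `"raw-normalized"`.
#' @export
normalize_isotopologue_intensities <- function(intensities,
                                               metabolite = NA_character_) {
  intensities <- as.numeric(intensities)
  if (any(intensities < 0)) stop("intensities must be non-negative")
  tot <- sum(intensities)
  if (tot <= 0) stop("all-zero intensity vector cannot be normalized")
  mid(intensities / tot, metabolite = metabolite,
      provenance = "raw-normalized")
}

#' Natural-abundance correction matrix for carbon
#'
#' Forward matrix mapping a tracer-only MID to the observed MID when each
#' unlabeled backbone carbon has probability `abundance` of being a
#' naturally occurring 13C. Entry (i, j) is the probability that a
#' molecule with j tracer labels is observed at mass m+i.
#'
#' @param n_carbons Number of backbone carbons.
#' @param abundance Natural 13C abundance (default 0.0107).
#' @return `(n_carbons + 1) x (n_carbons + 1)` lower-triangular matrix.
#' @export
carbon_correction_matrix <- function(n_carbons, abundance = 0.0107) {
  n <- n_carbons
  m <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    # j tracer-labeled carbons leave n - j carbons able to pick up natural 13C
    k <- 0:(n - j)
    m[j + 1L + k, j + 1L] <- stats::dbinom(k, n - j, abundance)
  }
  m
}

#' Correct a measured MID for natural 13C abundance
#'
#' Applies the inverse of the theoretical natural-isotope convolution
#' matrix, clips small negatives and renormalizes. Only backbone carbon is
#' corrected by default; other elements are ignored.
#'
#' @param x Measured MID (numeric or `mid`).
#' @param abundance Natural 13C abundance; set to 0 for the identity.
#' @return Corrected `mid` with provenance `"corrected"`.
#' @seealso [uncorrect_mid()] for the forward (re-contamination) direction.
#' @export
natural_abundance_correction <- function(x, abundance = 0.0107) {
  v <- as_mid_vector(x)
  n <- length(v) - 1L
  cm <- carbon_correction_matrix(n, abundance)
  if (rcond(cm) < 1e-12) stop("ill-conditioned correction matrix")
  corrected <- solve(cm, v)
  corrected[corrected < 0] <- 0
  mid(corrected / sum(corrected), metabolite = attr(x, "metabolite"),
      provenance = "corrected")
}

#' Apply the forward natural-abundance convolution to a clean MID
#'
#' @inheritParams natural_abundance_correction
#' @return Numeric MID vector as it would be observed on the instrument.
#' @export
uncorrect_mid <- function(x, abundance = 0.0107) {
  v <- as_mid_vector(x)
  cm <- carbon_correction_matrix(length(v) - 1L, abundance)
  as.numeric(cm %*% v)
}
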