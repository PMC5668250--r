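## Structural feature blocks derived from the SPD3 profile: secondary-
## structure counts, ASA composition, torsion-angle sine/cosine features
## and structure-class probability features.

#' Secondary-structure occurrence and composition
#'
#' `ssOccurrence` counts the residues in each secondary-structure state;
#' `ssComposition` divides the counts by the protein length L. The output
#' order is (H, E, C) — helix, strand, coil — following the conventional
#' listing of the three states.
#'
#' @param sp A [StructuralProfile-class].
#' @return Named numeric vector of length 3 in (H, E, C) order.
#'   Occurrences sum to L; compositions sum to 1.
#' @examples
#' sp <- StructuralProfile("toy", "HEC", asa = c(1, 2, 3),
#'   phi = c(0, 0, 0), psi = c(0, 0, 0), theta = c(0, 0, 0),
#'   tau = c(0, 0, 0), probs = diag(3))
#' ssOccurrence(sp)
#' ssComposition(sp)
#' @export
ssOccurrence <- function(sp) {
  stopifnot(is(sp, "StructuralProfile"))
  letters <- strsplit(sp@ss, "")[[1]]
  counts <- table(factor(letters, levels = c("H", "E", "C")))
  stats::setNames(as.numeric(counts), c("H", "E", "C"))
}

#' @rdname ssOccurrence
#' @export
ssComposition <- function(sp) {
  ssOccurrence(sp) / profileLength(sp)
}

#' Accessible-surface-area composition
#'
#' The length-normalized sum (i.e. mean) of the per-residue accessible
#' surface areas, in the file's native units (square Angstroms). Raw ASA
#' values are used; no per-residue maximum-ASA scaling is applied.
#'
#' @param sp A [StructuralProfile-class].
#' @return A single number.
#' @export
asaComposition <- function(sp) {
  stopifnot(is(sp, "StructuralProfile"))
  c(asa = mean(sp@asa))
}

#' Torsion-angle sine/cosine matrix
#'
#' Converts the four per-residue torsion angles from degrees to radians
#' and takes the sine and cosine of each, yielding an L x 8 matrix in
#' column order (sin phi, cos phi, sin psi, cos psi, sin tau, cos tau,
#' sin theta, cos theta). Every entry lies in \[-1, 1\] and each
#' (sin, cos) pair satisfies sin^2 + cos^2 = 1 by construction, so the
#' features are invariant to adding full turns to any input angle.
#'
#' @param sp A [StructuralProfile-class].
#' @return Numeric L x 8 matrix.
#' @export
angleMatrix <- function(sp) {
  stopifnot(is(sp, "StructuralProfile"))
  rad <- cbind(phi = sp@phi, psi = sp@psi, tau = sp@tau,
               theta = sp@theta) * pi / 180
  out <- matrix(0, nrow(rad), 8L)
  cn <- character(8L)
  for (a in seq_len(4L)) {
    out[, 2L * a - 1L] <- sin(rad[, a])
    out[, 2L * a] <- cos(rad[, a])
    cn[2L * a - 1L] <- paste0("sin_", colnames(rad)[a])
    cn[2L * a] <- paste0("cos_", colnames(rad)[a])
  }
  colnames(out) <- cn
  out
}

#' Structure-class probability matrix
#'
#' The L x 3 matrix of per-residue structure-class probabilities in
#' internal (C, H, E) column order, as a plain matrix ready for the
#' generic profile operators.
#'
#' @param sp A [StructuralProfile-class].
#' @return Numeric L x 3 matrix with columns C, H, E.
#' @export
structProbMatrix <- function(sp) {
  stopifnot(is(sp, "StructuralProfile"))
  sp@probs
}

#' Structural feature blocks from an SPD3 profile
#'
#' Computes the seven structural blocks in their canonical order:
#' secondary-structure composition (3), secondary-structure occurrence
#' (3), the combined composition block of ASA, angle sine/cosines and
#' structure-class probabilities (1 + 8 + 3 = 12), bigram of the angle
#' matrix at lag 1 (64), angle auto-covariance to the distance factor
#' (80 at `df = 10`), bigram of the probability matrix at lag 1 (9), and
#' probability auto-covariance (30 at `df = 10`). Total 201 under
#' defaults.
#'
#' @param sp A [StructuralProfile-class] with `L > df`.
#' @param df Distance factor for the auto-covariance blocks (default 10).
#' @return Named numeric vector; names are prefixed with the block name.
#' @export
structuralFeatures <- function(sp, df = 10L) {
  stopifnot(is(sp, "StructuralProfile"))
  ang <- angleMatrix(sp)
  prob <- structProbMatrix(sp)
  blocks <- list(
    ss_composition = ssComposition(sp),
    ss_occurrence = ssOccurrence(sp),
    asa_angle_prob_composition = c(asaComposition(sp),
                                   profileComposition(ang),
                                   profileComposition(prob)),
    angle_bigram = profileBigram(ang, lag = 1L),
    angle_autocov = profileAutoCovariance(ang, df = df),
    prob_bigram = profileBigram(prob, lag = 1L),
    prob_autocov = profileAutoCovariance(prob, df = df)
  )
  out <- unlist(blocks)
  names(out) <- unlist(lapply(names(blocks), function(b)
    paste(b, names(blocks[[b]]), sep = "_")))
  out
}
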