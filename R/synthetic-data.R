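## Synthetic PSSM/SPD3 profile generator. Emulates the statistical shape
## of the external tools' output — integer log-odds around per-residue
## baselines, a Markovian secondary-structure string, non-negative ASA,
## torsion angles in degrees and simplex probability rows — with an
## optional planted class difference so the whole pipeline is testable
## without PSI-BLAST or SPIDER runs.

.MARKOV_SS <- matrix(c(0.80, 0.10, 0.10,
                       0.10, 0.80, 0.10,
                       0.10, 0.10, 0.80),
                     3L, 3L, byrow = TRUE,
                     dimnames = list(c("C", "H", "E"), c("C", "H", "E")))

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate one synthetic PSSM / SPD3 profile pair
#'
#' Draws a random protein of length `L` and emulates both profiles:
#' \itemize{
#'   \item PSSM log-odds are integers in \[-10, 10\], centered at -1 with
#'     a +6 bump on the query residue's own column (real profiles score
#'     the observed residue highly) plus Gaussian noise (sd 2);
#'   \item the secondary-structure string follows a sticky 3-state Markov
#'     chain (self-transition 0.8);
#'   \item ASA is gamma-distributed (shape 2, scale 30, square
#'     Angstroms), angles are uniform on \[-180, 180\] degrees, and each
#'     probability row is Dirichlet-distributed with concentration 6 on
#'     the residue's true state and 1 elsewhere.
#' }
#' For `label = "binding"` a mean shift of size `effect` is added to the
#' PSSM columns of the basic residues R and K (which contact the DNA
#' backbone in real binders; here simply a documented, detectable
#' signal) and `effect` is added to the helix concentration of the
#' probability rows. With `effect = 0` the two classes are identically
#' distributed. Values are rounded to the precision that [writeSpd()] /
#' [writePssm()] print, so written fixtures round-trip exactly. Uses the
#' current RNG state; seed it (or use [generateCollection()]) for
#' reproducibility.
#'
#' @param L Protein length, at least 12 (the auto-covariance blocks need
#'   L > 10 at the default distance factor).
#' @param label `"binding"` or `"non-binding"`.
#' @param effect Size of the planted class difference (0 = none).
#' @param id Identifier given to both profiles.
#' @return List with elements `pssm` ([PssmProfile-class]) and `spd`
#'   ([StructuralProfile-class]).
#' @examples
#' set.seed(1)
#' pair <- generateProfilePair(30, "binding", effect = 2)
#' profileLength(pair$pssm)
#' @export
generateProfilePair <- function(L, label = c("non-binding", "binding"),
                                effect = 0, id = "synthetic") {
  label <- match.arg(label)
  L <- as.integer(L)
  if (L < 12L) stop("'L' must be at least 12")
  if (effect < 0) stop("'effect' must be non-negative")
  alpha <- pssmAlphabet()
  seq_letters <- sample(alpha, L, replace = TRUE)

  shift <- numeric(20L)
  if (label == "binding")
    shift[match(c("R", "K"), alpha)] <- effect
  scores <- matrix(stats::rnorm(L * 20L, mean = -1, sd = 2), L, 20L)
  scores <- sweep(scores, 2L, shift, "+")
  scores[cbind(seq_len(L), match(seq_letters, alpha))] <-
    scores[cbind(seq_len(L), match(seq_letters, alpha))] + 6
  scores <- pmin(pmax(round(scores), -10), 10)
  pssm <- PssmProfile(id, scores, paste(seq_letters, collapse = ""))

  ss <- character(L)
  ss[1L] <- sample(c("C", "H", "E"), 1L)
  for (i in seq_len(L - 1L))
    ss[i + 1L] <- sample(c("C", "H", "E"), 1L, prob = .MARKOV_SS[ss[i], ])
  asa <- round(stats::rgamma(L, shape = 2, scale = 30), 3L)
  angles <- matrix(round(stats::runif(4L * L, -180, 180), 3L), L, 4L)
  probs <- t(vapply(seq_len(L), function(i) {
    conc <- c(C = 1, H = 1, E = 1)
    conc[ss[i]] <- 6
    if (label == "binding") conc["H"] <- conc["H"] + effect
    .rdirichlet1(conc)
  }, numeric(3L)))
  # round to written precision, keeping rows summing exactly to 1
  probs[, 1:2] <- round(probs[, 1:2], 3L)
  probs[, 3L] <- round(pmax(0, 1 - probs[, 1L] - probs[, 2L]), 3L)
  spd <- StructuralProfile(id, paste(ss, collapse = ""), asa,
                           phi = angles[, 1L], psi = angles[, 2L],
                           theta = angles[, 3L], tau = angles[, 4L],
                           probs = probs)
  list(pssm = pssm, spd = spd)
}

#' Generate a labeled synthetic collection
#'
#' Draws `nPos` binding and `nNeg` non-binding proteins with lengths
#' uniform over `lengthRange` via [generateProfilePair()]. When `dir` is
#' given, also writes `<id>.pssm` and `<id>.spd3` files plus a
#' `labels.tsv` table there, all parseable by the package's readers.
#' Identical configurations (including `seed`) yield bit-identical
#' collections and files.
#'
#' @param nPos,nNeg Number of binding / non-binding proteins.
#' @param lengthRange Two integers: minimum and maximum protein length.
#' @param effect Planted class separation (see [generateProfilePair()]).
#' @param seed Integer seed for all randomness.
#' @param dir Optional output directory for profile files.
#' @return A [ProfileCollection-class].
#' @export
generateCollection <- function(nPos = 50L, nNeg = 50L,
                               lengthRange = c(50L, 150L), effect = 1,
                               seed = 1L, dir = NULL) {
  if (nPos < 0L || nNeg < 0L || nPos + nNeg < 1L)
    stop("counts must be non-negative and sum to at least 1")
  if (length(lengthRange) != 2L || lengthRange[1L] < 12L ||
      lengthRange[2L] < lengthRange[1L])
    stop("'lengthRange' must be (Lmin, Lmax) with Lmin >= 12")
  set.seed(seed)
  n <- nPos + nNeg
  labels <- rep(c("binding", "non-binding"), c(nPos, nNeg))
  ids <- sprintf("prot%03d", seq_len(n))
  pssm <- vector("list", n)
  spd <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sample(seq(lengthRange[1L], lengthRange[2L]), 1L)
    pair <- generateProfilePair(L, labels[i], effect = effect, id = ids[i])
    pssm[[i]] <- pair$pssm
    spd[[i]] <- pair$spd
  }
  coll <- ProfileCollection(ids, pssm, spd, labels)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      writePssm(pssm[[i]], file.path(dir, paste0(ids[i], ".pssm")))
      writeSpd(spd[[i]], file.path(dir, paste0(ids[i], ".spd3")))
    }
    utils::write.table(
      data.frame(id = ids, label = as.integer(labels == "binding")),
      file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  coll
}
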