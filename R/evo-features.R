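## Evolutionary feature blocks derived from the PSSM: logistic
## normalization, consensus sequence, amino-acid composition, CTD
## (composition/transition/distribution) descriptors, and the four
## matrix-operator blocks on the normalized profile.

#' Logistic normalization of a PSSM
#'
#' Maps the unbounded log-odds scores elementwise into (0, 1) with the
#' standard logistic function `1 / (1 + exp(-m))`. The transform is
#' strictly monotone per entry and independent of sequence length, so
#' products of normalized entries (bigram, auto-covariance) stay bounded.
#'
#' @param p A [PssmProfile-class].
#' @return Numeric L x 20 matrix with entries strictly in (0, 1), columns
#'   named by [pssmAlphabet()].
#' @examples
#' p <- PssmProfile("toy", matrix(0, 2, 20), "AC")
#' normalizePssm(p)[1, 1]  # logistic midpoint 0.5
#' @export
normalizePssm <- function(p) {
  stopifnot(is(p, "PssmProfile"))
  N <- 1 / (1 + exp(-p@scores))
  colnames(N) <- pssmAlphabet()
  N
}

#' Consensus sequence of a PSSM
#'
#' The amino acid with the highest substitution score at each position.
#' Ties are broken toward the smallest column index in PSI-BLAST order.
#'
#' @param p A [PssmProfile-class].
#' @return Single string of length L over the 20 standard letters.
#' @export
consensusSequence <- function(p) {
  stopifnot(is(p, "PssmProfile"))
  paste(pssmAlphabet()[apply(p@scores, 1L, which.max)], collapse = "")
}

#' Amino-acid composition
#'
#' The 20 per-letter occurrence counts of a protein sequence divided by
#' its length. In this method the sequence is the PSSM consensus, not the
#' original query.
#'
#' @param s A sequence string over the 20 standard letters, or a
#'   [PssmProfile-class] (whose consensus sequence is used).
#' @return Named numeric vector of length 20 summing to 1, in
#'   [pssmAlphabet()] order.
#' @examples
#' aminoAcidComposition("ACAC")
#' @export
aminoAcidComposition <- function(s) {
  if (is(s, "PssmProfile")) s <- consensusSequence(s)
  letters <- strsplit(s, "")[[1]]
  if (!all(letters %in% pssmAlphabet()))
    stop("sequence contains letters outside the 20 standard amino acids")
  counts <- table(factor(letters, levels = pssmAlphabet()))
  stats::setNames(as.numeric(counts) / length(letters), pssmAlphabet())
}

#' Classical three-class physicochemical groupings for CTD descriptors
#'
#' The five standard amino-acid attribute groupings used for
#' composition/transition/distribution (CTD) descriptors: hydrophobicity,
#' normalized van der Waals volume, polarity, polarizability and charge.
#' Each attribute partitions the 20 standard letters into three disjoint
#' classes. Users may pass their own list of the same shape to
#' [dubchakFeatures()].
#'
#' @return Named list of 5 groupings; each grouping is a list of three
#'   character vectors partitioning the 20 letters.
#' @references Dubchak et al.'s fold-recognition descriptor scheme, as
#'   standardized in common protein-descriptor toolkits.
#' @export
ctdGroupings <- function() {
  g <- list(
    hydrophobicity = list(
      polar      = c("R", "K", "E", "D", "Q", "N"),
      neutral    = c("G", "A", "S", "T", "P", "H", "Y"),
      hydrophobic = c("C", "L", "V", "I", "M", "F", "W")),
    vdw_volume = list(
      small  = c("G", "A", "S", "T", "P", "D", "C"),
      medium = c("N", "V", "E", "Q", "I", "L"),
      large  = c("M", "H", "K", "F", "R", "Y", "W")),
    polarity = list(
      low    = c("L", "I", "F", "W", "C", "M", "V", "Y"),
      medium = c("P", "A", "T", "G", "S"),
      high   = c("H", "Q", "R", "K", "N", "E", "D")),
    polarizability = list(
      low    = c("G", "A", "S", "D", "T"),
      medium = c("C", "P", "N", "V", "E", "Q", "I", "L"),
      high   = c("K", "M", "H", "F", "R", "Y", "W")),
    charge = list(
      positive = c("K", "R"),
      neutral  = c("A", "N", "C", "Q", "G", "H", "I", "L",
                   "M", "F", "P", "S", "T", "W", "Y", "V"),
      negative = c("D", "E"))
  )
  g
}

.checkGrouping <- function(grouping, name) {
  all_letters <- sort(unname(unlist(grouping)))
  if (length(grouping) != 3L ||
      !identical(all_letters, sort(pssmAlphabet())))
    stop(sprintf(
      "grouping '%s' must partition the 20 standard letters into 3 classes",
      name))
}

#' CTD (composition/transition/distribution) descriptors
#'
#' For each physicochemical attribute, residues are mapped to one of
#' three classes and three descriptor families are computed:
#' \describe{
#'   \item{composition}{fraction of residues in each class (3 values,
#'     summing to 1);}
#'   \item{transition}{for each unordered class pair, the number of
#'     adjacent residue pairs whose members fall in the two different
#'     classes, divided by L - 1 (3 values; zeros when L = 1);}
#'   \item{distribution}{for each class, the sequence positions
#'     (normalized by L) of its 1st, 25th-percentile, 50th-percentile,
#'     75th-percentile and last occurrence (5 values; zeros for a class
#'     absent from the sequence). The q-th percentile occurrence of a
#'     class with n occurrences is occurrence number `ceiling(q * n)`.}
#' }
#' This yields 21 values per attribute, 105 for the default 5 attributes.
#' As with [aminoAcidComposition()], the method applies this to the PSSM
#' consensus sequence.
#'
#' @param s Sequence string, or a [PssmProfile-class] (consensus used).
#' @param groupings List of three-class groupings; see [ctdGroupings()].
#' @return Named numeric vector of length `21 * length(groupings)`.
#' @export
dubchakFeatures <- function(s, groupings = ctdGroupings()) {
  if (is(s, "PssmProfile")) s <- consensusSequence(s)
  letters <- strsplit(s, "")[[1]]
  L <- length(letters)
  if (L < 1L) stop("sequence must contain at least one residue")
  out <- numeric(0)
  for (prop in names(groupings)) {
    grouping <- groupings[[prop]]
    .checkGrouping(grouping, prop)
    cls <- integer(L)
    for (g in 1:3) cls[letters %in% grouping[[g]]] <- g
    comp <- tabulate(cls, 3L) / L
    trans <- numeric(3L)  # pairs (1,2), (1,3), (2,3)
    if (L > 1L) {
      a <- cls[-L]; b <- cls[-1L]
      pair_id <- function(g1, g2) (a == g1 & b == g2) | (a == g2 & b == g1)
      trans <- c(sum(pair_id(1, 2)), sum(pair_id(1, 3)),
                 sum(pair_id(2, 3))) / (L - 1L)
    }
    distr <- numeric(15L)
    for (g in 1:3) {
      pos <- which(cls == g)
      if (length(pos)) {
        n_g <- length(pos)
        picks <- c(1L, ceiling(c(0.25, 0.5, 0.75) * n_g), n_g)
        distr[(g - 1L) * 5L + 1:5] <- pos[picks] / L
      }
    }
    block <- c(comp, trans, distr)
    names(block) <- paste0(prop, "_", c(
      paste0("comp_g", 1:3),
      c("trans_g1g2", "trans_g1g3", "trans_g2g3"),
      paste0("dist_g", rep(1:3, each = 5L), "_",
             rep(c("first", "p25", "p50", "p75", "last"), 3L))))
    out <- c(out, block)
  }
  out
}

#' Evolutionary feature blocks from a PSSM
#'
#' Computes the seven evolutionary blocks in their canonical order:
#' amino-acid composition of the consensus (20), CTD descriptors of the
#' consensus (105), bigram of the normalized PSSM at lag 1 (400), PSSM
#' composition (20), PSSM auto-covariance to the distance factor (200 at
#' `df = 10`), one-lead bigram at lag 2 (400), and segmented distribution
#' (200 at `stepPercent = 10`). Total 1345 under defaults.
#'
#' @param p A [PssmProfile-class] with `L > max(df, 2)`.
#' @param df Distance factor for the auto-covariance block (default 10).
#' @param stepPercent Percentage step for the segmented distribution
#'   (default 10; 5 and 25 are the other conventional settings).
#' @param groupings CTD groupings, see [ctdGroupings()].
#' @return Named numeric vector; names are prefixed with the block name.
#' @export
evolutionaryFeatures <- function(p, df = 10L, stepPercent = 10,
                                 groupings = ctdGroupings()) {
  stopifnot(is(p, "PssmProfile"))
  N <- normalizePssm(p)
  consensus <- consensusSequence(p)
  blocks <- list(
    aac = aminoAcidComposition(consensus),
    ctd = dubchakFeatures(consensus, groupings),
    pssm_bigram = profileBigram(N, lag = 1L),
    pssm_composition = profileComposition(N),
    pssm_autocov = profileAutoCovariance(N, df = df),
    pssm_lead_bigram = profileBigram(N, lag = 2L),
    pssm_segdist = segmentedDistribution(N, stepPercent = stepPercent)
  )
  out <- unlist(blocks)
  names(out) <- unlist(lapply(names(blocks), function(b)
    paste(b, names(blocks[[b]]), sep = "_")))
  out
}
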