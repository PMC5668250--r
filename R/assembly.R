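## Concatenation of the evolutionary and structural blocks into one
## feature vector with a declared, stable layout.

#' Feature-vector layout
#'
#' Describes the 14 feature blocks of the concatenated vector under the
#' given parameters: block name, group (evolutionary or structural),
#' size, and 1-based start offset. Under the defaults (`df = 10`,
#' `stepPercent = 10`) the evolutionary blocks contribute 1345 features,
#' the structural blocks 201, for 1546 in total.
#'
#' @param df Distance factor for the auto-covariance blocks.
#' @param stepPercent Percentage step of the segmented distribution.
#' @return A data.frame with columns `block`, `group`, `size`, `offset`;
#'   offsets are contiguous and non-overlapping.
#' @examples
#' lay <- featureLayout()
#' nrow(lay)            # 14 blocks
#' sum(lay$size)        # 1546
#' @export
featureLayout <- function(df = 10L, stepPercent = 10) {
  df <- as.integer(df)
  if (df < 1L) stop("'df' must be a positive integer")
  if (stepPercent <= 0 || stepPercent > 50 || (50 %% stepPercent) != 0)
    stop("'stepPercent' must lie in (0, 50] and divide 50")
  seg <- as.integer(2L * (50 / stepPercent))
  blocks <- data.frame(
    block = c("aac", "ctd", "pssm_bigram", "pssm_composition",
              "pssm_autocov", "pssm_lead_bigram", "pssm_segdist",
              "ss_composition", "ss_occurrence",
              "asa_angle_prob_composition", "angle_bigram",
              "angle_autocov", "prob_bigram", "prob_autocov"),
    group = rep(c("evolutionary", "structural"), c(7L, 7L)),
    size = c(20L, 105L, 400L, 20L, 20L * df, 400L, 20L * seg,
             3L, 3L, 12L, 64L, 8L * df, 9L, 3L * df),
    stringsAsFactors = FALSE
  )
  blocks$offset <- cumsum(c(1L, blocks$size[-nrow(blocks)]))
  blocks
}

#' Extract the full feature vector of one protein
#'
#' Concatenates the seven evolutionary blocks computed from the PSSM
#' ([evolutionaryFeatures()]) and the seven structural blocks computed
#' from the SPD3 profile ([structuralFeatures()]) in the order declared
#' by [featureLayout()]. The two profiles must describe the same protein
#' and therefore have equal length; extraction is fully deterministic,
#' and the vector length (1546 under defaults) does not depend on L.
#'
#' @param p A [PssmProfile-class].
#' @param sp A [StructuralProfile-class] of the same protein.
#' @param df Distance factor for auto-covariance blocks (default 10).
#' @param stepPercent Segmented-distribution step (default 10).
#' @param groupings CTD groupings, see [ctdGroupings()].
#' @return Named numeric vector whose names carry the block prefixes of
#'   the layout.
#' @export
extractFeatures <- function(p, sp, df = 10L, stepPercent = 10,
                            groupings = ctdGroupings()) {
  stopifnot(is(p, "PssmProfile"), is(sp, "StructuralProfile"))
  if (profileLength(p) != profileLength(sp))
    stop(sprintf(
      "profile alignment error: PSSM covers %d residues but the structural profile covers %d",
      profileLength(p), profileLength(sp)))
  if (profileLength(p) <= max(df, 2L))
    stop(sprintf("profiles must cover more than %d residues for df = %d",
                 max(df, 2L), df))
  out <- c(evolutionaryFeatures(p, df = df, stepPercent = stepPercent,
                                groupings = groupings),
           structuralFeatures(sp, df = df))
  lay <- featureLayout(df = df, stepPercent = stepPercent)
  stopifnot(length(out) == sum(lay$size))
  out
}

#' Feature table of a labeled collection
#'
#' Applies [extractFeatures()] to every protein of a collection and
#' stacks the vectors into an n x p matrix with protein ids as row names.
#'
#' @param collection A [ProfileCollection-class].
#' @inheritParams extractFeatures
#' @return Numeric matrix (one row per protein) with the layout's
#'   feature names as column names.
#' @export
featureTable <- function(collection, df = 10L, stepPercent = 10,
                         groupings = ctdGroupings()) {
  stopifnot(is(collection, "ProfileCollection"))
  n <- nProteins(collection)
  if (n == 0L) stop("collection is empty")
  rows <- lapply(seq_len(n), function(i)
    extractFeatures(collection@pssm[[i]], collection@spd[[i]], df = df,
                    stepPercent = stepPercent, groupings = groupings))
  x <- do.call(rbind, rows)
  rownames(x) <- collection@ids
  x
}
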