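#' Profile accessors
#'
#' `profileId` returns the protein identifier, `profileLength` the number
#' of residues L covered by a profile.
#'
#' @param x A [PssmProfile-class] or [StructuralProfile-class].
#' @return `profileId`: a string; `profileLength`: an integer.
#' @examples
#' p <- PssmProfile("toy", matrix(0, 3, 20), "ACD")
#' profileId(p)
#' profileLength(p)
#' @export
setGeneric("profileId", function(x) standardGeneric("profileId"))

#' @rdname profileId
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))

#' @rdname profileId
setMethod("profileId", "PssmProfile", function(x) x@id)
#' @rdname profileId
setMethod("profileId", "StructuralProfile", function(x) x@id)
#' @rdname profileId
setMethod("profileLength", "PssmProfile", function(x) nrow(x@scores))
#' @rdname profileId
setMethod("profileLength", "StructuralProfile", function(x) nchar(x@ss))

#' Access the slots of a PssmProfile
#'
#' `pssmScores` returns the L x 20 log-odds matrix (columns in PSI-BLAST
#' order); `profileSequence` returns the query residue string.
#'
#' @param x A [PssmProfile-class].
#' @return A numeric matrix or a string.
#' @export
pssmScores <- function(x) {
  stopifnot(is(x, "PssmProfile"))
  x@scores
}

#' @rdname pssmScores
#' @export
profileSequence <- function(x) {
  stopifnot(is(x, "PssmProfile"))
  x@sequence
}

#' Access the slots of a StructuralProfile
#'
#' `ssString` returns the secondary-structure string, `asaValues` the
#' accessible surface areas, `torsionAngles` an L x 4 matrix of degrees
#' with columns (phi, psi, theta, tau), and `structProbs` the L x 3
#' structure-class probability matrix in internal (C, H, E) order.
#'
#' @param x A [StructuralProfile-class].
#' @return A string, numeric vector or numeric matrix.
#' @export
ssString <- function(x) {
  stopifnot(is(x, "StructuralProfile"))
  x@ss
}

#' @rdname ssString
#' @export
asaValues <- function(x) {
  stopifnot(is(x, "StructuralProfile"))
  x@asa
}

#' @rdname ssString
#' @export
torsionAngles <- function(x) {
  stopifnot(is(x, "StructuralProfile"))
  cbind(phi = x@phi, psi = x@psi, theta = x@theta, tau = x@tau)
}

#' @rdname ssString
#' @export
structProbs <- function(x) {
  stopifnot(is(x, "StructuralProfile"))
  x@probs
}

#' ProfileCollection accessors
#'
#' @param x A [ProfileCollection-class].
#' @return `profileIds`: character vector of ids; `collectionLabels`: the
#'   label factor; `nProteins`: number of entries; `pssmProfiles` /
#'   `structuralProfiles`: the named lists of profiles.
#' @export
profileIds <- function(x) {
  stopifnot(is(x, "ProfileCollection"))
  x@ids
}

#' @rdname profileIds
#' @export
collectionLabels <- function(x) {
  stopifnot(is(x, "ProfileCollection"))
  stats::setNames(x@labels, x@ids)
}

#' @rdname profileIds
#' @export
nProteins <- function(x) {
  stopifnot(is(x, "ProfileCollection"))
  length(x@ids)
}

#' @rdname profileIds
#' @export
pssmProfiles <- function(x) {
  stopifnot(is(x, "ProfileCollection"))
  stats::setNames(x@pssm, x@ids)
}

#' @rdname profileIds
#' @export
structuralProfiles <- function(x) {
  stopifnot(is(x, "ProfileCollection"))
  stats::setNames(x@spd, x@ids)
}

#' @describeIn ProfileCollection-class subset by index or id
#' @param x,i A collection and an index/id vector.
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "ProfileCollection", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  if (anyNA(i)) stop("unknown protein id in subset")
  ProfileCollection(x@ids[i], x@pssm[i], x@spd[i], x@labels[i])
})

#' RankedFeatureSet accessors
#'
#' @param x A [RankedFeatureSet-class].
#' @return `selectedFeatures`: integer indices of the surviving columns;
#'   `eliminationOrder`: data.frame of (index, iteration) removals.
#' @export
selectedFeatures <- function(x) {
  stopifnot(is(x, "RankedFeatureSet"))
  x@selected
}

#' @rdname selectedFeatures
#' @export
eliminationOrder <- function(x) {
  stopifnot(is(x, "RankedFeatureSet"))
  x@eliminationOrder
}

#' Extract the metric values of a MetricsReport
#'
#' @param x A [MetricsReport-class].
#' @return Named numeric vector with elements `Sn`, `Sp`, `Acc`, `MCC`,
#'   `auROC`, `auPR`.
#' @export
metricValues <- function(x) {
  stopifnot(is(x, "MetricsReport"))
  c(Sn = x@sn, Sp = x@sp, Acc = x@acc, MCC = x@mcc,
    auROC = x@auroc, auPR = x@aupr)
}

#' @rdname metricValues
#' @export
confusionCounts <- function(x) {
  stopifnot(is(x, "MetricsReport"))
  x@counts
}

setMethod("show", "PssmProfile", function(object) {
  cat("PssmProfile '", object@id, "': L = ", profileLength(object),
      " residues x 20 log-odds columns\n", sep = "")
  cat("  sequence: ", .abbrevSeq(object@sequence), "\n", sep = "")
})

setMethod("show", "StructuralProfile", function(object) {
  cat("StructuralProfile '", object@id, "': L = ", profileLength(object),
      " residues\n", sep = "")
  cat("  ss: ", .abbrevSeq(object@ss), "\n", sep = "")
  cat("  mean ASA: ", signif(mean(object@asa), 4), " A^2\n", sep = "")
})

setMethod("show", "ProfileCollection", function(object) {
  tab <- table(object@labels)
  cat("ProfileCollection: ", length(object@ids), " proteins (",
      tab[["binding"]], " binding, ", tab[["non-binding"]],
      " non-binding)\n", sep = "")
})

setMethod("show", "RankedFeatureSet", function(object) {
  cat("RankedFeatureSet: ", object@k, " of ", object@nFeatures,
      " features selected (", nrow(object@eliminationOrder),
      " eliminated)\n", sep = "")
})

setMethod("show", "BindingModel", function(object) {
  cat("BindingModel: ", object@kernel, " kernel, C = ", object@cost, sep = "")
  if (object@kernel != "linear") cat(", gamma = ", object@gamma, sep = "")
  cat("\n  features: ", length(object@center), sep = "")
  if (!is.null(object@selection))
    cat(" -> ", object@selection@k, " after selection", sep = "")
  cat("\n")
})

setMethod("show", "MetricsReport", function(object) {
  v <- metricValues(object)
  cat("MetricsReport\n")
  for (nm in names(v))
    cat(sprintf("  %-5s %s\n", nm,
                ifelse(is.na(v[nm]), "NA", sprintf("%.4f", v[nm]))))
  cat("  counts:", paste(names(object@counts), object@counts,
                         sep = "=", collapse = " "), "\n")
})

.abbrevSeq <- function(s, width = 40L) {
  if (nchar(s) <= width) s else paste0(substr(s, 1, width - 3), "...")
}
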