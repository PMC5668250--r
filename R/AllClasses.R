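#' @import methods
NULL

#' PSI-BLAST column order of the 20 standard amino acids
#'
#' The fixed column order of the log-odds block in an ASCII PSSM file,
#' as printed by PSI-BLAST: `ARNDCQEGHILKMFPSTWYV`.
#'
#' @return A character vector of 20 single-letter amino-acid codes.
#' @examples
#' pssmAlphabet()
#' @export
pssmAlphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.SS_STATES <- c("C", "H", "E")

.validProteinLetters <- function(residues) {
  letters <- strsplit(residues, "")[[1]]
  all(letters %in% pssmAlphabet())
}

#' PssmProfile: per-residue evolutionary profile
#'
#' An L x 20 matrix of log-odds substitution scores for one protein, as
#' produced by iterative profile search (PSI-BLAST `-out_ascii_pssm`),
#' together with the query sequence. Columns follow the fixed PSI-BLAST
#' order [pssmAlphabet()].
#'
#' @slot id Single protein identifier.
#' @slot scores Numeric L x 20 matrix of log-odds scores.
#' @slot sequence Query residues as a single string over the 20 standard
#'   amino-acid letters (proteins containing ambiguity codes such as X or
#'   Z are rejected, mirroring the benchmark construction).
#'
#' @seealso [parsePssm()], [writePssm()], [normalizePssm()]
#' @export
setClass("PssmProfile",
  representation(id = "character", scores = "matrix", sequence = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
      msg <- c(msg, "'id' must be a single non-empty string")
    if (!is.numeric(object@scores))
      msg <- c(msg, "'scores' must be numeric")
    if (ncol(object@scores) != 20L)
      msg <- c(msg, "'scores' must have exactly 20 columns")
    if (nrow(object@scores) < 1L)
      msg <- c(msg, "profile must cover at least one residue")
    if (any(!is.finite(object@scores)))
      msg <- c(msg, "'scores' must be finite")
    if (length(object@sequence) != 1L)
      msg <- c(msg, "'sequence' must be a single string")
    else {
      if (nchar(object@sequence) != nrow(object@scores))
        msg <- c(msg, "sequence length must equal the number of score rows")
      if (!.validProteinLetters(object@sequence))
        msg <- c(msg, "sequence contains letters outside the 20 standard amino acids")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a PssmProfile
#'
#' @param id Protein identifier.
#' @param scores Numeric L x 20 matrix of log-odds scores in PSI-BLAST
#'   column order.
#' @param sequence Query residues (single string, length L).
#' @return A [PssmProfile-class] object.
#' @examples
#' p <- PssmProfile("toy", matrix(0, 3, 20), "ACD")
#' profileLength(p)
#' @export
PssmProfile <- function(id, scores, sequence) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  dimnames(scores) <- list(NULL, pssmAlphabet())
  new("PssmProfile", id = as.character(id), scores = scores,
      sequence = as.character(sequence))
}

#' StructuralProfile: per-residue predicted-structure profile
#'
#' Holds the content of a SPIDER2/SPIDER3 SPD3 file: a three-state
#' secondary-structure string (C = coil, H = helix, E = strand), the
#' predicted accessible surface area in square Angstroms, four backbone
#' torsion angles in degrees, and per-residue probabilities of the three
#' structure classes in internal column order (C, H, E).
#'
#' @slot id Single protein identifier.
#' @slot ss Secondary-structure string over \{C,H,E\}, length L.
#' @slot asa Numeric vector of accessible surface areas (>= 0), length L.
#' @slot phi,psi,theta,tau Numeric vectors of angles in degrees within
#'   \[-180, 180\], length L each.
#' @slot probs Numeric L x 3 matrix of structure-class probabilities,
#'   columns (C, H, E); each row sums to 1 within 1e-3.
#'
#' @seealso [parseSpd()], [writeSpd()], [structuralFeatures()]
#' @export
setClass("StructuralProfile",
  representation(id = "character", ss = "character", asa = "numeric",
                 phi = "numeric", psi = "numeric", theta = "numeric",
                 tau = "numeric", probs = "matrix"),
  validity = function(object) {
    msg <- character()
    L <- nchar(object@ss)
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "'id' must be a single non-empty string")
    if (L < 1L)
      msg <- c(msg, "profile must cover at least one residue")
    if (!all(strsplit(object@ss, "")[[1]] %in% .SS_STATES))
      msg <- c(msg, "secondary-structure string may only contain C, H, E")
    for (nm in c("asa", "phi", "psi", "theta", "tau")) {
      if (length(slot(object, nm)) != L)
        msg <- c(msg, sprintf("'%s' must have length %d", nm, L))
    }
    if (any(object@asa < 0))
      msg <- c(msg, "accessible surface area must be non-negative")
    for (nm in c("phi", "psi", "theta", "tau")) {
      v <- slot(object, nm)
      if (length(v) == L && any(v < -180 | v > 180))
        msg <- c(msg, sprintf("'%s' angles must lie in [-180, 180] degrees", nm))
    }
    if (nrow(object@probs) != L || ncol(object@probs) != 3L)
      msg <- c(msg, "'probs' must be an L x 3 matrix")
    else {
      if (any(object@probs < 0 | object@probs > 1))
        msg <- c(msg, "'probs' entries must lie in [0, 1]")
      if (any(abs(rowSums(object@probs) - 1) > 1e-3))
        msg <- c(msg, "each 'probs' row must sum to 1 within 1e-3")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a StructuralProfile
#'
#' @param id Protein identifier.
#' @param ss Secondary-structure string over \{C,H,E\}.
#' @param asa Accessible surface areas (square Angstroms, >= 0).
#' @param phi,psi,theta,tau Torsion angles in degrees, \[-180, 180\].
#' @param probs L x 3 matrix of structure-class probabilities in internal
#'   (C, H, E) column order.
#' @return A [StructuralProfile-class] object.
#' @examples
#' sp <- StructuralProfile("toy", "CH", asa = c(10, 20),
#'   phi = c(-60, 60), psi = c(0, 45), theta = c(90, 100), tau = c(10, 20),
#'   probs = rbind(c(1, 0, 0), c(0, 1, 0)))
#' ssComposition(sp)
#' @export
StructuralProfile <- function(id, ss, asa, phi, psi, theta, tau, probs) {
  probs <- as.matrix(probs)
  storage.mode(probs) <- "double"
  dimnames(probs) <- list(NULL, .SS_STATES)
  new("StructuralProfile", id = as.character(id), ss = as.character(ss),
      asa = as.numeric(asa), phi = as.numeric(phi), psi = as.numeric(psi),
      theta = as.numeric(theta), tau = as.numeric(tau), probs = probs)
}

#' ProfileCollection: labeled set of paired profiles
#'
#' A labeled collection of proteins, each represented by a matched
#' [PssmProfile-class] and [StructuralProfile-class] of equal length, with
#' a binary label (`binding` / `non-binding`).
#'
#' @slot ids Character vector of unique protein identifiers.
#' @slot pssm List of [PssmProfile-class] objects, one per id.
#' @slot spd List of [StructuralProfile-class] objects, one per id.
#' @slot labels Factor with levels `c("non-binding", "binding")`.
#'
#' @seealso [loadCollection()], [generateCollection()], [featureTable()]
#' @export
setClass("ProfileCollection",
  representation(ids = "character", pssm = "list", spd = "list",
                 labels = "factor"),
  validity = function(object) {
    msg <- character()
    n <- length(object@ids)
    if (anyDuplicated(object@ids))
      msg <- c(msg, "protein ids must be unique")
    if (length(object@pssm) != n || length(object@spd) != n ||
        length(object@labels) != n)
      msg <- c(msg, "ids, pssm, spd and labels must have equal length")
    if (!identical(levels(object@labels), c("non-binding", "binding")))
      msg <- c(msg, "labels must be a factor with levels non-binding, binding")
    if (length(msg) == 0L && n > 0L) {
      for (i in seq_len(n)) {
        if (profileLength(object@pssm[[i]]) != profileLength(object@spd[[i]])) {
          msg <- c(msg, sprintf(
            "entry '%s': PSSM and structural profile lengths differ",
            object@ids[i]))
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ProfileCollection
#'
#' @param ids Character vector of protein identifiers.
#' @param pssm List of [PssmProfile-class] objects.
#' @param spd List of [StructuralProfile-class] objects.
#' @param labels Character or factor of `"binding"` / `"non-binding"`.
#' @return A [ProfileCollection-class].
#' @export
ProfileCollection <- function(ids, pssm, spd, labels) {
  labels <- factor(as.character(labels), levels = c("non-binding", "binding"))
  if (anyNA(labels))
    stop("labels must be 'binding' or 'non-binding'")
  new("ProfileCollection", ids = as.character(ids), pssm = unname(pssm),
      spd = unname(spd), labels = labels)
}

#' RankedFeatureSet: result of recursive feature elimination
#'
#' Records the k surviving feature columns and the order in which the
#' remaining columns were eliminated.
#'
#' @slot selected Integer indices (into the source layout) of the k
#'   surviving features, in original column order.
#' @slot eliminationOrder data.frame with columns `index` and `iteration`:
#'   which original column was removed at which elimination round.
#' @slot k Target number of features.
#' @slot nFeatures Number of columns in the source feature table.
#' @slot featureNames Column names of the source table (may be empty).
#'
#' @seealso [rfeSelect()], [applySelection()]
#' @export
setClass("RankedFeatureSet",
  representation(selected = "integer", eliminationOrder = "data.frame",
                 k = "integer", nFeatures = "integer",
                 featureNames = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@selected) != object@k)
      msg <- c(msg, "length(selected) must equal k")
    if (length(intersect(object@selected, object@eliminationOrder$index)))
      msg <- c(msg, "selected and eliminated features must be disjoint")
    if (any(object@selected < 1L | object@selected > object@nFeatures))
      msg <- c(msg, "selected indices out of range")
    if (nrow(object@eliminationOrder) != object@nFeatures - object@k)
      msg <- c(msg, "eliminationOrder must account for all dropped features")
    if (length(msg)) msg else TRUE
  }
)

#' BindingModel: trained DNA-binding classifier
#'
#' A trained support vector machine together with everything needed to
#' reproduce its decision function on raw feature vectors: per-feature
#' standardization parameters learned on the training data, the optional
#' feature selection, and the kernel settings.
#'
#' @slot fit The underlying `e1071::svm` fit.
#' @slot kernel Kernel name: `"linear"`, `"rbf"` or `"sigmoid"`.
#' @slot cost Soft-margin constant C.
#' @slot gamma Kernel width (stored for all kernels; inert for linear).
#' @slot coef0 Sigmoid offset r.
#' @slot center,scaleSd Standardization parameters over the full input
#'   layout (applied before selection).
#' @slot selection A [RankedFeatureSet-class], or NULL for no selection.
#' @slot featureNames Expected input column names (may be empty).
#' @slot orientation +1 or -1: sign applied to raw libsvm decision values
#'   so that positive scores always mean `binding`.
#' @slot version Serialization format version.
#'
#' @seealso [trainBindingModel()], [predict,BindingModel-method],
#'   [saveModel()], [loadModel()]
#' @export
setClass("BindingModel",
  representation(fit = "ANY", kernel = "character", cost = "numeric",
                 gamma = "numeric", coef0 = "numeric", center = "numeric",
                 scaleSd = "numeric", selection = "ANY",
                 featureNames = "character", orientation = "numeric",
                 version = "integer"))

#' MetricsReport: binary-classification performance summary
#'
#' Sensitivity, specificity, accuracy, Matthews correlation coefficient
#' and the areas under the ROC and precision-recall curves, with the
#' underlying confusion counts.
#'
#' @slot sn,sp,acc Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and
#'   accuracy (TP+TN)/total, each in \[0, 1\].
#' @slot mcc Matthews correlation coefficient in \[-1, 1\]; 0 when any
#'   factor of its denominator is 0.
#' @slot auroc,aupr Areas under the ROC and precision-recall curves
#'   (NA when scores are not supplied).
#' @slot counts Named integer vector (TP, FP, TN, FN).
#'
#' @seealso [classificationMetrics()], [kfoldCV()], [jackknifeCV()]
#' @export
setClass("MetricsReport",
  representation(sn = "numeric", sp = "numeric", acc = "numeric",
                 mcc = "numeric", auroc = "numeric", aupr = "numeric",
                 counts = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@counts), c("TP", "FP", "TN", "FN")))
      msg <- c(msg, "counts must be named TP, FP, TN, FN")
    if (any(object@counts < 0L))
      msg <- c(msg, "confusion counts must be non-negative")
    if (object@mcc < -1 - 1e-12 || object@mcc > 1 + 1e-12)
      msg <- c(msg, "MCC must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  }
)
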