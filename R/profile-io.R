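## Readers and writers for the external text dialects the method
## consumes: PSI-BLAST ASCII PSSM, SPIDER SPD3, FASTA and label tables.
## The writers exist so that fixtures and worked examples can round-trip
## through the same parsers that handle real tool output.

.readInputLines <- function(file) {
  if (length(file) == 1L && !grepl("\n", file) &&
      (file.exists(file) || grepl("://", file))) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(paste(file, collapse = "\n"), "\n", fixed = TRUE))
  }
}

.isNumericToken <- function(tok) {
  suppressWarnings(!is.na(as.numeric(tok)))
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the file produced by `psiblast -out_ascii_pssm` (conventionally
#' three iterations against nr with E = 0.001, though the parser does not
#' enforce how the file was made): header lines, one body row per residue
#' with the position, the query residue, 20 log-odds integers, 20 weighted
#' observed percentages and trailing per-position statistics. Only the
#' log-odds block and the residue column are retained; the percentage
#' columns and the footer are discarded.
#'
#' @param file Path to a PSSM file, or the file content as a character
#'   vector of lines / single string.
#' @param id Protein identifier to record; defaults to the file base name.
#' @return A [PssmProfile-class].
#' @examples
#' p <- PssmProfile("toy", matrix(rep(-1:2, 15), 3, 20), "ACD")
#' f <- tempfile(fileext = ".pssm")
#' writePssm(p, f)
#' identical(pssmScores(parsePssm(f)), pssmScores(p))
#' @export
parsePssm <- function(file, id = NULL) {
  lines <- .readInputLines(file)
  if (is.null(id)) {
    id <- if (length(file) == 1L && file.exists(file))
      sub("\\.[^.]*$", "", basename(file)) else "pssm"
  }
  alpha <- pssmAlphabet()
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) %in% c(20L, 40L) && all(toks %in% alpha)) {
      header_at <- i
      break
    }
  }
  if (is.na(header_at))
    stop("PSSM format error: no header row of amino-acid column letters found")
  body <- character()
  body_lineno <- integer()
  for (i in seq((header_at + 1L), length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (!grepl("^[0-9]+\\s+[A-Za-z]\\s", ln)) break
    body <- c(body, ln)
    body_lineno <- c(body_lineno, i)
  }
  if (length(body) == 0L)
    stop("PSSM empty-profile error: no body rows after the header")
  L <- length(body)
  scores <- matrix(0, L, 20L)
  residues <- character(L)
  for (r in seq_len(L)) {
    toks <- strsplit(body[r], "\\s+")[[1]]
    residues[r] <- toks[2L]
    if (!(residues[r] %in% alpha))
      stop(sprintf(
        "PSSM line %d: residue '%s' is not one of the 20 standard amino acids",
        body_lineno[r], residues[r]))
    num <- toks[-(1:2)]
    if (!all(.isNumericToken(num)))
      stop(sprintf("PSSM malformed row at line %d: non-numeric field",
                   body_lineno[r]))
    # 40 profile fields, optionally followed by the two per-position
    # statistics (information content, gapless match weight).
    if (!(length(num) %in% c(40L, 41L, 42L)))
      stop(sprintf(
        "PSSM malformed row at line %d: expected 40 numeric profile fields (plus optional trailing statistics), found %d numeric fields",
        body_lineno[r], length(num)))
    scores[r, ] <- as.numeric(num[1:20])
  }
  PssmProfile(id, scores, paste(residues, collapse = ""))
}

#' Write a PssmProfile as a PSI-BLAST style ASCII file
#'
#' Emits a file that [parsePssm()] accepts and that round-trips the
#' log-odds block exactly (scores are printed with 10 significant digits;
#' genuine PSI-BLAST log-odds are integers). The percentage block is
#' written as zeros and the two trailing statistics as 0.00: neither is
#' consumed downstream.
#'
#' @param x A [PssmProfile-class].
#' @param file Output path, or NULL to return the lines invisibly.
#' @return The file content as a character vector of lines, invisibly.
#' @export
writePssm <- function(x, file = NULL) {
  stopifnot(is(x, "PssmProfile"))
  alpha <- pssmAlphabet()
  residues <- strsplit(x@sequence, "")[[1]]
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", c(alpha, alpha)), collapse = " "))
  )
  for (i in seq_len(profileLength(x))) {
    vals <- sprintf("%3s", sprintf("%.10g", x@scores[i, ]))
    pct <- sprintf("%3d", rep(0L, 20L))
    lines <- c(lines, paste0(sprintf("%5d %s  ", i, residues[i]),
                             paste(c(vals, pct), collapse = " "),
                             "  0.00 0.00"))
  }
  lines <- c(lines, "")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Parse a SPIDER SPD3 file
#'
#' Reads the per-residue output of SPIDER2/SPIDER3 (both share the same
#' body layout): a `#`-prefixed header line, then one row per residue
#' with index, amino acid, secondary-structure label, ASA, the four
#' torsion angles Phi, Psi, Theta, Tau in degrees, and the three
#' structure-class probabilities in file order P(C), P(E), P(H). The
#' probability columns are re-mapped to the package's internal (C, H, E)
#' order. Angles are stored in degrees; conversion to radians happens in
#' the feature layer.
#'
#' @inheritParams parsePssm
#' @return A [StructuralProfile-class].
#' @export
parseSpd <- function(file, id = NULL) {
  lines <- .readInputLines(file)
  if (is.null(id)) {
    id <- if (length(file) == 1L && file.exists(file))
      sub("\\.[^.]*$", "", basename(file)) else "spd"
  }
  if (length(lines) == 0L || !startsWith(trimws(lines[1L]), "#"))
    stop("SPD3 format error: first line must be a '#' header")
  body <- trimws(lines[-1L])
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    stop("SPD3 empty-profile error: no body rows")
  L <- length(body)
  idx <- integer(L)
  ss <- character(L)
  asa <- numeric(L)
  ang <- matrix(0, L, 4L)
  probs <- matrix(0, L, 3L)
  for (r in seq_len(L)) {
    toks <- strsplit(body[r], "\\s+")[[1]]
    if (length(toks) < 11L)
      stop(sprintf("SPD3 malformed row %d: expected 11 fields, found %d",
                   r, length(toks)))
    idx[r] <- as.integer(toks[1L])
    ss[r] <- toks[3L]
    if (!(ss[r] %in% .SS_STATES))
      stop(sprintf("SPD3 format error at row %d: SS symbol '%s' not in {C,H,E}",
                   r, ss[r]))
    vals <- as.numeric(toks[4:11])
    asa[r] <- vals[1L]
    ang[r, ] <- vals[2:5]
    p_ceh <- vals[6:8]  # file order C, E, H
    if (abs(sum(p_ceh) - 1) > 0.01)
      stop(sprintf(
        "SPD3 validation error at row %d: probabilities sum to %.4f, outside [0.99, 1.01]",
        r, sum(p_ceh)))
    probs[r, ] <- p_ceh[c(1L, 3L, 2L)]  # internal order C, H, E
  }
  if (L > 1L && any(diff(idx) <= 0L))
    stop("SPD3 format error: index column is not strictly increasing")
  StructuralProfile(id, paste(ss, collapse = ""), asa,
                    phi = ang[, 1L], psi = ang[, 2L],
                    theta = ang[, 3L], tau = ang[, 4L], probs = probs)
}

#' Write a StructuralProfile as an SPD3 file
#'
#' Emits the SPIDER body layout that [parseSpd()] accepts, with the
#' probability columns back in file order (C, E, H). Reals are printed
#' with three decimal places, matching the precision of genuine SPIDER
#' output; profiles whose values carry no more precision than that (all
#' profiles written by [generateProfilePair()]) round-trip exactly.
#'
#' @param x A [StructuralProfile-class].
#' @param file Output path, or NULL to return the lines invisibly.
#' @return The file content as lines, invisibly.
#' @export
writeSpd <- function(x, file = NULL) {
  stopifnot(is(x, "StructuralProfile"))
  ss <- strsplit(x@ss, "")[[1]]
  # derive the residue column from nothing: SPD files carry the sequence,
  # but it is unused downstream, so a placeholder is written
  lines <- "# index AA SS ASA Phi Psi Theta Tau P(C) P(E) P(H)"
  for (i in seq_len(profileLength(x))) {
    lines <- c(lines, sprintf(
      "%d A %s %.3f %.3f %.3f %.3f %.3f %.3f %.3f %.3f",
      i, ss[i], x@asa[i], x@phi[i], x@psi[i], x@theta[i], x@tau[i],
      x@probs[i, "C"], x@probs[i, "E"], x@probs[i, "H"]))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] used for optional
#' cross-checks between a profile's residue column and the source FASTA.
#'
#' @param file Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
readProteinFasta <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  stats::setNames(as.character(aa), names(aa))
}

#' Read a two-column label table
#'
#' Labels are supplied as a headerless two-column TSV: protein id and a
#' binary label where 1 means binding and 0 non-binding (the strings
#' `binding` / `non-binding` are also accepted).
#'
#' @param file Path to the TSV file.
#' @return Named factor with levels `c("non-binding", "binding")`.
#' @export
readLabelTable <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = c("character", "character"))
  lab <- tab$label
  lab <- ifelse(lab %in% c("1", "binding"), "binding",
         ifelse(lab %in% c("0", "non-binding"), "non-binding", NA))
  if (anyNA(lab))
    stop("labels must be 0/1 or binding/non-binding")
  stats::setNames(factor(lab, levels = c("non-binding", "binding")), tab$id)
}

#' Load a labeled collection of paired profile files
#'
#' For every id in the label table, reads `<id>.pssm` from `pssmDir` and
#' `<id>.spd3` from `spdDir` and assembles a [ProfileCollection-class].
#'
#' @param pssmDir Directory of PSI-BLAST ASCII PSSM files.
#' @param spdDir Directory of SPD3 files.
#' @param labelsFile Two-column TSV of (id, label); see [readLabelTable()].
#' @param skipBad If TRUE, proteins whose files are missing or fail to
#'   parse are dropped with a warning instead of aborting the load.
#' @return A [ProfileCollection-class].
#' @export
loadCollection <- function(pssmDir, spdDir, labelsFile, skipBad = FALSE) {
  labels <- readLabelTable(labelsFile)
  ids <- names(labels)
  pssm <- vector("list", length(ids))
  spd <- vector("list", length(ids))
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    pf <- file.path(pssmDir, paste0(ids[i], ".pssm"))
    sf <- file.path(spdDir, paste0(ids[i], ".spd3"))
    res <- tryCatch({
      if (!file.exists(pf)) stop(sprintf("missing PSSM file for id '%s'", ids[i]))
      if (!file.exists(sf)) stop(sprintf("missing SPD3 file for id '%s'", ids[i]))
      list(p = parsePssm(pf, id = ids[i]), s = parseSpd(sf, id = ids[i]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!skipBad) stop(conditionMessage(res))
      warning(sprintf("skipping '%s': %s", ids[i], conditionMessage(res)))
      next
    }
    pssm[[i]] <- res$p
    spd[[i]] <- res$s
    keep[i] <- TRUE
  }
  ProfileCollection(ids[keep], pssm[keep], spd[keep], labels[keep])
}
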