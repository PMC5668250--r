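makePssmText <- function(rows, residues) {
  header <- paste0("            ",
                   paste(sprintf("%3s", rep(pssmAlphabet(), 2)), collapse = " "))
  body <- vapply(seq_along(residues), function(i)
    paste0(sprintf("%5d %s  ", i, residues[i]),
           paste(sprintf("%3d", c(rows[[i]], rep(0L, 20))), collapse = " "),
           "  0.35 0.12"),
    character(1))
  c("", "Last position-specific scoring matrix computed", header, body, "")
}

test_that("parsePssm echoes the log-odds block, residue column and L", {
  rows <- list(c(2L, -1L, 0:17), rep(1L, 20), rep(-3L, 20))
  txt <- makePssmText(rows, c("A", "C", "D"))
  p <- parsePssm(txt, id = "fix")
  expect_s4_class(p, "PssmProfile")
  expect_identical(profileLength(p), 3L)
  expect_identical(unname(pssmScores(p)[1, 1]), 2)
  expect_identical(unname(pssmScores(p)[1, 2]), -1)
  expect_identical(profileSequence(p), "ACD")
  expect_identical(dim(pssmScores(p)), c(3L, 20L))
})

test_that("parsePssm rejects malformed input with informative errors", {
  rows <- list(rep(1L, 20))
  good <- makePssmText(rows, "A")
  expect_error(parsePssm(good[-3], id = "x"), "no header")
  bad_row <- good
  bad_row[4] <- "    1 A    1 2 3"
  expect_error(parsePssm(bad_row, id = "x"), "line 4")
  no_body <- good[1:3]
  expect_error(parsePssm(no_body, id = "x"), "empty-profile")
  bad_res <- good
  bad_res[4] <- sub("^(\\s*1) A", "\\1 X", bad_res[4])
  expect_error(parsePssm(bad_res, id = "x"), "standard amino acids")
})

test_that("written PSSM has the 40-field body contract and round-trips", {
  set.seed(21)
  p <- randomPssmProfile(60)
  lines <- writePssm(p)
  body <- grep("^\\s*\\d+\\s+[A-Z]\\s", lines, value = TRUE)
  expect_length(body, 60)
  n_num <- vapply(strsplit(trimws(body), "\\s+"), function(tok)
    sum(!is.na(suppressWarnings(as.numeric(tok[-2])))), integer(1))
  expect_true(all(n_num == 43L))  # position + 40 profile fields + 2 stats
  p2 <- parsePssm(lines, id = profileId(p))
  expect_identical(pssmScores(p2), pssmScores(p))
  expect_identical(profileSequence(p2), profileSequence(p))
})

test_that("parseSpd remaps (C,E,H) file order to internal (C,H,E)", {
  txt <- c("# index AA SS ASA Phi Psi Theta Tau P(C) P(E) P(H)",
           "1 A C 10.0 180.0 -60.0 90.0 10.0 1 0 0",
           "2 A H 12.0 -45.0 30.0 80.0 20.0 0 0 1")
  sp <- parseSpd(txt, id = "fix")
  expect_equal(unname(structProbs(sp)[1, ]), c(1, 0, 0))
  expect_equal(unname(structProbs(sp)[2, ]), c(0, 1, 0))
  expect_identical(unname(torsionAngles(sp)[1, "phi"]), 180)  # degrees, unconverted
  expect_identical(ssString(sp), "CH")
})

test_that("parseSpd enforces its validation rules", {
  hdr <- "# header"
  row <- function(i, ss, probs)
    paste(i, "A", ss, "10.0 0 0 0 0", paste(probs, collapse = " "))
  expect_error(parseSpd(c(hdr, row(1, "Q", c(1, 0, 0)))), "not in \\{C,H,E\\}")
  expect_error(parseSpd(c(hdr, row(1, "C", c(0.5, 0.3, 0.1)))),
               "outside \\[0.99, 1.01\\]")
  expect_error(parseSpd(c(hdr, row(2, "C", c(1, 0, 0)),
                          row(1, "C", c(1, 0, 0)))),
               "not strictly increasing")
  expect_error(parseSpd(c("1 A C 10 0 0 0 0 1 0 0")), "'#' header")
  expect_error(parseSpd(hdr), "empty-profile")
})

test_that("parse(write(x)) is the identity for both formats on random fixtures", {
  set.seed(22)
  for (i in 1:25) {
    L <- sample(12:40, 1)
    pair <- generateProfilePair(L, sample(c("binding", "non-binding"), 1),
                                effect = runif(1, 0, 2), id = "rt")
    p2 <- parsePssm(writePssm(pair$pssm), id = "rt")
    expect_identical(pssmScores(p2), pssmScores(pair$pssm))
    expect_identical(profileSequence(p2), profileSequence(pair$pssm))
    s2 <- parseSpd(writeSpd(pair$spd), id = "rt")
    expect_identical(ssString(s2), ssString(pair$spd))
    expect_identical(asaValues(s2), asaValues(pair$spd))
    expect_identical(torsionAngles(s2), torsionAngles(pair$spd))
    expect_identical(structProbs(s2), structProbs(pair$spd))
  }
  # L = 1 profile writes a single body row
  one <- PssmProfile("one", matrix(1, 1, 20), "A")
  expect_length(grep("^\\s*1\\s+A\\s", writePssm(one)), 1)
})

test_that("label tables and FASTA read back as expected", {
  tmp <- tempfile()
  writeLines(c("p1\t1", "p2\t0", "p3\tbinding"), tmp)
  lab <- readLabelTable(tmp)
  expect_identical(as.character(lab), c("binding", "non-binding", "binding"))
  expect_identical(names(lab), c("p1", "p2", "p3"))
  writeLines(c("p1\t2"), tmp)
  expect_error(readLabelTable(tmp), "0/1")

  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDEF", ">p2", "KLMNP"), fa)
  seqs <- readProteinFasta(fa)
  expect_identical(unname(seqs), c("ACDEF", "KLMNP"))
})

test_that("loadCollection pairs files by id and reports missing ones", {
  dir <- tempfile()
  coll <- generateCollection(nPos = 3, nNeg = 3, lengthRange = c(20, 30),
                             effect = 0, seed = 31, dir = dir)
  reloaded <- loadCollection(dir, dir, file.path(dir, "labels.tsv"))
  expect_identical(profileIds(reloaded), profileIds(coll))
  expect_identical(as.character(collectionLabels(reloaded)),
                   as.character(collectionLabels(coll)))
  expect_identical(pssmScores(pssmProfiles(reloaded)[["prot001"]]),
                   pssmScores(pssmProfiles(coll)[["prot001"]]))
  file.remove(file.path(dir, "prot002.spd3"))
  expect_error(loadCollection(dir, dir, file.path(dir, "labels.tsv")),
               "prot002")
  reduced <- suppressWarnings(
    loadCollection(dir, dir, file.path(dir, "labels.tsv"), skipBad = TRUE))
  expect_identical(nProteins(reduced), 5L)
})
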