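test_that("logistic normalization hits midpoint, symmetry and known values", {
  scores <- matrix(0, 2, 20)
  scores[1, 1] <- 2; scores[2, 1] <- -2
  p <- PssmProfile("t", scores, "AC")
  N <- normalizePssm(p)
  expect_equal(unname(N[1, 2]), 0.5)                       # m = 0
  expect_equal(unname(N[1, 1]), 1 / (1 + exp(-2)))         # 0.880797...
  expect_equal(unname(N[1, 1] + N[2, 1]), 1)               # logistic symmetry
  expect_true(all(N > 0 & N < 1))
})

test_that("normalization is strictly monotone per entry", {
  set.seed(41)
  m <- sort(rnorm(50, sd = 4))
  scores <- matrix(rep(m, length.out = 20 * 50), 50, 20)
  p <- PssmProfile("t", scores, paste(rep("A", 50), collapse = ""))
  expect_true(all(diff(normalizePssm(p)[, 1]) >
                  -1e-15))
  expect_true(all(diff(normalizePssm(p)[order(scores[, 1]), 1]) >= 0))
})

test_that("consensus takes the per-row argmax with first-column tie break", {
  scores <- matrix(0, 3, 20)
  scores[1, 2] <- 7                      # unique max at column R
  scores[3, 5] <- scores[3, 7] <- 4      # tie C vs E -> C (smaller index)
  p <- PssmProfile("t", scores, "AAA")
  cs <- consensusSequence(p)
  expect_identical(substr(cs, 1, 1), "R")
  expect_identical(substr(cs, 2, 2), "A")  # all-equal row -> first column
  expect_identical(substr(cs, 3, 3), "C")
  set.seed(42)
  rp <- randomPssmProfile(10)
  oracle <- paste(vapply(seq_len(10), function(i) {
    row <- pssmScores(rp)[i, ]
    pssmAlphabet()[which(row == max(row))[1]]
  }, character(1)), collapse = "")
  expect_identical(consensusSequence(rp), oracle)
})

test_that("amino-acid composition is the normalized letter count", {
  aac <- aminoAcidComposition("AAAA")
  expect_equal(unname(aac[["A"]]), 1)
  expect_equal(sum(aac), 1)
  aac2 <- aminoAcidComposition("ACAC")
  expect_equal(unname(aac2[c("A", "C")]), c(0.5, 0.5))
  expect_length(aac2, 20)
  expect_error(aminoAcidComposition("ABX"), "standard amino acids")
})

test_that("CTD groupings partition the alphabet and feed 105 features", {
  g <- ctdGroupings()
  expect_length(g, 5)
  for (prop in g)
    expect_setequal(unlist(prop), pssmAlphabet())
  d <- dubchakFeatures("ACDEFGHIKLMNPQRSTVWY")
  expect_length(d, 105)
})

test_that("CTD descriptors match direct-scan expectations", {
  # sequence entirely in the polar hydrophobicity group
  d <- dubchakFeatures("RRRR")
  h <- d[startsWith(names(d), "hydrophobicity_")]
  expect_equal(unname(h[paste0("hydrophobicity_comp_g", 1:3)]), c(1, 0, 0))
  expect_equal(unname(h[grep("trans", names(h))]), c(0, 0, 0))
  # group-1 distribution of 4 occurrences: picks 1, ceil(1)=1, 2, 3, 4
  expect_equal(unname(h[paste0("hydrophobicity_dist_g1_",
                               c("first", "p25", "p50", "p75", "last"))]),
               c(1, 1, 2, 3, 4) / 4)
  expect_true(all(h[grep("dist_g[23]", names(h))] == 0))

  # strict alternation between groups 1 and 2, L = 10: transition = 9/9
  alt <- dubchakFeatures(paste(rep(c("R", "G"), 5), collapse = ""))
  expect_equal(unname(alt[["hydrophobicity_trans_g1g2"]]), 1)

  # composition triple always sums to 1 per property
  set.seed(43)
  s <- paste(sample(pssmAlphabet(), 30, replace = TRUE), collapse = "")
  d2 <- dubchakFeatures(s)
  for (prop in names(ctdGroupings()))
    expect_equal(sum(d2[paste0(prop, "_comp_g", 1:3)]), 1)
})

test_that("single-residue sequences yield zero transitions, not errors", {
  d <- dubchakFeatures("K")
  expect_true(all(d[grep("trans", names(d))] == 0))
  expect_equal(unname(d[["charge_comp_g1"]]), 1)  # K is positive
})

test_that("evolutionary vector has the documented block structure", {
  set.seed(44)
  p <- randomPssmProfile(40)
  ev <- evolutionaryFeatures(p)
  expect_length(ev, 1345)
  N <- normalizePssm(p)
  expect_equal(unname(ev[grep("^pssm_composition_", names(ev))]),
               unname(profileComposition(N)))
  expect_equal(unname(ev[grep("^pssm_bigram_", names(ev))]),
               unname(profileBigram(N, 1)))
  expect_equal(unname(ev[grep("^pssm_lead_bigram_", names(ev))]),
               unname(profileBigram(N, 2)))
  expect_equal(unname(ev[grep("^pssm_autocov_", names(ev))]),
               unname(profileAutoCovariance(N, 10)))
  expect_equal(unname(ev[grep("^pssm_segdist_", names(ev))]),
               unname(segmentedDistribution(N, 10)))
  # constant all-0.5 normalized matrix -> composition all 0.5
  p0 <- PssmProfile("z", matrix(0, 100, 20),
                    paste(rep("A", 100), collapse = ""))
  ev0 <- evolutionaryFeatures(p0)
  expect_equal(unname(ev0[grep("^pssm_composition_", names(ev0))]),
               rep(0.5, 20))
})
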