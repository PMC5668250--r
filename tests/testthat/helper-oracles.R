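# Independent naive implementations of the profile operators, written as
# literal double loops over their defining sums. They deliberately share
# no code with the package and serve as oracles in the equivalence tests.

naiveComposition <- function(X) {
  L <- nrow(X); W <- ncol(X)
  out <- numeric(W)
  for (j in seq_len(W)) {
    s <- 0
    for (i in seq_len(L)) s <- s + X[i, j]
    out[j] <- s / L
  }
  out
}

naiveBigram <- function(X, lag) {
  L <- nrow(X); W <- ncol(X)
  out <- numeric(W * W)
  pos <- 0L
  for (k in seq_len(W)) {
    for (l in seq_len(W)) {
      pos <- pos + 1L
      s <- 0
      for (i in seq_len(L - lag)) s <- s + X[i, k] * X[i + lag, l]
      out[pos] <- s / L
    }
  }
  out
}

naiveAutoCov <- function(X, df) {
  L <- nrow(X); W <- ncol(X)
  out <- numeric(W * df)
  pos <- 0L
  for (j in seq_len(W)) {
    for (k in seq_len(df)) {
      pos <- pos + 1L
      s <- 0
      for (i in seq_len(L - k)) s <- s + X[i, j] * X[i + k, j]
      out[pos] <- s / L
    }
  }
  out
}

naiveSegDist <- function(X, stepPercent) {
  L <- nrow(X); W <- ncol(X)
  thresholds <- seq(stepPercent, 50, by = stepPercent) / 100
  out <- numeric(0)
  for (j in seq_len(W)) {
    total <- sum(X[, j])
    top <- numeric(length(thresholds))
    bottom <- numeric(length(thresholds))
    for (t in seq_along(thresholds)) {
      s <- 0
      for (i in seq_len(L)) {
        s <- s + X[i, j]
        if (s >= thresholds[t] * total - 1e-12 * total) { top[t] <- i / L; break }
      }
      s <- 0
      for (i in rev(seq_len(L))) {
        s <- s + X[i, j]
        if (s >= thresholds[t] * total - 1e-12 * total) {
          bottom[t] <- (L - i + 1) / L
          break
        }
      }
    }
    out <- c(out, top, bottom)
  }
  out
}

# Mann-Whitney auROC by exhaustive pairwise comparison, ties half credit.
pairwiseAuroc <- function(labels, scores) {
  pos <- scores[labels == "binding"]
  neg <- scores[labels == "non-binding"]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# A tiny deterministic profile pair for structural tests.
toyStructuralProfile <- function(ss = "CHECHECHECHE",
                                 id = "toy") {
  L <- nchar(ss)
  StructuralProfile(id, ss,
    asa = seq(10, by = 5, length.out = L),
    phi = seq(-150, 150, length.out = L),
    psi = seq(-120, 120, length.out = L),
    theta = seq(-90, 90, length.out = L),
    tau = seq(-60, 60, length.out = L),
    probs = {
      p <- matrix(0.1, L, 3)
      states <- strsplit(ss, "")[[1]]
      for (i in seq_len(L)) p[i, match(states[i], c("C", "H", "E"))] <- 0.8
      p
    })
}

randomPssmProfile <- function(L, id = "rand") {
  scores <- matrix(sample(-10:10, L * 20, replace = TRUE), L, 20)
  seqs <- paste(sample(pssmAlphabet(), L, replace = TRUE), collapse = "")
  PssmProfile(id, scores, seqs)
}
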