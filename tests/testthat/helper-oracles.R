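# Shared fixtures and independent brute-force oracles.

AA <- aa_alphabet()

rand_seq <- function(L, probs = NULL) {
  paste(sample(AA, L, replace = TRUE, prob = probs), collapse = "")
}

# Brute-force amino-acid composition: plain counting loop.
oracle_ac <- function(residues) {
  ch <- strsplit(residues, "")[[1]]
  v <- vapply(AA, function(a) sum(ch == a), 0) / length(ch)
  names(v) <- AA
  v
}

# Brute-force dipeptide tally over all adjacent pairs.
oracle_dc <- function(residues) {
  ch <- strsplit(residues, "")[[1]]
  L <- length(ch)
  v <- setNames(numeric(400), as.vector(t(outer(AA, AA, paste0))))
  for (p in seq_len(L - 1)) {
    pair <- paste0(ch[p], ch[p + 1])
    v[pair] <- v[pair] + 1
  }
  v / (L - 1)
}

# Brute-force PSSM composition: explicit double loop over positions/columns.
oracle_pssm_comp <- function(scores_alpha, residues) {
  ch <- strsplit(residues, "")[[1]]
  L <- length(ch)
  out <- matrix(0, 20, 20, dimnames = list(AA, AA))
  for (p in seq_len(L)) {
    for (b in seq_len(20)) {
      out[ch[p], b] <- out[ch[p], b] + 1 / (1 + exp(-scores_alpha[p, b]))
    }
  }
  setNames(as.vector(t(out / L)), as.vector(t(outer(AA, AA, paste0))))
}

# Exhaustive pairwise AUC oracle: P(score+ > score-) + 1/2 P(tie).
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Direct evaluation of the four metric formulas.
oracle_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  list(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

# Slow R-level best-offset ungapped identity, independent of the C++ one.
oracle_identity <- function(a, b) {
  s <- if (nchar(a) <= nchar(b)) a else b
  l <- if (nchar(a) <= nchar(b)) b else a
  sc <- strsplit(s, "")[[1]]
  lc <- strsplit(l, "")[[1]]
  best <- 0
  for (off in 0:(length(lc) - length(sc))) {
    best <- max(best, sum(sc == lc[off + seq_along(sc)]))
  }
  best / length(sc)
}

# Small labelled dataset for model tests: scaled-down benchmark.
small_benchmark <- function(seed = 7, scale = 0.12) {
  default_benchmark(seed = seed, scale = scale)
}

# Mutate a template sequence at a given fraction of positions.
mutate_seq <- function(template, rate) {
  ch <- strsplit(template, "")[[1]]
  k <- max(0, round(rate * length(ch)))
  if (k > 0) {
    pos <- sample(seq_along(ch), k)
    ch[pos] <- sample(AA, k, replace = TRUE)
  }
  paste(ch, collapse = "")
}
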