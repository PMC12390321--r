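# Independent oracles and shared fixtures. Oracles deliberately avoid the
# package's code paths: exhaustive scans, direct pair counting, textbook
# formulas.

# Exhaustive per-window Hamming scan (substring-based, no shared code with
# min_mismatch_batch).
naive_min_mismatch <- function(peptide, proteome) {
  L <- nchar(peptide)
  pc <- strsplit(peptide, "")[[1]]
  best <- L
  for (s in proteome) {
    n <- nchar(s)
    if (n < L) next
    for (i in seq_len(n - L + 1)) {
      w <- strsplit(substring(s, i, i + L - 1), "")[[1]]
      best <- min(best, sum(w != pc))
    }
  }
  best
}

# AUC by direct concordant-pair counting (ties = 1/2).
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Textbook Benjamini-Hochberg step-up.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Shared small residue encoder built from a seeded synthetic property table.
test_encoder <- local({
  enc <- NULL
  function() {
    if (is.null(enc)) {
      pm <- read_aaindex(make_property_table(seed = 7, n_props = 30, n_missing = 3))
      enc <<- fit_residue_encoder(pm)
    }
    enc
  }
})

# Nearest-centroid classifier (2-fold, standardized features): an independent
# reference learner for planted-signal recovery checks.
nearest_centroid_auc <- function(x, y, seed = 1) {
  keep <- apply(x, 2, stats::sd) > 0
  z <- scale(x[, keep, drop = FALSE])
  set.seed(seed)
  n <- nrow(z)
  half <- sample(n, n %/% 2)
  fold_auc <- function(train, test) {
    c1 <- colMeans(z[train, , drop = FALSE][y[train] == 1, , drop = FALSE])
    c0 <- colMeans(z[train, , drop = FALSE][y[train] == 0, , drop = FALSE])
    s <- apply(z[test, , drop = FALSE], 1, function(r) sum((r - c0)^2) - sum((r - c1)^2))
    pairwise_auc(s, y[test])
  }
  mean(c(
    fold_auc(half, setdiff(seq_len(n), half)),
    fold_auc(setdiff(seq_len(n), half), half)
  ))
}

# Vectorized unique random peptide pool with a given length mix.
random_peptide_pool <- function(n, length_mix = c(`9` = 0.7, `10` = 0.2, `11` = 0.1),
                                seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  counts <- round(n * length_mix * 1.02) + 5 # headroom for dedup
  out <- unlist(lapply(names(counts), function(l) {
    L <- as.integer(l)
    m <- matrix(sample(aa, counts[[l]] * L, replace = TRUE), ncol = L)
    apply(m, 1, paste, collapse = "")
  }))
  unique(out)
}

random_peptides <- function(n, length = 9, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], length, replace = TRUE),
      collapse = ""
    )
  }, character(1))
}
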