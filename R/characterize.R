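# Dataset composition diagnostics: per-position amino-acid frequencies,
# frequency-difference logos, positionwise chi-square tests with
# Benjamini-Hochberg correction, and per-position Shannon entropy.
# Analyses default to 9-mers, the dominant length class.

#' Per-position amino-acid frequency matrix
#'
#' @param peptides character vector; only peptides of `length` are used.
#' @param length peptide length analyzed (default 9).
#' @return a `position_frequency_matrix`: list with `length`, `counts`
#'   (position x 20 integer matrix), `freqs` (rows sum to 1).
#' @export
position_frequency_matrix <- function(peptides, length = 9L) {
  peptides <- validate_peptides(peptides)
  peptides <- peptides[nchar(peptides) == length]
  if (length(peptides) == 0) {
    stop(sprintf("no peptides of length %d", length), call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(peptides, "")), ncol = length, byrow = TRUE)
  counts <- t(apply(chars, 2, function(col) {
    table(factor(col, levels = AA_CANONICAL))
  }))
  dimnames(counts) <- list(paste0("pos", seq_len(length)), AA_CANONICAL)
  structure(
    list(
      length = as.integer(length),
      counts = counts,
      freqs = counts / rowSums(counts)
    ),
    class = "position_frequency_matrix"
  )
}

#' Frequency-difference logo matrix between two peptide sets
#'
#' Entry (position, residue) is `freqA - freqB`: positive values mark residues
#' enriched in set A (immunogenic), negative values residues enriched in set B.
#'
#' @param setA,setB character vectors of peptides.
#' @param length peptide length analyzed (default 9).
#' @return list with `diff` (position x 20 signed matrix) and
#'   `total_abs_diff` (per-position sum of absolute differences).
#' @export
frequency_difference_logo <- function(setA, setB, length = 9L) {
  fa <- position_frequency_matrix(setA, length)$freqs
  fb <- position_frequency_matrix(setB, length)$freqs
  d <- fa - fb
  list(diff = d, total_abs_diff = rowSums(abs(d)))
}

#' Positionwise chi-square tests of residue composition
#'
#' At each position, tests the 2 x 20 contingency table of residue counts in
#' the two sets (categories with zero total count are dropped); p-values are
#' Benjamini-Hochberg adjusted across positions.
#'
#' @inheritParams frequency_difference_logo
#' @return data.frame with columns `position`, `statistic`, `df`, `p`,
#'   `p_adjusted`.
#' @export
positionwise_chi_square <- function(setA, setB, length = 9L) {
  ca <- position_frequency_matrix(setA, length)$counts
  cb <- position_frequency_matrix(setB, length)$counts
  res <- lapply(seq_len(length), function(p) {
    tab <- rbind(A = ca[p, ], B = cb[p, ])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      # both sets fully conserved to the same residue: no contrast to test
      return(c(statistic = 0, df = 0, p = 1))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    c(statistic = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$position <- seq_len(length)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[, c("position", "statistic", "df", "p", "p_adjusted")]
}

#' Per-position Shannon entropy (nats)
#'
#' `H(p) = -sum f log f` over residues with positive frequency; ranges from 0
#' (complete conservation) to `log(20)` (~3, maximal diversity).
#'
#' @inheritParams position_frequency_matrix
#' @return numeric vector of per-position entropies.
#' @export
positional_entropy <- function(peptides, length = 9L) {
  f <- position_frequency_matrix(peptides, length)$freqs
  apply(f, 1, function(row) {
    row <- row[row > 0]
    -sum(row * log(row))
  })
}

#' Per-position characterization summary of two peptide sets
#'
#' @inheritParams frequency_difference_logo
#' @return data.frame with per-position `total_abs_diff`, `entropy_A`,
#'   `entropy_B`, chi-square `statistic`, `p`, `p_adjusted`.
#' @export
characterize_sets <- function(setA, setB, length = 9L) {
  logo <- frequency_difference_logo(setA, setB, length)
  chi <- positionwise_chi_square(setA, setB, length)
  data.frame(
    position = chi$position,
    total_abs_diff = unname(logo$total_abs_diff),
    entropy_A = unname(positional_entropy(setA, length)),
    entropy_B = unname(positional_entropy(setB, length)),
    statistic = chi$statistic,
    p = chi$p,
    p_adjusted = chi$p_adjusted
  )
}
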