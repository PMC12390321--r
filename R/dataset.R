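# Training-set assembly: non-self filtering against a reference proteome and
# length-stratified subsampling to the target class ratio.
#
# "Mismatch" is a pure Hamming distance over equal-length windows (no gaps):
# the minimum number of substitutions separating the peptide from any window
# of any protein. Exact-substring peptides (distance 0) are self and removed
# from both classes; negatives must additionally sit within 1-3 mismatches of
# the proteome so they plausibly derive from somatic mutations.

#' Read a reference proteome from FASTA
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return named character vector of protein sequences.
#' @export
read_proteome_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Minimum Hamming distance from a peptide to a proteome
#'
#' Scans every equal-length window of every protein and returns the minimum
#' number of mismatching positions. 0 means the peptide is an exact substring
#' of the proteome (self).
#'
#' @param peptide a 9-11-mer sequence.
#' @param proteome named character vector of protein sequences (or anything
#'   coercible via `as.character`).
#' @return a non-negative integer.
#' @export
#' @examples
#' min_mismatch_to_proteome("MKTAYIAKR", c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"))
min_mismatch_to_proteome <- function(peptide, proteome) {
  min_mismatch_batch(peptide, proteome)[[1]]
}

#' @rdname min_mismatch_to_proteome
#' @param peptides character vector of peptides (batch form; the proteome is
#'   preprocessed once).
#' @return `min_mismatch_batch()` returns an integer vector parallel to
#'   `peptides`.
#' @export
min_mismatch_batch <- function(peptides, proteome) {
  proteome <- as.character(proteome)
  if (length(proteome) == 0 || all(!nzchar(proteome))) {
    stop("empty proteome", call. = FALSE)
  }
  peptides <- validate_peptides(peptides)
  prot_int <- lapply(proteome, utf8ToInt)
  out <- integer(length(peptides))
  for (i in seq_along(peptides)) {
    p <- utf8ToInt(peptides[i])
    L <- length(p)
    best <- L
    for (s in prot_int) {
      n <- length(s)
      if (n < L) next
      nw <- n - L + 1L
      mism <- integer(nw)
      for (j in seq_len(L)) {
        mism <- mism + (s[j:(j + nw - 1L)] != p[j])
        # partial mismatch counts only grow: abandon once no window can win
        if (min(mism) >= best) break
      }
      best <- min(best, min(mism))
      if (best == 0L) break
    }
    out[i] <- best
  }
  out
}

#' Assemble the positive (immunogenic) peptide set
#'
#' Retains unique 9-11-mers recorded as T-cell positive that are non-self
#' (at least one mismatch to the reference proteome). First-occurrence order
#' is preserved.
#'
#' @param records data.frame with columns `peptide` and `assay_class`
#'   (values `tcell_positive` / `presented_only`).
#' @param proteome named character vector of protein sequences.
#' @return character vector of retained peptides.
#' @export
build_positive_set <- function(records, proteome) {
  stopifnot(all(c("peptide", "assay_class") %in% names(records)))
  pep <- validate_peptides(records$peptide[records$assay_class == "tcell_positive"])
  pep <- pep[!duplicated(pep)]
  pep[min_mismatch_batch(pep, proteome) >= 1L]
}

#' Assemble the negative (presented, non-immunogenic) peptide set
#'
#' Retains unique presented-only peptides that are not in the positive set
#' and carry 1-3 mismatches to the reference proteome (non-self, but close
#' enough to plausibly arise from somatic mutation).
#'
#' @inheritParams build_positive_set
#' @param positives peptides already assigned to the positive class.
#' @return character vector of retained peptides.
#' @export
build_negative_set <- function(records, proteome, positives = character()) {
  stopifnot(all(c("peptide", "assay_class") %in% names(records)))
  pep <- validate_peptides(records$peptide[records$assay_class == "presented_only"])
  pep <- pep[!duplicated(pep)]
  pep <- setdiff(pep, positives)
  mm <- min_mismatch_batch(pep, proteome)
  pep[mm >= 1L & mm <= 3L]
}

#' Subsample negatives to a target class ratio, preserving length distribution
#'
#' Retains `floor(ratio * |positives|)` negatives, apportioned across peptide
#' lengths by the positive set's length distribution using the
#' largest-remainder method, then sampled without replacement within each
#' length stratum (seeded; ties broken by input order).
#'
#' @param positives,negatives character vectors of peptides.
#' @param ratio negatives-to-positives ratio (default 3.5).
#' @param seed integer seed for the within-stratum draw.
#' @return an object of class `training_dataset` with fields `positives`,
#'   `negatives`, `length_histogram` (per class), `ratio`.
#' @export
subsample_to_ratio <- function(positives, negatives, ratio = 3.5, seed = 1L) {
  positives <- validate_peptides(positives)
  negatives <- validate_peptides(negatives)
  if (length(intersect(positives, negatives)) > 0) {
    stop("positives and negatives overlap", call. = FALSE)
  }
  target <- floor(ratio * length(positives))
  if (length(negatives) < target) {
    stop(sprintf(
      "need %d negatives for ratio %.2f but only %d available",
      target, ratio, length(negatives)
    ), call. = FALSE)
  }
  pos_len <- nchar(positives)
  neg_len <- nchar(negatives)
  lens <- sort(unique(pos_len))
  props <- as.numeric(table(factor(pos_len, levels = lens))) / length(positives)
  quota <- largest_remainder(target * props, target)
  names(quota) <- lens
  avail <- table(factor(neg_len, levels = lens))
  short <- which(quota > as.numeric(avail))
  if (length(short) > 0) {
    stop(sprintf(
      "length stratum %s: quota %d exceeds available negatives (%d)",
      lens[short[1]], quota[short[1]], as.numeric(avail)[short[1]]
    ), call. = FALSE)
  }
  kept <- with_seed(seed, {
    unlist(lapply(seq_along(lens), function(i) {
      pool <- which(neg_len == lens[i])
      pool[sample.int(length(pool), quota[i])]
    }))
  })
  kept_neg <- negatives[sort(kept)]
  structure(
    list(
      positives = positives,
      negatives = kept_neg,
      length_histogram = list(
        positives = table(nchar(positives)),
        negatives = table(nchar(kept_neg))
      ),
      ratio = length(kept_neg) / length(positives)
    ),
    class = "training_dataset"
  )
}

# Largest-remainder apportionment of a real-valued quota vector to integers
# summing to `total`; ties broken by position order.
largest_remainder <- function(x, total) {
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(-(x - base), seq_along(x))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' @export
print.training_dataset <- function(x, ...) {
  cat(sprintf(
    "<training_dataset> %d positives, %d negatives (ratio 1:%.2f)\n",
    length(x$positives), length(x$negatives), x$ratio
  ))
  invisible(x)
}

#' Flatten a training dataset to a data.frame
#'
#' @param dataset a `training_dataset`.
#' @return data.frame with columns `peptide`, `label` (1 = immunogenic),
#'   `length`.
#' @export
dataset_table <- function(dataset) {
  stopifnot(inherits(dataset, "training_dataset"))
  data.frame(
    peptide = c(dataset$positives, dataset$negatives),
    label = rep(c(1L, 0L), c(length(dataset$positives), length(dataset$negatives))),
    length = nchar(c(dataset$positives, dataset$negatives)),
    stringsAsFactors = FALSE
  )
}
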