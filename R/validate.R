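# Shared sequence validation and seeded-RNG helpers.

#' Check peptide sequences against the standard amino-acid alphabet
#'
#' @param peptides character vector of peptide sequences.
#' @param lengths allowed lengths (default 9-11, the class I ligand sizes the
#'   model supports).
#' @return the validated (uppercased) peptides, invisibly usable downstream.
#' @keywords internal
validate_peptides <- function(peptides, lengths = 9:11) {
  if (!is.character(peptides) || length(peptides) == 0) {
    stop("peptides must be a non-empty character vector", call. = FALSE)
  }
  peptides <- toupper(peptides)
  nc <- nchar(peptides)
  bad_len <- which(!(nc %in% lengths))
  if (length(bad_len) > 0) {
    stop(sprintf(
      "peptide '%s' has length %d; allowed lengths: %s",
      peptides[bad_len[1]], nc[bad_len[1]], paste(lengths, collapse = ", ")
    ), call. = FALSE)
  }
  letters_used <- unique(strsplit(paste(peptides, collapse = ""), "")[[1]])
  bad <- setdiff(letters_used, AA_CANONICAL)
  if (length(bad) > 0) {
    stop(sprintf(
      "non-standard residue(s) %s; only the 20 standard amino acids are supported",
      paste(sQuote(bad), collapse = ", ")
    ), call. = FALSE)
  }
  peptides
}

#' Evaluate an expression with a temporary, restored RNG state
#'
#' All stochastic operations in the package route their seed through this
#' helper so they are pure functions of their arguments and never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
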