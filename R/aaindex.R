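# AAindex1 flat-file parsing and the amino-acid property matrix container.

# Residue order used by the AAindex1 "I" block: first value line gives
# A R N D C Q E G H I, second gives L K M F P S T W V Y.
AAINDEX_ORDER <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y"
)

#' Construct an amino-acid property matrix
#'
#' The container behind peptide encoding: one row per standard amino acid
#' (canonical order `ACDEFGHIKLMNPQRSTVWY`), one column per numerical
#' property scale. A completeness mask records which properties have no
#' missing values.
#'
#' @param values numeric 20 x P matrix; rownames must be the 20 standard
#'   one-letter codes (any order; rows are reordered canonically).
#' @param properties character vector of P unique property identifiers
#'   (defaults to `colnames(values)`).
#' @return an object of class `aa_property_matrix` with fields
#'   `amino_acids`, `properties`, `values`, `complete_mask`.
#' @export
#' @examples
#' m <- matrix(rnorm(40), nrow = 20, dimnames = list(
#'   strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], c("p1", "p2")
#' ))
#' pm <- property_matrix(m)
#' pm$complete_mask
property_matrix <- function(values, properties = colnames(values)) {
  if (!is.matrix(values) || nrow(values) != 20) {
    stop("values must be a numeric matrix with exactly 20 rows", call. = FALSE)
  }
  if (is.null(rownames(values)) || !setequal(rownames(values), AA_CANONICAL)) {
    stop("rownames(values) must be the 20 standard one-letter codes", call. = FALSE)
  }
  if (is.null(properties) || anyDuplicated(properties)) {
    stop("property identifiers must be present and unique", call. = FALSE)
  }
  if (length(properties) != ncol(values)) {
    stop("length(properties) must match ncol(values)", call. = FALSE)
  }
  values <- values[AA_CANONICAL, , drop = FALSE]
  colnames(values) <- properties
  structure(
    list(
      amino_acids = AA_CANONICAL,
      properties = properties,
      values = values,
      complete_mask = apply(values, 2, function(x) !anyNA(x))
    ),
    class = "aa_property_matrix"
  )
}

#' @export
print.aa_property_matrix <- function(x, ...) {
  cat(sprintf(
    "<aa_property_matrix> %d properties (%d complete) x 20 amino acids\n",
    length(x$properties), sum(x$complete_mask)
  ))
  invisible(x)
}

#' Parse an AAindex1 flat file into a property matrix
#'
#' Reads the AAindex1 record format: records separated by `//`, each carrying
#' an `H` accession line and an `I` block whose two value lines list the 20
#' per-residue values in the fixed A/R/N/D/C/Q/E/G/H/I then L/K/M/F/P/S/T/W/V/Y
#' order. `NA` entries are allowed and flagged in the completeness mask.
#'
#' @param source path to an AAindex1 file, or a character vector of its lines.
#' @return an [property_matrix()] with one column per record, rows reordered to
#'   the canonical amino-acid order.
#' @export
read_aaindex <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "//")))
  cols <- list()
  for (rec in recs) {
    rec <- rec[rec != "//" & nzchar(trimws(rec))]
    if (length(rec) == 0) next
    h <- grep("^H ", rec, value = TRUE)
    if (length(h) != 1) {
      stop(sprintf(
        "malformed AAindex record (no unique H line) starting at '%s'",
        substr(rec[1], 1, 40)
      ), call. = FALSE)
    }
    acc <- trimws(sub("^H ", "", h))
    i_at <- grep("^I ", rec)
    if (length(i_at) != 1 || i_at + 2 > length(rec)) {
      stop(sprintf("malformed AAindex record '%s': missing I block", acc),
        call. = FALSE
      )
    }
    vals <- unlist(strsplit(trimws(rec[c(i_at + 1, i_at + 2)]), "[[:space:]]+"))
    if (length(vals) != 20) {
      stop(sprintf(
        "malformed AAindex record '%s': %d values in I block, expected 20",
        acc, length(vals)
      ), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(ifelse(vals == "NA", NA, vals)))
    if (any(is.na(v) & vals != "NA")) {
      stop(sprintf("malformed AAindex record '%s': non-numeric value", acc),
        call. = FALSE
      )
    }
    names(v) <- AAINDEX_ORDER
    cols[[acc]] <- v[AA_CANONICAL]
  }
  if (length(cols) == 0) stop("no AAindex records found", call. = FALSE)
  property_matrix(do.call(cbind, cols), properties = names(cols))
}

#' Drop properties with missing values
#'
#' @param pm an [property_matrix()].
#' @return the property matrix restricted to complete columns.
#' @export
filter_complete <- function(pm) {
  stopifnot(inherits(pm, "aa_property_matrix"))
  keep <- pm$complete_mask
  if (!any(keep)) stop("no complete properties remain", call. = FALSE)
  property_matrix(pm$values[, keep, drop = FALSE], pm$properties[keep])
}
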