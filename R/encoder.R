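# Per-residue physicochemical embedding and the ordered peptide feature vector.
#
# The 20 amino acids are the observations and the complete AAindex property
# scales the variables. Properties are z-scaled (population variance, n = 20)
# and reduced by PCA; each amino acid's coordinates on the first 10 components
# form its embedding. A 9-11-mer is encoded as 11 positional slots of 10
# components each (N-terminally anchored, trailing slots zero for shorter
# peptides) plus 8 global descriptors: 118 ordered features.

N_SLOTS <- 11L
FEATURE_DIM <- 118L

#' Feature names of the 118-dimensional peptide encoding
#'
#' @param n_components number of principal components per positional slot.
#' @return character vector: 11 x 10 positional labels then 8 descriptor names.
#' @export
feature_slot_labels <- function(n_components = 10L) {
  c(
    as.vector(vapply(
      seq_len(N_SLOTS),
      function(p) paste0("pos", p, "_pc", seq_len(n_components)),
      character(n_components)
    )),
    GLOBAL_DESCRIPTOR_NAMES
  )
}

#' Fit the per-residue embedding from an amino-acid property matrix
#'
#' Filters incomplete properties, z-scales each retained property across the
#' 20 amino acids using the population variance (divide by 20), and extracts
#' principal components by SVD. Components are ordered by decreasing explained
#' variance and signed so that each loading vector's largest-magnitude element
#' is positive, making the embedding reproducible across linear-algebra
#' backends.
#'
#' @param props an [property_matrix()].
#' @param n_components number of components to retain (default 10).
#' @return an object of class `residue_encoder` with fields `means`, `sds`,
#'   `loadings` (P' x k), `embedding` (20 x k), `variance_explained`,
#'   `properties`.
#' @export
fit_residue_encoder <- function(props, n_components = 10L) {
  stopifnot(inherits(props, "aa_property_matrix"))
  props <- filter_complete(props)
  x <- props$values
  if (ncol(x) < n_components) {
    stop(sprintf(
      "only %d complete properties; need at least n_components = %d",
      ncol(x), n_components
    ), call. = FALSE)
  }
  mu <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, mu)^2)) # population sd, n = 20
  if (any(sds == 0)) {
    stop(sprintf(
      "property '%s' is constant across amino acids; z-scaling undefined",
      props$properties[which(sds == 0)[1]]
    ), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, mu), 2, sds, "/")
  dec <- svd(z)
  # sign convention: largest-magnitude loading element positive
  flip <- vapply(seq_len(ncol(dec$v)), function(j) {
    v <- dec$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  v <- sweep(dec$v, 2, flip, "*")[, seq_len(n_components), drop = FALSE]
  ve <- dec$d^2 / sum(dec$d^2)
  emb <- z %*% v
  dimnames(emb) <- list(AA_CANONICAL, paste0("pc", seq_len(n_components)))
  dimnames(v) <- list(props$properties, colnames(emb))
  structure(
    list(
      means = stats::setNames(mu, props$properties),
      sds = stats::setNames(sds, props$properties),
      loadings = v,
      embedding = emb,
      variance_explained = ve[seq_len(n_components)],
      properties = props$properties
    ),
    class = "residue_encoder"
  )
}

#' @export
print.residue_encoder <- function(x, ...) {
  cat(sprintf(
    "<residue_encoder> %d properties -> %d components (cumulative variance %.3f)\n",
    length(x$properties), ncol(x$embedding), sum(x$variance_explained)
  ))
  invisible(x)
}

#' Encode peptides as ordered 118-dimensional feature vectors
#'
#' Residues 1..L fill positional slots 1..L in sequence order with their
#' 10-component embeddings; for 9- and 10-mers the trailing slots are exactly
#' zero. The 8 global descriptors are appended.
#'
#' @param peptides character vector of 9-11-mer sequences.
#' @param encoder a fitted [fit_residue_encoder()] object.
#' @return a numeric matrix (length(peptides) x 118) with named columns and
#'   the peptides as rownames.
#' @export
encode_peptides <- function(peptides, encoder) {
  stopifnot(inherits(encoder, "residue_encoder"))
  peptides <- validate_peptides(peptides)
  k <- ncol(encoder$embedding)
  out <- matrix(0, nrow = length(peptides), ncol = N_SLOTS * k + 8L,
    dimnames = list(peptides, feature_slot_labels(k))
  )
  for (i in seq_along(peptides)) {
    r <- strsplit(peptides[i], "")[[1]]
    pos <- t(encoder$embedding[r, , drop = FALSE]) # k x L, column-major = slot order
    out[i, seq_len(length(r) * k)] <- as.vector(pos)
    out[i, N_SLOTS * k + seq_len(8L)] <- global_descriptors(peptides[i])
  }
  out
}

#' @rdname encode_peptides
#' @param peptide a single peptide sequence.
#' @return `encode_peptide()` returns a single named numeric vector of
#'   length 118.
#' @export
encode_peptide <- function(peptide, encoder) {
  encode_peptides(peptide, encoder)[1, ]
}

#' Serialize a residue encoder to JSON
#'
#' Round-trip lossless: numbers are written at full precision.
#'
#' @param encoder a `residue_encoder`.
#' @param path output file path.
#' @export
write_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "residue_encoder"))
  payload <- list(
    properties = encoder$properties,
    means = unname(encoder$means),
    sds = unname(encoder$sds),
    loadings = encoder$loadings,
    embedding = encoder$embedding,
    variance_explained = encoder$variance_explained
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_encoder
#' @return `read_encoder()` returns the restored `residue_encoder`.
#' @export
read_encoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- as.matrix(p$loadings)
  embedding <- as.matrix(p$embedding)
  k <- ncol(embedding)
  dimnames(loadings) <- list(p$properties, paste0("pc", seq_len(k)))
  dimnames(embedding) <- list(AA_CANONICAL, paste0("pc", seq_len(k)))
  structure(
    list(
      means = stats::setNames(p$means, p$properties),
      sds = stats::setNames(p$sds, p$properties),
      loadings = loadings,
      embedding = embedding,
      variance_explained = p$variance_explained,
      properties = p$properties
    ),
    class = "residue_encoder"
  )
}
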