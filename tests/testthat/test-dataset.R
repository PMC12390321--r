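# Non-self filtering against the proteome and class-ratio subsampling.

fixture_proteome <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")

test_that("exact substrings have mismatch 0 and near-misses count substitutions", {
  expect_equal(min_mismatch_to_proteome("MKTAYIAKQ", fixture_proteome), 0L)
  expect_equal(min_mismatch_to_proteome("MKTAYIAKR", fixture_proteome), 1L)
  expect_equal(
    min_mismatch_to_proteome("WWWWWWWWW", fixture_proteome),
    naive_min_mismatch("WWWWWWWWW", fixture_proteome)
  )
  expect_error(min_mismatch_to_proteome("MKTAYIAKQ", character(0)), "empty proteome")
})

test_that("mismatch search equals the exhaustive window-scan oracle", {
  prot <- make_proteome(seed = 21, total_length = 5000)$proteins
  queries <- c(
    random_peptides(15, 9, seed = 31),
    random_peptides(10, 10, seed = 32),
    random_peptides(10, 11, seed = 33),
    # near-copies of proteome windows, to exercise small distances
    vapply(1:10, function(i) {
      w <- substring(prot[1], i * 37, i * 37 + 8)
      substr(w, 3, 3) <- if (substr(w, 3, 3) == "A") "C" else "A"
      w
    }, character(1))
  )
  got <- min_mismatch_batch(queries, prot)
  want <- vapply(queries, naive_min_mismatch, integer(1) + 0, proteome = prot)
  expect_equal(got, unname(as.integer(want)))
})

test_that("positive set drops self peptides and duplicates, keeps input order", {
  records <- data.frame(
    peptide = c(
      "MKTAYIAKQ", # self: exact substring
      "MKTAYIAKR", # valid (1 mismatch)
      "MKTAYIAKR", # duplicate
      "WWWWWWWWW", "HHHHHHHHH", "DDDDDDDDD"
    ),
    assay_class = "tcell_positive"
  )
  pos <- build_positive_set(records, fixture_proteome)
  expect_equal(pos, c("MKTAYIAKR", "WWWWWWWWW", "HHHHHHHHH", "DDDDDDDDD"))
})

test_that("negative set keeps 1-3 mismatches, excluding positives", {
  base <- "MKTAYIAKQ" # distance 0 window
  mut <- function(p, at) {
    for (i in at) substr(p, i, i) <- if (substr(p, i, i) == "W") "H" else "W"
    p
  }
  cand <- c(
    base, # 0 -> excluded
    mut(base, 1), # 1 -> kept
    mut(base, 2), # 1 -> kept, but listed in positives below
    mut(base, c(1, 2)), # 2 -> kept
    mut(base, c(1, 2, 3)), # 3 -> kept
    mut(base, c(1, 2, 3, 4)), # 4 -> excluded
    "MKTAYIAKQ", # duplicate of self
    mut(base, 9) # 1 -> kept
  )
  dist <- vapply(cand, naive_min_mismatch, numeric(1), proteome = fixture_proteome)
  expect_equal(unname(dist), c(0, 1, 1, 2, 3, 4, 0, 1))
  records <- data.frame(peptide = cand, assay_class = "presented_only")
  neg <- build_negative_set(records, fixture_proteome, positives = mut(base, 2))
  expect_equal(neg, c(mut(base, 1), mut(base, c(1, 2)), mut(base, c(1, 2, 3)), mut(base, 9)))
  expect_length(neg, 4)
})

test_that("assembly is idempotent on its own output", {
  records <- data.frame(
    peptide = c("MKTAYIAKR", "WWWWWWWWW", "HHHHHHHHH"),
    assay_class = "tcell_positive"
  )
  pos <- build_positive_set(records, fixture_proteome)
  again <- build_positive_set(
    data.frame(peptide = pos, assay_class = "tcell_positive"),
    fixture_proteome
  )
  expect_identical(again, pos)
})

test_that("subsampling retains floor(ratio * positives) negatives", {
  pos <- random_peptides(2, 9, seed = 41)
  neg <- random_peptides(40, 9, seed = 42)
  neg <- setdiff(neg, pos)
  ds <- subsample_to_ratio(pos, neg, ratio = 3.5, seed = 1)
  expect_length(ds$negatives, 7)
})

test_that("length strata follow largest-remainder apportionment", {
  pos <- c(random_peptides(6, 9, seed = 51), random_peptides(4, 10, seed = 52))
  neg <- c(random_peptides(30, 9, seed = 53), random_peptides(30, 10, seed = 54))
  ds <- subsample_to_ratio(pos, neg, ratio = 2, seed = 9)
  expect_length(ds$negatives, 20)
  expect_equal(as.vector(table(nchar(ds$negatives))[c("9", "10")]), c(12L, 8L))
})

test_that("subsampled length proportions track the positive distribution", {
  spec <- fixture_spec(seed = 77, n_positive = 200, n_negative = 1200)
  d <- make_labeled_peptides(spec)
  pos <- unique(d$peptide[d$label == 1])
  neg <- setdiff(unique(d$peptide[d$label == 0]), pos)
  ds <- subsample_to_ratio(pos, neg, ratio = 3.5, seed = 5)
  p_prop <- prop.table(table(factor(nchar(ds$positives), levels = 9:11)))
  n_prop <- prop.table(table(factor(nchar(ds$negatives), levels = 9:11)))
  expect_true(all(abs(p_prop - n_prop) < 1 / length(ds$negatives) + 1e-9))
  expect_length(intersect(ds$positives, ds$negatives), 0)
})

test_that("subsampling is reproducible and errors name an infeasible stratum", {
  pos <- random_peptides(4, 9, seed = 61)
  neg <- setdiff(random_peptides(60, 9, seed = 62), pos)
  a <- subsample_to_ratio(pos, neg, ratio = 3.5, seed = 2)
  b <- subsample_to_ratio(pos, neg, ratio = 3.5, seed = 2)
  expect_identical(a$negatives, b$negatives)
  neg10 <- random_peptides(50, 10, seed = 63)
  expect_error(
    subsample_to_ratio(pos, neg10, ratio = 3.5, seed = 2),
    "stratum 9"
  )
})

test_that("FASTA proteomes round-trip through the package reader", {
  gen <- make_proteome(seed = 8, total_length = 2000, planted_peptides = "MKTAYIAKQ")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(gen$fasta, path, sep = "")
  prot <- read_proteome_fasta(path)
  expect_identical(unname(prot), unname(gen$proteins))
  expect_identical(names(prot), names(gen$proteins))
})
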