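# Mutation-covering peptide enumeration, the max-mean biomarker, median-split
# survival stratification, and the paired vaccine hit-rate test.

test_that("an interior substitution with full flanks yields 30 covering peptides", {
  window <- paste(rep("A", 10), collapse = "")
  window <- paste0(window, "W", paste(rep("C", 10), collapse = "")) # mutation at 11
  peps <- enumerate_covering_peptides(window, 11)
  expect_length(peps, 30) # 9 + 10 + 11 windows containing the site
  expect_true(all(grepl("W", peps)))
  expect_true(all(nchar(peps) %in% 9:11))
})

test_that("a mutation at the protein start yields one window per length", {
  window <- paste0("W", paste(rep("A", 15), collapse = ""))
  peps <- enumerate_covering_peptides(window, 1)
  expect_length(peps, 3)
  expect_equal(substr(peps, 1, 1), rep("W", 3))
})

test_that("multi-residue spans match brute-force window enumeration", {
  set.seed(44)
  window <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40, replace = TRUE),
    collapse = ""
  )
  span <- c(18, 20)
  got <- sort(enumerate_covering_peptides(window, span[1], span[2]))
  want <- unique(unlist(lapply(9:11, function(L) {
    starts <- seq_len(nchar(window) - L + 1)
    w <- substring(window, starts, starts + L - 1)
    w[starts <= span[2] & starts + L - 1 >= span[1]]
  })))
  expect_equal(got, sort(want))
})

test_that("short windows warn and return nothing", {
  expect_warning(out <- enumerate_covering_peptides("AAAWAAA", 4), "shorter than 9")
  expect_length(out, 0)
})

test_that("max-mean is the maximum per-mutation mean score", {
  flank <- paste(rep("A", 12), collapse = "")
  muts <- data.frame(
    patient_id = "PT1",
    mutation_id = c("m1", "m2"),
    mutant_protein_window = c(
      paste0(flank, "W", flank),
      paste0(flank, "Y", flank)
    ),
    span_start = 13, span_end = 13
  )
  # stub scorer keyed on the mutated residue
  scorer <- function(peps) ifelse(grepl("W", peps), 0.3, 0.5)
  mm <- tumor_maxmean(muts, scorer)
  expect_equal(as.numeric(mm), 0.5)
  expect_equal(unname(attr(mm, "per_mutation")), c(0.3, 0.5))
  # a single mutation scoring {0.2, 0.4} on average -> 0.3
  scorer2 <- local({
    i <- 0
    function(peps) rep_len(c(0.2, 0.4), length(peps))
  })
  mm2 <- tumor_maxmean(muts[1, ], scorer2)
  expect_equal(as.numeric(mm2), 0.3)
  # adding a mutation never decreases the biomarker
  expect_gte(as.numeric(tumor_maxmean(muts, scorer)), as.numeric(tumor_maxmean(muts[1, ], scorer)))
  # invariant to mutation order
  expect_equal(as.numeric(tumor_maxmean(muts[2:1, ], scorer)), 0.5)
})

test_that("cohort max-mean uses a real trained scorer end to end", {
  enc <- test_encoder()
  spec <- fixture_spec(seed = 105, n_positive = 80, n_negative = 180)
  d <- make_labeled_peptides(spec)
  m <- train_forest(encode_peptides(d$peptide, enc), d$label,
    forest_config(n_trees = 100, seed = 5))
  flank <- paste(rep("G", 11), collapse = "")
  muts <- data.frame(
    patient_id = rep(c("PT1", "PT2"), each = 1),
    mutation_id = c("m1", "m2"),
    mutant_protein_window = paste0(flank, c("L", "D"), flank),
    span_start = 12, span_end = 12
  )
  out <- cohort_maxmean(muts, forest_scorer(m, enc))
  expect_equal(out$patient_id, c("PT1", "PT2"))
  expect_true(all(out$maxmean_score >= 0 & out$maxmean_score <= 1))
})

test_that("median split sends ties low and partitions the records", {
  rec <- data.frame(patient_id = 1:10, score = 1:10)
  sp <- median_split(rec, "score")
  expect_equal(sp$low$score, 1:5)
  expect_equal(sp$high$score, 6:10)
  # odd n with distinct values: median element lands low
  rec7 <- data.frame(score = 1:7)
  sp7 <- median_split(rec7, "score")
  expect_equal(nrow(sp7$low), 4)
  expect_equal(nrow(sp7$high), 3)
  # ties at the median all land low
  rec_t <- data.frame(score = c(1, 2, 2, 2, 3))
  sp_t <- median_split(rec_t, "score")
  expect_equal(nrow(sp_t$low), 4)
  expect_equal(nrow(sp_t$high), 1)
  expect_error(median_split(data.frame(score = rep(2, 5)), "score"), "identical")
})

test_that("logrank matches the hand-worked event-time table", {
  time <- c(5, 10, 15, 5, 12, 20)
  event <- c(1, 0, 1, 1, 1, 0)
  group <- rep(c("A", "B"), each = 3)
  lr <- km_logrank(time, event, group)
  # hand tables: t=5 (d=2, N=6), t=12 (d=1, N=3), t=15 (d=1, N=2)
  # O_A = 2, E_A = 1 + 1/3 + 1/2 = 11/6, V = 0.4 + 2/9 + 1/4
  expect_equal(unname(lr$observed), c(2, 2))
  expect_equal(unname(lr$expected), c(11 / 6, 13 / 6), tolerance = 1e-12)
  expect_equal(lr$chisq, (2 - 11 / 6)^2 / (0.4 + 2 / 9 + 0.25), tolerance = 1e-12)
  expect_equal(lr$p, stats::pchisq(lr$chisq, 1, lower.tail = FALSE))
  # relabeling invariance
  lr_swapped <- km_logrank(time, event, rev(group))
  expect_equal(lr_swapped$chisq, lr$chisq)
})

test_that("identical groups give a null logrank and KM starts at 1, nonincreasing", {
  time <- rep(c(3, 6, 9, 12), 2)
  event <- rep(c(1, 0, 1, 1), 2)
  group <- rep(c("A", "B"), each = 4)
  lr <- km_logrank(time, event, group)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  s <- summary(lr$fit)$surv
  expect_true(all(s <= 1 + 1e-12))
  expect_true(all(diff(summary(lr$fit, times = c(0, 3, 9, 12))$surv[1:4]) <= 1e-12))
})

test_that("logrank degenerate inputs are rejected", {
  expect_error(km_logrank(c(1, 2), c(0, 0), c("A", "B")), "no observed events")
  expect_error(km_logrank(1:3, c(1, 1, 1), c("A", "A", "A")), "two non-empty groups")
})

test_that("paired z on hit-rate differences matches hand arithmetic", {
  # five patients, differences 0.2, 0.1, 0.3, 0.0, 0.4 (model - original)
  orig <- c(0.2, 0.3, 0.1, 0.5, 0.2)
  modl <- orig + c(0.2, 0.1, 0.3, 0.0, 0.4)
  designs <- do.call(rbind, lapply(1:5, function(i) {
    rbind(
      data.frame(
        patient_id = paste0("PT", i), method = "original",
        responded = rep(c(1, 0), c(round(orig[i] * 10), 10 - round(orig[i] * 10)))
      ),
      data.frame(
        patient_id = paste0("PT", i), method = "model",
        responded = rep(c(1, 0), c(round(modl[i] * 10), 10 - round(modl[i] * 10)))
      )
    )
  }))
  res <- hitrate_paired_z(designs)
  expect_equal(unname(res$differences[paste0("PT", 1:5)]),
    c(0.2, 0.1, 0.3, 0.0, 0.4),
    tolerance = 1e-12
  )
  # mean 0.2, sample sd 0.158114: z = 0.2 / (0.158114 / sqrt(5))
  expect_equal(res$z, 0.2 / (sqrt(0.025) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$z, 2.8284, tolerance = 1e-4)
  expect_equal(res$p, 2 * pnorm(-res$z))
})

test_that("paired z contracts: identical designs, degenerate sd, patient mismatch", {
  d <- data.frame(
    patient_id = rep(c("PT1", "PT2"), each = 4),
    method = rep(c("original", "model"), 4),
    responded = rep(c(1, 1, 0, 0), 2)
  )
  res <- hitrate_paired_z(d)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  d_const <- data.frame(
    patient_id = rep(c("PT1", "PT2"), each = 2),
    method = rep(c("original", "model"), 2),
    responded = c(0, 1, 0, 1)
  )
  expect_error(hitrate_paired_z(d_const), "degenerate")
  d_mis <- d[d$patient_id == "PT1" | d$method == "original", ]
  expect_error(hitrate_paired_z(d_mis), "patient sets differ")
})
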