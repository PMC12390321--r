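# Clinical downstream analyses: the tumor max-mean immunogenicity biomarker,
# median-split survival stratification with Kaplan-Meier curves and logrank
# testing, and paired comparison of vaccine-design hit rates.

#' Enumerate all 9-11-mers covering a mutated span
#'
#' Every window of length 9, 10, and 11 inside the mutant protein window that
#' contains at least one altered residue; unique, ordered by length then start.
#' A single interior substitution with full flanks yields 9 + 10 + 11 = 30
#' peptides.
#'
#' @param window mutant protein sequence containing the altered residue(s),
#'   ideally with >= 10 flanking residues on each side.
#' @param span_start,span_end 1-based inclusive positions of the altered
#'   residues within `window`.
#' @return character vector of peptides (empty, with a warning, if the window
#'   is shorter than 9 residues).
#' @export
enumerate_covering_peptides <- function(window, span_start, span_end = span_start) {
  window <- toupper(window)
  n <- nchar(window)
  stopifnot(span_start >= 1, span_end >= span_start, span_end <= n)
  bad <- setdiff(unique(strsplit(window, "")[[1]]), AA_CANONICAL)
  if (length(bad) > 0) {
    stop(sprintf("non-standard residue(s) %s in window", paste(sQuote(bad), collapse = ", ")),
      call. = FALSE
    )
  }
  if (n < 9) {
    warning("protein window shorter than 9 residues; no peptides enumerated")
    return(character(0))
  }
  out <- character(0)
  for (L in 9:11) {
    if (n < L) next
    starts <- max(1L, span_start - L + 1L):min(span_end, n - L + 1L)
    starts <- starts[starts + L - 1L >= span_start] # must still cover the span
    out <- c(out, substring(window, starts, starts + L - 1L))
  }
  unique(out)
}

#' Tumor max-mean immunogenicity biomarker
#'
#' For each mutation, the mean immunogenicity score over all 9-11-mers covering
#' the altered span; the biomarker is the maximum of these per-mutation means
#' across the tumor - the immunogenicity of its most immunogenic region.
#'
#' @param mutations data.frame with columns `mutation_id`,
#'   `mutant_protein_window`, `span_start`, `span_end` (and optionally
#'   `patient_id`; see [cohort_maxmean()]).
#' @param scorer function mapping a character vector of peptides to scores in
#'   \[0, 1\], e.g. from [forest_scorer()].
#' @return the max-mean value (numeric scalar in \[0, 1\]) with the
#'   per-mutation means attached as attribute `per_mutation`.
#' @export
tumor_maxmean <- function(mutations, scorer) {
  req <- c("mutation_id", "mutant_protein_window", "span_start", "span_end")
  stopifnot(all(req %in% names(mutations)))
  means <- vapply(seq_len(nrow(mutations)), function(i) {
    peps <- enumerate_covering_peptides(
      mutations$mutant_protein_window[i],
      mutations$span_start[i], mutations$span_end[i]
    )
    if (length(peps) == 0) return(NA_real_)
    mean(scorer(peps))
  }, numeric(1))
  names(means) <- mutations$mutation_id
  if (all(is.na(means))) stop("no scorable peptides in any mutation", call. = FALSE)
  structure(max(means, na.rm = TRUE), per_mutation = means)
}

#' Per-patient max-mean biomarker over a mutation table
#'
#' @inheritParams tumor_maxmean
#' @return data.frame with columns `patient_id`, `maxmean_score`.
#' @export
cohort_maxmean <- function(mutations, scorer) {
  stopifnot("patient_id" %in% names(mutations))
  ids <- unique(mutations$patient_id)
  data.frame(
    patient_id = ids,
    maxmean_score = vapply(ids, function(p) {
      as.numeric(tumor_maxmean(mutations[mutations$patient_id == p, , drop = FALSE], scorer))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Median split of a biomarker
#'
#' Values at or below the median go to the low group, values above it to the
#' high group (ties at the median land low, a documented deterministic rule).
#'
#' @param records data.frame of patient records.
#' @param biomarker_field name of the numeric column to split on.
#' @return list with `low` and `high` data.frames and the `median` used.
#' @export
median_split <- function(records, biomarker_field) {
  stopifnot(biomarker_field %in% names(records), nrow(records) >= 2)
  v <- records[[biomarker_field]]
  if (length(unique(v)) < 2) {
    stop("all biomarker values identical; median split undefined", call. = FALSE)
  }
  m <- stats::median(v)
  list(
    low = records[v <= m, , drop = FALSE],
    high = records[v > m, , drop = FALSE],
    median = m
  )
}

#' Kaplan-Meier curves and two-sample logrank test
#'
#' Product-limit survival estimates per group and the logrank chi-square from
#' observed-minus-expected events at each distinct event time (1 df).
#'
#' @param time follow-up times (e.g. days of overall survival).
#' @param event 1 = death observed, 0 = censored.
#' @param group two-level grouping vector (e.g. biomarker high/low).
#' @return list with `fit` (a [survival::survfit] object for plotting),
#'   `chisq`, `p`, and the per-group observed/expected event counts.
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2) stop("need exactly two non-empty groups", call. = FALSE)
  if (sum(event) == 0) stop("no observed events; logrank undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(
    fit = survival::survfit(survival::Surv(time, event) ~ group),
    chisq = unname(sd$chisq),
    p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    observed = sd$obs,
    expected = sd$exp
  )
}

#' Paired z-test of vaccine hit rates
#'
#' Each patient contributes a hit-rate pair: the fraction of immunoreactive
#' epitopes in the original design and in the model-prioritized design of the
#' same size. The test is a one-sample z on the per-patient differences,
#' `z = mean(d) / (sd(d) / sqrt(n))` with the sample standard deviation and a
#' two-sided normal p-value.
#'
#' @param designs data.frame with columns `patient_id`, `responded` (0/1 per
#'   epitope), `method` (`original` or `model`).
#' @return list with `hit_rate_original`, `hit_rate_model`, per-patient
#'   `differences` (model - original), `z`, `p`.
#' @export
hitrate_paired_z <- function(designs) {
  stopifnot(all(c("patient_id", "responded", "method") %in% names(designs)))
  stopifnot(all(designs$method %in% c("original", "model")))
  rate <- function(m) {
    d <- designs[designs$method == m, , drop = FALSE]
    tapply(d$responded, d$patient_id, mean)
  }
  orig <- rate("original")
  alt <- rate("model")
  if (!setequal(names(orig), names(alt))) {
    stop("patient sets differ between the two arms", call. = FALSE)
  }
  alt <- alt[names(orig)]
  d <- stats::setNames(as.numeric(alt - orig), names(orig))
  n <- length(d)
  if (n < 2) stop("need at least 2 patients", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0 && mean(d) != 0) {
    stop("all per-patient differences identical and nonzero; z undefined (degenerate)",
      call. = FALSE
    )
  }
  z <- if (s == 0) 0 else mean(d) / (s / sqrt(n))
  list(
    hit_rate_original = mean(orig),
    hit_rate_model = mean(alt),
    differences = d,
    z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
}
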