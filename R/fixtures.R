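# Seeded generators for every input the package consumes: AAindex1-format
# property tables, labeled peptide sets with a planted class signal, random
# proteomes with planted peptides and mismatch variants, and survival cohorts.
# All generators are pure functions of their seed and spec, and their outputs
# round-trip through the package's own readers.

# Residues with positive Kyte-Doolittle hydropathy; the planted class signal
# shifts usage toward this set because hydrophobicity at and around anchor
# positions is the dominant compositional difference between immunogenic and
# non-immunogenic presented peptides.
HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V")

#' Specification of the synthetic study conditions
#'
#' Defaults describe the emulated training conditions: 2000 peptides at the
#' 1:3.5 positive-to-negative class ratio, a 70/20/10 length mix over
#' 9/10/11-mers, hydrophobic enrichment (effect_size 0.9) planted at positions
#' 1, 5 and 7, a 5 kaa proteome, and an exponential survival cohort.
#'
#' @param seed master seed.
#' @param n_positive,n_negative class sizes.
#' @param length_mix named proportions over lengths 9/10/11 (must sum to 1).
#' @param signal_positions peptide positions carrying the class signal.
#' @param effect_size shift of hydrophobic-residue usage probability in
#'   positives at signal positions, in \[0, 1\]: 0 = no signal, 1 = fully
#'   hydrophobic.
#' @param proteome_length total residues of the synthetic proteome.
#' @param baseline_hazard,hazard_ratio,censoring_rate survival-cohort
#'   parameters: daily event hazard of the reference (high-biomarker) arm,
#'   hazard multiplier of the low-biomarker arm, and expected fraction
#'   censored.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_positive = 444L, n_negative = 1556L,
                         length_mix = c(`9` = 0.7, `10` = 0.2, `11` = 0.1),
                         signal_positions = c(1L, 5L, 7L),
                         effect_size = 0.9,
                         proteome_length = 5000L,
                         baseline_hazard = 1 / 400,
                         hazard_ratio = 2,
                         censoring_rate = 0.2) {
  stopifnot(abs(sum(length_mix) - 1) < 1e-9, effect_size >= 0, effect_size <= 1)
  structure(
    list(
      seed = as.integer(seed), n_positive = as.integer(n_positive),
      n_negative = as.integer(n_negative), length_mix = length_mix,
      signal_positions = as.integer(signal_positions),
      effect_size = effect_size, proteome_length = as.integer(proteome_length),
      baseline_hazard = baseline_hazard, hazard_ratio = hazard_ratio,
      censoring_rate = censoring_rate
    ),
    class = "fixture_spec"
  )
}

#' Generate an AAindex1-format property table
#'
#' Random standard-normal property values written in the AAindex1 flat-file
#' record format (`H`/`D` lines, two `I`-block value lines, `//` separators);
#' `n_missing` records carry an `NA` entry.
#'
#' @param seed integer seed.
#' @param n_props number of property records (>= 10).
#' @param n_missing number of records given one missing value.
#' @return a single string of AAindex1 text.
#' @export
make_property_table <- function(seed = 1L, n_props = 30L, n_missing = 3L) {
  stopifnot(n_props >= 10, n_missing >= 0, n_missing <= n_props)
  with_seed(seed, {
    miss <- sample.int(n_props, n_missing)
    recs <- vapply(seq_len(n_props), function(i) {
      v <- sprintf("%8.3f", stats::rnorm(20))
      if (i %in% miss) v[sample.int(20, 1)] <- sprintf("%8s", "NA")
      paste(
        sprintf("H SYNT%06d", i),
        sprintf("D synthetic property scale %d", i),
        "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
        paste0("  ", paste(v[1:10], collapse = "")),
        paste0("  ", paste(v[11:20], collapse = "")),
        "//",
        sep = "\n"
      )
    }, character(1))
    paste0(paste(recs, collapse = "\n"), "\n")
  })
}

sample_residues <- function(n, p_hydro) {
  other <- setdiff(AA_CANONICAL, HYDROPHOBIC_SET)
  hydro <- stats::runif(n) < p_hydro
  out <- character(n)
  out[hydro] <- sample(HYDROPHOBIC_SET, sum(hydro), replace = TRUE)
  out[!hydro] <- sample(other, sum(!hydro), replace = TRUE)
  out
}

#' Generate labeled peptides with a planted hydrophobicity signal
#'
#' Positives draw residues at `signal_positions` from a hydrophobic-enriched
#' distribution (`P(hydrophobic) = 7/20 + effect_size * 13/20`, uniform within
#' the hydrophobic and non-hydrophobic sets); all other positions, and all
#' positions of negatives, are uniform over the 20 residues. Lengths follow
#' `length_mix` deterministically (largest-remainder counts per class).
#'
#' @param spec a [fixture_spec()].
#' @return data.frame with columns `peptide`, `label` (1 = positive).
#' @export
make_labeled_peptides <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  base_h <- length(HYDROPHOBIC_SET) / 20
  p_sig <- base_h + spec$effect_size * (1 - base_h)
  lens <- as.integer(names(spec$length_mix))
  gen_class <- function(n, positive) {
    counts <- largest_remainder(n * spec$length_mix, n)
    unlist(lapply(seq_along(lens), function(li) {
      L <- lens[li]
      m <- counts[li]
      if (m == 0) return(character(0))
      vapply(seq_len(m), function(i) {
        r <- sample_residues(L, base_h)
        if (positive) {
          sig <- spec$signal_positions[spec$signal_positions <= L]
          r[sig] <- sample_residues(length(sig), p_sig)
        }
        paste(r, collapse = "")
      }, character(1))
    }))
  }
  with_seed(spec$seed, {
    data.frame(
      peptide = c(gen_class(spec$n_positive, TRUE), gen_class(spec$n_negative, FALSE)),
      label = rep(c(1L, 0L), c(spec$n_positive, spec$n_negative)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a random proteome with planted peptides and mismatch variants
#'
#' Random proteins totaling about `total_length` residues; each planted
#' peptide is written into a protein as an exact substring (mismatch 0).
#' For every planted peptide, variants mutated at k = 1, 2, 3 positions are
#' emitted with their nominal distance (their true minimum distance is <= k,
#' and equals k with high probability on random backgrounds).
#'
#' @param seed integer seed.
#' @param total_length total proteome size in residues.
#' @param planted_peptides 9-11-mers to embed as exact substrings.
#' @return list with `proteins` (named character), `fasta` (text), `planted`,
#'   and `variants` (data.frame `peptide`, `k`, `origin`).
#' @export
make_proteome <- function(seed = 1L, total_length = 5000L,
                          planted_peptides = character()) {
  if (length(planted_peptides) > 0) {
    planted_peptides <- validate_peptides(planted_peptides)
  }
  with_seed(seed, {
    n_prot <- max(1L, round(total_length / 500))
    sizes <- largest_remainder(rep(total_length / n_prot, n_prot), total_length)
    proteins <- vapply(sizes, function(L) {
      paste(sample(AA_CANONICAL, L, replace = TRUE), collapse = "")
    }, character(1))
    names(proteins) <- sprintf("SYNPROT%03d", seq_along(proteins))
    for (i in seq_along(planted_peptides)) {
      host <- (i - 1L) %% n_prot + 1L
      pep <- planted_peptides[i]
      if (nchar(proteins[host]) < nchar(pep)) {
        stop("planted peptide longer than a protein", call. = FALSE)
      }
      at <- sample.int(nchar(proteins[host]) - nchar(pep) + 1L, 1)
      substr(proteins[host], at, at + nchar(pep) - 1L) <- pep
    }
    variants <- NULL
    if (length(planted_peptides) > 0) {
      variants <- do.call(rbind, lapply(planted_peptides, function(pep) {
        do.call(rbind, lapply(1:3, function(k) {
          r <- strsplit(pep, "")[[1]]
          at <- sample.int(length(r), k)
          r[at] <- vapply(r[at], function(a) sample(setdiff(AA_CANONICAL, a), 1), character(1))
          data.frame(
            peptide = paste(r, collapse = ""), k = k, origin = pep,
            stringsAsFactors = FALSE
          )
        }))
      }))
    }
    list(
      proteins = proteins,
      fasta = paste0(paste(sprintf(">%s\n%s", names(proteins), proteins), collapse = "\n"), "\n"),
      planted = planted_peptides,
      variants = variants
    )
  })
}

#' Generate a synthetic survival cohort
#'
#' Exponential event times whose hazard is multiplied by `hazard_ratio` in the
#' low-biomarker arm, with independent exponential censoring tuned so the
#' expected censored fraction equals `censoring_rate`.
#'
#' @param spec a [fixture_spec()] (uses the survival parameters and seed).
#' @param n_per_arm patients per biomarker arm.
#' @return data.frame with `patient_id`, `os_days`, `event` (1 = death),
#'   `group` (`high`/`low` biomarker), `maxmean_score`, `n_mutations`.
#' @export
make_survival_cohort <- function(spec = fixture_spec(), n_per_arm = 50L) {
  stopifnot(inherits(spec, "fixture_spec"), spec$hazard_ratio > 0)
  with_seed(spec$seed, {
    n <- 2L * n_per_arm
    group <- rep(c("high", "low"), each = n_per_arm)
    rate <- spec$baseline_hazard * ifelse(group == "low", spec$hazard_ratio, 1)
    t_event <- stats::rexp(n, rate)
    cr <- spec$censoring_rate
    if (cr >= 1) {
      os <- t_event * stats::runif(n) # administrative cut before every event
      event <- rep(0L, n)
    } else if (cr <= 0) {
      os <- t_event
      event <- rep(1L, n)
    } else {
      t_cens <- stats::rexp(n, rate * cr / (1 - cr))
      os <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    data.frame(
      patient_id = sprintf("PT%03d", seq_len(n)),
      os_days = os,
      event = event,
      group = group,
      maxmean_score = stats::runif(n, ifelse(group == "high", 0.5, 0), ifelse(group == "high", 1, 0.5)),
      n_mutations = stats::rpois(n, ifelse(group == "high", 150, 60)),
      stringsAsFactors = FALSE
    )
  })
}
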