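#' Build matched wild-type / phosphomimetic observations per phosphosite
#'
#' Mutation-centred pairing: for every bait and phosphosite, each
#' phosphomimetic library entry covering the site is paired with its
#' wild-type partner peptide, one datapoint per overlapping peptide per
#' replicate. A peptide absent from a replicate's table counts as zero;
#' datapoints where both members are zero carry no information for the
#' enrichment score and are excluded (this is what bounds the score at
#' plus/minus the number of retained datapoints).
#'
#' @param counts Normalized, day-merged counts with `bait_id`,
#'   `replicate_id`, `peptide`, `norm_count`.
#' @param design Design tibble from [generate_variants()].
#' @return A tibble with one row per datapoint: `bait_id`, `protein_ac`,
#'   `site_position`, `replicate_id`, `peptide_pm`, `peptide_wt`,
#'   `nc_wt`, `nc_pm`.
#' @export
build_pair_observations <- function(counts, design) {
  pm_entries <- filter(design, .data$variant == "phosphomimetic")
  if (!all(pm_entries$wt_peptide %in%
             design$peptide[design$variant == "wild_type"])) {
    abort("design integrity error: phosphomimetic entry without a wild-type partner")
  }
  reps <- distinct(counts, .data$bait_id, .data$replicate_id)
  lookup <- counts |>
    select("bait_id", "replicate_id", "peptide", "norm_count")

  tidyr::crossing(reps,
                  select(pm_entries, "protein_ac", "site_position",
                         peptide_pm = "peptide", peptide_wt = "wt_peptide")) |>
    left_join(lookup,
              by = c("bait_id", "replicate_id", peptide_pm = "peptide")) |>
    rename(nc_pm = "norm_count") |>
    left_join(lookup,
              by = c("bait_id", "replicate_id", peptide_wt = "peptide")) |>
    rename(nc_wt = "norm_count") |>
    mutate(nc_pm = tidyr::replace_na(.data$nc_pm, 0),
           nc_wt = tidyr::replace_na(.data$nc_wt, 0)) |>
    filter(.data$nc_wt + .data$nc_pm > 0) |>
    select("bait_id", "protein_ac", "site_position", "replicate_id",
           "peptide_pm", "peptide_wt", "nc_wt", "nc_pm")
}

#' Phosphomimetic enrichment score
#'
#' For n matched datapoints, `PES = sum(nc_pm/(nc_wt + nc_pm)) -
#' sum(nc_wt/(nc_wt + nc_pm))`; each datapoint contributes a value in
#' \[-1, 1\], so the score is bounded by plus/minus n. Positive scores
#' mean the glutamate (phosphomimetic) peptide is preferentially
#' enriched, negative scores mean the wild type is preferred.
#'
#' @param nc_wt,nc_pm Non-negative normalized counts for the wild-type
#'   and phosphomimetic members of each datapoint; `nc_wt + nc_pm` must
#'   be positive for every datapoint.
#' @return The PES, a single number in `[-length(nc_wt), length(nc_wt)]`.
#' @export
#' @examples
#' pes(10, 30)   # +0.5
#' pes(c(5, 8, 2), c(0, 0, 0))  # -3, the lower bound
pes <- function(nc_wt, nc_pm) {
  stopifnot(length(nc_wt) == length(nc_pm))
  if (any(nc_wt < 0 | nc_pm < 0)) abort("counts must be non-negative")
  tot <- nc_wt + nc_pm
  if (any(tot == 0)) {
    abort("datapoint with nc_wt = nc_pm = 0; exclude it upstream (see build_pair_observations)")
  }
  sum(nc_pm / tot) - sum(nc_wt / tot)
}

#' Two-sided Mann-Whitney test
#'
#' Exact null distribution when both groups have at most `exact_max`
#' observations and the data are tie-free; otherwise the normal
#' approximation with mid-ranks, tie-corrected variance and continuity
#' correction.
#'
#' @param x,y Numeric vectors (e.g. wild-type and phosphomimetic
#'   normalized counts).
#' @param exact_max Largest group size for the exact branch (default 10).
#' @return The two-sided p-value.
#' @export
mann_whitney_two_sided <- function(x, y, exact_max = 10L) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  use_exact <- length(x) <= exact_max && length(y) <= exact_max
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  unname(res$p.value)
}

#' Classify phospho-modulation from PES and p-value
#'
#' @param pes Numeric vector of enrichment scores.
#' @param p_value Numeric vector of Mann-Whitney p-values.
#' @param pes_min Minimum absolute PES (default 2).
#' @param p_max Maximum p-value (default 0.01; use 0.001 for the
#'   stringent mode).
#' @return Character vector: `"enabling"`, `"disabling"` or
#'   `"not_significant"`.
#' @export
classify_modulation <- function(pes, p_value, pes_min = 2, p_max = 0.01) {
  case_when(
    p_value <= p_max & pes >= pes_min ~ "enabling",
    p_value <= p_max & pes <= -pes_min ~ "disabling",
    .default = "not_significant"
  )
}

#' PES, significance and classification per bait and phosphosite
#'
#' @param pairs Datapoint tibble from [build_pair_observations()].
#' @inheritParams classify_modulation
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column
#'   (`p_adj`); the classification still uses the raw p-values, matching
#'   the reference analysis.
#' @return A `pes_results` tibble: `bait_id`, `protein_ac`,
#'   `site_position`, `n`, `pes`, `p_value`, (`p_adj`,) `classification`.
#' @export
pes_scores <- function(pairs, pes_min = 2, p_max = 0.01, adjust = FALSE) {
  out <- pairs |>
    group_by(.data$bait_id, .data$protein_ac, .data$site_position) |>
    summarise(
      n = n(),
      pes = pes(.data$nc_wt, .data$nc_pm),
      p_value = mann_whitney_two_sided(.data$nc_wt, .data$nc_pm),
      .groups = "drop"
    )
  if (adjust) out <- mutate(out, p_adj = stats::p.adjust(.data$p_value, "BH"))
  out <- mutate(out, classification = classify_modulation(
    .data$pes, .data$p_value, pes_min = pes_min, p_max = p_max))
  class(out) <- c("pes_results", class(out))
  attr(out, "cutoffs") <- list(pes_min = pes_min, p_max = p_max)
  out
}

#' Count modulated phosphosites in a PES results table
#'
#' Convenience filter used for dataset-level summaries: how many
#' bait-phosphosite pairs are called modulated at given cutoffs.
#'
#' @param results A tibble with `pes` and `p_value` columns (e.g. from
#'   [pes_scores()] or a published results dataset).
#' @inheritParams classify_modulation
#' @return A one-row tibble: `n_total`, `n_modulated`, `n_enabling`,
#'   `n_disabling`, `fraction_modulated`.
#' @export
count_modulated <- function(results, pes_min = 2, p_max = 0.01) {
  cls <- classify_modulation(results$pes, results$p_value,
                             pes_min = pes_min, p_max = p_max)
  tibble(
    n_total = length(cls),
    n_modulated = sum(cls != "not_significant"),
    n_enabling = sum(cls == "enabling"),
    n_disabling = sum(cls == "disabling"),
    fraction_modulated = mean(cls != "not_significant")
  )
}

#' Parse dissociation-constant cells
#'
#' Accepts plain numbers (micromolar; thousands separators allowed), an
#' upper bound written `"<x"`, or `"n.b."` for no detectable binding.
#'
#' @param x Character (or numeric) vector of K_D cells.
#' @return A tibble with `value` (numeric; the bound value for `"<x"`,
#'   NA for `"n.b."`) and `bound` (`"exact"`, `"upper"`, `"none"`).
#' @export
parse_kd <- function(x) {
  x <- trimws(as.character(x))
  is_nb <- grepl("^n\\.?b\\.?$", x, ignore.case = TRUE)
  is_upper <- grepl("^<", x)
  num <- suppressWarnings(as.numeric(gsub("[,<  ]", "", x)))
  bad <- !is_nb & is.na(num)
  if (any(bad)) {
    abort(paste("non-parseable K_D cell(s):",
                paste(unique(x[bad]), collapse = ", ")))
  }
  if (any(num <= 0, na.rm = TRUE)) abort("K_D values must be positive")
  tibble(value = ifelse(is_nb, NA_real_, num),
         bound = case_when(is_nb ~ "none", is_upper ~ "upper",
                           .default = "exact"))
}

#' Affinity fold change and direction
#'
#' Fold change between a reference and a variant dissociation constant:
#' `fold = max(r, 1/r)` with `r = kd_reference / kd_variant`. Direction
#' is `"enabling"` when the variant binds at least `threshold`-fold
#' tighter than the reference, `"disabling"` when at least
#' `threshold`-fold weaker, otherwise `"neutral"`. Bound cells propagate
#' directionally: a variant `"<x"` gives a fold of at least
#' `kd_reference / x`; `"n.b."` counts as an unbounded loss of affinity.
#'
#' @param kd_reference,kd_variant K_D values (numeric micromolar or
#'   strings as in [parse_kd()]).
#' @param threshold Minimum fold change called a direction (default 2).
#' @return A tibble with `fold` (lower bound when a cell was a bound;
#'   `Inf` for `"n.b."`) and `direction`.
#' @export
#' @examples
#' fold_change(134, "<3")   # enabling, fold >= 44.7
#' fold_change(16, "n.b.")  # disabling, unbounded fold
fold_change <- function(kd_reference, kd_variant, threshold = 2) {
  ref <- parse_kd(kd_reference)
  var <- parse_kd(kd_variant)
  n <- max(nrow(ref), nrow(var))
  if (nrow(ref) == 1L) ref <- ref[rep(1L, n), ]
  if (nrow(var) == 1L) var <- var[rep(1L, n), ]
  pmap(list(ref$value, ref$bound, var$value, var$bound),
       function(rv, rb, vv, vb) {
         if (vb == "none") {
           return(tibble(fold = Inf, direction = "disabling"))
         }
         if (rb == "none") {
           return(tibble(fold = Inf, direction = "enabling"))
         }
         r <- rv / vv
         fold <- max(r, 1 / r)
         # an upper bound on the variant only supports the enabling call
         if (vb == "upper" && r < threshold) {
           return(tibble(fold = NA_real_, direction = "neutral"))
         }
         dir <- if (fold < threshold) "neutral" else
           if (r >= 1) "enabling" else "disabling"
         tibble(fold = fold, direction = dir)
       }) |>
    bind_rows()
}

select_representative <- function(records) {
  if (!"pocket" %in% names(records)) return(records)
  records |>
    group_by(.data$bait) |>
    filter(n_distinct(.data$pocket, na.rm = TRUE) <= 1L |
             is.na(.data$pocket) | .data$pocket == "major") |>
    ungroup()
}

#' Concordance between PES calls and orthogonal affinity data
#'
#' Evaluates how well the phage-display classification (PES with
#' Mann-Whitney p-value) predicts the direction of the affinity change
#' measured by fluorescence polarization between wild-type and
#' phosphorylated peptides. A record *passes* the cutoffs when
#' `p_value <= p_max` and `|pes| >= pes_min`; a passing record *agrees*
#' when the sign of its PES matches an at-least-`fold_min` change of
#' K_D in the same direction. For baits probed through several binding
#' pockets, only the major pocket is kept as representative.
#'
#' @param records Validation tibble (see [read_affinity_panel()]).
#' @param fold_min Minimum K_D fold change counted as a real affinity
#'   effect (default 2).
#' @inheritParams classify_modulation
#' @return A `concordance` object: list with `verdicts` (per-record
#'   tibble), `n_tested`, `n_pass`, `n_agree`, `agreement_fraction`.
#' @export
#' @examples
#' conc <- concordance(read_affinity_panel())
#' conc
concordance <- function(records, fold_min = 2, pes_min = 2, p_max = 0.01) {
  reps <- select_representative(records)
  fc <- fold_change(reps$kd_wt, reps$kd_phos, threshold = fold_min)
  verdicts <- reps |>
    mutate(
      fold_phos = fc$fold,
      affinity_direction = fc$direction,
      pes_direction = case_when(.data$pes >= 0 ~ "enabling",
                                .default = "disabling"),
      pass = .data$p_value <= p_max & abs(.data$pes) >= pes_min,
      agree = .data$pass & .data$affinity_direction == .data$pes_direction
    )
  structure(list(
    verdicts = verdicts,
    n_tested = nrow(verdicts),
    n_pass = sum(verdicts$pass),
    n_agree = sum(verdicts$agree),
    agreement_fraction = sum(verdicts$agree) / sum(verdicts$pass)
  ), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("PES / affinity concordance\n")
  cat(sprintf("  records tested:  %d\n", x$n_tested))
  cat(sprintf("  pass cutoffs:    %d\n", x$n_pass))
  cat(sprintf("  agree:           %d (%.0f%%)\n", x$n_agree,
              100 * x$agreement_fraction))
  invisible(x)
}

signed_log2_fold <- function(kd_ref, kd_var) {
  ref <- parse_kd(kd_ref)
  var <- parse_kd(kd_var)
  ifelse(ref$bound == "exact" & var$bound == "exact",
         log2(ref$value / var$value), NA_real_)
}

#' Correlation of phosphomimetic and phosphorylated affinity fold changes
#'
#' Spearman correlation between the signed log2 K_D fold changes
#' wild-type vs phosphomimetic and wild-type vs phosphorylated over the
#' panel records with finite values on both axes (bounds and "n.b." rows
#' are excluded).
#'
#' @param records Validation tibble (see [read_affinity_panel()]).
#' @return A one-row tibble: `n`, `rho`.
#' @export
affinity_fold_correlation <- function(records) {
  f_pm <- signed_log2_fold(records$kd_wt, records$kd_pm)
  f_ph <- signed_log2_fold(records$kd_wt, records$kd_phos)
  ok <- is.finite(f_pm) & is.finite(f_ph)
  tibble(n = sum(ok),
         rho = cor(f_pm[ok], f_ph[ok], method = "spearman"))
}

#' Correlation of PES with the phosphorylation affinity fold change
#'
#' Spearman correlation between the PES and the signed log2 K_D fold
#' change wild-type vs phosphorylated peptide, over representative
#' records (major pocket for multi-pocket baits) with finite affinities.
#'
#' @param records Validation tibble (see [read_affinity_panel()]).
#' @return A one-row tibble: `n`, `rho`.
#' @export
pes_fold_correlation <- function(records) {
  reps <- select_representative(records)
  f_ph <- signed_log2_fold(reps$kd_wt, reps$kd_phos)
  ok <- is.finite(f_ph) & is.finite(reps$pes)
  tibble(n = sum(ok),
         rho = cor(reps$pes[ok], f_ph[ok], method = "spearman"))
}

#' Annotate significant results with kinases and phosphatases
#'
#' @param results `pes_results` tibble from [pes_scores()].
#' @param sites Phosphosite tibble carrying `kinases` / `phosphatases`
#'   columns (semicolon-separated labels, empty or NA when unknown).
#' @return `results` with `kinases`, `phosphatases` and `has_kinase`
#'   columns joined on.
#' @export
annotate_regulators <- function(results, sites) {
  ann <- sites |>
    select("protein_ac", position = "position",
           any_of(c("kinases", "phosphatases")))
  out <- left_join(results, ann,
                   by = c("protein_ac", site_position = "position"))
  if (!"kinases" %in% names(out)) out$kinases <- NA_character_
  if (!"phosphatases" %in% names(out)) out$phosphatases <- NA_character_
  mutate(out, has_kinase = !is.na(.data$kinases) & nzchar(.data$kinases))
}

#' Summarise regulator annotation of significant sites
#'
#' @param annotated Output of [annotate_regulators()].
#' @return A one-row tibble: `n_significant`, `n_with_kinase`,
#'   `fraction_with_kinase`.
#' @export
summarise_regulators <- function(annotated) {
  sig <- filter(annotated, .data$classification != "not_significant")
  tibble(
    n_significant = nrow(sig),
    n_with_kinase = sum(sig$has_kinase),
    fraction_with_kinase = if (nrow(sig) == 0) NA_real_ else
      mean(sig$has_kinase)
  )
}
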