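#' Mean Phred quality of reads
#'
#' @param quality Character vector of Phred+33-encoded quality strings.
#' @return Numeric vector of per-read mean Phred scores.
#' @export
mean_phred <- function(quality) {
  vapply(quality, function(q) {
    if (is.na(q) || nchar(q) == 0) {
      abort("read is missing per-base quality scores")
    }
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter reads on average quality
#'
#' Keeps reads whose mean Phred score is at least `min_quality`
#' (inclusive; a read averaging exactly 20 is conserved).
#'
#' @param reads Tibble from [read_fastq()].
#' @param min_quality Minimum mean Phred score (default 20).
#' @return The retained rows of `reads`.
#' @export
quality_filter <- function(reads, min_quality = 20) {
  reads[mean_phred(reads$quality) >= min_quality, , drop = FALSE]
}

#' Demultiplex reads by 5'/3' barcode pairs
#'
#' A read is assigned to an experiment when its first bases exactly match
#' that experiment's 5' barcode and its last bases exactly match the 3'
#' barcode. Reads matching no (or, impossibly under unique pairs, more
#' than one) experiment get `experiment_id = NA`.
#'
#' @param reads Tibble with a `sequence` column.
#' @param barcode_map Tibble from [read_barcode_map()].
#' @return `reads` with an added `experiment_id` column; the number of
#'   unassigned reads is reported via the `"n_unassigned"` attribute.
#' @export
demultiplex_reads <- function(reads, barcode_map) {
  if (anyDuplicated(barcode_map[c("barcode_5", "barcode_3")])) {
    abort("duplicate 5'/3' barcode pair in the barcode map")
  }
  if (any(nchar(barcode_map$barcode_5) == 0 |
            nchar(barcode_map$barcode_3) == 0)) {
    abort("barcodes must be non-empty")
  }
  n5 <- unique(nchar(barcode_map$barcode_5))
  n3 <- unique(nchar(barcode_map$barcode_3))
  if (length(n5) != 1L || length(n3) != 1L) {
    abort("barcodes must have a fixed length within the map")
  }
  len <- nchar(reads$sequence)
  key <- paste(substr(reads$sequence, 1L, n5),
               substr(reads$sequence, len - n3 + 1L, len))
  lookup <- setNames(barcode_map$experiment_id,
                     paste(barcode_map$barcode_5, barcode_map$barcode_3))
  out <- mutate(reads, experiment_id = unname(lookup[key]))
  attr(out, "n_unassigned") <- sum(is.na(out$experiment_id))
  out
}

#' Trim adapters and translate the peptide-coding insert
#'
#' Extracts the insert between the 5' and 3' adapters and translates it
#' with the standard genetic code. Reads are rejected (peptide NA) with a
#' reason code: `"adapter"` (an adapter was not found), `"frame"` (insert
#' length not a multiple of 3, or empty) or `"stop"` (in-frame stop
#' codon).
#'
#' @param reads Tibble with a `sequence` column.
#' @param adapter_5,adapter_3 Constant DNA sequences flanking the insert.
#' @return `reads` with added `peptide` and `reject_reason` columns.
#' @export
trim_translate <- function(reads, adapter_5, adapter_3) {
  seqs <- reads$sequence
  p5 <- regexpr(adapter_5, seqs, fixed = TRUE)
  # search the 3' adapter after the 5' one
  ins_start <- ifelse(p5 == -1L, NA_integer_,
                      as.integer(p5) + nchar(adapter_5))
  rest <- ifelse(is.na(ins_start), "", substr(seqs, ins_start, nchar(seqs)))
  p3 <- regexpr(adapter_3, rest, fixed = TRUE)
  ins <- ifelse(is.na(ins_start) | p3 == -1L, NA_character_,
                substr(rest, 1L, as.integer(p3) - 1L))

  reason <- rep(NA_character_, length(seqs))
  reason[is.na(ins)] <- "adapter"
  frame_ok <- !is.na(ins) & nchar(ins) > 0 & nchar(ins) %% 3L == 0L
  reason[is.na(reason) & !frame_ok] <- "frame"

  pep <- rep(NA_character_, length(seqs))
  if (any(frame_ok)) pep[frame_ok] <- translate_dna(ins[frame_ok])
  has_stop <- !is.na(pep) & grepl("*", pep, fixed = TRUE)
  reason[is.na(reason) & has_stop] <- "stop"
  pep[!is.na(reason)] <- NA_character_
  mutate(reads, peptide = pep, reject_reason = reason)
}

#' Tally peptides and apply the design / singleton filters
#'
#' Counts identical peptides, drops peptides absent from the library
#' design, and drops singletons (read count 1, or more generally counts
#' below `min_count`).
#'
#' @param peptides Character vector of translated peptides (rejected reads
#'   already removed), or a tibble with a `peptide` column.
#' @param design Design tibble; matching is by exact amino-acid identity,
#'   so synonymous DNA variants collapse to one peptide.
#' @param min_count Minimum retained read count (default 2: singletons
#'   removed).
#' @return A tibble `peptide`, `count`.
#' @export
count_and_filter <- function(peptides, design, min_count = 2L) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- peptides[!is.na(peptides)]
  tibble(peptide = peptides) |>
    count(.data$peptide, name = "count") |>
    filter(.data$peptide %in% design$peptide, .data$count >= min_count)
}

#' Normalize peptide counts to a fixed per-experiment total
#'
#' Counts-per-million: within each experiment the counts are scaled so
#' they sum to `scale` (1e6 by default). Experiments with zero total are
#' flagged with a warning and left at zero.
#'
#' @param counts Tibble with `peptide` and `count` columns; any of
#'   `experiment_id`, `bait_id`, `replicate_id`, `selection_day` columns
#'   present are treated as the experiment grouping.
#' @param scale Normalization constant (default 1e6).
#' @return `counts` with an added `norm_count` column.
#' @export
normalize_counts <- function(counts, scale = 1e6) {
  keys <- intersect(c("experiment_id", "bait_id", "replicate_id",
                      "selection_day"), names(counts))
  out <- counts |>
    group_by(across(all_of(keys))) |>
    mutate(norm_count = if (sum(.data$count) > 0)
      .data$count / sum(.data$count) * scale else 0) |>
    ungroup()
  if (any(out$norm_count == 0 & out$count == 0)) {
    warn("experiment(s) with zero total count flagged; norm_count left at 0")
  }
  out
}

#' Merge selection days of one replicate
#'
#' Averages normalized counts across selection days, counting a peptide
#' absent on a day as zero on that day. The result is independent of day
#' order and idempotent on identical tables.
#'
#' @param counts Tibble with `selection_day`, `peptide` and `norm_count`
#'   columns; extra grouping columns (`bait_id`, `replicate_id`, ...) are
#'   carried through.
#' @return A tibble with one row per peptide (per residual grouping) and
#'   `norm_count` replaced by the across-day mean.
#' @export
merge_days <- function(counts) {
  keys <- intersect(c("experiment_id", "bait_id", "replicate_id"),
                    names(counts))
  counts |>
    group_by(across(all_of(keys))) |>
    group_modify(function(df, key) {
      n_days <- n_distinct(df$selection_day)
      df |>
        group_by(.data$peptide) |>
        summarise(norm_count = sum(.data$norm_count) / n_days,
                  .groups = "drop")
    }) |>
    ungroup()
}

#' Confidence levels for enriched peptides
#'
#' Four additive binary criteria per peptide within a bait: found in at
#' least two replicate selections; supported by an overlapping designed
#' peptide from the same protein region that is also enriched; matches
#' the bait's consensus-motif pattern; mean normalized count at or above
#' the median of the bait's enriched peptides. The level is the number of
#' satisfied criteria, mapped to classes 0 = none, 1 = low, 2-3 = medium,
#' 4 = high.
#'
#' @param counts Merged, normalized counts with `bait_id`,
#'   `replicate_id`, `peptide`, `norm_count`.
#' @param design Design tibble (for tile coordinates).
#' @param motif_patterns Named character vector of regular expressions per
#'   `bait_id` (optional; missing baits simply cannot satisfy the motif
#'   criterion).
#' @return A tibble `bait_id`, `peptide`, `n_replicates`,
#'   `overlap_support`, `motif_match`, `count_rank`, `confidence_level`,
#'   `confidence_class`.
#' @export
score_confidence <- function(counts, design, motif_patterns = NULL) {
  coords <- design |>
    distinct(.data$peptide, .data$protein_ac, .data$tile_start,
             .data$tile_end)
  per_pep <- counts |>
    group_by(.data$bait_id, .data$peptide) |>
    summarise(n_replicates = n_distinct(.data$replicate_id),
              mean_count = mean(.data$norm_count), .groups = "drop") |>
    left_join(coords, by = "peptide", relationship = "many-to-many")

  per_pep |>
    group_by(.data$bait_id) |>
    group_modify(function(df, key) {
      overlap <- map_lgl(seq_len(nrow(df)), function(i) {
        if (is.na(df$protein_ac[i])) return(FALSE)
        any(df$protein_ac == df$protein_ac[i] &
              df$peptide != df$peptide[i] &
              df$tile_start <= df$tile_end[i] &
              df$tile_end >= df$tile_start[i], na.rm = TRUE)
      })
      pattern <- if (!is.null(motif_patterns))
        motif_patterns[[as.character(key$bait_id)]] else NULL
      motif <- if (is.null(pattern)) rep(FALSE, nrow(df)) else
        grepl(pattern, df$peptide)
      tibble(
        peptide = df$peptide,
        n_replicates = df$n_replicates,
        overlap_support = overlap,
        motif_match = motif,
        count_rank = df$mean_count >= median(df$mean_count)
      )
    }) |>
    ungroup() |>
    distinct() |>
    mutate(
      confidence_level = (.data$n_replicates >= 2L) + .data$overlap_support +
        .data$motif_match + .data$count_rank,
      confidence_class = c("none", "low", "medium", "medium",
                           "high")[.data$confidence_level + 1L]
    )
}

#' Library coverage from naive-library sequencing
#'
#' The observed coverage is the fraction of designed peptides seen in the
#' union of the naive samples. With two or more samples the maximum
#' attainable coverage is extrapolated from the accumulation curve of
#' cumulative unique designed peptides versus sample number using a
#' two-parameter saturating exponential `C(k) = C_max (1 - exp(-b k))`;
#' with a single sample no extrapolation is attempted.
#'
#' @param naive_counts Tibble with `sample_id` and `peptide` columns
#'   (counts optional).
#' @param design Design tibble.
#' @return A `coverage_estimate` list: `n_designed`, `n_observed`,
#'   `observed_fraction`, `estimated_max_coverage`, `accumulation`
#'   (tibble of the curve).
#' @export
estimate_coverage <- function(naive_counts, design) {
  designed <- unique(design$peptide)
  samples <- split(naive_counts$peptide, naive_counts$sample_id)
  seen <- character(0)
  cum <- vapply(samples, function(p) {
    seen <<- union(seen, intersect(p, designed))
    length(seen)
  }, numeric(1))
  n_obs <- length(seen)
  obs_frac <- n_obs / length(designed)
  acc <- tibble(n_samples = seq_along(cum), n_unique = unname(cum))

  est <- obs_frac
  if (length(cum) >= 2L && stats::sd(cum) > 0) {
    fit <- tryCatch(
      nls(n_unique ~ cmax * (1 - exp(-b * n_samples)), data = acc,
          start = list(cmax = max(cum) * 1.1, b = 0.5),
          control = list(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est <- min(unname(coef(fit)[["cmax"]]) / length(designed), 1)
      est <- max(est, obs_frac)
    }
  }
  structure(list(
    n_designed = length(designed), n_observed = n_obs,
    observed_fraction = obs_frac, estimated_max_coverage = est,
    accumulation = acc
  ), class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat("Library coverage\n")
  cat(sprintf("  designed peptides: %d\n", x$n_designed))
  cat(sprintf("  observed:          %d (%.1f%%)\n", x$n_observed,
              100 * x$observed_fraction))
  cat(sprintf("  estimated maximum: %.1f%%\n",
              100 * x$estimated_max_coverage))
  invisible(x)
}
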