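#' Simulate a toy proteome with phosphosites and disordered regions
#'
#' Random protein sequences with residue frequencies loosely matching the
#' human proteome (serine/threonine together around 13%), one disordered
#' region per protein, and phosphosites drawn from the region's S/T
#' residues. Localization probabilities and functional scores are Beta
#' distributed (defaults put most localization probabilities above 0.75
#' and spread functional scores broadly, so the design filter keeps a
#' realistic minority of sites).
#'
#' @param n_proteins Number of proteins.
#' @param mean_length Mean protein length (lengths are uniform between
#'   half and 1.5 times this value, minimum 30).
#' @param site_density Probability that an S/T residue inside a
#'   disordered region is a reported phosphosite (default 0.05).
#' @param loc_shape,func_shape Length-2 shape parameters of the Beta
#'   distributions for localization probability and functional score.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list with tibbles `proteome`, `sites`, `regions`.
#' @export
simulate_proteome <- function(n_proteins = 20, mean_length = 120,
                              site_density = 0.05,
                              loc_shape = c(8, 2), func_shape = c(2, 2),
                              seed = 1L) {
  aa_freq <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8,
               E = 7.1, G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7,
               M = 2.1, F = 3.6, P = 6.3, S = 8.3, T = 5.3, W = 1.2,
               Y = 2.7, V = 6.0)
  withr::with_seed(seed, {
    lens <- pmax(30L, as.integer(runif(n_proteins, mean_length * 0.5,
                                       mean_length * 1.5)))
    proteome <- tibble(
      protein_ac = sprintf("SIM%04d", seq_len(n_proteins)),
      sequence = vapply(lens, function(n) {
        paste(sample(names(aa_freq), n, replace = TRUE,
                     prob = aa_freq), collapse = "")
      }, character(1))
    )
    regions <- proteome |>
      mutate(len = nchar(.data$sequence)) |>
      mutate(
        start = map_int(.data$len, function(n)
          sample.int(max(1L, n %/% 4L), 1L)),
        end = pmin(.data$len,
                   .data$start + map_int(.data$len, function(n)
                     as.integer(runif(1, n * 0.4, n * 0.9))))
      ) |>
      select("protein_ac", "start", "end")
    sites <- proteome |>
      inner_join(regions, by = "protein_ac") |>
      mutate(hits = pmap(list(.data$sequence, .data$start, .data$end),
                         function(sq, s, e) {
                           res <- strsplit(substr(sq, s, e), "")[[1]]
                           pos <- which(res %in% c("S", "T"))
                           keep <- pos[runif(length(pos)) < site_density]
                           tibble(position = keep + s - 1L,
                                  residue = res[keep])
                         })) |>
      select("protein_ac", "hits") |>
      tidyr::unnest("hits") |>
      mutate(
        localization_prob = round(rbeta(n(), loc_shape[1], loc_shape[2]), 4),
        functional_score = round(rbeta(n(), func_shape[1], func_shape[2]), 4)
      )
    list(proteome = proteome, sites = sites, regions = regions)
  })
}

#' Simulate phage selection counts over rounds
#'
#' Serial panning model: every library entry starts at equal abundance;
#' each selection round multiplies its abundance by a per-entry
#' enrichment factor (the phosphomimetic variant additionally by its
#' site's `pm_preference`), then sequencing-depth reads are drawn
#' multinomially and become the next round's abundances. Non-binders
#' have enrichment 1 by default.
#'
#' @param design Design tibble from [generate_variants()].
#' @param effects Tibble of true effects with `protein_ac`,
#'   `site_position`, `enrichment` (per-round factor for both members of
#'   the pair) and `pm_preference` (extra factor for the phosphomimetic
#'   member; 1 = no preference).
#' @param n_rounds Selection rounds ("days", default 2).
#' @param depth Reads per experiment per round (default 1e5).
#' @param n_replicates Replicate selections (default 3).
#' @param bait_id Label for the simulated bait (default "bait1").
#' @param seed Integer seed.
#' @return A list: `counts` (tibble `bait_id`, `replicate_id`,
#'   `selection_day`, `peptide`, `count`) and `truth` (the expanded
#'   per-entry fitness table).
#' @export
simulate_selection <- function(design, effects, n_rounds = 2, depth = 1e5,
                               n_replicates = 3, bait_id = "bait1",
                               seed = 1L) {
  fitness <- design |>
    left_join(effects, by = c("protein_ac", "site_position")) |>
    group_by(.data$protein_ac, .data$tile_start, .data$tile_end) |>
    mutate(
      # enrichment is a property of the tile pair: the wild-type member
      # and every phosphomimetic member share it, so the only wt/pm
      # asymmetry is pm_preference
      enrichment = max(c(1, .data$enrichment), na.rm = TRUE)
    ) |>
    ungroup() |>
    mutate(
      pm_preference = tidyr::replace_na(.data$pm_preference, 1),
      fitness = .data$enrichment *
        ifelse(.data$variant == "phosphomimetic", .data$pm_preference, 1)
    )
  # collapse shared wild-type sequences to one displayed clone each
  clones <- fitness |>
    group_by(.data$peptide) |>
    summarise(fitness = max(.data$fitness), .groups = "drop")

  counts <- withr::with_seed(seed, {
    out <- vector("list", n_replicates * n_rounds)
    k <- 0L
    for (rep_i in seq_len(n_replicates)) {
      abundance <- rep(1, nrow(clones))
      for (round_i in seq_len(n_rounds)) {
        w <- abundance * clones$fitness
        cnt <- if (depth > 0 && sum(w) > 0)
          as.vector(rmultinom(1, depth, w)) else rep(0L, nrow(clones))
        abundance <- cnt
        k <- k + 1L
        out[[k]] <- tibble(
          bait_id = bait_id,
          replicate_id = paste0("rep", rep_i),
          selection_day = round_i,
          peptide = clones$peptide,
          count = cnt
        )
      }
    }
    bind_rows(out) |> filter(.data$count > 0)
  })
  list(counts = counts, truth = fitness)
}

#' Write simulated selection counts as barcoded FASTQ reads
#'
#' Turns a count table into error-free reads of the form
#' `barcode5 + adapter5 + oligo + adapter3 + barcode3` with uniform high
#' base qualities, enabling end-to-end tests of demultiplexing, quality
#' filtering, trimming and translation.
#'
#' @param counts Count tibble (`replicate_id`, `selection_day`,
#'   `peptide`, `count`); each read repeats a peptide's oligo `count`
#'   times.
#' @param design Design tibble with an `oligo` column.
#' @param barcode_map Tibble `experiment_id`, `barcode_5`, `barcode_3`;
#'   `experiment_id` must match `paste(replicate_id, selection_day, sep
#'   = "_")`.
#' @param adapter_5,adapter_3 Constant adapter sequences.
#' @param path Output FASTQ path.
#' @param quality_char Phred+33 character for every base (default `"I"`,
#'   Q40).
#' @return `path`, invisibly.
#' @export
write_selection_fastq <- function(counts, design, barcode_map,
                                  adapter_5, adapter_3, path,
                                  quality_char = "I") {
  oligos <- design |> distinct(.data$peptide, .data$oligo)
  reads <- counts |>
    mutate(experiment_id = paste(.data$replicate_id, .data$selection_day,
                                 sep = "_")) |>
    inner_join(oligos, by = "peptide") |>
    inner_join(barcode_map, by = "experiment_id") |>
    tidyr::uncount(.data$count) |>
    mutate(
      read_id = sprintf("read%07d", row_number()),
      sequence = paste0(.data$barcode_5, adapter_5, .data$oligo,
                        adapter_3, .data$barcode_3),
      quality = strrep(quality_char, nchar(.data$sequence))
    ) |>
    select("read_id", "sequence", "quality")
  write_fastq(reads, path)
}

#' Simulate a fluorescence-polarization plate
#'
#' Saturation curves come from the quadratic 1:1 ligand-depletion model;
#' displacement curves from the full three-species competitive
#' equilibrium solved numerically. Gaussian noise with standard
#' deviation `noise_sd` (mP) is added on top.
#'
#' @param kind `"saturation"` or `"displacement"`.
#' @param concentrations Series of total protein (saturation) or total
#'   competitor (displacement) concentrations, micromolar.
#' @param probe_kd Probe dissociation constant (micromolar).
#' @param probe_total Total probe concentration (micromolar).
#' @param protein_total Total protein in the displacement mix
#'   (micromolar; ignored for saturation).
#' @param ki True competitor dissociation constant (displacement only).
#' @param signal_free,signal_bound mP of free and fully bound probe.
#' @param active_fraction Multiplier on the nominal protein
#'   concentrations (saturation only; default 1).
#' @param noise_sd Gaussian noise in mP (default 0).
#' @param seed Integer seed.
#' @return A tibble `concentration`, `signal`.
#' @export
simulate_fp <- function(kind = c("saturation", "displacement"),
                        concentrations, probe_kd, probe_total,
                        protein_total = NULL, ki = NULL,
                        signal_free = 50, signal_bound = 250,
                        active_fraction = 1, noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  bound <- if (kind == "saturation") {
    quadratic_bound_fraction(active_fraction * concentrations,
                             probe_total, probe_kd)
  } else {
    stopifnot(!is.null(protein_total), !is.null(ki))
    solve_competitive_equilibrium(protein_total, probe_total,
                                  concentrations, probe_kd,
                                  ki)$bound_fraction
  }
  signal <- signal_free + (signal_bound - signal_free) * bound
  withr::with_seed(seed, {
    tibble(concentration = concentrations,
           signal = signal + rnorm(length(signal), 0, noise_sd))
  })
}

# Straight-line reference scoring used only to stamp expected results
# into simulated fixtures; deliberately written with base-R loops,
# independent of the dplyr analysis pipeline.
reference_pes_table <- function(counts, design, pes_min = 2, p_max = 0.01) {
  pm <- design[design$variant == "phosphomimetic", ]
  norm <- counts
  key <- paste(norm$bait_id, norm$replicate_id, norm$selection_day)
  for (k in unique(key)) {
    idx <- key == k
    norm$count[idx] <- norm$count[idx] / sum(norm$count[idx]) * 1e6
  }
  # average days per replicate
  merged <- list()
  for (b in unique(norm$bait_id)) for (r in unique(norm$replicate_id)) {
    sub <- norm[norm$bait_id == b & norm$replicate_id == r, ]
    if (nrow(sub) == 0) next
    days <- unique(sub$selection_day)
    agg <- tapply(sub$count, sub$peptide, sum) / length(days)
    merged[[paste(b, r)]] <- data.frame(
      bait_id = b, replicate_id = r, peptide = names(agg),
      nc = as.numeric(agg), stringsAsFactors = FALSE)
  }
  merged <- do.call(rbind, merged)
  out <- list()
  sites <- unique(pm[c("protein_ac", "site_position")])
  for (b in unique(merged$bait_id)) {
    reps <- unique(merged$replicate_id[merged$bait_id == b])
    for (i in seq_len(nrow(sites))) {
      entries <- pm[pm$protein_ac == sites$protein_ac[i] &
                      pm$site_position == sites$site_position[i], ]
      wt_v <- c(); pm_v <- c()
      for (r in reps) for (j in seq_len(nrow(entries))) {
        tab <- merged[merged$bait_id == b & merged$replicate_id == r, ]
        w <- tab$nc[match(entries$wt_peptide[j], tab$peptide)]
        m <- tab$nc[match(entries$peptide[j], tab$peptide)]
        w <- ifelse(is.na(w), 0, w); m <- ifelse(is.na(m), 0, m)
        if (w + m > 0) { wt_v <- c(wt_v, w); pm_v <- c(pm_v, m) }
      }
      if (length(wt_v) == 0) next
      score <- sum((pm_v - wt_v) / (wt_v + pm_v))
      pval <- suppressWarnings(
        wilcox.test(wt_v, pm_v, exact = length(wt_v) <= 10)$p.value)
      cls <- if (pval <= p_max && score >= pes_min) "enabling"
        else if (pval <= p_max && score <= -pes_min) "disabling"
        else "not_significant"
      out[[length(out) + 1]] <- data.frame(
        bait_id = b, protein_ac = sites$protein_ac[i],
        site_position = sites$site_position[i], n = length(wt_v),
        pes = score, p_value = pval, classification = cls,
        stringsAsFactors = FALSE)
    }
  }
  as_tibble(do.call(rbind, out))
}

#' Generate a complete miniature study fixture
#'
#' Writes a self-contained simulated study to `dir`: proteome FASTA,
#' phosphosite and region TSVs, library design TSV, per-round selection
#' count TSV, the true-effect table, and the expected per-site
#' classifications computed by an independent straight-line reference
#' implementation of the scoring path.
#'
#' @param dir Output directory (created if missing).
#' @param n_proteins,site_density Passed to [simulate_proteome()].
#' @param effect_fraction Fraction of designed phosphosites given a true
#'   phosphomimetic preference (default 0.3).
#' @param pm_preference Multiplicative preference of affected sites;
#'   half the affected sites get `pm_preference`, half
#'   `1 / pm_preference` (default 4).
#' @param n_rounds,depth,n_replicates Passed to [simulate_selection()].
#' @param seed Integer seed.
#' @return Invisibly, a list with the in-memory `design`, `counts`,
#'   `truth`, `expected` objects and the file paths written.
#' @export
simulate_fixture <- function(dir, n_proteins = 30, site_density = 0.08,
                             effect_fraction = 0.3, pm_preference = 4,
                             n_rounds = 2, depth = 1e5, n_replicates = 3,
                             seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_proteome(n_proteins = n_proteins,
                           site_density = site_density, seed = seed)
  kept <- filter_phosphosites(sim$sites)
  tiles <- tile_regions(sim$regions, sim$proteome)
  design <- suppressWarnings(generate_variants(tiles, kept))

  sites <- distinct(filter(design, .data$variant == "phosphomimetic"),
                    .data$protein_ac, .data$site_position)
  effects <- withr::with_seed(seed + 1L, {
    n <- nrow(sites)
    affected <- runif(n) < effect_fraction
    dirn <- runif(n) < 0.5
    sites |>
      mutate(
        enrichment = exp(runif(n, log(2), log(8))),
        pm_preference = ifelse(!affected, 1,
                               ifelse(dirn, pm_preference,
                                      1 / pm_preference))
      )
  })
  sel <- simulate_selection(design, effects, n_rounds = n_rounds,
                            depth = depth, n_replicates = n_replicates,
                            seed = seed + 2L)
  expected <- reference_pes_table(sel$counts, design)

  paths <- list(
    proteome = file.path(dir, "proteome.fasta"),
    sites = file.path(dir, "phosphosites.tsv"),
    regions = file.path(dir, "regions.tsv"),
    design = file.path(dir, "design.tsv"),
    counts = file.path(dir, "selection_counts.tsv"),
    truth = file.path(dir, "true_effects.tsv"),
    expected = file.path(dir, "expected_scores.tsv")
  )
  write_proteome(sim$proteome, paths$proteome)
  readr::write_tsv(sim$sites, paths$sites)
  readr::write_tsv(sim$regions, paths$regions)
  readr::write_tsv(design, paths$design)
  readr::write_tsv(sel$counts, paths$counts)
  readr::write_tsv(effects, paths$truth)
  readr::write_tsv(expected, paths$expected)
  invisible(list(design = design, counts = sel$counts, effects = effects,
                 expected = expected, paths = paths))
}
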