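#' Filter phosphosites by localization probability and functional score
#'
#' Keeps serine/threonine phosphosites with localization probability and
#' functional score at or above the cutoffs. Proteins where no site passes
#' still contribute their single best site (highest functional score, ties
#' broken by lowest position), flagged `rescued`. Proteins on the rescue
#' list keep all their sites regardless of the cutoffs.
#'
#' @param sites Tibble of phosphosite records (`protein_ac`, `position`,
#'   `residue`, `localization_prob`, `functional_score`, plus optional
#'   annotation columns).
#' @param loc_min Minimum localization probability (default 0.75).
#' @param func_min Minimum functional score (default 0.4524).
#' @param rescue_accessions Character vector of protein accessions whose
#'   sites are all kept.
#' @return The kept rows of `sites` with an added logical `rescued` column
#'   (TRUE for sites kept despite failing a cutoff).
#' @export
#' @examples
#' sites <- tibble::tibble(
#'   protein_ac = c("P1", "P1", "P2"), position = c(5L, 9L, 3L),
#'   residue = c("S", "T", "S"),
#'   localization_prob = c(0.9, 0.6, 0.95),
#'   functional_score = c(0.5, 0.4, 0.1)
#' )
#' filter_phosphosites(sites)
filter_phosphosites <- function(sites, loc_min = 0.75, func_min = 0.4524,
                                rescue_accessions = character()) {
  stopifnot(is.data.frame(sites))
  bad_res <- !sites$residue %in% c("S", "T")
  if (any(bad_res)) {
    warn(paste0(
      sum(bad_res), " phosphosite record(s) rejected (residue not S/T): ",
      paste(utils::head(paste0(sites$protein_ac[bad_res], ":",
                               sites$position[bad_res]), 5),
            collapse = ", ")
    ))
    sites <- sites[!bad_res, , drop = FALSE]
  }
  scores <- c(sites$localization_prob, sites$functional_score)
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    abort("localization_prob and functional_score must lie in [0, 1]")
  }

  sites |>
    mutate(.pass = .data$localization_prob >= loc_min &
             .data$functional_score >= func_min) |>
    group_by(.data$protein_ac) |>
    arrange(desc(.data$functional_score), .data$position, .by_group = TRUE) |>
    mutate(
      .rescue_best = !any(.data$.pass) & row_number() == 1L,
      .rescue_list = .data$protein_ac %in% rescue_accessions,
      .keep_row = .data$.pass | .data$.rescue_best | .data$.rescue_list
    ) |>
    ungroup() |>
    filter(.data$.keep_row) |>
    mutate(rescued = !.data$.pass) |>
    select(-".pass", -".rescue_best", -".rescue_list", -".keep_row") |>
    arrange(.data$protein_ac, .data$position)
}

tile_one_region <- function(start, end, length, step) {
  span <- end - start + 1L
  if (span <= length) return(tibble(start = start, end = end))
  starts <- seq.int(start, end - length + 1L, by = step)
  ends <- starts + length - 1L
  if (max(ends) < end) {
    starts <- c(starts, end - length + 1L)
    ends <- c(ends, end)
  }
  tibble(start = as.integer(starts), end = as.integer(ends))
}

#' Tile disordered regions into overlapping peptides
#'
#' Each region is cut into `length`-mer tiles starting every `step`
#' residues (defaults: 16-mers overlapping by 12). If the last regular
#' tile stops short of the region end, one extra tile anchored at the end
#' is added so every residue is covered. Regions shorter than `length`
#' yield a single short tile spanning the whole region.
#'
#' @param regions Tibble with `protein_ac`, `start`, `end` (1-based
#'   inclusive).
#' @param proteome Tibble from [read_proteome()].
#' @param length Tile length in residues (default 16).
#' @param step Offset between consecutive tile starts (default 4, i.e.
#'   12-residue overlap).
#' @return A tibble of tiles: `protein_ac`, `start`, `end`, `sequence`.
#' @export
tile_regions <- function(regions, proteome, length = 16L, step = 4L) {
  seqs <- setNames(proteome$sequence, proteome$protein_ac)
  missing <- setdiff(regions$protein_ac, names(seqs))
  if (length(missing) > 0) {
    abort(paste("regions reference proteins absent from the proteome:",
                paste(utils::head(missing, 5), collapse = ", ")))
  }
  plen <- nchar(seqs)[regions$protein_ac]
  bad <- regions$start < 1L | regions$end > plen | regions$start > regions$end
  if (any(bad)) {
    abort(paste("region outside protein bounds:",
                paste(utils::head(paste0(regions$protein_ac[bad], ":",
                                         regions$start[bad], "-",
                                         regions$end[bad]), 5),
                      collapse = ", ")))
  }
  regions |>
    mutate(.tiles = map2(.data$start, .data$end, tile_one_region,
                         length = length, step = step)) |>
    select("protein_ac", ".tiles") |>
    tidyr::unnest(".tiles") |>
    distinct() |>
    mutate(sequence = unname(substr(seqs[.data$protein_ac], .data$start,
                                    .data$end)))
}

#' Generate wild-type / phosphomimetic library entries
#'
#' Maps filtered phosphosites onto the tiled peptides. Every (tile, site)
#' pair yields one phosphomimetic entry with exactly that serine/threonine
#' replaced by glutamate; a tile with several sites yields several
#' single-mutant entries, never a double mutant. One wild-type entry per
#' distinct tile sequence is shared by all its phosphomimetic partners.
#'
#' @param tiles Tibble from [tile_regions()].
#' @param sites Tibble from [filter_phosphosites()].
#' @return A design tibble with columns `protein_ac`, `tile_start`,
#'   `tile_end`, `variant` (`"wild_type"` / `"phosphomimetic"`),
#'   `site_position` (protein coordinate, NA for wild type), `mut_offset`
#'   (1-based position inside the peptide, NA for wild type), `peptide`,
#'   and `wt_peptide` (the matched wild-type sequence). Sites covered by
#'   no tile are reported via a warning and the `"uncovered_sites"`
#'   attribute.
#' @export
generate_variants <- function(tiles, sites) {
  hits <- inner_join(
    tiles, sites,
    by = join_by("protein_ac", "start" <= "position", "end" >= "position")
  ) |>
    mutate(mut_offset = .data$position - .data$start + 1L)

  bad <- substr(hits$sequence, hits$mut_offset, hits$mut_offset) != hits$residue
  if (any(bad)) {
    abort(paste(
      "phosphosite residue does not match the proteome:",
      paste(utils::head(paste0(hits$protein_ac[bad], ":", hits$position[bad],
                               hits$residue[bad]), 5), collapse = ", ")))
  }

  uncovered <- anti_join(
    sites, hits, by = c("protein_ac", "position")
  )
  if (nrow(uncovered) > 0) {
    warn(paste0(nrow(uncovered),
                " phosphosite(s) not covered by any tile; see attr(.,",
                " \"uncovered_sites\")"))
  }

  pm <- hits |>
    mutate(
      variant = "phosphomimetic",
      peptide = paste0(substr(.data$sequence, 1L, .data$mut_offset - 1L), "E",
                       substr(.data$sequence, .data$mut_offset + 1L,
                              nchar(.data$sequence))),
      wt_peptide = .data$sequence
    ) |>
    select("protein_ac", tile_start = "start", tile_end = "end", "variant",
           site_position = "position", "mut_offset", "peptide", "wt_peptide")

  wt <- hits |>
    distinct(.data$protein_ac, .data$start, .data$end, .data$sequence) |>
    distinct(.data$sequence, .keep_all = TRUE) |>
    transmute(
      protein_ac = .data$protein_ac,
      tile_start = .data$start, tile_end = .data$end,
      variant = "wild_type",
      site_position = NA_integer_, mut_offset = NA_integer_,
      peptide = .data$sequence, wt_peptide = .data$sequence
    )

  out <- bind_rows(wt, pm) |>
    arrange(.data$protein_ac, .data$tile_start, .data$variant,
            .data$site_position)
  attr(out, "uncovered_sites") <- uncovered
  out
}

scan_forbidden <- function(dna, motifs) {
  pos <- lapply(motifs, function(m) {
    out <- integer()
    from <- 1L
    repeat {
      hit <- regexpr(m, substr(dna, from, nchar(dna)), fixed = TRUE)
      if (hit == -1L) break
      out <- c(out, from + as.integer(hit) - 1L)
      from <- from + as.integer(hit)
    }
    out
  })
  sort(unique(unlist(pos)))
}

#' Reverse translate a peptide with restriction-site avoidance
#'
#' Deterministic greedy reverse translation: every residue gets its
#' top-ranked codon; if the assembled oligo (including the fixed vector
#' flanks) contains a forbidden motif, the left-most codon overlapping the
#' left-most occurrence that still has a lower-ranked alternative is
#' bumped to its next codon, and the scan repeats until the construct is
#' clean. The default forbidden motif is the SmaI site (CCCGGG), which
#' must be absent because SmaI digestion removes non-recombinant phagemid
#' during library construction.
#'
#' @param peptide Character vector of peptides (standard 20 amino acids).
#' @param codon_table Ranked codon tibble (see [ecoli_codon_table()]).
#' @param forbidden_motifs DNA motifs that must not occur in
#'   `flank_5prime + oligo + flank_3prime`.
#' @param flank_5prime,flank_3prime Fixed vector sequences flanking the
#'   insert in the display phagemid; motifs spanning the junctions are
#'   checked too.
#' @return Character vector of oligos, same length as `peptide`.
#' @export
#' @examples
#' reverse_translate("PGSR")
reverse_translate <- function(peptide,
                              codon_table = ecoli_codon_table(),
                              forbidden_motifs = "CCCGGG",
                              flank_5prime = "", flank_3prime = "") {
  codons <- split(codon_table$codon[order(codon_table$amino_acid,
                                          codon_table$rank)],
                  sort(codon_table$amino_acid))
  vapply(peptide, function(p) {
    aa <- strsplit(p, "")[[1]]
    unknown <- setdiff(aa, names(codons))
    if (length(unknown) > 0) {
      abort(paste0("peptide '", p, "' contains unsupported residue(s): ",
                   paste(unique(unknown), collapse = ", ")))
    }
    ranks <- rep(1L, length(aa))
    max_rank <- lengths(codons)[aa]
    for (iter in seq_len(length(aa) * max(vapply(codons, length, 1L)) + 1L)) {
      oligo <- paste(mapply(function(a, r) codons[[a]][r], aa, ranks),
                     collapse = "")
      ctx <- paste0(flank_5prime, oligo, flank_3prime)
      occ <- scan_forbidden(ctx, forbidden_motifs)
      if (length(occ) == 0L) return(oligo)
      # codon indices (within the insert) overlapping the left-most hit
      hit_start <- occ[1] - nchar(flank_5prime)
      hit_end <- hit_start + max(nchar(forbidden_motifs)) - 1L
      idx <- which((seq_along(aa) - 1L) * 3L + 1L <= hit_end &
                     (seq_along(aa) - 1L) * 3L + 3L >= hit_start)
      if (length(idx) == 0L) {
        abort(paste0("forbidden motif lies entirely within the fixed flanks",
                     " and cannot be removed by codon choice"))
      }
      bump <- idx[ranks[idx] < max_rank[idx]][1]
      if (is.na(bump)) {
        # exhausted alternatives under the hit; reset and bump to the right
        idx2 <- which(seq_along(aa) > max(idx) & ranks < max_rank)
        if (length(idx2) == 0L) {
          abort(paste0("cannot avoid forbidden motif in peptide '", p, "'"))
        }
        bump <- idx2[1]
      }
      ranks[bump] <- ranks[bump] + 1L
    }
    abort(paste0("codon substitution did not converge for peptide '", p, "'"))
  }, character(1), USE.NAMES = FALSE)
}

#' Attach oligos to a library design
#'
#' @param design Design tibble from [generate_variants()].
#' @inheritParams reverse_translate
#' @return `design` with an added `oligo` column.
#' @export
design_oligos <- function(design, codon_table = ecoli_codon_table(),
                          forbidden_motifs = "CCCGGG",
                          flank_5prime = "", flank_3prime = "") {
  uniq <- unique(design$peptide)
  oligos <- setNames(
    reverse_translate(uniq, codon_table, forbidden_motifs,
                      flank_5prime, flank_3prime),
    uniq
  )
  mutate(design, oligo = unname(oligos[.data$peptide]))
}

#' Translate DNA to peptide (standard genetic code)
#'
#' @param dna Character vector of in-frame DNA sequences.
#' @return Character vector of amino-acid sequences (stop = `*`).
#' @export
translate_dna <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     no.init.codon = TRUE))
}

#' Summary statistics of a library design
#'
#' @param design Design tibble from [generate_variants()].
#' @return A `library_stats` list: `n_phosphosites`, `n_peptides`
#'   (distinct displayed sequences), `n_pairs` (tile x site combinations),
#'   `fraction_complete_pairs` (phosphomimetic entries whose wild-type
#'   partner is present), `site_coverage` (tibble: tiles covering each
#'   site) and `mut_position` (tibble: histogram of mutated positions
#'   within the peptide).
#' @export
compute_library_stats <- function(design) {
  pm <- filter(design, .data$variant == "phosphomimetic")
  wt_seqs <- design$peptide[design$variant == "wild_type"]
  cov <- pm |>
    count(.data$protein_ac, .data$site_position, name = "n_tiles") |>
    count(.data$n_tiles, name = "n_sites")
  pos <- count(pm, .data$mut_offset, name = "n_entries")
  out <- list(
    n_phosphosites = nrow(distinct(pm, .data$protein_ac, .data$site_position)),
    n_peptides = length(unique(design$peptide)),
    n_pairs = nrow(pm),
    fraction_complete_pairs = if (nrow(pm) == 0) NA_real_ else
      mean(pm$wt_peptide %in% wt_seqs),
    site_coverage = cov,
    mut_position = pos
  )
  structure(out, class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat("Peptide library design\n")
  cat("  phosphosites:        ", x$n_phosphosites, "\n")
  cat("  distinct peptides:   ", x$n_peptides, "\n")
  cat("  wt/pm pairs:         ", x$n_pairs, "\n")
  cat("  complete pairs:      ",
      ifelse(is.na(x$fraction_complete_pairs), "NA",
             sprintf("%.1f%%", 100 * x$fraction_complete_pairs)), "\n")
  invisible(x)
}
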