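#' Read a proteome FASTA file
#'
#' @param path Path to a (possibly gzipped) FASTA file of protein sequences.
#'   Accession is the first whitespace-delimited token of each header.
#' @return A tibble with columns `protein_ac` and `sequence`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble(
    protein_ac = sub("\\s.*$", "", names(aa)),
    sequence = as.character(aa)
  )
}

#' Write a proteome tibble to FASTA
#'
#' @param proteome Tibble with `protein_ac` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$protein_ac))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a phosphosite table
#'
#' Expected columns: `protein_ac`, `position` (1-based), `residue` (S/T),
#' `localization_prob`, `functional_score`, and optional `kinases` /
#' `phosphatases` (semicolon-separated regulator labels).
#'
#' @param path Path to a TSV file.
#' @return A tibble of phosphosite records.
#' @export
read_phosphosites <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    protein_ac = readr::col_character(),
                    position = readr::col_integer(),
                    residue = readr::col_character(),
                    localization_prob = readr::col_double(),
                    functional_score = readr::col_double(),
                    .default = readr::col_character()
                  ))
}

#' Read a disordered-region interval table
#'
#' @param path Path to a TSV with columns `protein_ac`, `start`, `end`
#'   (1-based inclusive).
#' @return A tibble of regions.
#' @export
read_regions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    protein_ac = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer()
                  ))
}

#' Read / write a peptide library design
#'
#' The design TSV is the interchange format between library design and the
#' selection/scoring modules: one row per displayed peptide.
#'
#' @param path Path to the design TSV.
#' @return A tibble (one row per library entry).
#' @export
read_design <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    protein_ac = readr::col_character(),
                    tile_start = readr::col_integer(),
                    tile_end = readr::col_integer(),
                    variant = readr::col_character(),
                    site_position = readr::col_integer(),
                    mut_offset = readr::col_integer(),
                    peptide = readr::col_character(),
                    .default = readr::col_character()
                  ))
}

#' @rdname read_design
#' @param design Design tibble from [generate_variants()].
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' Write design oligos as FASTA
#'
#' @param design Design tibble carrying an `oligo` column (see
#'   [design_oligos()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(design, path) {
  if (!"oligo" %in% names(design)) {
    abort("design has no `oligo` column; run design_oligos() first")
  }
  ids <- paste(design$protein_ac, design$tile_start, design$tile_end,
               design$variant,
               ifelse(is.na(design$site_position), "wt", design$site_position),
               sep = "|")
  dna <- Biostrings::DNAStringSet(setNames(design$oligo, ids))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to a (possibly gzipped) FASTQ file.
#' @return A tibble with columns `read_id`, `sequence` and `quality`
#'   (Phred+33 encoded string).
#' @export
read_fastq <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
  tibble(
    read_id = sub("\\s.*$", "", names(reads)),
    sequence = as.character(reads),
    quality = as.character(S4Vectors::mcols(reads)$qualities)
  )
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a barcode map
#'
#' JSON format: an object mapping experiment id to an object with
#' `barcode_5` and `barcode_3` fields, e.g.
#' `{"exp1": {"barcode_5": "ACGT", "barcode_3": "TTGA"}}`.
#'
#' @param path Path to the JSON barcode map.
#' @return A tibble with `experiment_id`, `barcode_5`, `barcode_3`.
#' @export
read_barcode_map <- function(path) {
  raw <- jsonlite::read_json(path)
  tibble(
    experiment_id = names(raw),
    barcode_5 = map_chr(raw, "barcode_5"),
    barcode_3 = map_chr(raw, "barcode_3")
  )
}

#' Read a per-experiment peptide count table
#'
#' @param path TSV with at least `peptide` and `count` columns; extra
#'   annotation columns (experiment, bait, replicate, day) are preserved.
#' @return A tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read an FP plate table
#'
#' @param path TSV with columns `concentration` (micromolar) and `signal`
#'   (mP); an optional `replicate` column is preserved.
#' @return A tibble.
#' @export
read_plate <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    concentration = readr::col_double(),
                    signal = readr::col_double(),
                    .default = readr::col_guess()
                  ))
}

#' Curated affinity validation panel
#'
#' Reads a validation table of fluorescence-polarization affinities for
#' wild-type, phosphomimetic (S/T to E) and phosphorylated versions of the
#' same peptide against a panel of bait domains, together with the
#' phage-display PES and Mann-Whitney p-value for the matching
#' bait-phosphosite pair. K_D cells are strings: a number (micromolar),
#' a bound such as `"<3"`, or `"n.b."` for no detectable binding.
#'
#' The packaged default (`system.file("extdata", "affinity_panel.tsv",
#' package = "phosdisplay")`) is the published 32-triplet benchmark panel
#' used by [concordance()].
#'
#' @param path Path to the panel TSV; defaults to the packaged panel.
#' @return A tibble with columns `bait`, `pocket`, `position_label`,
#'   `ligand`, `kd_wt`, `kd_pm`, `kd_phos` (character), `pes`, `p_value`.
#' @export
read_affinity_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "affinity_panel.tsv",
                        package = "phosdisplay", mustWork = TRUE)
  }
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    bait = readr::col_character(),
                    pocket = readr::col_character(),
                    position_label = readr::col_character(),
                    ligand = readr::col_character(),
                    kd_wt = readr::col_character(),
                    kd_pm = readr::col_character(),
                    kd_phos = readr::col_character(),
                    pes = readr::col_double(),
                    p_value = readr::col_double()
                  ))
}
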