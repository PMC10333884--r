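test_that("phosphosite filter applies both cutoffs and the rescue rules", {
  sites <- tibble::tibble(
    protein_ac = c("A", "A", "B", "B", "C", "C"),
    position = c(5L, 9L, 3L, 7L, 2L, 8L),
    residue = c("S", "T", "S", "T", "S", "S"),
    localization_prob = c(0.80, 0.90, 0.90, 0.60, 0.80, 0.95),
    functional_score = c(0.50, 0.10, 0.30, 0.40, 0.46, 0.60)
  )
  kept <- filter_phosphosites(sites)

  # exhaustive check of the predicate on the toy table
  pass <- sites$localization_prob >= 0.75 & sites$functional_score >= 0.4524
  expect_true(all(!kept$rescued == pass[match(
    paste(kept$protein_ac, kept$position),
    paste(sites$protein_ac, sites$position))]))

  # protein A: one passing site kept, failing one dropped
  expect_equal(kept$position[kept$protein_ac == "A"], 5L)
  expect_false(kept$rescued[kept$protein_ac == "A"])

  # protein B: nothing passes; highest functional score rescued
  expect_equal(kept$position[kept$protein_ac == "B"], 7L)
  expect_true(kept$rescued[kept$protein_ac == "B"])

  # every input protein contributes at least one site
  expect_setequal(unique(kept$protein_ac), unique(sites$protein_ac))
})

test_that("rescue list keeps all sites of listed proteins", {
  sites <- tibble::tibble(
    protein_ac = c("X", "X"), position = c(1L, 5L), residue = c("S", "S"),
    localization_prob = c(0.1, 0.2), functional_score = c(0.1, 0.2)
  )
  kept <- filter_phosphosites(sites, rescue_accessions = "X")
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$rescued))
})

test_that("invalid phosphosite records are rejected or raise errors", {
  sites <- tibble::tibble(
    protein_ac = c("A", "A"), position = c(1L, 2L), residue = c("Y", "S"),
    localization_prob = c(0.9, 0.9), functional_score = c(0.9, 0.9)
  )
  expect_warning(kept <- filter_phosphosites(sites), "residue not S/T")
  expect_equal(kept$position, 2L)
  sites$residue <- "S"
  sites$functional_score[1] <- 1.2
  expect_error(filter_phosphosites(sites), "\\[0, 1\\]")
})

test_that("tiling matches the enumeration oracle on canonical cases", {
  prot <- tibble::tibble(protein_ac = "P",
                         sequence = strrep("ACDEFGHIKL", 10))
  for (span in c(16L, 24L, 18L, 7L, 40L)) {
    regions <- tibble::tibble(protein_ac = "P", start = 3L,
                              end = 3L + span - 1L)
    tl <- tile_regions(regions, prot)
    expected <- oracle_tiles(3L, 3L + span - 1L)
    expect_equal(cbind(tl$start, tl$end), unname(expected),
                 info = paste("span", span))
  }
  # region of length 24: starts at offsets 0, 4, 8
  tl24 <- tile_regions(tibble::tibble(protein_ac = "P", start = 1L,
                                      end = 24L), prot)
  expect_equal(tl24$start, c(1L, 5L, 9L))
  expect_equal(tl24$end, c(16L, 20L, 24L))
  # length 18: regular tile plus end-anchored tile
  tl18 <- tile_regions(tibble::tibble(protein_ac = "P", start = 1L,
                                      end = 18L), prot)
  expect_equal(tl18$start, c(1L, 3L))
  expect_equal(tl18$end, c(16L, 18L))
})

test_that("tiling invariants hold on random regions", {
  withr::with_seed(42, {
    prot <- tibble::tibble(
      protein_ac = "P",
      sequence = paste(sample(c("A", "S", "T", "G", "L"), 500,
                              replace = TRUE), collapse = ""))
    for (i in 1:300) {
      s <- sample.int(480, 1)
      e <- min(500L, s + sample.int(60, 1))
      tl <- tile_regions(tibble::tibble(protein_ac = "P", start = s,
                                        end = e), prot)
      covered <- sort(unique(unlist(Map(seq, tl$start, tl$end))))
      expect_identical(covered, seq(s, e))
      expect_true(sum(tl$end - tl$start + 1L != 16L) <= 1L)
      reg <- tl[seq_len(max(1, nrow(tl) - 1)), ]
      if (nrow(reg) > 1 && e - s + 1L > 16L) {
        expect_true(all(diff(reg$start) == 4L))
      }
    }
  })
  expect_error(
    tile_regions(tibble::tibble(protein_ac = "P", start = 1L, end = 10L),
                 tibble::tibble(protein_ac = "P", sequence = "ACDEF")),
    "outside protein bounds")
})

test_that("variant generation emits single-mutant pairs only", {
  prot <- tiny_proteome()
  regions <- tibble::tibble(protein_ac = "PROT1", start = 1L, end = 36L)
  tiles <- tile_regions(regions, prot)
  # two sites inside the first tile (positions 5 and 7: S and T)
  sites <- tibble::tibble(
    protein_ac = "PROT1", position = c(5L, 7L), residue = c("S", "T"),
    localization_prob = 0.9, functional_score = 0.9, rescued = FALSE
  )
  design <- generate_variants(tiles, sites)
  first_tile <- dplyr::filter(design, tile_start == 1L)
  expect_equal(sum(first_tile$variant == "wild_type"), 1L)
  expect_equal(sum(first_tile$variant == "phosphomimetic"), 2L)
  # each phosphomimetic entry differs from wild type at exactly one S/T -> E
  pm <- dplyr::filter(design, variant == "phosphomimetic")
  for (i in seq_len(nrow(pm))) {
    a <- strsplit(pm$wt_peptide[i], "")[[1]]
    b <- strsplit(pm$peptide[i], "")[[1]]
    diffs <- which(a != b)
    expect_length(diffs, 1L)
    expect_true(a[diffs] %in% c("S", "T"))
    expect_equal(b[diffs], "E")
  }
  # pair count per site equals brute-force tile membership
  for (p in unique(sites$position)) {
    n_tiles <- sum(tiles$start <= p & tiles$end >= p)
    expect_equal(sum(pm$site_position == p), n_tiles)
  }
  # residue mismatch is a validation error
  bad <- dplyr::mutate(sites, position = position + 1L)
  bad$residue <- c("S", "T")
  expect_error(suppressWarnings(generate_variants(tiles, bad)),
               "does not match the proteome")
})

test_that("uncovered sites are reported", {
  prot <- tiny_proteome()
  tiles <- tile_regions(
    tibble::tibble(protein_ac = "PROT1", start = 1L, end = 16L), prot)
  sites <- tibble::tibble(
    protein_ac = "PROT1", position = c(5L, 30L), residue = c("S", "T"),
    localization_prob = 0.9, functional_score = 0.9
  )
  expect_warning(design <- generate_variants(tiles, sites), "not covered")
  expect_equal(attr(design, "uncovered_sites")$position, 30L)
})

test_that("reverse translation round-trips and avoids forbidden motifs", {
  withr::with_seed(7, {
    peps <- replicate(25, paste(sample(c("A", "C", "D", "E", "F", "G",
                                         "H", "I", "K", "L", "M", "N",
                                         "P", "Q", "R", "S", "T", "V",
                                         "W", "Y"), 16, replace = TRUE),
                                collapse = ""))
  })
  oligos <- reverse_translate(peps)
  expect_equal(translate_dna(oligos), peps)
  expect_false(any(grepl("CCCGGG", oligos, fixed = TRUE)))
})

test_that("codon fallback removes a motif created by top-ranked codons", {
  contrived <- tibble::tibble(
    amino_acid = c("P", "P", "G", "G"),
    codon = c("CCC", "CCG", "GGG", "GGT"),
    rank = c(1L, 2L, 1L, 2L)
  )
  oligo <- reverse_translate("PG", codon_table = contrived)
  expect_equal(translate_dna(oligo), "PG")
  # exhaustive 6-mer window scan
  windows <- vapply(seq_len(nchar(oligo) - 5L),
                    function(i) substr(oligo, i, i + 5L), character(1))
  expect_false("CCCGGG" %in% windows)

  # junction case: motif spans the 5' flank and the first codon
  oligo2 <- reverse_translate("GK", codon_table = tibble::tibble(
    amino_acid = c("G", "G", "K"), codon = c("GGG", "GGT", "AAA"),
    rank = c(1L, 2L, 1L)), flank_5prime = "TTCCC")
  ctx <- paste0("TTCCC", oligo2)
  expect_false(grepl("CCCGGG", ctx, fixed = TRUE))
  expect_equal(translate_dna(oligo2), "GK")

  # a motif fixed entirely inside the flanks cannot be repaired
  expect_error(
    reverse_translate("AK", flank_5prime = "ACCCGGGT"),
    "within the fixed flanks")
})

test_that("library statistics count sites, peptides and pairs", {
  empty <- generate_variants(
    tibble::tibble(protein_ac = character(), start = integer(),
                   end = integer(), sequence = character()),
    tibble::tibble(protein_ac = character(), position = integer(),
                   residue = character()))
  st0 <- compute_library_stats(empty)
  expect_equal(st0$n_phosphosites, 0L)
  expect_equal(st0$n_peptides, 0L)
  expect_equal(st0$n_pairs, 0L)

  prot <- tiny_proteome()
  tiles <- tile_regions(
    tibble::tibble(protein_ac = "PROT1", start = 1L, end = 16L), prot)
  sites <- tibble::tibble(
    protein_ac = "PROT1", position = c(5L, 7L), residue = c("S", "T"),
    localization_prob = 0.9, functional_score = 0.9)
  st <- compute_library_stats(generate_variants(tiles, sites))
  expect_equal(st$n_peptides, 3L)
  expect_equal(st$n_pairs, 2L)
  expect_equal(st$fraction_complete_pairs, 1)

  # 3 overlapping tiles covering one site -> coverage histogram entry at 3
  tiles3 <- tile_regions(
    tibble::tibble(protein_ac = "PROT1", start = 1L, end = 28L), prot)
  sites3 <- tibble::tibble(
    protein_ac = "PROT1", position = 19L, residue = "S",
    localization_prob = 0.9, functional_score = 0.9)
  st3 <- compute_library_stats(
    suppressWarnings(generate_variants(tiles3, sites3)))
  n_cov <- sum(tiles3$start <= 19 & tiles3$end >= 19)
  expect_equal(st3$site_coverage$n_tiles, n_cov)
})
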