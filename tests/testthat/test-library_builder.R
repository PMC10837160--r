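test_that("filter_pavs_by_maf applies a strict 10% cutoff", {
  pavs <- tibble::tibble(variant_id = c("a", "b", "c"),
                         maf = c(0.12, 0.10, 0.08))
  kept <- filter_pavs_by_maf(pavs)
  expect_identical(kept$variant_id, "a")
  expect_error(filter_pavs_by_maf(tibble::tibble(variant_id = "x", maf = 0.6)),
               "0.5")
})

test_that("inject_variant substitutes a single residue", {
  expect_identical(
    inject_variant("MKR", list(protein_pos = 2, ref_aa = "K", alt_aa = "R")),
    "MRR"
  )
  # the incretin pro-peptide case: ALELA[S/G]QANR at positions 98-107
  prot <- paste0(strrep("A", 97), "ALELASQANR", strrep("A", 20))
  out <- inject_variant(prot, list(protein_pos = 103, ref_aa = "S",
                                   alt_aa = "G"))
  expect_identical(substring(out, 98, 107), "ALELAGQANR")
  expect_identical(nchar(out), nchar(prot))
  expect_identical(substring(out, 1, 97), substring(prot, 1, 97))

  expect_error(
    inject_variant("MKR", list(protein_pos = 2, ref_aa = "E", alt_aa = "D")),
    "mismatch"
  )
})

test_that("digest reproduces the worked examples", {
  d <- digest("ACDEFGH")
  expect_identical(nrow(d), 1L)
  expect_identical(d$sequence, "ACDEFGH")
  expect_identical(d$start_pos, 1L)
  expect_identical(d$missed_cleavages, 0L)

  expect_identical(nrow(digest("ACDEF")), 0L)

  d <- digest("MKAAAAAARCCCCCCK")
  expect_true(any(d$sequence == "AAAAAAR" & d$start_pos == 3 &
                    d$missed_cleavages == 0))
  expect_true(any(d$sequence == "AAAAAARCCCCCCK" & d$start_pos == 3 &
                    d$missed_cleavages == 1))
  expect_identical(digest_key(d), digest_key(oracle_digest("MKAAAAAARCCCCCCK")))

  d <- digest("MAAAAAAKDDDDDDR")
  expect_true(any(d$sequence == "MAAAAAAK" & d$start_pos == 1 &
                    d$missed_cleavages == 0 & !d$met_excised))
  expect_true(any(d$sequence == "AAAAAAK" & d$start_pos == 2 &
                    d$missed_cleavages == 0 & d$met_excised))
  expect_true(any(d$sequence == "DDDDDDR" & d$start_pos == 9 &
                    d$missed_cleavages == 0))
  expect_identical(digest_key(d), digest_key(oracle_digest("MAAAAAAKDDDDDDR")))

  expect_error(digest("ACDEFGHX"), "X")
})

test_that("digest equals the substring-enumeration oracle on random proteins", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(5:200, 1)
    seq <- random_protein(n)
    params <- list(
      list(7, 30, 1, TRUE),
      list(5, 20, 1, FALSE),
      list(7, 30, 0, TRUE)
    )[[sample(3, 1)]]
    d <- digest(seq, params[[1]], params[[2]], params[[3]], params[[4]])
    o <- oracle_digest(seq, params[[1]], params[[2]], params[[3]], params[[4]])
    expect_identical(digest_key(d), digest_key(o))
  }
})

test_that("match_peptides classifies simple, discarded and complex cases", {
  # the incretin-style S>G simple match
  ref <- "KALELASQANRK"  # fragment ALELASQANR at start 2
  pav <- list(variant_id = "v1", protein_pos = 7, ref_aa = "S", alt_aa = "G")
  alt <- inject_variant(ref, pav)
  mm <- match_peptides(digest(ref), digest(alt), pav)
  simple <- mm[mm$match_class == "simple", ]
  expect_true(any(simple$ref_sequence == "ALELASQANR" &
                    simple$alt_sequence == "ALELAGQANR"))
  expect_true(all(nchar(simple$ref_sequence) == nchar(simple$alt_sequence)))

  # K>R at a cleavage site: the cleavage pattern is preserved, C-terminal
  # residue differs, so the pair is simple (the F5 rs4524 pattern)
  ref <- "AAADDDKEEEFFFR"
  pav <- list(variant_id = "v2", protein_pos = 7, ref_aa = "K", alt_aa = "R")
  alt <- inject_variant(ref, pav)
  mm <- match_peptides(digest(ref), digest(alt), pav)
  expect_true(any(mm$match_class == "simple" &
                    mm$ref_sequence == "AAADDDK" &
                    mm$alt_sequence == "AAADDDR"))

  # N>K creating a new cleavage site: shortened alternate fragments are
  # discarded
  ref <- "AAADDDNEEEFFFR"
  pav <- list(variant_id = "v3", protein_pos = 7, ref_aa = "N", alt_aa = "K")
  alt <- inject_variant(ref, pav)
  mm <- match_peptides(digest(ref), digest(alt), pav)
  expect_true(all(mm$match_class[!is.na(mm$alt_sequence) &
                                   is.na(mm$ref_sequence)] == "discarded"))
  expect_false(any(mm$match_class == "simple"))

  # variant in an undetectable region: empty result with a warning
  ref <- "AAKCCKDDK"  # all fragments below length 7
  pav <- list(variant_id = "v4", protein_pos = 4, ref_aa = "C", alt_aa = "S")
  alt <- inject_variant(ref, pav)
  expect_warning(mm <- match_peptides(digest(ref), digest(alt), pav),
                 "not covered")
  expect_identical(nrow(mm), 0L)
})

test_that("build_libraries obeys the stated set algebra", {
  model <- tibble::tibble(
    protein_id = "P1",
    protein_seq = "MAAAAAAKALELASQANRCCCCCCKDDDDDDR"
  )
  # zero PAVs: all three libraries identical
  libs0 <- build_libraries(model, tibble::tibble(
    variant_id = character(), rsid = character(), protein_id = character(),
    protein_pos = integer(), ref_aa = character(), alt_aa = character(),
    maf = numeric()
  ))
  expect_identical(digest_key(libs0$reference),
                   digest_key(libs0$pav_inclusive))
  expect_identical(digest_key(libs0$reference),
                   digest_key(libs0$pav_exclusive))

  # one simple-match PAV: counts follow from the digestion oracle
  pav <- tibble::tibble(variant_id = "chr1:1:A:G", rsid = "rs1",
                        protein_id = "P1", protein_pos = 14L,
                        ref_aa = "S", alt_aa = "G", maf = 0.3)
  libs <- build_libraries(model, pav)
  ref_d <- oracle_digest(model$protein_seq)
  alt_d <- oracle_digest(inject_variant(model$protein_seq, pav))
  overlaps <- function(d) d$start_pos <= 14 & 14 <= d$start_pos +
    nchar(d$sequence) - 1
  n_ref_overlap <- sum(overlaps(ref_d))
  n_alt_overlap <- sum(overlaps(alt_d))
  expect_identical(nrow(libs$pav_inclusive),
                   nrow(libs$reference) + n_alt_overlap)
  expect_identical(nrow(libs$pav_exclusive),
                   nrow(libs$reference) - n_ref_overlap)
  expect_identical(libs$isoforms$name, "P1_rs1")
  expect_identical(libs$isoforms$sequence,
                   inject_variant(model$protein_seq, pav))

  # subset relations at the sequence level
  expect_true(all(libs$pav_exclusive$sequence %in% libs$reference$sequence))
  expect_true(all(libs$reference$sequence %in% libs$pav_inclusive$sequence))
  # no variant-overlapping peptide, of either origin, in the exclusive set
  expect_true(all(libs$pav_exclusive$origin == "invariant"))
  expect_false(any(overlaps(libs$pav_exclusive)))

  # simple pairs: equal length, equal start, >= 1 differing position
  simple <- libs$matches[libs$matches$match_class == "simple", ]
  expect_gt(nrow(simple), 0)
  expect_true(all(nchar(simple$ref_sequence) == nchar(simple$alt_sequence)))
  expect_true(all(simple$ref_sequence != simple$alt_sequence))
  # S>G does not touch K/R boundaries: exactly one differing position
  diffs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, simple$ref_sequence, simple$alt_sequence)
  expect_true(all(diffs == 1))
})

test_that("build_libraries treats variants independently", {
  model <- tibble::tibble(
    protein_id = "P1",
    protein_seq = "MAAAAAAKALELASQANRCCCCCCKDDDDDDR"
  )
  pavs <- tibble::tibble(
    variant_id = c("chr1:1:A:G", "chr1:2:C:T"),
    rsid = c("rs1", NA),
    protein_id = "P1",
    protein_pos = c(14L, 27L),
    ref_aa = c("S", "D"), alt_aa = c("G", "E"), maf = c(0.3, 0.2)
  )
  libs <- build_libraries(model, pavs)
  expect_identical(nrow(libs$isoforms), 2L)
  # missing rsid falls back to the chrom:pos:ref:alt identifier
  expect_setequal(libs$isoforms$name, c("P1_rs1", "P1_chr1:2:C:T"))
  # each isoform carries exactly one substitution
  n_diff <- vapply(libs$isoforms$sequence, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(model$protein_seq, "")[[1]])
  }, numeric(1))
  expect_true(all(n_diff == 1))

  expect_error(
    build_libraries(model, dplyr::mutate(pavs, variant_id = "dup")),
    "Duplicate variant_id"
  )
})

test_that("library set algebra holds on random simulated models", {
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, n_proteins = 3, n_pavs = 2,
                      n_samples = 10)
    gm <- simulate_gene_model(cfg)
    pavs <- simulate_pavs(cfg, gm)
    libs <- build_libraries(gm$model, pavs)
    expect_true(all(libs$pav_exclusive$sequence %in% libs$reference$sequence))
    expect_true(all(libs$reference$sequence %in% libs$pav_inclusive$sequence))
    expect_true(all(libs$pav_exclusive$origin == "invariant"))
    # exclusive library never overlaps a retained PAV position
    for (i in seq_len(nrow(pavs))) {
      excl <- libs$pav_exclusive[libs$pav_exclusive$protein_id ==
                                   pavs$protein_id[i], ]
      hit <- excl$start_pos <= pavs$protein_pos[i] &
        pavs$protein_pos[i] <= excl$start_pos + nchar(excl$sequence) - 1
      expect_false(any(hit))
    }
  }
})

test_that("write_library_set emits readable FASTA and TSV", {
  cfg <- sim_config(seed = 5, n_proteins = 2, n_pavs = 1, n_samples = 10)
  gm <- simulate_gene_model(cfg)
  pavs <- simulate_pavs(cfg, gm)
  libs <- build_libraries(gm$model, pavs)
  dir <- withr::local_tempdir()
  write_library_set(libs, gm$model, dir)
  fa <- Biostrings::readAAStringSet(file.path(dir, "pav_inclusive.fasta"))
  expect_identical(length(fa), nrow(gm$model) + nrow(libs$isoforms))
  tsv <- readr::read_tsv(file.path(dir, "reference_peptides.tsv"),
                         show_col_types = FALSE)
  expect_identical(nrow(tsv), nrow(libs$reference))
})
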