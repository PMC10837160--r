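test_that("translate_cds handles single codons, stop trimming and failures", {
  toy <- toy_entry("ATG")
  expect_identical(translate_cds(toy$entry, toy$genome)$protein, "M")

  toy <- toy_entry("ATGTAA")
  tr <- translate_cds(toy$entry, toy$genome)
  expect_identical(tr$protein, "M")
  expect_true(tr$valid)

  # internal stop invalidates
  toy <- toy_entry("ATGTAACCC", protein_seq = "MX")
  tr <- translate_cds(toy$entry, toy$genome)
  expect_false(tr$valid)
  expect_identical(tr$reason, "internal_stop_codon")

  # length not a multiple of three invalidates
  toy <- toy_entry("ATGA", protein_seq = "M")
  expect_false(translate_cds(toy$entry, toy$genome)$valid)

  # block out of genome bounds errors
  toy <- toy_entry("ATGTAA")
  bad <- toy$entry
  bad$blocks[[1]]$end <- 99L
  expect_error(translate_cds(bad, toy$genome), "bounds")
})

test_that("translate_cds splices minus-strand genes over two blocks", {
  # CDS ATGAAACGTTAA (M-K-R-stop); genomic minus-strand layout with an intron
  cds <- "ATGAAACGTTAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  # split revcomp into two exons with a 10 nt intron between
  exon1 <- substring(rc, 1, 5); exon2 <- substring(rc, 6, 12)
  genome <- c(chrT = paste0("AAA", exon1, "GGGGGGGGGG", exon2, "TT"))
  blocks <- tibble::tibble(start = c(3L, 18L), end = c(8L, 25L))
  blocks <- blocks[2:1, ]  # transcription order: descending on minus strand
  entry <- tibble::tibble(
    protein_id = "TOYM", chrom = "chrT", strand = "-",
    blocks = list(blocks), cds_length = 12L, protein_seq = "MKR",
    is_canonical = TRUE, bed_line = 1L
  )
  tr <- translate_cds(entry, genome)
  expect_true(tr$valid)
  expect_identical(tr$protein, "MKR")
  expect_identical(tr$cds, cds)
})

test_that("load_gene_model joins BED records with protein sequences", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">P1", "MKR", ">P2", "MAAAAAAK"), fa)

  # empty BED: zero entries, everything unmapped
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), bed)
  cand <- quiet(load_gene_model(bed, fa))
  expect_identical(nrow(cand), 0L)
  expect_setequal(attr(cand, "unmapped"), c("P1", "P2"))

  # a two-block plus-strand record: CDS length is the sum of block sizes
  writeLines("chrT\t10\t40\tP1\t0\t+\t10\t40\t0\t2\t6,9\t0,21", bed)
  cand <- quiet(load_gene_model(bed, fa))
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$cds_length, 15L)
  expect_identical(cand$blocks[[1]]$start, c(10L, 31L))
  expect_identical(cand$blocks[[1]]$end, c(16L, 40L))

  # BED name absent from FASTA: dropped with a warning
  writeLines("chrT\t10\t40\tNOPE\t0\t+\t10\t40\t0\t1\t30\t0", bed)
  expect_warning(load_gene_model(bed, fa), "no matching FASTA")

  # malformed line errors name the line number
  writeLines(c("chrT\t0\t9\tP1\t0\t+\t0\t9\t0\t1\t9\t0",
               "chrT\tbroken"), bed)
  expect_error(quiet(load_gene_model(bed, fa)), "line 2")

  # duplicate FASTA identifiers error
  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">P1", "MKR", ">P1", "MKR"), fa2)
  writeLines("chrT\t0\t9\tP1\t0\t+\t0\t9\t0\t1\t9\t0", bed)
  expect_error(load_gene_model(bed, fa2), "Duplicate FASTA")
})

test_that("resolve_ambiguous_mappings applies the selection cascade", {
  # single candidate is kept unchanged
  toy <- toy_entry("ATGAAACGTTAA")
  res <- quiet(resolve_ambiguous_mappings(toy$entry, toy$genome))
  expect_identical(nrow(res), 1L)
  expect_identical(res$protein_id, "TOY1")

  # two candidates, only one translation-exact: that one is kept
  good <- toy_entry("ATGAAACGTTAA")   # translates to MKR
  genome <- c(good$genome, chrB = "ATGGGGGGGTAA")  # translates to MGG
  cand <- dplyr::bind_rows(
    good$entry,
    dplyr::mutate(toy_entry("ATGGGGGGGTAA", chrom = "chrB",
                            protein_seq = "MKR")$entry, bed_line = 2L)
  )
  res <- quiet(resolve_ambiguous_mappings(cand, genome))
  expect_identical(res$chrom, "chrT")
  expect_true(res$translation_match)

  # two canonical candidates in one chromosome: first in BED order wins
  g2 <- c(chrT = paste0("ATGAAACGTTAA", "ATGAAACGTTAA"))
  c1 <- toy_entry("ATGAAACGTTAA")$entry
  c2 <- c1
  c2$blocks <- list(tibble::tibble(start = 12L, end = 24L))
  c2$bed_line <- 2L
  res <- quiet(resolve_ambiguous_mappings(dplyr::bind_rows(c1, c2), g2))
  expect_identical(nrow(res), 1L)
  expect_identical(res$bed_line, 1L)

  # across chromosomes with no exact translation: alphanumeric chromosome
  ca <- toy_entry("ATGAAAAAATAA", chrom = "chrA", protein_seq = "MQQ")$entry
  cb <- toy_entry("ATGAAAAAATAA", chrom = "chrB", protein_seq = "MQQ")$entry
  ca$is_canonical <- FALSE; cb$is_canonical <- FALSE; cb$bed_line <- 2L
  gAB <- c(chrA = "ATGAAAAAATAA", chrB = "ATGAAAAAATAA")
  res <- quiet(resolve_ambiguous_mappings(dplyr::bind_rows(cb, ca), gAB))
  expect_identical(res$chrom, "chrA")
})

test_that("map_variant_to_protein returns missense records only", {
  toy <- toy_entry("ATGAAACGTTAA")  # MKR + stop

  # codon-2 base 1 A>G: AAA -> GAA, K>E
  rec <- map_variant_to_protein(
    list(chrom = "chrT", pos = 4, ref = "A", alt = "G", maf = 0.2),
    toy$entry, toy$genome
  )
  expect_identical(rec$protein_pos, 2L)
  expect_identical(rec$ref_aa, "K")
  expect_identical(rec$alt_aa, "E")
  expect_identical(rec$variant_id, "chrT:4:A:G")

  # codon-2 base 3 A>G: AAA -> AAG, synonymous
  expect_null(map_variant_to_protein(
    list(chrom = "chrT", pos = 6, ref = "A", alt = "G"),
    toy$entry, toy$genome
  ))

  # outside all CDS blocks (trailing stop codon counts as non-coding output)
  expect_null(map_variant_to_protein(
    list(chrom = "chrT", pos = 11, ref = "A", alt = "C"),
    toy$entry, toy$genome
  ))

  # stop gain is excluded: codon-2 AAA -> TAA
  expect_null(map_variant_to_protein(
    list(chrom = "chrT", pos = 4, ref = "A", alt = "T"),
    toy$entry, toy$genome
  ))

  # genome/VCF reference mismatch warns and skips
  expect_warning(
    out <- map_variant_to_protein(
      list(chrom = "chrT", pos = 4, ref = "C", alt = "G"),
      toy$entry, toy$genome
    ),
    "does not match"
  )
  expect_null(out)
})

test_that("plus- and minus-strand encodings of one gene give identical PAVs", {
  cds <- "ATGAAACGTGATTTCTAA"  # M K R D F
  plus <- toy_entry(cds, chrom = "chrP", strand = "+")
  minus <- toy_entry(cds, chrom = "chrM", strand = "-")
  # variant at CDS offset 10 (codon 4, D>V: GAT -> GTT)
  offset <- 10L
  plus_rec <- map_variant_to_protein(
    list(chrom = "chrP", pos = offset + 1L, ref = "A", alt = "T"),
    plus$entry, plus$genome
  )
  n <- nchar(cds)
  minus_rec <- map_variant_to_protein(
    list(chrom = "chrM", pos = n - offset, ref = "T", alt = "A"),
    minus$entry, minus$genome
  )
  expect_identical(plus_rec$protein_pos, minus_rec$protein_pos)
  expect_identical(plus_rec$ref_aa, minus_rec$ref_aa)
  expect_identical(plus_rec$alt_aa, minus_rec$alt_aa)
  expect_identical(plus_rec$ref_aa, "D")
  expect_identical(plus_rec$alt_aa, "V")
})

test_that("simulated gene models round-trip through translation and mapping", {
  cfg <- sim_config(seed = 42, n_proteins = 6, n_pavs = 3)
  gm <- simulate_gene_model(cfg)
  expect_identical(nrow(gm$model), 6L)
  for (i in seq_len(nrow(gm$model))) {
    tr <- translate_cds(gm$model[i, ], gm$genome)
    expect_true(tr$valid)
    expect_identical(tr$protein, gm$model$protein_seq[i])
  }
  # every simulated PAV re-maps to the identical record
  pavs <- simulate_pavs(cfg, gm)
  for (i in seq_len(nrow(pavs))) {
    entry <- gm$model[gm$model$protein_id == pavs$protein_id[i], ]
    rec <- map_variant_to_protein(pavs[i, ], entry, gm$genome)
    expect_identical(rec$protein_pos, pavs$protein_pos[i])
    expect_identical(rec$ref_aa, pavs$ref_aa[i])
    expect_identical(rec$alt_aa, pavs$alt_aa[i])
    # idempotence: mapping twice gives the same record
    expect_identical(rec, map_variant_to_protein(pavs[i, ], entry, gm$genome))
  }
})

test_that("gene model files round-trip through load_gene_model and the VCF reader", {
  cfg <- sim_config(seed = 7, n_proteins = 4, n_pavs = 2, n_samples = 30)
  dir <- withr::local_tempdir()
  study <- quiet(simulate_study(cfg, out_dir = dir))

  cand <- quiet(load_gene_model(file.path(dir, "model.bed"),
                                file.path(dir, "proteins.fa")))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  model <- quiet(resolve_ambiguous_mappings(cand, genome))
  expect_identical(nrow(model), 4L)
  expect_true(all(model$translation_match))
  expect_true(all(model$is_canonical))

  vcf <- read_genotype_vcf(file.path(dir, "genotypes.vcf"))
  expect_setequal(vcf$variants$variant_id, study$pavs$variant_id)
  joined <- dplyr::inner_join(
    vcf$dosages, study$genotypes$dosages,
    by = c("sample", "variant_id"), suffix = c("_vcf", "_sim")
  )
  expect_identical(nrow(joined), nrow(study$genotypes$dosages))
  expect_true(all(joined$dosage_vcf == joined$dosage_sim))

  # and the PAVs can be re-derived from files alone
  remapped <- quiet(map_variants(vcf$variants, model, genome))
  expect_setequal(remapped$variant_id, study$pavs$variant_id)
})
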