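#' Read a BED12 gene-model track
#'
#' Parses a BED12 file describing the coding blocks of each protein. The
#' `name` field (column 4) is taken as the protein identifier. An optional
#' 13th column, when present, is interpreted as a canonical-isoform flag
#' (`1`/`true`/`canonical`, case-insensitive, mark an entry canonical);
#' without it all entries are treated as non-canonical.
#'
#' @param path Path to a BED12 (or BED12+1) file.
#' @return A tibble with one row per BED record: `bed_line`, `chrom`,
#'   `chrom_start`, `chrom_end`, `protein_id`, `strand`, `block_count`,
#'   `block_sizes`, `block_starts` (integer list-columns), `is_canonical`.
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble(
      bed_line = integer(), chrom = character(), chrom_start = integer(),
      chrom_end = integer(), protein_id = character(), strand = character(),
      block_count = integer(), block_sizes = list(), block_starts = list(),
      is_canonical = logical()
    ))
  }
  parse_line <- function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      abort(sprintf("Malformed BED line %d: expected >= 12 fields, found %d.",
                    i, length(f)))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    nblk <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
    starts <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
    if (anyNA(c(start, end, nblk)) || anyNA(sizes) || anyNA(starts)) {
      abort(sprintf("Malformed BED line %d: non-numeric coordinate field.", i))
    }
    if (!f[6] %in% c("+", "-")) {
      abort(sprintf("Malformed BED line %d: strand must be '+' or '-'.", i))
    }
    if (length(sizes) != nblk || length(starts) != nblk) {
      abort(sprintf(
        "Malformed BED line %d: blockCount %d does not match %d sizes / %d starts.",
        i, nblk, length(sizes), length(starts)
      ))
    }
    canonical <- FALSE
    if (length(f) >= 13) {
      canonical <- tolower(trimws(f[13])) %in% c("1", "true", "canonical", "yes")
    }
    tibble(
      bed_line = i, chrom = f[1], chrom_start = start, chrom_end = end,
      protein_id = f[4], strand = f[6], block_count = nblk,
      block_sizes = list(sizes), block_starts = list(starts),
      is_canonical = canonical
    )
  }
  list_rbind(map(seq_along(lines), parse_line))
}

blocks_from_bed <- function(chrom_start, block_sizes, block_starts, strand) {
  start <- chrom_start + block_starts
  blk <- tibble(start = start, end = start + block_sizes)
  if (strand == "-") blk <- blk[rev(seq_len(nrow(blk))), ]
  blk
}

#' Pair a BED12 gene model with a protein FASTA
#'
#' Joins BED records to protein sequences by identifier, producing candidate
#' gene-model entries. One protein id may have several candidate placements
#' (resolved later by [resolve_ambiguous_mappings()]). Coding blocks are
#' stored as 0-based half-open genomic intervals in transcription order
#' (descending genomic coordinates on the minus strand).
#'
#' @param bed_path Path to a BED12 file (see [read_bed12()]).
#' @param protein_fasta_path Path to a protein FASTA; identifiers must be
#'   unique.
#' @return A tibble of candidates: `protein_id`, `chrom`, `strand`, `blocks`
#'   (list-column of tibbles with `start`, `end`), `cds_length`,
#'   `protein_seq`, `is_canonical`, `bed_line`. Proteins present in the FASTA
#'   but absent from the BED are reported in the `unmapped` attribute (and a
#'   message); BED records whose id is missing from the FASTA are dropped
#'   with a warning.
#' @export
load_gene_model <- function(bed_path, protein_fasta_path) {
  bed <- read_bed12(bed_path)
  prot <- read_protein_fasta(protein_fasta_path)

  orphan_bed <- setdiff(bed$protein_id, prot$protein_id)
  if (length(orphan_bed) > 0) {
    warn(sprintf(
      "%d BED record(s) with no matching FASTA entry dropped: %s",
      length(orphan_bed), paste(head(orphan_bed, 5), collapse = ", ")
    ))
  }
  unmapped <- setdiff(prot$protein_id, bed$protein_id)
  if (length(unmapped) > 0) {
    inform(sprintf("%d protein(s) in the FASTA are unmapped in the BED.",
                   length(unmapped)))
  }

  cand <- bed |>
    inner_join(prot, by = "protein_id") |>
    mutate(
      blocks = pmap(
        list(.data$chrom_start, .data$block_sizes, .data$block_starts, .data$strand),
        blocks_from_bed
      ),
      cds_length = map_int(.data$block_sizes, sum)
    ) |>
    select("protein_id", "chrom", "strand", "blocks", "cds_length",
           "protein_seq", "is_canonical", "bed_line")
  attr(cand, "unmapped") <- unmapped
  cand
}

#' Translate the coding sequence of a gene-model entry
#'
#' Extracts the coding blocks from the genome (reverse-complementing on the
#' minus strand), concatenates them in transcription order, and translates
#' with the standard codon table. A single trailing stop codon is trimmed
#' silently; an internal stop, a CDS length that is not a multiple of three,
#' or blocks outside the genome invalidate the entry.
#'
#' @param entry A one-row gene-model tibble (or a list) with `chrom`,
#'   `strand` and `blocks`.
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @return A list with `protein` (amino-acid string or `NA`), `cds` (the
#'   spliced coding DNA), `valid` and `reason`.
#' @export
translate_cds <- function(entry, genome) {
  if (is.data.frame(entry)) {
    stopifnot(nrow(entry) == 1)
    entry <- as.list(entry)
    entry$blocks <- entry$blocks[[1]]
  }
  chrom_seq <- get_chrom_seq(genome, entry$chrom)
  blk <- entry$blocks
  if (any(blk$start < 0) || any(blk$end > nchar(chrom_seq)) ||
      any(blk$end <= blk$start)) {
    abort("Coding block out of genome bounds.")
  }
  pieces <- str_sub(chrom_seq, blk$start + 1L, blk$end)
  if (entry$strand == "-") {
    # blocks arrive in transcription order (descending); splice then revcomp
    cds <- revcomp_dna(paste(rev(pieces), collapse = ""))
  } else {
    cds <- paste(pieces, collapse = "")
  }
  fail <- function(reason) list(protein = NA_character_, cds = cds,
                                valid = FALSE, reason = reason)
  if (nchar(cds) %% 3 != 0) {
    return(fail("cds_length_not_multiple_of_3"))
  }
  aa <- translate_dna(cds)
  if (endsWith(aa, "*")) aa <- str_sub(aa, 1, nchar(aa) - 1)
  if (grepl("*", aa, fixed = TRUE)) {
    return(fail("internal_stop_codon"))
  }
  if (!nzchar(aa)) {
    return(fail("empty_translation"))
  }
  list(protein = aa, cds = cds, valid = TRUE, reason = NA_character_)
}

#' Resolve proteins that map to several gene-model placements
#'
#' Applies a deterministic selection cascade to candidate placements of each
#' protein id: (1) a unique candidate is kept as-is; (2) otherwise prefer
#' candidates whose translated CDS equals the FASTA sequence exactly;
#' (3) otherwise prefer candidates whose translation is in-frame and starts
#' with methionine; (4) if candidates remain on several chromosomes, prefer
#' canonical ones, then the alphanumerically first chromosome; (5) if several
#' remain on one chromosome, keep the first in BED order.
#'
#' @param candidates Candidate tibble from [load_gene_model()].
#' @param genome Genome sequences for translation checks.
#' @return A tibble with one row per retained protein id, plus columns
#'   `translation` and `translation_match`. Proteins with no usable candidate
#'   are reported in the `excluded` attribute with a reason.
#' @export
resolve_ambiguous_mappings <- function(candidates, genome) {
  excluded <- tibble(protein_id = character(), reason = character())
  pick <- function(df) {
    tr <- map(seq_len(nrow(df)), function(i) {
      res <- tryCatch(translate_cds(df[i, ], genome),
                      error = function(e) list(protein = NA_character_,
                                               valid = FALSE,
                                               reason = conditionMessage(e)))
      res
    })
    df$translation <- map_chr(tr, "protein")
    df$translation_valid <- map_lgl(tr, "valid")
    df$translation_match <- !is.na(df$translation) &
      df$translation == df$protein_seq
    if (nrow(df) == 1) return(df)
    exact <- df[df$translation_match, , drop = FALSE]
    if (nrow(exact) >= 1) {
      df <- exact
    } else {
      met <- df[df$translation_valid &
                  !is.na(df$translation) &
                  startsWith(df$translation, "M"), , drop = FALSE]
      if (nrow(met) >= 1) df <- met
    }
    if (nrow(df) > 1 && n_distinct(df$chrom) > 1) {
      if (any(df$is_canonical)) df <- df[df$is_canonical, , drop = FALSE]
      if (n_distinct(df$chrom) > 1) {
        df <- df[df$chrom == sort(unique(df$chrom))[1], , drop = FALSE]
      }
    }
    if (nrow(df) > 1) {
      df <- df[order(df$bed_line), , drop = FALSE][1, , drop = FALSE]
    }
    df
  }
  out <- list()
  for (pid in unique(candidates$protein_id)) {
    df <- candidates[candidates$protein_id == pid, , drop = FALSE]
    res <- tryCatch(pick(df), error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excluded <- bind_rows(excluded, tibble(protein_id = pid, reason = res))
    } else {
      out[[pid]] <- res
    }
  }
  model <- list_rbind(out)
  if (nrow(excluded) > 0) {
    inform(sprintf("%d protein(s) excluded during mapping resolution.",
                   nrow(excluded)))
  }
  attr(model, "excluded") <- excluded
  model
}

# Map a 0-based genomic position to its 0-based CDS offset, or NA when the
# position is outside all blocks. `blocks` are in transcription order.
genomic_to_cds_offset <- function(p0, blocks, strand) {
  offset <- 0L
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$start[i]; e <- blocks$end[i]
    if (p0 >= s && p0 < e) {
      within <- if (strand == "-") (e - 1L) - p0 else p0 - s
      return(offset + within)
    }
    offset <- offset + (e - s)
  }
  NA_integer_
}

# Inverse: 0-based CDS offset to 1-based genomic position.
cds_offset_to_genomic <- function(offset, blocks, strand) {
  for (i in seq_len(nrow(blocks))) {
    w <- blocks$end[i] - blocks$start[i]
    if (offset < w) {
      p0 <- if (strand == "-") (blocks$end[i] - 1L) - offset else blocks$start[i] + offset
      return(p0 + 1L)
    }
    offset <- offset - w
  }
  NA_integer_
}

#' Map a genomic SNV to its protein consequence
#'
#' Returns a PAV record when the substitution falls inside a coding block and
#' changes the encoded amino acid into a different amino acid (missense).
#' Synonymous changes, stop gains/losses, positions in the trailing stop
#' codon, and non-coding positions return `NULL`: only single amino-acid
#' substitutions feed the library builder. A genome/VCF reference mismatch
#' raises a warning and skips the variant.
#'
#' @param variant A list or one-row data frame with `chrom`, `pos` (1-based,
#'   VCF convention), `ref`, `alt` (single bases, plus-strand), and
#'   optionally `rsid` and `maf`.
#' @param entry A resolved one-row gene-model entry.
#' @param genome Genome sequences.
#' @return A one-row tibble (`variant_id`, `rsid`, `protein_id`,
#'   `protein_pos`, `ref_aa`, `alt_aa`, `maf`) or `NULL`.
#' @export
map_variant_to_protein <- function(variant, entry, genome) {
  if (is.data.frame(variant)) {
    stopifnot(nrow(variant) == 1)
    variant <- as.list(variant)
  }
  if (is.data.frame(entry)) {
    stopifnot(nrow(entry) == 1)
    entry <- as.list(entry)
    entry$blocks <- entry$blocks[[1]]
  }
  if (!identical(variant$chrom, entry$chrom)) return(NULL)
  if (nchar(variant$ref) != 1 || nchar(variant$alt) != 1) {
    abort("Only single-nucleotide substitutions are supported.")
  }
  p0 <- as.integer(variant$pos) - 1L
  offset <- genomic_to_cds_offset(p0, entry$blocks, entry$strand)
  if (is.na(offset)) return(NULL)

  chrom_seq <- get_chrom_seq(genome, entry$chrom)
  genome_base <- toupper(str_sub(chrom_seq, p0 + 1L, p0 + 1L))
  if (genome_base != toupper(variant$ref)) {
    warn(sprintf(
      "Variant %s:%s %s>%s: genome base '%s' does not match the VCF ref; skipped.",
      variant$chrom, variant$pos, variant$ref, variant$alt, genome_base
    ))
    return(NULL)
  }

  tr <- translate_cds(entry, genome)
  if (!tr$valid) return(NULL)
  ref_base_cds <- if (entry$strand == "-") complement_base(toupper(variant$ref)) else toupper(variant$ref)
  alt_base_cds <- if (entry$strand == "-") complement_base(toupper(variant$alt)) else toupper(variant$alt)

  codon_idx <- offset %/% 3L
  within <- offset %% 3L
  if (codon_idx + 1L > nchar(tr$protein)) return(NULL)  # trailing stop codon
  codon <- str_sub(tr$cds, 3L * codon_idx + 1L, 3L * codon_idx + 3L)
  stopifnot(str_sub(codon, within + 1L, within + 1L) == ref_base_cds)
  alt_codon <- codon
  str_sub(alt_codon, within + 1L, within + 1L) <- alt_base_cds

  ref_aa <- codon_to_aa(codon)
  alt_aa <- codon_to_aa(alt_codon)
  if (ref_aa == alt_aa || ref_aa == "*" || alt_aa == "*") return(NULL)

  protein_pos <- codon_idx + 1L
  model_aa <- str_sub(entry$protein_seq, protein_pos, protein_pos)
  if (model_aa != ref_aa) {
    warn(sprintf(
      "Variant %s:%s: translated residue '%s' disagrees with gene-model residue '%s'; skipped.",
      variant$chrom, variant$pos, ref_aa, model_aa
    ))
    return(NULL)
  }
  tibble(
    variant_id = sprintf("%s:%s:%s:%s", variant$chrom, variant$pos,
                         toupper(variant$ref), toupper(variant$alt)),
    rsid = (variant$rsid %||% NA_character_),
    protein_id = entry$protein_id,
    protein_pos = protein_pos,
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    maf = as.numeric(variant$maf %||% NA_real_)
  )
}

#' Map a table of genomic SNVs to PAV records across a gene model
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `rsid`, `maf`.
#' @param model Resolved gene model (one row per protein).
#' @param genome Genome sequences.
#' @return A tibble of PAV records (possibly zero rows).
#' @export
map_variants <- function(variants, model, genome) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    hits <- model[model$chrom == v$chrom, , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      rec <- map_variant_to_protein(v, hits[j, ], genome)
      if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      variant_id = character(), rsid = character(), protein_id = character(),
      protein_pos = integer(), ref_aa = character(), alt_aa = character(),
      maf = numeric()
    ))
  }
  list_rbind(rows)
}

#' Read genotype dosages and allele frequencies from a VCF
#'
#' Uses `VariantAnnotation` to parse the VCF and returns per-sample minor/
#' alternate allele dosages coded 0-1-2 (NA where the genotype is missing).
#'
#' @param path Path to an uncompressed or bgzipped VCF with GT genotypes.
#' @return A list with `variants` (tibble: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `rsid`, `af`) and `dosages` (long tibble: `sample`,
#'   `variant_id`, `dosage`).
#' @export
read_genotype_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
  rsid <- names(rr)
  info <- VariantAnnotation::info(vcf)
  af <- if ("AF" %in% names(info)) {
    vapply(info$AF, function(x) as.numeric(x)[1], numeric(1))
  } else {
    rep(NA_real_, length(rr))
  }
  variant_id <- sprintf("%s:%d:%s:%s", chrom, pos, ref, alt)
  gt <- VariantAnnotation::geno(vcf)$GT
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  dosages <- as_tibble(as.table(dose), .name_repair = "minimal")
  names(dosages) <- c("row", "sample", "dosage")
  dosages$variant_id <- variant_id[match(dosages$row, rownames(gt))]
  list(
    variants = tibble(variant_id = variant_id, chrom = chrom, pos = pos,
                      ref = ref, alt = alt, rsid = rsid, af = af),
    dosages = dosages |> select("sample", "variant_id", "dosage")
  )
}
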