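#' Filter PAV records by minor allele frequency
#'
#' Keeps protein-altering variants with MAF strictly greater than the
#' threshold (default 10%, the common-variant cutoff used for library
#' construction).
#'
#' @param pavs Tibble of PAV records with a `maf` column in `[0, 0.5]`.
#' @param threshold MAF threshold (strict `>`).
#' @return The filtered tibble.
#' @export
filter_pavs_by_maf <- function(pavs, threshold = 0.10) {
  if (any(is.na(pavs$maf)) || any(pavs$maf < 0) || any(pavs$maf > 0.5)) {
    abort("`maf` must lie in [0, 0.5] for every PAV.")
  }
  filter(pavs, .data$maf > threshold)
}

#' Inject a single amino-acid substitution into a protein sequence
#'
#' @param protein_seq Reference amino-acid string.
#' @param pav A PAV record (list or one-row tibble) with `protein_pos`,
#'   `ref_aa`, `alt_aa`.
#' @return The sequence with `alt_aa` at `protein_pos`; same length.
#' @export
inject_variant <- function(protein_seq, pav) {
  if (is.data.frame(pav)) pav <- as.list(pav[1, ])
  pos <- as.integer(pav$protein_pos)
  if (pos < 1 || pos > nchar(protein_seq)) {
    abort(sprintf("protein_pos %d outside sequence of length %d.",
                  pos, nchar(protein_seq)))
  }
  have <- str_sub(protein_seq, pos, pos)
  if (have != pav$ref_aa) {
    abort(sprintf(
      "Reference residue mismatch for %s at position %d of %s: expected '%s', found '%s'.",
      pav$variant_id %||% "variant", pos, pav$protein_id %||% "protein",
      pav$ref_aa, have
    ))
  }
  out <- protein_seq
  str_sub(out, pos, pos) <- pav$alt_aa
  out
}

#' In silico tryptic digestion
#'
#' Cleaves strictly after every K or R (no proline exception, mirroring
#' `--cut K*,R*` search settings), enumerates peptides with up to
#' `max_missed` missed cleavages, and applies the length filter afterwards.
#' With `met_excision`, peptides starting at position 1 of a protein whose
#' first residue is methionine are additionally emitted without the leading
#' M (subject to the same length filter), mirroring the `--met-excision`
#' flag.
#'
#' @param protein_seq Amino-acid string (standard residues only).
#' @param min_len,max_len Peptide length bounds (inclusive; defaults 7 and 30).
#' @param max_missed Maximum missed cleavages (default 1).
#' @param met_excision Emit N-terminal Met-excised forms (default TRUE).
#' @return Tibble with `sequence`, `start_pos` (1-based), `missed_cleavages`,
#'   `met_excised`.
#' @export
digest <- function(protein_seq, min_len = 7, max_len = 30, max_missed = 1,
                   met_excision = TRUE) {
  check_protein_seq(protein_seq)
  n <- nchar(protein_seq)
  res <- strsplit(protein_seq, "")[[1]]
  # fragment boundaries: 0, every position of K/R, and the protein end
  cuts <- which(res %in% c("K", "R"))
  bounds <- unique(c(0L, cuts, n))
  nb <- length(bounds)
  rows <- list()
  for (i in seq_len(nb - 1L)) {
    for (mc in 0:max_missed) {
      j <- i + 1L + mc
      if (j > nb) break
      start <- bounds[i] + 1L
      end <- bounds[j]
      rows[[length(rows) + 1L]] <- c(start, end, mc)
    }
  }
  m <- do.call(rbind, rows)
  pep <- tibble(
    sequence = str_sub(protein_seq, m[, 1], m[, 2]),
    start_pos = as.integer(m[, 1]),
    missed_cleavages = as.integer(m[, 3]),
    met_excised = FALSE
  )
  if (met_excision && res[1] == "M") {
    nterm <- pep |>
      filter(.data$start_pos == 1L, nchar(.data$sequence) >= 2L) |>
      mutate(
        sequence = str_sub(.data$sequence, 2L),
        start_pos = 2L,
        met_excised = TRUE
      )
    pep <- bind_rows(pep, nterm)
  }
  pep |>
    filter(nchar(.data$sequence) >= min_len, nchar(.data$sequence) <= max_len) |>
    arrange(.data$start_pos, .data$missed_cleavages, .data$met_excised)
}

peptide_overlaps <- function(digest_tbl, protein_pos) {
  digest_tbl$start_pos <= protein_pos &
    protein_pos <= digest_tbl$start_pos + nchar(digest_tbl$sequence) - 1L
}

#' Match reference and alternate digests around a variant position
#'
#' Pairs variant-overlapping peptides from the reference and injected
#' digests. A pair is `simple` when both peptides have equal length, equal
#' start position (within the same missed-cleavage and Met-excision stratum)
#' and differ in sequence. Unpaired alternate peptides caused by the gain or
#' loss of a K/R cleavage site are `discarded`; remaining unpaired
#' variant-overlapping peptides are `complex`. Peptides not overlapping the
#' variant are invariant and excluded from pairing.
#'
#' @param ref_digest,alt_digest Digest tibbles from [digest()] of the
#'   reference and injected sequence of the same protein.
#' @param pav The PAV record that was injected.
#' @return Tibble with `ref_sequence`, `alt_sequence`, `start_pos`,
#'   `missed_cleavages`, `met_excised`, `match_class`.
#' @export
match_peptides <- function(ref_digest, alt_digest, pav) {
  if (is.data.frame(pav)) pav <- as.list(pav[1, ])
  pos <- as.integer(pav$protein_pos)
  ref_ov <- ref_digest[peptide_overlaps(ref_digest, pos), , drop = FALSE]
  alt_ov <- alt_digest[peptide_overlaps(alt_digest, pos), , drop = FALSE]
  empty <- tibble(
    ref_sequence = character(), alt_sequence = character(),
    start_pos = integer(), missed_cleavages = integer(),
    met_excised = logical(), match_class = character()
  )
  if (nrow(ref_ov) == 0) {
    warn(sprintf("Variant %s at position %d is not covered by any reference peptide.",
                 pav$variant_id %||% "?", pos))
    return(empty)
  }
  key <- c("start_pos", "missed_cleavages", "met_excised")
  ref_ov <- mutate(ref_ov, len = nchar(.data$sequence)) |>
    rename(ref_sequence = "sequence")
  alt_ov <- mutate(alt_ov, len = nchar(.data$sequence)) |>
    rename(alt_sequence = "sequence")
  paired <- inner_join(ref_ov, alt_ov, by = c(key, "len")) |>
    filter(.data$ref_sequence != .data$alt_sequence) |>
    mutate(match_class = "simple")
  kr_change <- pav$ref_aa %in% c("K", "R") || pav$alt_aa %in% c("K", "R")
  alt_unpaired <- anti_join(alt_ov, paired, by = c(key, "len")) |>
    mutate(ref_sequence = NA_character_,
           match_class = if (kr_change) "discarded" else "complex")
  ref_unpaired <- anti_join(ref_ov, paired, by = c(key, "len")) |>
    mutate(alt_sequence = NA_character_, match_class = "complex")
  bind_rows(paired, alt_unpaired, ref_unpaired) |>
    select("ref_sequence", "alt_sequence", "start_pos", "missed_cleavages",
           "met_excised", "match_class") |>
    arrange(.data$start_pos, .data$missed_cleavages, .data$met_excised)
}

#' Build the reference, PAV-inclusive and PAV-exclusive peptide libraries
#'
#' Each MAF-filtered PAV is injected independently into the pure reference
#' background of its protein (one substitution per injected sequence). The
#' *reference* library is the tryptic digest of the reference proteome; the
#' *PAV-inclusive* library adds simple-match alternate peptides (and one
#' isoform protein entry per variant, named `protein-id_rsid`); the
#' *PAV-exclusive* library removes every variant-overlapping peptide,
#' alternate and reference alike.
#'
#' @param model Resolved gene model tibble (needs `protein_id`,
#'   `protein_seq`), or any tibble with those columns.
#' @param pavs Tibble of PAV records, already MAF-filtered and validated.
#' @param min_len,max_len,max_missed,met_excision Digestion parameters
#'   passed to [digest()].
#' @return An object of class `library_set`: a list with tibbles
#'   `reference`, `pav_inclusive`, `pav_exclusive` (columns `sequence`,
#'   `protein_id`, `start_pos`, `missed_cleavages`, `met_excised`, `origin`,
#'   `variant_id`, `match_class`), `isoforms` (`name`, `protein_id`,
#'   `variant_id`, `sequence`), `matches` (per-variant pairing table) and
#'   `params`.
#' @export
build_libraries <- function(model, pavs, min_len = 7, max_len = 30,
                            max_missed = 1, met_excision = TRUE) {
  if (anyDuplicated(pavs$variant_id)) {
    abort(sprintf("Duplicate variant_id: %s",
                  paste(unique(pavs$variant_id[duplicated(pavs$variant_id)]),
                        collapse = ", ")))
  }
  missing_prot <- setdiff(pavs$protein_id, model$protein_id)
  if (length(missing_prot) > 0) {
    abort(sprintf("PAVs reference proteins absent from the model: %s",
                  paste(missing_prot, collapse = ", ")))
  }
  dig <- function(seq) digest(seq, min_len, max_len, max_missed, met_excision)

  ref_digests <- setNames(map(model$protein_seq, dig), model$protein_id)
  reference <- imap(ref_digests, function(d, pid) mutate(d, protein_id = pid)) |>
    list_rbind() |>
    mutate(origin = "invariant", variant_id = NA_character_,
           match_class = "n/a")

  alt_rows <- list()
  ref_allele_rows <- list()
  match_rows <- list()
  isoforms <- list()
  seqs <- setNames(model$protein_seq, model$protein_id)

  for (i in seq_len(nrow(pavs))) {
    pav <- as.list(pavs[i, ])
    ref_seq <- seqs[[pav$protein_id]]
    alt_seq <- inject_variant(ref_seq, pav)
    alt_digest <- dig(alt_seq)
    mm <- suppressWarnings(match_peptides(ref_digests[[pav$protein_id]],
                                          alt_digest, pav))
    iso_tag <- if (!is.null(pav$rsid) && !is.na(pav$rsid) && nzchar(pav$rsid)) {
      pav$rsid
    } else {
      pav$variant_id
    }
    isoforms[[i]] <- tibble(
      name = paste0(pav$protein_id, "_", iso_tag),
      protein_id = pav$protein_id, variant_id = pav$variant_id,
      sequence = alt_seq
    )
    if (nrow(mm) > 0) {
      match_rows[[i]] <- mutate(mm, protein_id = pav$protein_id,
                                variant_id = pav$variant_id)
      simple <- filter(mm, .data$match_class == "simple")
      if (nrow(simple) > 0) {
        alt_rows[[i]] <- tibble(
          sequence = simple$alt_sequence,
          start_pos = simple$start_pos,
          missed_cleavages = simple$missed_cleavages,
          met_excised = simple$met_excised,
          protein_id = pav$protein_id,
          origin = "alt_allele", variant_id = pav$variant_id,
          match_class = "simple"
        )
      }
      ref_side <- filter(mm, !is.na(.data$ref_sequence))
      if (nrow(ref_side) > 0) {
        ref_allele_rows[[i]] <- tibble(
          sequence = ref_side$ref_sequence,
          start_pos = ref_side$start_pos,
          missed_cleavages = ref_side$missed_cleavages,
          met_excised = ref_side$met_excised,
          protein_id = pav$protein_id,
          origin = "ref_allele", variant_id = pav$variant_id,
          match_class = ref_side$match_class
        )
      }
    }
  }
  ref_allele <- list_rbind(ref_allele_rows)
  alt_allele <- list_rbind(alt_rows)

  # annotate reference rows that overlap a variant (one row per peptide/PAV)
  if (nrow(ref_allele) > 0) {
    annotated_reference <- bind_rows(
      anti_join(reference, ref_allele,
                by = c("sequence", "protein_id", "start_pos",
                       "missed_cleavages", "met_excised")),
      ref_allele
    )
  } else {
    annotated_reference <- reference
  }

  pav_inclusive <- bind_rows(annotated_reference, alt_allele)
  pav_exclusive <- annotated_reference |>
    filter(.data$origin == "invariant")

  structure(list(
    reference = arrange(annotated_reference, .data$protein_id, .data$start_pos,
                        .data$missed_cleavages),
    pav_inclusive = arrange(pav_inclusive, .data$protein_id, .data$start_pos,
                            .data$missed_cleavages),
    pav_exclusive = arrange(pav_exclusive, .data$protein_id, .data$start_pos,
                            .data$missed_cleavages),
    isoforms = list_rbind(isoforms),
    matches = list_rbind(match_rows),
    params = list(min_len = min_len, max_len = max_len,
                  max_missed = max_missed, met_excision = met_excision,
                  n_proteins = nrow(model), n_pavs = nrow(pavs))
  ), class = "library_set")
}

#' @export
print.library_set <- function(x, ...) {
  cat("<library_set>\n")
  cat(sprintf("  proteins: %d, PAVs: %d\n", x$params$n_proteins,
              x$params$n_pavs))
  cat(sprintf("  reference:     %6d peptide entries\n", nrow(x$reference)))
  cat(sprintf("  PAV-inclusive: %6d peptide entries (+%d isoform entries)\n",
              nrow(x$pav_inclusive), nrow(x$isoforms)))
  cat(sprintf("  PAV-exclusive: %6d peptide entries\n", nrow(x$pav_exclusive)))
  invisible(x)
}

#' Extract the peptide table of one library
#'
#' @param libraries A `library_set`.
#' @param which One of `"reference"`, `"pav_inclusive"`, `"pav_exclusive"`.
#' @return The peptide tibble.
#' @export
library_peptides <- function(libraries,
                             which = c("reference", "pav_inclusive",
                                       "pav_exclusive")) {
  stopifnot(inherits(libraries, "library_set"))
  which <- match.arg(which)
  libraries[[which]]
}

#' Write a library set to FASTA + TSV files
#'
#' Emits, per library, a peptide-level TSV and a FASTA of protein entries
#' (reference proteins, plus variant isoforms in the PAV-inclusive library).
#'
#' @param libraries A `library_set`.
#' @param model The gene model used to build it (for reference sequences).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_library_set <- function(libraries, model, dir) {
  stopifnot(inherits(libraries, "library_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (lib in c("reference", "pav_inclusive", "pav_exclusive")) {
    tsv <- file.path(dir, paste0(lib, "_peptides.tsv"))
    readr::write_tsv(libraries[[lib]], tsv)
    seqs <- setNames(model$protein_seq, model$protein_id)
    if (lib == "pav_inclusive" && nrow(libraries$isoforms) > 0) {
      seqs <- c(seqs, setNames(libraries$isoforms$sequence,
                               libraries$isoforms$name))
    }
    fa <- file.path(dir, paste0(lib, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fa)
    paths <- c(paths, tsv, fa)
  }
  invisible(paths)
}
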