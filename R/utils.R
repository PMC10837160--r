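# Internal sequence helpers. All protein positions are 1-based; BED blocks are
# 0-based half-open genomic intervals kept in transcription order.

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein_seq <- function(seq, arg = "protein_seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort(sprintf("`%s` must be a non-empty amino-acid string.", arg))
  }
  chars <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(chars, STANDARD_AA)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` contains non-standard residues: %s", arg,
      paste(bad, collapse = ", ")
    ))
  }
  invisible(seq)
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# Strict in-frame translation of a DNA string (standard code); returns the
# amino-acid string with "*" for stops. Length must be a multiple of 3.
translate_dna <- function(x) {
  stopifnot(nchar(x) %% 3 == 0)
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x),
    genetic.code = Biostrings::GENETIC_CODE, no.init.codon = TRUE
  ))
}

codon_to_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

# Normalize a genome to a named character vector of chromosome sequences.
genome_seqs <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(genome)
  }
  abort("`genome` must be a named character vector or a Biostrings::DNAStringSet.")
}

get_chrom_seq <- function(genome, chrom) {
  seqs <- genome_seqs(genome)
  if (!chrom %in% names(seqs)) {
    abort(sprintf("Chromosome '%s' not present in the genome.", chrom))
  }
  seqs[[chrom]]
}

# Read a FASTA of amino-acid sequences into a tibble(id, sequence); the id is
# the first whitespace-delimited token of the header.
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "Duplicate FASTA identifiers: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  tibble(protein_id = ids, protein_seq = as.character(aa))
}
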