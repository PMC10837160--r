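# Independent oracles used to pin expected values. These deliberately take a
# different computational route from the package implementation.

# Brute-force tryptic digestion: enumerate every substring of allowed length
# and keep those whose boundaries are valid cleavage boundaries with at most
# `max_missed` internal K/R. Met-excised forms are substrings that drop the
# leading M of a protein-start peptide and inherit its missed-cleavage count.
oracle_digest <- function(seq, min_len = 7, max_len = 30, max_missed = 1,
                          met_excision = TRUE) {
  n <- nchar(seq)
  res <- strsplit(seq, "")[[1]]
  is_kr <- res %in% c("K", "R")
  ckr <- c(0L, cumsum(is_kr))  # ckr[p + 1] = # of K/R in positions 1..p
  rows <- list()
  for (i in seq_len(n)) {
    start_ok <- i == 1L || is_kr[i - 1L]
    if (!start_ok) next
    for (j in i:n) {
      end_ok <- j == n || is_kr[j]
      if (!end_ok) next
      mc <- ckr[j] - ckr[i]  # internal K/R strictly before position j
      if (mc > max_missed) next
      len <- j - i + 1L
      if (len >= min_len && len <= max_len) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = substring(seq, i, j), start_pos = i,
          missed_cleavages = mc, met_excised = FALSE
        )
      }
      if (met_excision && i == 1L && res[1] == "M" && (len - 1L) >= min_len &&
          (len - 1L) <= max_len) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = substring(seq, 2L, j), start_pos = 2L,
          missed_cleavages = mc, met_excised = TRUE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sequence = character(), start_pos = integer(),
                      missed_cleavages = integer(), met_excised = logical())
  }
  unique(out[order(out$start_pos, out$missed_cleavages, out$met_excised), ])
}

digest_key <- function(d) {
  sort(paste(d$sequence, d$start_pos, d$missed_cleavages, d$met_excised,
             sep = "|"))
}

# Exhaustive hypergeometric enumeration for a 2x2 table with fixed margins,
# conditioning on the column margin and using log-binomial arithmetic.
oracle_fisher_p <- function(tbl) {
  a <- tbl[1, 1]
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ])
  c1 <- sum(tbl[, 1]); c2 <- sum(tbl[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  N <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  p_obs <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1)
  sum(exp(logp)[exp(logp) <= exp(p_obs) * (1 + 1e-7)])
}

random_protein <- function(n, aa = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# A one-gene toy model on a bare CDS laid end-to-end on one chromosome.
toy_entry <- function(cds, protein_id = "TOY1", chrom = "chrT",
                      strand = "+", protein_seq = NULL) {
  genome <- if (strand == "+") {
    stats::setNames(cds, chrom)
  } else {
    stats::setNames(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds))),
      chrom
    )
  }
  n <- nchar(cds)
  blocks <- tibble::tibble(start = 0L, end = n)
  if (is.null(protein_seq)) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             no.init.codon = TRUE))
    protein_seq <- sub("\\*$", "", aa)
  }
  list(
    entry = tibble::tibble(
      protein_id = protein_id, chrom = chrom, strand = strand,
      blocks = list(blocks), cds_length = n, protein_seq = protein_seq,
      is_canonical = TRUE, bed_line = 1L
    ),
    genome = genome
  )
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
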