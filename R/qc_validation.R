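#' Filter features by detection fraction
#'
#' Keeps feature groups whose detection fraction across samples is strictly
#' greater than `min_frac` (the conventional "> 20% of samples" filter uses
#' `min_frac = 0.2`). Detection is a strictly positive quantity, or the
#' `detected` column where present. The filter is idempotent.
#'
#' @param x Long tibble with a `sample` column, a `quantity` and/or
#'   `detected` column, and any number of feature columns.
#' @param min_frac Detection-fraction threshold in `[0, 1)`, strict `>`.
#' @param feature_cols Columns defining a feature; defaults to every column
#'   except `sample`, `quantity`, `detected`.
#' @param n_samples Denominator for the fraction; defaults to the number of
#'   distinct samples in `x`.
#' @return `x` restricted to rows of features passing the filter.
#' @export
filter_by_detection_fraction <- function(x, min_frac,
                                         feature_cols = NULL,
                                         n_samples = NULL) {
  if (min_frac < 0 || min_frac >= 1) abort("`min_frac` must lie in [0, 1).")
  x <- as_tibble(x)
  if (!"detected" %in% names(x)) {
    x$detected <- !is.na(x$quantity) & x$quantity > 0
  }
  feature_cols <- feature_cols %||%
    setdiff(names(x), c("sample", "quantity", "detected"))
  n_samples <- n_samples %||% n_distinct(x$sample)
  keep <- x |>
    group_by(across(all_of(feature_cols))) |>
    summarise(.frac = sum(.data$detected) / .env$n_samples, .groups = "drop") |>
    filter(.data$.frac > min_frac) |>
    select(-".frac")
  semi_join(x, keep, by = feature_cols)
}

#' Cross-nanoparticle peptide correlation QC
#'
#' Nanoparticle fractions act as internal technical replicates: a peptide
#' quantified in two or more fractions should correlate across samples.
#' Restricts to precursors of the given charge that pass the detection-
#' fraction filter, computes the Spearman correlation over shared detected
#' samples for every nanoparticle pair a peptide appears in, and summarises
#' the distribution.
#'
#' @param intensities Long tibble with `peptide_sequence` (or
#'   `stripped_sequence`), `nanoparticle`, `precursor_charge`, `sample`,
#'   `quantity`.
#' @param charge_filter Keep only precursors of this charge (default 2;
#'   `NULL` keeps all).
#' @param min_frac Detection-fraction filter per peptide x nanoparticle
#'   (default 0.2, strict `>`).
#' @param min_shared Minimum shared detected samples for a pair (default 3;
#'   pairs below are skipped).
#' @return Object of class `correlation_summary`: list with `per_pair`
#'   (tibble `peptide_sequence`, `np_a`, `np_b`, `n_shared`, `rho`),
#'   `counts` (peptides by number of fractions detected-in) and `summary`
#'   (median rho overall and for exactly-two-fraction peptides).
#' @export
cross_nanoparticle_correlation <- function(intensities, charge_filter = 2,
                                           min_frac = 0.2, min_shared = 3) {
  x <- as_tibble(intensities)
  if (!"peptide_sequence" %in% names(x) && "stripped_sequence" %in% names(x)) {
    x <- rename(x, peptide_sequence = "stripped_sequence")
  }
  if (!"quantity" %in% names(x) && "precursor_quantity" %in% names(x)) {
    x <- rename(x, quantity = "precursor_quantity")
  }
  if (n_distinct(x$nanoparticle) < 2) {
    abort("Need intensities from at least 2 nanoparticles.")
  }
  if (!is.null(charge_filter)) {
    x <- filter(x, .data$precursor_charge == charge_filter)
  }
  x <- filter(x, !is.na(.data$quantity), .data$quantity > 0)
  n_samples <- n_distinct(x$sample)
  x <- filter_by_detection_fraction(
    x, min_frac, feature_cols = c("peptide_sequence", "nanoparticle"),
    n_samples = n_samples
  )

  counts <- x |>
    distinct(.data$peptide_sequence, .data$nanoparticle) |>
    count(.data$peptide_sequence, name = "n_fractions") |>
    count(.data$n_fractions, name = "n_peptides")

  frac_of <- x |>
    distinct(.data$peptide_sequence, .data$nanoparticle) |>
    group_by(.data$peptide_sequence) |>
    summarise(n_fractions = n(), .groups = "drop")

  pairs <- list()
  multi <- frac_of$peptide_sequence[frac_of$n_fractions >= 2]
  xs <- x |> filter(.data$peptide_sequence %in% multi)
  for (pep in multi) {
    xp <- xs |> filter(.data$peptide_sequence == pep)
    nps <- sort(unique(xp$nanoparticle))
    for (i in seq_along(nps)) {
      for (j in seq_along(nps)) {
        if (j <= i) next
        a <- xp |> filter(.data$nanoparticle == nps[i])
        b <- xp |> filter(.data$nanoparticle == nps[j])
        shared <- inner_join(select(a, "sample", qa = "quantity"),
                             select(b, "sample", qb = "quantity"),
                             by = "sample")
        if (nrow(shared) < min_shared) next
        pairs[[length(pairs) + 1L]] <- tibble(
          peptide_sequence = pep, np_a = nps[i], np_b = nps[j],
          n_shared = nrow(shared),
          rho = suppressWarnings(cor(shared$qa, shared$qb,
                                     method = "spearman"))
        )
      }
    }
  }
  per_pair <- list_rbind(pairs)
  two_frac <- frac_of$peptide_sequence[frac_of$n_fractions == 2]
  summary <- tibble(
    n_peptides = nrow(frac_of),
    n_pairs = nrow(per_pair),
    median_rho = if (nrow(per_pair) > 0) median(per_pair$rho, na.rm = TRUE) else NA_real_,
    median_rho_two_fractions = {
      sub <- filter(per_pair, .data$peptide_sequence %in% two_frac)
      if (nrow(sub) > 0) median(sub$rho, na.rm = TRUE) else NA_real_
    }
  )
  structure(list(per_pair = per_pair, counts = counts, summary = summary),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat("<correlation_summary>\n")
  cat(sprintf("  %d peptide(s), %d nanoparticle pair(s), median rho = %.2f\n",
              x$summary$n_peptides, x$summary$n_pairs, x$summary$median_rho))
  invisible(x)
}

#' Flag suspect identifications by genotype discordance
#'
#' A variant whose reference- and alternate-allele peptides are both
#' detected in most samples *lacking* the corresponding allele is a likely
#' false-positive identification (two near-isobaric peptides confused by
#' the search, e.g. an E > D substitution). For each signal the detection
#' fraction among samples with zero copies of its allele is read off the
#' stored contingency table; a variant (within nanoparticle/charge strata
#' when present) is flagged when both alleles exceed the threshold.
#'
#' @param fisher_results Result tibble from [mspav_scan()] (needs
#'   `variant_id`, `allele`, `table_major`, `table_minor`).
#' @param threshold Discordant detection fraction above which an allele is
#'   suspect (default 0.9).
#' @return Tibble per variant (x strata) with per-allele discordant
#'   detection fractions and a `flagged` column.
#' @export
genotype_concordance_flags <- function(fisher_results, threshold = 0.9) {
  x <- as_tibble(fisher_results)
  # detection fraction among samples lacking the signal's allele: column
  # "absent" of the allele's own table
  disc <- function(tab) {
    absent <- tab[, "absent"]
    if (sum(absent) == 0) return(NA_real_)
    absent["detected"] / sum(absent)
  }
  x <- x |>
    mutate(discordant_frac = map_dbl(seq_len(n()), function(i) {
      tab <- if (x$allele[i] == "alt") x$table_minor[[i]] else x$table_major[[i]]
      disc(tab)
    }))
  strata <- intersect(names(x), c("nanoparticle", "precursor_charge",
                                  "missed_cleavages"))
  x |>
    group_by(across(all_of(c("variant_id", strata)))) |>
    summarise(
      ref_discordant_frac = suppressWarnings(max(
        .data$discordant_frac[.data$allele == "ref"], -Inf)),
      alt_discordant_frac = suppressWarnings(max(
        .data$discordant_frac[.data$allele == "alt"], -Inf)),
      .groups = "drop"
    ) |>
    mutate(
      ref_discordant_frac = if_else(is.finite(.data$ref_discordant_frac),
                                    .data$ref_discordant_frac, NA_real_),
      alt_discordant_frac = if_else(is.finite(.data$alt_discordant_frac),
                                    .data$alt_discordant_frac, NA_real_),
      flagged = !is.na(.data$ref_discordant_frac) &
        !is.na(.data$alt_discordant_frac) &
        .data$ref_discordant_frac > threshold &
        .data$alt_discordant_frac > threshold
    )
}

#' Write a QC report
#'
#' @param correlation A `correlation_summary`.
#' @param flags Flag table from [genotype_concordance_flags()] (optional).
#' @param dir Output directory.
#' @return Invisibly, the paths written (per-pair TSV + summary JSON).
#' @export
write_qc_report <- function(correlation, flags = NULL, dir) {
  stopifnot(inherits(correlation, "correlation_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "qc_peptide_correlations.tsv")
  readr::write_tsv(correlation$per_pair, tsv)
  paths <- tsv
  if (!is.null(flags)) {
    ftsv <- file.path(dir, "qc_concordance_flags.tsv")
    readr::write_tsv(flags, ftsv)
    paths <- c(paths, ftsv)
  }
  js <- file.path(dir, "qc_summary.json")
  jsonlite::write_json(
    list(summary = correlation$summary, counts = correlation$counts),
    js, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, js))
}
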