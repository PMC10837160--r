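#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' Exact hypergeometric p-value with fixed margins. For the two-sided test
#' the p-value sums the probabilities of all tables at most as probable as
#' the observed one, with the conventional `(1 + 1e-7)` tie tolerance (the
#' convention of R's `fisher.test`). A table with a zero margin is
#' degenerate and returns `p = 1`.
#'
#' @param tbl A 2x2 integer matrix of counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   referring to the count in cell `[1, 1]`.
#' @return The p-value.
#' @export
fisher_exact_p <- function(tbl, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(tbl), all(dim(tbl) == 2), all(tbl >= 0))
  a <- tbl[1, 1]
  k <- sum(tbl[1, ])           # row-1 margin (draws)
  white <- sum(tbl[, 1])       # column-1 margin
  black <- sum(tbl[, 2])
  if (k == 0 || sum(tbl[2, ]) == 0 || white == 0 || black == 0) {
    return(1)
  }
  lo <- max(0, k - black)
  hi <- min(k, white)
  xs <- lo:hi
  dens <- dhyper(xs, white, black, k)
  d0 <- dhyper(a, white, black, k)
  p <- switch(alternative,
    two.sided = sum(dens[dens <= d0 * (1 + 1e-7)]),
    greater = sum(dens[xs >= a]),
    less = sum(dens[xs <= a])
  )
  min(1, p)
}

is_degenerate_2x2 <- function(tbl) {
  any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)
}

#' Genotype-detection association for one variant-peptide signal
#'
#' Builds two 2x2 detection-by-carrier tables — one for presence of at least
#' one copy of the major allele (dosage <= 1) and one for presence of at
#' least one copy of the minor allele (dosage >= 1) — and tests each with
#' Fisher's exact test. Samples with missing genotype are excluded.
#' Degenerate tables (a zero margin) yield `p = 1` and are flagged.
#'
#' @param detections Logical vector: was the peptide detected in each sample.
#' @param genotypes Minor-allele dosage per sample, coded 0/1/2 (NA =
#'   missing), aligned with `detections`.
#' @param alternative Sidedness of the test (default two-sided).
#' @return One-row tibble: `n`, `n_detected`, `p_maj`, `p_min`, `p_best`,
#'   `allele_best`, `degenerate`, and list-columns `table_major`,
#'   `table_minor` (rows detected/not, columns allele present/absent).
#' @export
fisher_detection_test <- function(detections, genotypes,
                                  alternative = "two.sided") {
  stopifnot(length(detections) == length(genotypes))
  keep <- !is.na(genotypes)
  if (!any(keep)) abort("All genotypes are missing.")
  det <- as.logical(detections[keep])
  g <- genotypes[keep]
  if (!all(g %in% 0:2)) abort("Genotypes must be coded 0, 1, 2 or NA.")

  build <- function(present) {
    matrix(
      c(sum(det & present), sum(det & !present),
        sum(!det & present), sum(!det & !present)),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("detected", "not_detected"), c("present", "absent"))
    )
  }
  tab_maj <- build(g <= 1)  # carries >= 1 major-allele copy
  tab_min <- build(g >= 1)  # carries >= 1 minor-allele copy
  p_maj <- fisher_exact_p(tab_maj, alternative)
  p_min <- fisher_exact_p(tab_min, alternative)
  tibble(
    n = length(g),
    n_detected = sum(det),
    p_maj = p_maj,
    p_min = p_min,
    p_best = min(p_maj, p_min),
    allele_best = if (p_min <= p_maj) "minor" else "major",
    degenerate = is_degenerate_2x2(tab_maj) || is_degenerate_2x2(tab_min),
    table_major = list(tab_maj),
    table_minor = list(tab_min)
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_signals Number of tested signals (the Bonferroni family size).
#' @return `alpha / n_signals`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_signals) {
  if (!is.numeric(n_signals) || length(n_signals) != 1 || is.na(n_signals) ||
      n_signals < 1) {
    abort("`n_signals` must be a single integer >= 1.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  alpha / n_signals
}

#' Build detection and intensity matrices from a quantification report
#'
#' Maps report rows to library peptide annotations and enumerates detection
#' signals: one per unique (peptide sequence, variant, allele, nanoparticle,
#' precursor charge, missed cleavages) combination, restricted to peptides
#' of variant origin (`ref_allele` / `alt_allele`). A detection is a
#' strictly positive reported quantity. Duplicate (sample, precursor) rows
#' keep the maximum quantity with a warning; report peptides absent from the
#' library are counted and ignored.
#'
#' @param report Tibble of report rows with columns `sample` (run),
#'   `stripped_sequence`, `precursor_charge`, `precursor_quantity` and
#'   `nanoparticle`. DIA-NN-dialect column names (`Run`,
#'   `Stripped.Sequence`, `Precursor.Charge`, `Precursor.Quantity`) are
#'   accepted and renamed.
#' @param libraries A `library_set`; the PAV-inclusive annotation supplies
#'   origin and variant ids.
#' @return An object of class `detection_matrix`: list with `signals`
#'   (tibble of signal definitions, keyed `signal_id`), `detections` (long
#'   tibble `signal_id` x `sample` with `detected`, `quantity`), and
#'   `samples` (character vector of all report samples).
#' @export
detections_from_report <- function(report, libraries) {
  report <- normalize_report(report)
  samples <- sort(unique(report$sample))

  dup <- report |>
    count(.data$sample, .data$nanoparticle, .data$stripped_sequence,
          .data$precursor_charge) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(sprintf("%d duplicate (sample, precursor) row group(s): keeping the maximum quantity.",
                 nrow(dup)))
    report <- report |>
      group_by(.data$sample, .data$nanoparticle, .data$stripped_sequence,
               .data$precursor_charge) |>
      summarise(precursor_quantity = max(.data$precursor_quantity),
                .groups = "drop")
  }

  lib <- library_peptides(libraries, "pav_inclusive")
  known <- unique(lib$sequence)
  unknown <- setdiff(unique(report$stripped_sequence), known)
  if (length(unknown) > 0) {
    inform(sprintf("%d report peptide(s) absent from the library were ignored.",
                   length(unknown)))
  }

  ann <- lib |>
    filter(.data$origin %in% c("ref_allele", "alt_allele")) |>
    distinct(.data$sequence, .data$protein_id, .data$variant_id,
             .data$origin, .data$missed_cleavages) |>
    mutate(allele = if_else(.data$origin == "alt_allele", "alt", "ref")) |>
    rename(peptide_sequence = "sequence")

  hits <- report |>
    rename(peptide_sequence = "stripped_sequence") |>
    inner_join(ann, by = "peptide_sequence", relationship = "many-to-many")

  if (nrow(hits) == 0) {
    signals <- tibble(
      signal_id = integer(), peptide_sequence = character(),
      protein_id = character(), variant_id = character(),
      allele = character(), nanoparticle = character(),
      precursor_charge = integer(), missed_cleavages = integer()
    )
    return(structure(list(
      signals = signals,
      detections = tibble(signal_id = integer(), sample = character(),
                          quantity = numeric(), detected = logical()),
      samples = samples
    ), class = "detection_matrix"))
  }

  signals <- hits |>
    distinct(.data$peptide_sequence, .data$protein_id, .data$variant_id,
             .data$allele, .data$nanoparticle, .data$precursor_charge,
             .data$missed_cleavages) |>
    arrange(.data$variant_id, .data$peptide_sequence, .data$nanoparticle,
            .data$precursor_charge, .data$missed_cleavages) |>
    mutate(signal_id = row_number()) |>
    relocate("signal_id")

  detections <- hits |>
    inner_join(signals,
               by = c("peptide_sequence", "protein_id", "variant_id",
                      "allele", "nanoparticle", "precursor_charge",
                      "missed_cleavages")) |>
    group_by(.data$signal_id, .data$sample) |>
    summarise(quantity = max(.data$precursor_quantity), .groups = "drop") |>
    complete(signal_id = signals$signal_id, sample = samples,
             fill = list(quantity = 0)) |>
    mutate(detected = .data$quantity > 0)

  structure(list(signals = signals, detections = detections,
                 samples = samples),
            class = "detection_matrix")
}

normalize_report <- function(report) {
  report <- as_tibble(report)
  dia_map <- c(
    sample = "Run", protein_group = "Protein.Group",
    stripped_sequence = "Stripped.Sequence",
    precursor_charge = "Precursor.Charge",
    precursor_quantity = "Precursor.Quantity"
  )
  for (nm in names(dia_map)) {
    if (!nm %in% names(report) && dia_map[[nm]] %in% names(report)) {
      names(report)[names(report) == dia_map[[nm]]] <- nm
    }
  }
  if (!"nanoparticle" %in% names(report)) {
    report$nanoparticle <- "NP1"
  }
  need <- c("sample", "stripped_sequence", "precursor_charge",
            "precursor_quantity", "nanoparticle")
  miss <- setdiff(need, names(report))
  if (length(miss) > 0) {
    abort(sprintf("Report is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  report
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("<detection_matrix>\n")
  cat(sprintf("  %d signal(s) x %d sample(s)\n", nrow(x$signals),
              length(x$samples)))
  invisible(x)
}

#' Read a DIA-NN-dialect quantification report
#'
#' @param path Path to a TSV with columns `Run`, `Protein.Group`,
#'   `Stripped.Sequence`, `Precursor.Charge`, `Precursor.Quantity`.
#' @param nanoparticle Label of the nanoparticle fraction this report
#'   belongs to.
#' @return A normalized report tibble (see [detections_from_report()]).
#' @export
read_dia_report <- function(path, nanoparticle = "NP1") {
  report <- readr::read_tsv(path, show_col_types = FALSE)
  report$nanoparticle <- nanoparticle
  normalize_report(report)
}

#' Run the Fisher detection test over every signal of a detection matrix
#'
#' Joins each signal's detection vector with the genotypes of its variant
#' (samples without genotype are dropped per test) and applies
#' [fisher_detection_test()].
#'
#' @param detection_matrix A `detection_matrix`.
#' @param dosages Long tibble `sample`, `variant_id`, `dosage` (0/1/2, NA
#'   missing).
#' @param alternative Sidedness passed through.
#' @return Tibble of per-signal results (signal columns + Fisher columns).
#' @export
mspav_scan <- function(detection_matrix, dosages, alternative = "two.sided") {
  stopifnot(inherits(detection_matrix, "detection_matrix"))
  sig <- detection_matrix$signals
  det <- detection_matrix$detections
  rows <- map(seq_len(nrow(sig)), function(i) {
    s <- sig[i, ]
    d <- det |> filter(.data$signal_id == s$signal_id) |> arrange(.data$sample)
    g <- dosages |>
      filter(.data$variant_id == s$variant_id) |>
      select("sample", "dosage")
    dd <- inner_join(d, g, by = "sample")
    if (nrow(dd) == 0 || all(is.na(dd$dosage))) return(NULL)
    bind_cols(s, fisher_detection_test(dd$detected, dd$dosage, alternative))
  })
  list_rbind(keep(rows, ~ !is.null(.x)))
}

#' Call MS-PAVs from a family of Fisher results
#'
#' A signal is significant when its best allele p-value is strictly below
#' the Bonferroni threshold `alpha / n_signals`, the family size being the
#' number of tested signals. The summary de-duplicates significant signals
#' into unique peptides, variants and genes.
#'
#' @param results Tibble of per-signal Fisher results (needs `p_best`;
#'   `peptide_sequence`, `variant_id`, `protein_id` are used when present).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `calls` (input + `significant`), `threshold`, and
#'   `summary` (one-row tibble of de-duplicated counts).
#' @export
call_mspavs <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) {
    return(structure(list(
      calls = results,
      threshold = NA_real_,
      summary = tibble(n_signals = 0L, n_significant = 0L, n_peptides = 0L,
                       n_variants = 0L, n_genes = 0L)
    ), class = "mspav_calls"))
  }
  thr <- bonferroni_threshold(alpha, nrow(results))
  calls <- mutate(results, significant = .data$p_best < thr)
  sig <- filter(calls, .data$significant)
  cnt <- function(col) {
    if (col %in% names(sig)) n_distinct(sig[[col]]) else NA_integer_
  }
  structure(list(
    calls = calls,
    threshold = thr,
    summary = tibble(
      n_signals = nrow(calls),
      n_significant = nrow(sig),
      n_peptides = cnt("peptide_sequence"),
      n_variants = cnt("variant_id"),
      n_genes = cnt("protein_id")
    )
  ), class = "mspav_calls")
}

#' Peptide intensity versus genotype regression
#'
#' Ordinary least squares of peptide intensity on minor-allele dosage coded
#' 0-1-2, with missing intensities set to zero (the peptide-level "pX"
#' model; zero encodes non-detection).
#'
#' @param intensities Numeric vector of peptide intensities (NA = not
#'   detected, treated as 0).
#' @param genotypes Dosage vector 0/1/2 (NA = missing genotype; such samples
#'   are excluded).
#' @return One-row tibble with `beta`, `p_x`, `n`.
#' @export
peptide_intensity_genotype_lm <- function(intensities, genotypes) {
  stopifnot(length(intensities) == length(genotypes))
  keep <- !is.na(genotypes)
  y <- intensities[keep]
  g <- genotypes[keep]
  y[is.na(y)] <- 0
  if (length(y) < 3) abort("Need at least 3 samples with non-missing genotype.")
  if (var(g) == 0) abort("Genotype is constant; no association can be fit.")
  fit <- lm(y ~ g)
  sm <- summary(fit)$coefficients
  tibble(beta = sm["g", "Estimate"], p_x = sm["g", "Pr(>|t|)"],
         n = length(y))
}
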