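#' Roll peptide intensities up to protein level
#'
#' Aggregates detected peptide intensities into a per-protein trace, per
#' sample and nanoparticle, using only peptides that belong to the chosen
#' library. Two roll-ups are provided: `"median_log"` (default; median of
#' log2 intensities of the detected library peptides) and `"sum"` (sum of
#' raw intensities, missing peptides contributing nothing). The median is
#' robust to a dropped peptide; the sum is deliberately sensitive to one —
#' which is exactly the mechanism behind the epitope effect — so the epitope
#' demonstration uses `"sum"`.
#'
#' @param peptide_intensities Long tibble with `sample`, `nanoparticle`,
#'   `stripped_sequence` (or `sequence`), `precursor_quantity` (or
#'   `quantity`). Zero/NA quantities count as not detected.
#' @param library Peptide tibble defining membership (`sequence`,
#'   `protein_id`), e.g. from [library_peptides()], or a `library_set`
#'   (its reference table is used).
#' @param method `"median_log"` or `"sum"`.
#' @return Long tibble `protein_id`, `sample`, `nanoparticle`, `value`
#'   (log2 scale for `"median_log"`, raw for `"sum"`). Proteins without any
#'   library peptide in the data are absent and reported via a message.
#' @export
rollup_protein <- function(peptide_intensities, library,
                           method = c("median_log", "sum")) {
  method <- match.arg(method)
  if (inherits(library, "library_set")) library <- library$reference
  x <- as_tibble(peptide_intensities)
  if (!"stripped_sequence" %in% names(x) && "sequence" %in% names(x)) {
    x <- rename(x, stripped_sequence = "sequence")
  }
  if (!"precursor_quantity" %in% names(x) && "quantity" %in% names(x)) {
    x <- rename(x, precursor_quantity = "quantity")
  }
  if (!"nanoparticle" %in% names(x)) x$nanoparticle <- "NP1"
  members <- distinct(library, .data$sequence, .data$protein_id)
  absent <- setdiff(unique(members$protein_id),
                    members$protein_id[members$sequence %in% x$stripped_sequence])
  if (length(absent) > 0) {
    inform(sprintf("%d protein(s) have no library peptide in the data.",
                   length(absent)))
  }
  x |>
    filter(!is.na(.data$precursor_quantity), .data$precursor_quantity > 0) |>
    inner_join(members, by = c("stripped_sequence" = "sequence"),
               relationship = "many-to-many") |>
    group_by(.data$protein_id, .data$sample, .data$nanoparticle) |>
    summarise(
      value = if (.env$method == "median_log") {
        median(log2(.data$precursor_quantity))
      } else {
        sum(.data$precursor_quantity)
      },
      .groups = "drop"
    )
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles using average ranks for ties and the
#' Blom offset `(r - 3/8) / (n + 1/4)`. Missing values stay missing and do
#' not consume ranks.
#'
#' @param values Numeric vector with possible NAs.
#' @return Transformed vector of the same length.
#' @export
inverse_normal <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) abort("Need at least 3 non-missing values.")
  if (length(unique(values[ok])) == 1) {
    abort("All values identical; inverse-normal transform undefined.")
  }
  r <- rank(values, na.last = "keep", ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Covariate-adjusted protein-level genotype association (pQTL model)
#'
#' Regresses inverse-normalized protein intensities (missing values
#' excluded, transform applied within the analyzed complete cases) on
#' minor-allele copy number, adjusting for the supplied covariates
#' (age, sex, BMI, diabetes status and genotype principal components in the
#' standard setup).
#'
#' @param protein Numeric vector of protein intensities (NA = missing,
#'   excluded).
#' @param genotype Minor-allele dosage 0/1/2 per sample.
#' @param covariates Data frame of covariates aligned with `protein`; all
#'   columns enter the model. Complete cases are required.
#' @param variant_id,protein_group,library_tag Optional labels carried into
#'   the result.
#' @return An object of class `pqtl_fit`; see [tidy.pqtl_fit()].
#' @export
pqtl_lm <- function(protein, genotype, covariates, variant_id = NULL,
                    protein_group = NULL, library_tag = NULL) {
  covariates <- as_tibble(covariates)
  stopifnot(length(protein) == length(genotype),
            nrow(covariates) == length(protein))
  keep <- !is.na(protein) & !is.na(genotype) & complete.cases(covariates)
  n <- sum(keep)
  if (n < ncol(covariates) + 3) {
    abort(sprintf("Too few complete cases (%d) for %d covariates.",
                  n, ncol(covariates)))
  }
  g <- genotype[keep]
  if (var(g) == 0) abort("Genotype is constant; no association can be fit.")
  df <- bind_cols(
    tibble(.y = inverse_normal(protein[keep]), .g = g),
    covariates[keep, ]
  )
  fit <- lm(.y ~ ., data = df)
  if (anyNA(coef(fit))) {
    abort(sprintf("Rank-deficient design; collinear column(s): %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  structure(list(
    fit = fit,
    beta = sm[".g", "Estimate"],
    se = sm[".g", "Std. Error"],
    statistic = sm[".g", "t value"],
    p_y = sm[".g", "Pr(>|t|)"],
    n = n,
    variant_id = variant_id %||% NA_character_,
    protein_group = protein_group %||% NA_character_,
    library_tag = library_tag %||% NA_character_
  ), class = "pqtl_fit")
}

#' @export
print.pqtl_fit <- function(x, ...) {
  cat("<pqtl_fit>", x$variant_id, "~", x$protein_group,
      sprintf("[%s]", x$library_tag), "\n")
  cat(sprintf("  beta = %.4f (se %.4f), p = %.3g, n = %d\n",
              x$beta, x$se, x$p_y, x$n))
  invisible(x)
}

#' Tidy a pQTL fit into a one-row tibble
#'
#' @param x A `pqtl_fit`.
#' @param ... Unused.
#' @return Tibble with `variant_id`, `protein_group`, `library_tag`,
#'   `beta`, `se`, `statistic`, `p_y`, `n`.
#' @export
tidy.pqtl_fit <- function(x, ...) {
  tibble(
    variant_id = x$variant_id, protein_group = x$protein_group,
    library_tag = x$library_tag, beta = x$beta, se = x$se,
    statistic = x$statistic, p_y = x$p_y, n = x$n
  )
}

#' Model-level summary of a pQTL fit
#'
#' @param x A `pqtl_fit`.
#' @param ... Unused.
#' @return One-row tibble with `r.squared`, `adj.r.squared`, `sigma`,
#'   `df.residual`, `nobs`.
#' @export
glance.pqtl_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(
    r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma, df.residual = x$fit$df.residual,
    nobs = x$n
  )
}

#' Run the pQTL model for each PAV against its own protein
#'
#' Convenience driver: for each variant/protein pair in `pavs`, and each
#' nanoparticle in the quantification, fits [pqtl_lm()] of the protein trace
#' on the variant's dosage.
#'
#' @param quant Protein quantification (long tibble from
#'   [rollup_protein()]).
#' @param dosages Long tibble `sample`, `variant_id`, `dosage`.
#' @param covariates Tibble with a `sample` column plus covariate columns.
#' @param pavs Tibble with `variant_id`, `protein_id`.
#' @param library_tag Label stored in the results.
#' @return Tidied tibble (one row per variant x protein x nanoparticle),
#'   with a `nanoparticle` column.
#' @export
pqtl_scan <- function(quant, dosages, covariates, pavs,
                      library_tag = "reference") {
  stopifnot("sample" %in% names(covariates))
  cov_cols <- setdiff(names(covariates), "sample")
  rows <- list()
  pairs <- distinct(pavs, .data$variant_id, .data$protein_id)
  for (i in seq_len(nrow(pairs))) {
    v <- pairs$variant_id[i]; p <- pairs$protein_id[i]
    q <- filter(quant, .data$protein_id == p)
    for (np in unique(q$nanoparticle)) {
      dat <- covariates |>
        left_join(filter(q, .data$nanoparticle == np) |>
                    select("sample", "value"), by = "sample") |>
        inner_join(filter(dosages, .data$variant_id == v) |>
                     select("sample", "dosage"), by = "sample")
      res <- tryCatch(
        tidy(pqtl_lm(dat$value, dat$dosage, dat[cov_cols],
                     variant_id = v, protein_group = p,
                     library_tag = library_tag)),
        error = function(e) NULL
      )
      if (!is.null(res)) {
        res$nanoparticle <- np
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  list_rbind(rows)
}

#' Call MS-pQTLs at genome-wide significance
#'
#' @param results Tidied pQTL results (needs `p_y`).
#' @param threshold Significance threshold, strict `<` (default `5e-8`).
#' @return The rows of `results` with `p_y < threshold`.
#' @export
call_mspqtls <- function(results, threshold = 5e-8) {
  filter(results, .data$p_y < threshold)
}

#' Classify variants into the three pQTL regimens
#'
#' Compares the protein-level association computed with the reference
#' library against the one computed with the PAV-exclusive library:
#' significant in both = `robust_pqtl`; significant with the reference
#' library only = `epitope_effect` (the association is carried by the
#' genotype-dependently missing variant peptide, not by protein abundance);
#' significant in neither = `underpowered`. The unexpected configuration —
#' significant with the PAV-exclusive library only — is classified
#' `robust_pqtl` with `discordant = TRUE`.
#'
#' @param result_ref,result_excl Tidied pQTL result tibbles (columns
#'   `variant_id`, `protein_group`, `p_y`, plus `nanoparticle` if present)
#'   for the reference and PAV-exclusive libraries.
#' @param threshold Per-test significance threshold (strict `<`).
#' @return Tibble keyed like the inputs with `p_ref`, `p_excl`, `regimen`,
#'   `discordant`.
#' @export
classify_regimens <- function(result_ref, result_excl, threshold = 5e-8) {
  keys <- intersect(intersect(names(result_ref), names(result_excl)),
                    c("variant_id", "protein_group", "nanoparticle"))
  stopifnot(length(keys) > 0)
  inner_join(
    select(result_ref, all_of(keys), p_ref = "p_y"),
    select(result_excl, all_of(keys), p_excl = "p_y"),
    by = keys
  ) |>
    mutate(
      sig_ref = .data$p_ref < threshold,
      sig_excl = .data$p_excl < threshold,
      regimen = case_when(
        .data$sig_ref & .data$sig_excl ~ "robust_pqtl",
        .data$sig_ref & !.data$sig_excl ~ "epitope_effect",
        !.data$sig_ref & .data$sig_excl ~ "robust_pqtl",
        TRUE ~ "underpowered"
      ),
      discordant = !.data$sig_ref & .data$sig_excl
    ) |>
    select(-"sig_ref", -"sig_excl")
}

#' Proteome-wide association with non-genetic determinants
#'
#' Fits one joint linear model per protein: inverse-normalized intensities
#' against all supplied determinants (age, sex, BMI, diabetes status and
#' genotype principal components in the standard setup), and reports one
#' row per determinant.
#'
#' @param protein Numeric intensity vector (NA = missing, excluded).
#' @param covariates Data frame of determinants; all columns enter.
#' @return Tibble with `term`, `estimate`, `se`, `statistic`, `p`, `n`.
#' @export
pwas_lm <- function(protein, covariates) {
  covariates <- as_tibble(covariates)
  stopifnot(nrow(covariates) == length(protein))
  keep <- !is.na(protein) & complete.cases(covariates)
  n <- sum(keep)
  if (n < ncol(covariates) + 2) {
    abort(sprintf("Too few complete cases (%d) for %d determinants.",
                  n, ncol(covariates)))
  }
  df <- bind_cols(tibble(.y = inverse_normal(protein[keep])),
                  covariates[keep, ])
  fit <- lm(.y ~ ., data = df)
  if (anyNA(coef(fit))) {
    abort(sprintf("Rank-deficient design; collinear column(s): %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  tibble(
    term = terms,
    estimate = sm[terms, "Estimate"],
    se = sm[terms, "Std. Error"],
    statistic = sm[terms, "t value"],
    p = sm[terms, "Pr(>|t|)"],
    n = n
  )
}

#' PWAS over a protein quantification matrix
#'
#' Applies the detection-fraction filter (share of shared samples with a
#' quantified value strictly greater than `min_detect_frac`) per protein x
#' nanoparticle, then fits [pwas_lm()] for each retained combination.
#'
#' @param quant Long protein quantification tibble (`protein_id`, `sample`,
#'   `nanoparticle`, `value`).
#' @param covariates Tibble with `sample` plus determinant columns.
#' @param min_detect_frac Detection-fraction filter (default 0.80).
#' @return Tibble of per-determinant results with `protein_id`,
#'   `nanoparticle` columns.
#' @export
pwas_scan <- function(quant, covariates, min_detect_frac = 0.80) {
  stopifnot("sample" %in% names(covariates))
  cov_cols <- setdiff(names(covariates), "sample")
  shared <- covariates$sample
  rows <- list()
  combos <- distinct(quant, .data$protein_id, .data$nanoparticle)
  for (i in seq_len(nrow(combos))) {
    q <- quant |>
      filter(.data$protein_id == combos$protein_id[i],
             .data$nanoparticle == combos$nanoparticle[i])
    dat <- covariates |>
      left_join(select(q, "sample", "value"), by = "sample")
    if (mean(!is.na(dat$value)) <= min_detect_frac) next
    res <- tryCatch(pwas_lm(dat$value, dat[cov_cols]),
                    error = function(e) NULL)
    if (!is.null(res)) {
      res$protein_id <- combos$protein_id[i]
      res$nanoparticle <- combos$nanoparticle[i]
      rows[[length(rows) + 1L]] <- res
    }
  }
  list_rbind(rows)
}

#' Compare protein quantifications from two libraries
#'
#' Per protein and nanoparticle, Spearman correlation over
#' pairwise-complete samples between two quantifications (e.g. reference
#' vs PAV-exclusive), with summary fractions at the conventional
#' `rho > 0.8` (strong agreement) and `rho < 0.5` (substantial change)
#' cutoffs.
#'
#' @param quant_a,quant_b Long protein quantification tibbles.
#' @return List with `per_protein` (tibble `protein_id`, `nanoparticle`,
#'   `n_shared`, `rho`) and `summary` (one-row tibble with counts and
#'   fractions). Combinations with fewer than 3 shared observations are
#'   excluded from the summary denominator (rho = NA).
#' @export
compare_library_quants <- function(quant_a, quant_b) {
  joined <- inner_join(
    rename(quant_a, value_a = "value"),
    rename(quant_b, value_b = "value"),
    by = c("protein_id", "sample", "nanoparticle")
  )
  per <- joined |>
    group_by(.data$protein_id, .data$nanoparticle) |>
    summarise(
      n_shared = sum(!is.na(.data$value_a) & !is.na(.data$value_b)),
      rho = if (sum(!is.na(.data$value_a) & !is.na(.data$value_b)) >= 3) {
        suppressWarnings(cor(.data$value_a, .data$value_b,
                             method = "spearman", use = "pairwise"))
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  n_excluded <- sum(is.na(per$rho))
  if (n_excluded > 0) {
    warn(sprintf("%d protein/nanoparticle combination(s) with < 3 shared observations excluded.",
                 n_excluded))
  }
  ok <- filter(per, !is.na(.data$rho))
  summary <- tibble(
    n_compared = nrow(ok),
    n_excluded = n_excluded,
    n_rho_gt_0.8 = sum(ok$rho > 0.8),
    frac_rho_gt_0.8 = if (nrow(ok) > 0) mean(ok$rho > 0.8) else NA_real_,
    n_rho_lt_0.5 = sum(ok$rho < 0.5),
    frac_rho_lt_0.5 = if (nrow(ok) > 0) mean(ok$rho < 0.5) else NA_real_
  )
  list(per_protein = per, summary = summary)
}
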