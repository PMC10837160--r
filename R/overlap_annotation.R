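#' Wrap external pQTL summary statistics
#'
#' @param associations Tibble with `variant_id`, `target_id`, `p` — one row
#'   per reported variant-target association on an external (typically
#'   affinity-based) platform.
#' @param platform Platform label.
#' @param n_assayed_proteins Number of proteins assayed on the platform;
#'   defaults to the number of distinct targets in `associations`.
#' @param assayed_targets Character vector of all assayed target ids;
#'   defaults to the distinct targets in `associations`.
#' @return Object of class `external_summary`.
#' @export
external_summary <- function(associations, platform,
                             n_assayed_proteins = NULL,
                             assayed_targets = NULL) {
  associations <- as_tibble(associations)
  need <- c("variant_id", "target_id", "p")
  miss <- setdiff(need, names(associations))
  if (length(miss) > 0) {
    abort(sprintf("`associations` missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (any(associations$p <= 0 | associations$p > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].")
  }
  assayed_targets <- assayed_targets %||% unique(associations$target_id)
  n_assayed_proteins <- n_assayed_proteins %||% length(assayed_targets)
  if (n_assayed_proteins < n_distinct(associations$target_id)) {
    abort("`n_assayed_proteins` is smaller than the number of distinct targets.")
  }
  structure(list(associations = associations, platform = platform,
                 n_assayed_proteins = n_assayed_proteins,
                 assayed_targets = assayed_targets),
            class = "external_summary")
}

#' Classify MS-PAVs against an external pQTL platform
#'
#' For each MS-PAV, looks up its associations in the external summary
#' statistics and assigns: `cis` when the variant's own protein was assayed
#' and shows `p < alpha / n_variants`; otherwise `trans_only` when any
#' other target shows `p < alpha / n_variants / n_assayed_proteins`;
#' otherwise `not_assayed` when the own protein is absent from the
#' platform; otherwise `none`. Variants absent from the table altogether
#' contribute no association rows (classed `none` or `not_assayed` by assay
#' status) and are counted in a message.
#'
#' @param mspavs Tibble with `variant_id` and the own-target key column.
#' @param external An [external_summary()].
#' @param n_variants Bonferroni family for the cis test; defaults to the
#'   number of distinct MS-PAV variants queried.
#' @param alpha Base significance level (default 0.05).
#' @param key Column of `mspavs` naming the variant's own target (default
#'   `"protein_id"`).
#' @return List with `classes` (tibble `variant_id`, `own_target`,
#'   `assayed`, `own_p`, `best_trans_p`, `class`, `platform`) and `summary`
#'   (Table-2-style one-row count tibble).
#' @export
classify_overlap <- function(mspavs, external, n_variants = NULL,
                             alpha = 0.05, key = "protein_id") {
  stopifnot(inherits(external, "external_summary"))
  mspavs <- distinct(as_tibble(mspavs), .data$variant_id,
                     own_target = .data[[key]])
  n_variants <- n_variants %||% n_distinct(mspavs$variant_id)
  cis_thr <- alpha / n_variants
  trans_thr <- alpha / n_variants / external$n_assayed_proteins

  assoc <- external$associations
  absent <- setdiff(mspavs$variant_id, assoc$variant_id)
  if (length(absent) > 0) {
    inform(sprintf("%d variant(s) missing from the %s summary statistics.",
                   length(absent), external$platform))
  }

  classes <- mspavs |>
    mutate(
      assayed = .data$own_target %in% external$assayed_targets,
      own_p = map_dbl(seq_len(n()), function(i) {
        hit <- assoc$p[assoc$variant_id == mspavs$variant_id[i] &
                         assoc$target_id == mspavs$own_target[i]]
        if (length(hit) == 0) NA_real_ else min(hit)
      }),
      best_trans_p = map_dbl(seq_len(n()), function(i) {
        hit <- assoc$p[assoc$variant_id == mspavs$variant_id[i] &
                         assoc$target_id != mspavs$own_target[i]]
        if (length(hit) == 0) NA_real_ else min(hit)
      }),
      class = case_when(
        .data$assayed & !is.na(.data$own_p) & .data$own_p < cis_thr ~ "cis",
        !is.na(.data$best_trans_p) & .data$best_trans_p < trans_thr ~ "trans_only",
        !.data$assayed ~ "not_assayed",
        TRUE ~ "none"
      ),
      platform = external$platform
    )

  summary <- tibble(
    platform = external$platform,
    n_variants = nrow(classes),
    n_assayed = sum(classes$assayed),
    n_not_assayed = sum(!classes$assayed),
    n_cis = sum(classes$class == "cis"),
    n_trans_not_cis = sum(classes$class == "trans_only"),
    n_any_overlap = sum(classes$class %in% c("cis", "trans_only")),
    n_no_overlap = sum(!classes$class %in% c("cis", "trans_only")),
    cis_threshold = cis_thr,
    trans_threshold = trans_thr
  )
  list(classes = classes, summary = summary)
}

#' Aggregate per-platform overlap classes across platforms
#'
#' @param class_tables List of `classes` tibbles from [classify_overlap()].
#' @return Tibble `variant_id`, `aggregate_class` with precedence
#'   cis > trans_only > none > not_assayed.
#' @export
aggregate_overlap <- function(class_tables) {
  all_classes <- list_rbind(class_tables)
  rank <- c(cis = 1, trans_only = 2, none = 3, not_assayed = 4)
  all_classes |>
    group_by(.data$variant_id) |>
    summarise(
      aggregate_class = names(rank)[min(rank[.data$class])],
      .groups = "drop"
    )
}
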