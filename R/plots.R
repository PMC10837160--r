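#' Boxplot of intensities by genotype
#'
#' The standard per-variant diagnostic: protein or peptide intensity
#' stratified by genotype (0/1/2 copies of the minor allele), one panel
#' per nanoparticle.
#'
#' @param values Long tibble with `sample`, `value` and optionally
#'   `nanoparticle`.
#' @param dosages Long tibble `sample`, `variant_id`, `dosage`.
#' @param variant_id Variant to stratify by.
#' @param log2 Plot values on log2 scale (default FALSE; roll-ups from
#'   `median_log` are already log2).
#' @return A ggplot object.
#' @export
plot_genotype_intensity <- function(values, dosages, variant_id,
                                    log2 = FALSE) {
  dat <- values |>
    inner_join(
      dosages |>
        filter(.data$variant_id == .env$variant_id) |>
        select("sample", "dosage"),
      by = "sample"
    ) |>
    filter(!is.na(.data$dosage), !is.na(.data$value)) |>
    mutate(
      genotype = factor(.data$dosage, levels = 0:2,
                        labels = c("ref hom", "het", "alt hom")),
      value = if (log2) base::log2(.data$value) else .data$value
    )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$genotype,
                                         y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = sprintf("genotype at %s", variant_id),
                  y = "intensity", title = variant_id) +
    ggplot2::theme_minimal()
  if ("nanoparticle" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(~nanoparticle)
  }
  p
}

#' Volcano-style overview of MS-PAV calls
#'
#' Plots each signal's detection count against the -log10 of its best
#' Fisher p-value, with the Bonferroni threshold drawn.
#'
#' @param object Result of [call_mspavs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mspav_calls <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$n_detected,
                               y = -log10(.data$p_best),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "detections", y = expression(-log[10](p)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Bar chart of pQTL regimen classifications
#'
#' @param regimens Tibble from [classify_regimens()].
#' @return A ggplot object.
#' @export
plot_regimen_counts <- function(regimens) {
  ggplot2::ggplot(regimens, ggplot2::aes(x = .data$regimen)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "variants") +
    ggplot2::theme_minimal()
}
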