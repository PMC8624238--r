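#' Ratio chart of MLPA dosage quotients
#'
#' The classic MLPA ratio chart: one point per target probe in exon order,
#' horizontal reference lines at the deletion and duplication thresholds.
#' Points falling below the lower line indicate deleted probes, points
#' above the upper line duplicated probes; probes between the lines are
#' consistent with two copies.
#'
#' @param dq Dosage-quotient table from [normalize_run()].
#' @param samples Optional character vector restricting which samples are
#'   shown (default: all test samples).
#' @param config Configuration (threshold lines).
#' @return A ggplot object, faceted by sample.
#' @export
plot_mlpa_ratios <- function(dq, samples = NULL,
                             config = fh_default_config()) {
  d <- as_tibble(dq)
  if (is.null(samples)) {
    samples <- unique(d$sample_id[d$role == "test"])
  }
  d <- filter(d, .data$sample_id %in% samples) |>
    mutate(
      target = factor(.data$target, levels = unique(.data$target)),
      state = dplyr::case_when(
        .data$dq < config$mlpa$del_threshold ~ "deletion",
        .data$dq > config$mlpa$dup_threshold ~ "duplication",
        .default = "normal"
      )
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$target, y = .data$dq,
                                  colour = .data$state)) +
    ggplot2::geom_hline(yintercept = config$mlpa$del_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_hline(yintercept = config$mlpa$dup_threshold,
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(
      deletion = "firebrick", duplication = "steelblue", normal = "grey30"
    )) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = "probe target", y = "dosage quotient",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname plot_mlpa_ratios
#' @param object A dosage-quotient table.
#' @param ... Passed to [plot_mlpa_ratios()].
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fh_mlpa_dq <- function(object, ...) {
  plot_mlpa_ratios(object, ...)
}

#' Detection-yield bar chart for a cohort summary
#'
#' Shows the per-gene-group split (LDLR / APOB / other) among
#' variant-positive probands as percentages.
#'
#' @param object An `fh_cohort_summary`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fh_cohort_summary <- function(object, ...) {
  d <- object$by_gene_group
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_group, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)",
                                                    .data$n, .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = NULL, y = "% of variant-positive probands",
      title = sprintf("Molecular yield: %d/%d subjects positive (%.1f%%)",
                      object$n_variant_positive, object$n_subjects,
                      object$subject_yield_percent)
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of DLCN bands
#'
#' @param scores Output of [score_dlcn()].
#' @return A ggplot bar chart of band counts.
#' @export
plot_dlcn_bands <- function(scores) {
  d <- count(as_tibble(scores),
             band = factor(.data$band, levels = c("unlikely", "possible",
                                                  "probable", "definite")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$band, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "DLCN band", y = "subjects") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
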