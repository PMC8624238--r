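# broom-style accessors for the package's result objects

#' Tidy a filter report
#'
#' @param x An `fh_filter_report`.
#' @param ... Ignored.
#' @return The per-record audit trail: `variant_id`, `removed_at` (`NA`
#'   for survivors) and `consensus`.
#' @export
#' @exportS3Method generics::tidy
tidy.fh_filter_report <- function(x, ...) {
  x$audit
}

#' @rdname tidy.fh_filter_report
#' @return For `glance()`: a one-row tibble of step counts.
#' @export
#' @exportS3Method generics::glance
glance.fh_filter_report <- function(x, ...) {
  tibble(
    input_count = x$input_count,
    removed_rarity = x$steps$n_removed[x$steps$step == "rarity"],
    removed_assertion = x$steps$n_removed[x$steps$step == "assertion"],
    surviving = nrow(x$surviving)
  )
}

#' Tidy a cohort summary
#'
#' @param x An `fh_cohort_summary`.
#' @param ... Ignored.
#' @return A long tibble with one row per reported count: `group`,
#'   `metric`, `n`, `denominator`, `percent`.
#' @export
#' @exportS3Method generics::tidy
tidy.fh_cohort_summary <- function(x, ...) {
  bind_rows(
    tibble(group = "cohort", metric = "variant_positive",
           n = x$n_variant_positive, denominator = x$n_subjects,
           percent = x$subject_yield_percent),
    tibble(group = "positive_probands",
           metric = x$by_gene_group$gene_group,
           n = x$by_gene_group$n, denominator = x$n_positive_probands,
           percent = x$by_gene_group$percent),
    tibble(group = "children", metric = "variant_positive",
           n = x$children$n_positive, denominator = x$children$n,
           percent = x$children$percent)
  )
}

#' @rdname tidy.fh_cohort_summary
#' @return For `glance()`: a one-row headline tibble.
#' @export
#' @exportS3Method generics::glance
glance.fh_cohort_summary <- function(x, ...) {
  grp <- function(g) {
    i <- match(g, x$by_gene_group$gene_group)
    if (is.na(i)) NA_real_ else x$by_gene_group$percent[i]
  }
  tibble(
    n_subjects = x$n_subjects,
    n_probands = x$n_probands,
    n_variant_positive = x$n_variant_positive,
    subject_yield_percent = x$subject_yield_percent,
    ldlr_percent = grp("LDLR"),
    apob_percent = grp("APOB"),
    other_percent = grp("other"),
    children_percent = x$children$percent
  )
}

#' Summaries of a cascade plan
#'
#' @param x An `fh_cascade_plan`.
#' @param ... Ignored.
#' @return For `glance()`: one row with the proband, number of waves and
#'   number of proposed individuals.
#' @export
#' @exportS3Method generics::glance
glance.fh_cascade_plan <- function(x, ...) {
  tibble(
    proband_id = attr(x, "proband_id"),
    n_waves = if (nrow(x)) max(x$wave) else 0L,
    n_proposed = nrow(x)
  )
}
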