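# Annotated variant tables are plain tibbles, one row per (variant, alt
# allele). Recognized columns:
#   variant_id chrom pos ref alt gene hgvs_c hgvs_p zygosity clinvar hgmd_id
#   af_<source>   allele frequency in [0,1]; NA = not observed in that source
#   pred_<tool>   "damaging" / "tolerated" / "unknown"
#   cons_<tool>   numeric conservation score
#   null_variant  logical: protein-null allele (nonsense, frameshift,
#                 canonical +/-1,2 splice) -- consumed by auto_evidence()

af_cols   <- function(x) grep("^af_",   names(x), value = TRUE)
pred_cols <- function(x) grep("^pred_", names(x), value = TRUE)
cons_cols <- function(x) grep("^cons_", names(x), value = TRUE)

# max frequency across sources; absent everywhere (all NA) counts as 0,
# i.e. an unobserved allele is treated as novel and passes the rarity step
max_af <- function(records) {
  cols <- af_cols(records)
  if (!length(cols) || !nrow(records)) return(rep(0, nrow(records)))
  m <- as.matrix(records[cols])
  apply(m, 1, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
}

#' Conservation percentile of a score within a reference distribution
#'
#' Fraction of reference scores strictly below `score`, with ties counting
#' one half (midrank). A variant is called conserved when its percentile
#' reaches the configured threshold (default 0.7), i.e. its score is greater
#' than those of at least 70% of the reference variants.
#'
#' @param score Numeric score(s) to place.
#' @param reference_scores Non-empty numeric vector of scores from the
#'   reference variant set (`NA`s dropped).
#' @return Percentile(s) in \[0, 1\].
#' @export
#' @examples
#' conservation_percentile(0.9, seq(0.1, 0.8, by = 0.1))
conservation_percentile <- function(score, reference_scores) {
  reference_scores <- reference_scores[!is.na(reference_scores)]
  if (!length(reference_scores)) {
    abort("conservation reference set is empty")
  }
  vapply(score, function(s) {
    if (is.na(s)) return(NA_real_)
    (sum(reference_scores < s) + 0.5 * sum(reference_scores == s)) /
      length(reference_scores)
  }, numeric(1))
}

#' In-silico predictor consensus for annotated variants
#'
#' Summarizes the per-tool pathogenicity calls (`pred_*` columns) and
#' conservation scores (`cons_*` columns) of each record into one of
#' `"damaging"`, `"benign_leaning"` or `"indeterminate"`. A record is
#' damaging when the fraction of damaging calls among tools that reported
#' (non-unknown) reaches `predictor_damaging_fraction` AND at least one
#' conservation tool places it at or above the conservation percentile
#' threshold within the reference set; benign-leaning when the damaging
#' fraction is at most one minus that fraction; otherwise (including no
#' reporting tool at all) indeterminate. Consensus is a tag only -- the
#' filter cascade never removes a record because of it.
#'
#' @param records Annotated variant tibble.
#' @param config Filter configuration (`fh_default_config()$filter`).
#' @param conservation_reference Tibble supplying the reference
#'   distribution of each `cons_*` tool; defaults to `records` itself
#'   (panel-wide reference).
#' @return Character vector, one element per record.
#' @export
predictor_consensus <- function(records, config = fh_default_config()$filter,
                                conservation_reference = records) {
  records <- as_tibble(records)
  n <- nrow(records)
  if (!n) return(character())
  pc <- pred_cols(records)
  calls <- if (length(pc)) as.matrix(records[pc]) else
    matrix(NA_character_, n, 0)
  known <- !is.na(calls) & calls != "unknown"
  n_known <- rowSums(known)
  frac_damaging <- ifelse(
    n_known > 0, rowSums(calls == "damaging" & known) / pmax(n_known, 1), NA
  )
  cc <- intersect(cons_cols(records), cons_cols(conservation_reference))
  conserved <- rep(FALSE, n)
  for (tool in cc) {
    refs <- conservation_reference[[tool]]
    if (all(is.na(refs))) next
    pct <- conservation_percentile(records[[tool]], refs)
    conserved <- conserved |
      (!is.na(pct) & pct >= config$conservation_percentile_threshold)
  }
  thr <- config$predictor_damaging_fraction
  dplyr::case_when(
    n_known == 0 ~ "indeterminate",
    frac_damaging >= thr & conserved ~ "damaging",
    frac_damaging <= 1 - thr ~ "benign_leaning",
    .default = "indeterminate"
  )
}

#' Rare-variant filter cascade
#'
#' Applies the annotation-driven filtering steps to a variant table, in
#' order: (1) remove records whose maximum allele frequency across sources
#' reaches `rare_af_threshold` (absent everywhere counts as frequency 0,
#' so never-observed alleles pass); (2) remove records whose clinical
#' assertion is in `excluded_assertions` (default benign / likely benign);
#' (3) tag the survivors with the in-silico [predictor_consensus()] --
#' predictors are a supplementary tool and never remove a record on their
#' own. Every removed record is recorded with the step that dropped it.
#'
#' @param records Annotated variant tibble.
#' @param config Full configuration or its `filter` element.
#' @return An object of class `fh_filter_report`: a list with
#'   `input_count`, `steps` (per-step counts), `surviving` (tibble with a
#'   `consensus` column added) and `audit` (one row per input record with
#'   `removed_at` and `consensus`). `tidy()` returns the audit trail,
#'   `glance()` the step counts.
#' @export
apply_filter_cascade <- function(records, config = fh_default_config()) {
  fcfg <- if (!is.null(config$filter)) config$filter else config
  records <- as_tibble(records)
  n <- nrow(records)
  removed_at <- rep(NA_character_, n)

  af <- max_af(records)
  removed_at[af >= fcfg$rare_af_threshold] <- "rarity"

  assertion <- if ("clinvar" %in% names(records)) records$clinvar else
    rep(NA_character_, n)
  drop2 <- is.na(removed_at) & !is.na(assertion) &
    assertion %in% fcfg$excluded_assertions
  removed_at[drop2] <- "assertion"

  keep <- is.na(removed_at)
  consensus <- rep(NA_character_, n)
  if (any(keep)) {
    consensus[keep] <- predictor_consensus(
      records[keep, , drop = FALSE], fcfg,
      conservation_reference = records[keep, , drop = FALSE]
    )
  }

  steps <- tibble(
    step = c("rarity", "assertion", "consensus_tag"),
    n_in = c(n, n - sum(removed_at == "rarity", na.rm = TRUE),
             sum(keep)),
    n_removed = c(sum(removed_at == "rarity", na.rm = TRUE),
                  sum(removed_at == "assertion", na.rm = TRUE), 0L),
  ) |>
    mutate(n_out = .data$n_in - .data$n_removed)

  surviving <- records[keep, , drop = FALSE]
  surviving$consensus <- consensus[keep]
  audit <- tibble(
    variant_id = if ("variant_id" %in% names(records)) records$variant_id
      else as.character(seq_len(n)),
    removed_at = removed_at,
    consensus = consensus
  )
  structure(
    list(input_count = n, steps = steps, surviving = surviving,
         audit = audit, config = fcfg),
    class = "fh_filter_report"
  )
}

#' @export
print.fh_filter_report <- function(x, ...) {
  cat(sprintf("<fh_filter_report> %d record(s) in, %d surviving\n",
              x$input_count, nrow(x$surviving)))
  print(x$steps)
  invisible(x)
}

#' Order filter survivors for review
#'
#' Ranks the surviving records of a filter report into review tiers:
#' (1) asserted pathogenic / likely pathogenic; (2) records at a position
#' with a described pathogenic allele in `known_table` (same chromosome,
#' position and reference allele -- the alternate allele may differ);
#' (3) novel records with a damaging predictor consensus; (4) the
#' remainder. Ties within a tier are broken by (chrom, pos), stably.
#'
#' @param report An `fh_filter_report`.
#' @param known_table Annotated variant tibble of known pathogenic entries
#'   (its `clinvar` column, when present, restricts matching to
#'   pathogenic / likely pathogenic rows).
#' @return The surviving records, ordered, with a `tier` column.
#' @export
prioritize_candidates <- function(report, known_table = NULL) {
  stopifnot(inherits(report, "fh_filter_report"))
  s <- report$surviving
  if (!nrow(s)) {
    return(bind_cols(s, tibble(tier = integer())))
  }
  asserted <- !is.na(s$clinvar) &
    s$clinvar %in% c("pathogenic", "likely_pathogenic")
  known_hit <- rep(FALSE, nrow(s))
  if (!is.null(known_table) && nrow(known_table)) {
    kt <- as_tibble(known_table)
    if ("clinvar" %in% names(kt)) {
      kt <- filter(kt, is.na(.data$clinvar) |
                     .data$clinvar %in% c("pathogenic", "likely_pathogenic"))
    }
    key_s <- paste(s$chrom, s$pos, s$ref)
    known_hit <- key_s %in% paste(kt$chrom, kt$pos, kt$ref)
  }
  damaging <- !is.na(s$consensus) & s$consensus == "damaging"
  tier <- dplyr::case_when(
    asserted ~ 1L,
    known_hit ~ 2L,
    damaging ~ 3L,
    .default = 4L
  )
  s$tier <- tier
  arrange(s, .data$tier, .data$chrom, .data$pos)
}
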