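# MLPA dosage analysis. A run is a long tibble, one row per
# (sample, probe) peak:
#   sample_id  role ("test"/"control")  probe_id
#   target     "promoter", an exon number (integer-like), or NA for
#              reference probes
#   is_reference  logical
#   peak       non-negative fluorescence peak intensity

validate_mlpa_run <- function(run) {
  run <- as_tibble(run)
  needed <- c("sample_id", "role", "probe_id", "target", "is_reference", "peak")
  missing_cols <- setdiff(needed, names(run))
  if (length(missing_cols)) {
    abort(paste0("MLPA run is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!any(run$role == "control")) abort("MLPA run needs >= 1 control sample")
  if (length(unique(run$probe_id[run$is_reference])) < 2L) {
    abort("MLPA run needs >= 2 reference probes")
  }
  if (any(!is.finite(run$peak) | run$peak < 0)) {
    abort("MLPA peaks must be finite and >= 0")
  }
  run
}

#' Normalize an MLPA run to dosage quotients
#'
#' Two-stage normalization replacing vendor software: within each sample,
#' every probe peak is divided by the mean of that sample's reference-probe
#' peaks (cancelling per-sample scale, e.g. DNA input or pipetting); then,
#' for each probe, the intra-sample value is divided by the median of the
#' intra-sample values across the control samples. The resulting dosage
#' quotient (DQ) is ~1 for two copies, ~0.5 for a heterozygous deletion and
#' ~1.5 for a heterozygous duplication.
#'
#' @param run An MLPA run tibble (see [gen_mlpa_run()]).
#' @param config Unused placeholder for interface symmetry; thresholds are
#'   applied in [call_exon_events()].
#' @return A tibble `sample_id`, `role`, `probe_id`, `target`, `dq` for the
#'   non-reference (target) probes.
#' @export
normalize_run <- function(run, config = fh_default_config()) {
  run <- validate_mlpa_run(run)
  intra <- run |>
    group_by(.data$sample_id) |>
    mutate(ref_mean = mean(.data$peak[.data$is_reference])) |>
    ungroup()
  bad <- intra$ref_mean == 0
  if (any(bad)) {
    abort(sprintf("all reference peaks are zero in sample %s",
                  intra$sample_id[bad][1]))
  }
  intra <- mutate(intra, intra_ratio = .data$peak / .data$ref_mean)
  ctrl <- intra |>
    filter(.data$role == "control") |>
    group_by(.data$probe_id) |>
    summarise(ctrl_median = median(.data$intra_ratio), .groups = "drop")
  if (any(ctrl$ctrl_median == 0)) {
    abort(sprintf("zero control median for probe %s",
                  ctrl$probe_id[ctrl$ctrl_median == 0][1]))
  }
  intra |>
    left_join(ctrl, by = "probe_id") |>
    mutate(dq = .data$intra_ratio / .data$ctrl_median) |>
    filter(!.data$is_reference) |>
    select("sample_id", "role", "probe_id", "target", "dq") |>
    arrange(.data$sample_id, .data$probe_id)
}

#' Call per-exon copy-number events from dosage quotients
#'
#' Assigns a per-probe state -- deletion when DQ is below the deletion
#' threshold (default 0.7), duplication when above the duplication
#' threshold (default 1.3), normal otherwise -- and merges runs of adjacent
#' targets (in the supplied exon order) sharing a non-normal state into one
#' event. Single-probe events are allowed. A deletion whose mean DQ falls
#' below the homozygous threshold (default 0.25) is flagged homozygous.
#'
#' @param dq A dosage-quotient table from [normalize_run()].
#' @param exon_order Character vector of targets in genomic order, e.g.
#'   `c("promoter", 1:18)`. Every target in `dq` must appear.
#' @param config Configuration; `mlpa` element holds the thresholds.
#' @return A tibble, one row per event: `sample_id`, `event`
#'   ("deletion"/"duplication"), `first_target`, `last_target`,
#'   `exon_start`, `exon_end` (integer exon numbers, `NA` for the
#'   promoter), `n_probes`, `mean_dq`, `homozygous`.
#' @export
call_exon_events <- function(dq, exon_order, config = fh_default_config()) {
  mcfg <- config$mlpa
  exon_order <- as.character(exon_order)
  dq <- mutate(as_tibble(dq), target = as.character(.data$target))
  unknown <- setdiff(unique(dq$target), exon_order)
  if (length(unknown)) {
    abort(paste0("exon_order is missing target(s): ",
                 paste(unknown, collapse = ", ")))
  }
  calls <- dq |>
    mutate(
      ord = match(.data$target, .env$exon_order),
      state = dplyr::case_when(
        .data$dq < mcfg$del_threshold ~ "deletion",
        .data$dq > mcfg$dup_threshold ~ "duplication",
        .default = "normal"
      )
    ) |>
    arrange(.data$sample_id, .data$ord) |>
    group_by(.data$sample_id) |>
    mutate(
      new_run = .data$state != lag(.data$state, default = "") |
        .data$ord != lag(.data$ord, default = -1L) + 1L,
      run_id = cumsum(.data$new_run)
    ) |>
    group_by(.data$sample_id, .data$run_id) |>
    summarise(
      event = .data$state[1],
      first_target = .data$target[1],
      last_target = .data$target[dplyr::n()],
      n_probes = dplyr::n(),
      mean_dq = mean(.data$dq),
      .groups = "drop"
    ) |>
    filter(.data$event != "normal") |>
    mutate(
      exon_start = suppressWarnings(as.integer(.data$first_target)),
      exon_end = suppressWarnings(as.integer(.data$last_target)),
      homozygous = .data$event == "deletion" &
        .data$mean_dq < mcfg$homo_del_threshold
    ) |>
    select("sample_id", "event", "first_target", "last_target",
           "exon_start", "exon_end", "n_probes", "mean_dq", "homozygous")
  calls
}

#' Partial LDLR exon boundary table (NM_000527.4)
#'
#' Cumulative cDNA end coordinates of selected LDLR exons on transcript
#' NM_000527.4, sufficient to name deletions of exons 2--10 and of exon 15.
#' The table is deliberately partial; supply a complete per-transcript
#' table for other spans.
#'
#' @return A tibble `exon`, `cdna_end`.
#' @export
ldlr_exon_boundaries <- function() {
  tibble(exon = c(1L, 10L, 14L, 15L), cdna_end = c(67L, 1586L, 2140L, 2311L))
}

#' HGVS-style name for a whole-exon deletion
#'
#' Formats the uncertain-breakpoint coding-DNA description of a deletion of
#' exons `a..b`: with `x` the cDNA end of exon `a - 1` and `z` the cDNA end
#' of exon `b`, the name is
#' `"<transcript>:c.(x+1_y-1)_(z+1_w-1)del"` with `y = x + 1`,
#' `w = z + 1` -- i.e. breakpoints lie in the flanking introns.
#'
#' @param exon_start,exon_end First and last deleted exon (integers,
#'   `exon_start >= 2`).
#' @param boundaries Exon boundary table with columns `exon`, `cdna_end`
#'   (defaults to the packaged partial LDLR table).
#' @param transcript Transcript accession used as prefix.
#' @return The HGVS deletion string.
#' @export
#' @examples
#' format_deletion_hgvs(2, 10)
format_deletion_hgvs <- function(exon_start, exon_end,
                                 boundaries = ldlr_exon_boundaries(),
                                 transcript = "NM_000527.4") {
  stopifnot(length(exon_start) == 1L, length(exon_end) == 1L)
  if (is.na(exon_start) || is.na(exon_end) || exon_start < 2L ||
      exon_end < exon_start) {
    abort("need integer exons with 2 <= exon_start <= exon_end")
  }
  lookup <- function(exon) {
    hit <- boundaries$cdna_end[boundaries$exon == exon]
    if (!length(hit)) {
      abort(sprintf("boundary table lacks the cDNA end of exon %d", exon))
    }
    hit[1]
  }
  x <- lookup(exon_start - 1L)
  z <- lookup(exon_end)
  sprintf("%s:c.(%d+1_%d-1)_(%d+1_%d-1)del", transcript, x, x + 1L, z, z + 1L)
}
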