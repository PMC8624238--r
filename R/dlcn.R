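#' Friedewald LDL-C estimate
#'
#' Estimates LDL-C from total cholesterol, HDL-C and triglycerides, all in
#' mmol/L: `ldl = tc - hdl - tg / 2.2`. The formula is invalid at high
#' triglycerides, and values above the configured threshold (default
#' 4.5 mmol/L) are flagged as requiring a direct measurement rather than
#' rejected -- the software cannot perform the measurement itself.
#'
#' @param tc,hdl,tg Total cholesterol, HDL-C, triglycerides (mmol/L);
#'   vectors are recycled by the usual rules.
#' @param config A configuration list (see [fh_default_config()]); the
#'   `friedewald` element holds `direct_threshold` and `tg_max`.
#' @return A tibble with columns `ldl` (mmol/L) and `direct_required`.
#' @export
#' @examples
#' compute_friedewald_ldl(8.6, 1.4, 1.8)
compute_friedewald_ldl <- function(tc, hdl, tg, config = fh_default_config()) {
  if (any(tc <= 0 | hdl <= 0 | tg <= 0)) {
    abort("tc, hdl and tg must all be > 0")
  }
  if (any(tg > config$friedewald$tg_max)) {
    abort(sprintf(
      "Friedewald invalid at high TG (> %.1f mmol/L); use a direct LDL-C measurement",
      config$friedewald$tg_max
    ))
  }
  ldl <- tc - hdl - tg / 2.2
  if (any(ldl <= 0)) {
    abort("non-physiological Friedewald result (LDL-C <= 0)")
  }
  tibble(ldl = ldl, direct_required = ldl > config$friedewald$direct_threshold)
}

#' Compare LDL-C to the age/sex-specific 95th percentile
#'
#' `TRUE` iff `ldl` strictly exceeds the 95th-percentile value for the
#' subject's sex and age band; a tie does not count as exceeding.
#'
#' @param sex "F" or "M" (vectorized).
#' @param age Age in years.
#' @param ldl LDL-C in mmol/L.
#' @param table Percentile lookup with columns `sex`, `age_min`, `age_max`,
#'   `p95`; defaults to the packaged synthetic table
#'   ([fh_default_p95_table()]).
#' @return Logical vector.
#' @export
exceeds_95th_percentile <- function(sex, age, ldl, table = fh_default_p95_table()) {
  n <- max(length(sex), length(age), length(ldl))
  sex <- rep_len(sex, n); age <- rep_len(age, n); ldl <- rep_len(ldl, n)
  idx <- purrr::map_int(seq_len(n), function(i) {
    hit <- which(table$sex == sex[i] & table$age_min <= age[i] &
                   age[i] <= table$age_max)
    if (!length(hit)) {
      abort(sprintf(
        "no 95th-percentile entry covers sex %s, age %s", sex[i], age[i]
      ))
    }
    hit[1]
  })
  ldl > table$p95[idx]
}

#' Classify a DLCN total score into a diagnostic band
#'
#' With the default bands: total > 8 is "definite", 6--8 "probable", 3--5
#' "possible" and below 3 "unlikely". The three ranges plus the open ends
#' partition the whole score axis; [load_config()] rejects gapped or
#' overlapping bands.
#'
#' @param total Integer score(s), >= 0.
#' @param bands Band element of the configuration
#'   (`fh_default_config()$dlcn$bands`).
#' @return Character vector in
#'   `c("unlikely", "possible", "probable", "definite")`.
#' @export
classify_band <- function(total, bands = fh_default_config()$dlcn$bands) {
  if (any(total < 0)) abort("DLCN total must be >= 0")
  bb <- band_bounds(bands)
  dplyr::case_when(
    total >= bb$definite_min ~ "definite",
    total >= bb$probable_min ~ "probable",
    total >= bb$possible_min ~ "possible",
    .default = "unlikely"
  )
}

#' Score subjects with the Dutch Lipid Clinic Network criteria
#'
#' Computes the five group subscores (family history, clinical history,
#' physical examination, LDL-C, DNA), the total score and the diagnostic
#' band for every row of a subject table. Within each group the subscore is
#' the MAXIMUM of the points of the satisfied criteria (0 when none is
#' satisfied); the total is the sum of the five subscores. An untested DNA
#' result contributes 0, so pre- and post-genetic scores are both
#' computable. Setting `config$dlcn$aggregate = "sum"` switches the
#' within-group rule to a sum for sensitivity analysis.
#'
#' @param subjects A tibble with the DLCN input columns (`fam_premature_cvd`,
#'   `fam_ldl_above_p95`, `fam_xanthoma_or_arcus`, `fam_child_ldl_above_p95`,
#'   `premature_cad`, `premature_cerebral_or_peripheral`,
#'   `tendon_xanthomata`, `arcus_cornealis_before_45`, `dlcn_ldl`,
#'   `dna_functional_mutation`). Missing logical inputs count as `FALSE`;
#'   a missing `dlcn_ldl` scores 0 points. A `subject_id` column, if
#'   present, is carried through.
#' @param config Configuration list; see [fh_default_config()] for the
#'   point table.
#' @return A tibble with one row per subject: `subject_id` (when available),
#'   `family_points`, `clinical_points`, `physical_points`, `ldl_points`,
#'   `dna_points`, `total` and `band`.
#' @export
#' @examples
#' score_dlcn(tibble::tibble(
#'   tendon_xanthomata = TRUE, dlcn_ldl = 7.0,
#'   premature_cad = TRUE, dna_functional_mutation = "yes"
#' ))
score_dlcn <- function(subjects, config = fh_default_config()) {
  subjects <- as_tibble(subjects)
  n <- nrow(subjects)
  if (n == 0L) {
    return(tibble(
      subject_id = character(), family_points = numeric(),
      clinical_points = numeric(), physical_points = numeric(),
      ldl_points = numeric(), dna_points = numeric(), total = numeric(),
      band = character()
    ))
  }
  lgl <- function(col) {
    x <- if (col %in% names(subjects)) subjects[[col]] else rep(NA, n)
    !is.na(x) & x
  }
  pts <- config$dlcn$points
  agg <- match.arg(config$dlcn$aggregate, c("max", "sum"))
  group_score <- function(flags, points) {
    # flags: list of logical vectors aligned with `points`
    mat <- mapply(function(f, p) ifelse(f, p, 0), flags, points)
    mat <- matrix(mat, nrow = n)
    if (agg == "max") apply(mat, 1, max) else rowSums(mat)
  }
  family_points <- group_score(
    list(lgl("fam_premature_cvd"), lgl("fam_ldl_above_p95"),
         lgl("fam_xanthoma_or_arcus"), lgl("fam_child_ldl_above_p95")),
    unlist(pts$family)
  )
  clinical_points <- group_score(
    list(lgl("premature_cad"), lgl("premature_cerebral_or_peripheral")),
    unlist(pts$clinical)
  )
  physical_points <- group_score(
    list(lgl("tendon_xanthomata"), lgl("arcus_cornealis_before_45")),
    unlist(pts$physical)
  )
  ldl <- if ("dlcn_ldl" %in% names(subjects)) subjects$dlcn_ldl else rep(NA_real_, n)
  if (any(!is.na(ldl) & ldl < 0)) abort("dlcn_ldl must be >= 0 when present")
  ldl_points <- rep(0, n)
  for (band in pts$ldl) {  # ordered by decreasing lower bound
    ldl_points <- ifelse(!is.na(ldl) & ldl >= band$min & ldl_points == 0,
                         band$points, ldl_points)
  }
  dna <- if ("dna_functional_mutation" %in% names(subjects)) {
    subjects$dna_functional_mutation
  } else {
    rep("untested", n)
  }
  dna_points <- ifelse(!is.na(dna) & dna == "yes", pts$dna_yes, 0)
  total <- family_points + clinical_points + physical_points +
    ldl_points + dna_points
  out <- tibble(
    family_points = as.numeric(family_points),
    clinical_points = as.numeric(clinical_points),
    physical_points = as.numeric(physical_points),
    ldl_points = as.numeric(ldl_points),
    dna_points = as.numeric(dna_points),
    total = as.numeric(total),
    band = classify_band(total, config$dlcn$bands)
  )
  if ("subject_id" %in% names(subjects)) {
    out <- bind_cols(tibble(subject_id = subjects$subject_id), out)
  }
  out
}
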