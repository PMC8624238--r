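#' Default analysis configuration
#'
#' Returns the full default configuration used across the package: the DLCN
#' point table and score bands, the 95th-percentile LDL-C lookup table, the
#' rare-variant filter thresholds, the ACMG frequency cut-offs, and the MLPA
#' dosage-quotient thresholds. Every value can be overridden, either by
#' passing replacement elements here or by loading a YAML file with
#' [load_config()].
#'
#' The DLCN point values are the published Dutch Lipid Clinic Network table:
#' family history (premature CVD 1, LDL-C above the 95th percentile 1,
#' tendon xanthomata or arcus cornealis in a relative 2, child with LDL-C
#' above the 95th percentile 2), clinical history (premature coronary disease
#' 2, premature cerebral or peripheral vascular disease 1), physical
#' examination (tendon xanthomata 6, arcus cornealis before age 45 4), LDL-C
#' bands (>= 8.5 mmol/L 8; 6.5--8.4 5; 5.0--6.4 3; 4.0--4.9 1) and a
#' functional DNA mutation (8). Within each group the subscore is the maximum
#' of the satisfied criteria; the total is the sum over groups.
#'
#' @param ... Named elements merged (recursively) over the defaults, e.g.
#'   `filter = list(rare_af_threshold = 0.01)`.
#'
#' @return A named list with elements `dlcn`, `p95_table`, `filter`, `acmg`,
#'   `mlpa`, `friedewald` and `seed`.
#' @seealso [load_config()], [score_dlcn()], [apply_filter_cascade()]
#' @export
#' @examples
#' cfg <- fh_default_config()
#' cfg$dlcn$bands
fh_default_config <- function(...) {
  cfg <- list(
    dlcn = list(
      # within-group aggregation: "max" (standard DLCN) or "sum"
      aggregate = "max",
      points = list(
        family = list(
          premature_cvd = 1, ldl_above_p95 = 1,
          xanthoma_or_arcus = 2, child_ldl_above_p95 = 2
        ),
        clinical = list(
          premature_cad = 2, premature_cerebral_or_peripheral = 1
        ),
        physical = list(
          tendon_xanthomata = 6, arcus_cornealis_before_45 = 4
        ),
        # ordered by decreasing lower bound; first match wins
        ldl = list(
          list(min = 8.5, points = 8),
          list(min = 6.5, points = 5),
          list(min = 5.0, points = 3),
          list(min = 4.0, points = 1)
        ),
        dna_yes = 8
      ),
      # inclusive integer ranges; definite is open-ended above probable
      bands = list(possible = c(3, 5), probable = c(6, 8), definite_min = 9)
    ),
    p95_table = fh_default_p95_table(),
    filter = list(
      rare_af_threshold = 0.005,
      conservation_percentile_threshold = 0.7,
      predictor_damaging_fraction = 0.5,
      excluded_assertions = c("benign", "likely_benign")
    ),
    acmg = list(ba1_af = 0.05, pm2_af = 1e-4),
    mlpa = list(
      del_threshold = 0.7, dup_threshold = 1.3, homo_del_threshold = 0.25
    ),
    friedewald = list(direct_threshold = 4.5, tg_max = 4.5),
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    cfg <- modifyList(cfg, overrides)
  }
  validate_config(cfg)
}

#' Synthetic age/sex 95th-percentile LDL-C table
#'
#' A placeholder lookup of the age- and sex-specific 95th percentile of
#' LDL-C (mmol/L) used by the DLCN family-history criteria. The values are
#' SYNTHETIC and NOT CLINICAL: population percentile tables are
#' region-specific and not redistributed here. Replace with a real table via
#' the `p95_table` config element for any clinical use.
#'
#' @return A tibble with columns `sex` ("F"/"M"), `age_min`, `age_max`
#'   (inclusive years) and `p95` (mmol/L), covering ages 0--120.
#' @export
fh_default_p95_table <- function() {
  bands <- tibble(
    age_min = c(0L, 10L, 20L, 30L, 40L, 50L, 60L),
    age_max = c(9L, 19L, 29L, 39L, 49L, 59L, 120L),
    p95_f = c(3.4, 3.5, 3.8, 4.1, 4.4, 4.7, 4.8),
    p95_m = c(3.4, 3.5, 4.0, 4.3, 4.5, 4.6, 4.7)
  )
  bind_rows(
    tibble(sex = "F", bands[c("age_min", "age_max")], p95 = bands$p95_f),
    tibble(sex = "M", bands[c("age_min", "age_max")], p95 = bands$p95_m)
  )
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it recursively over
#' [fh_default_config()]: keys absent from the file keep their defaults.
#' The merged configuration is validated (DLCN bands must partition the
#' score axis, all thresholds finite, fractions in \[0, 1\]).
#'
#' @param path Path to a YAML file. Any subset of the default structure may
#'   be present.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  user <- yaml::read_yaml(path)
  cfg <- fh_default_config()
  if (length(user)) {
    cfg <- modifyList(cfg, user)
  }
  if (!is.data.frame(cfg$p95_table)) {
    cfg$p95_table <- as_tibble(as.data.frame(cfg$p95_table))
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  b <- cfg$dlcn$bands
  poss <- as.integer(b$possible)
  prob <- as.integer(b$probable)
  defm <- as.integer(b$definite_min)
  if (length(poss) != 2L || length(prob) != 2L || length(defm) != 1L) {
    abort("dlcn bands must give possible = [lo, hi], probable = [lo, hi], definite_min")
  }
  if (poss[1] > poss[2] || prob[1] > prob[2]) {
    abort("dlcn band ranges must be ordered lo <= hi")
  }
  if (prob[1] != poss[2] + 1L) {
    abort(sprintf(
      "dlcn bands do not partition the score axis: possible ends at %d but probable starts at %d",
      poss[2], prob[1]
    ))
  }
  if (defm != prob[2] + 1L) {
    abort(sprintf(
      "dlcn bands do not partition the score axis: probable ends at %d but definite starts at %d",
      prob[2], defm
    ))
  }
  fr <- cfg$filter
  fracs <- c(
    fr$rare_af_threshold, fr$conservation_percentile_threshold,
    fr$predictor_damaging_fraction, cfg$acmg$ba1_af, cfg$acmg$pm2_af
  )
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    abort("filter/acmg thresholds must be finite fractions in [0, 1]")
  }
  ml <- cfg$mlpa
  if (!(ml$homo_del_threshold < ml$del_threshold &&
        ml$del_threshold < ml$dup_threshold)) {
    abort("mlpa thresholds must satisfy homo_del < del < dup")
  }
  p95 <- cfg$p95_table
  stopifnot(all(c("sex", "age_min", "age_max", "p95") %in% names(p95)))
  cfg
}

# inclusive band bounds as a small lookup used by classify_band()
band_bounds <- function(bands) {
  list(
    possible_min = as.integer(bands$possible[1]),
    probable_min = as.integer(bands$probable[1]),
    definite_min = as.integer(bands$definite_min)
  )
}
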