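# ACMG/AMP 2015-style evidence combination. Criteria are coded items
# (PVS1, PS1-4, PM1-6, PP1-5, BA1, BS1-4, BP1-7); classification depends
# only on the per-strength counts, via a data-driven combining table.

acmg_categories <- c("pvs", "ps", "pm", "pp", "ba", "bs", "bp")

code_category <- function(codes) {
  dplyr::case_when(
    grepl("^PVS", codes) ~ "pvs",
    grepl("^PS", codes) ~ "ps",
    grepl("^PM", codes) ~ "pm",
    grepl("^PP", codes) ~ "pp",
    grepl("^BA", codes) ~ "ba",
    grepl("^BS", codes) ~ "bs",
    grepl("^BP", codes) ~ "bp",
    .default = NA_character_
  )
}

#' Count ACMG evidence codes per strength category
#'
#' @param codes Character vector of active codes (e.g. `c("PVS1", "PM2")`).
#' @return Named integer vector over `pvs, ps, pm, pp, ba, bs, bp`.
#' @export
evidence_counts <- function(codes) {
  cat <- code_category(codes)
  if (anyNA(cat)) {
    abort(paste0("unrecognized ACMG code(s): ",
                 paste(codes[is.na(cat)], collapse = ", ")))
  }
  vapply(acmg_categories, function(k) sum(cat == k), integer(1))
}

#' The ACMG combining-rule table
#'
#' The 2015 recommendations' combining rules encoded as data: each row is a
#' rule with the minimum number of codes required in each strength category
#' for the given class. A rule fires when every minimum is met; the
#' pathogenic side takes the strongest fired class, the benign side
#' likewise, and [classify_acmg()] resolves the two sides. Users may pass
#' an amended table to [classify_acmg()].
#'
#' @return A tibble with columns `class`, `rule` and the seven category
#'   minima.
#' @export
acmg_rule_table <- function() {
  tibble::tribble(
    ~class, ~rule, ~pvs, ~ps, ~pm, ~pp, ~ba, ~bs, ~bp,
    "pathogenic", "P.Ia: PVS1 + >=1 PS", 1L, 1L, 0L, 0L, 0L, 0L, 0L,
    "pathogenic", "P.Ib: PVS1 + >=2 PM", 1L, 0L, 2L, 0L, 0L, 0L, 0L,
    "pathogenic", "P.Ic: PVS1 + 1 PM + 1 PP", 1L, 0L, 1L, 1L, 0L, 0L, 0L,
    "pathogenic", "P.Id: PVS1 + >=2 PP", 1L, 0L, 0L, 2L, 0L, 0L, 0L,
    "pathogenic", "P.II: >=2 PS", 0L, 2L, 0L, 0L, 0L, 0L, 0L,
    "pathogenic", "P.IIIa: 1 PS + >=3 PM", 0L, 1L, 3L, 0L, 0L, 0L, 0L,
    "pathogenic", "P.IIIb: 1 PS + 2 PM + >=2 PP", 0L, 1L, 2L, 2L, 0L, 0L, 0L,
    "pathogenic", "P.IIIc: 1 PS + 1 PM + >=4 PP", 0L, 1L, 1L, 4L, 0L, 0L, 0L,
    "likely_pathogenic", "LP.I: PVS1 + 1 PM", 1L, 0L, 1L, 0L, 0L, 0L, 0L,
    "likely_pathogenic", "LP.II: 1 PS + 1-2 PM", 0L, 1L, 1L, 0L, 0L, 0L, 0L,
    "likely_pathogenic", "LP.III: 1 PS + >=2 PP", 0L, 1L, 0L, 2L, 0L, 0L, 0L,
    "likely_pathogenic", "LP.IV: >=3 PM", 0L, 0L, 3L, 0L, 0L, 0L, 0L,
    "likely_pathogenic", "LP.V: 2 PM + >=2 PP", 0L, 0L, 2L, 2L, 0L, 0L, 0L,
    "likely_pathogenic", "LP.VI: 1 PM + >=4 PP", 0L, 0L, 1L, 4L, 0L, 0L, 0L,
    "benign", "B.I: BA1", 0L, 0L, 0L, 0L, 1L, 0L, 0L,
    "benign", "B.II: >=2 BS", 0L, 0L, 0L, 0L, 0L, 2L, 0L,
    "likely_benign", "LB.I: 1 BS + 1 BP", 0L, 0L, 0L, 0L, 0L, 1L, 1L,
    "likely_benign", "LB.II: >=2 BP", 0L, 0L, 0L, 0L, 0L, 0L, 2L
  )
}

validate_rule_table <- function(rules) {
  needed <- c("class", "rule", acmg_categories)
  if (!is.data.frame(rules) || !all(needed %in% names(rules))) {
    abort("malformed ACMG rule table: need columns class, rule and the seven category minima")
  }
  ok_class <- rules$class %in%
    c("pathogenic", "likely_pathogenic", "benign", "likely_benign")
  if (!all(ok_class)) abort("malformed ACMG rule table: unknown class value")
  if (any(as.matrix(rules[acmg_categories]) < 0)) {
    abort("malformed ACMG rule table: negative minimum")
  }
  rules
}

classify_counts <- function(counts, rules) {
  mins <- as.matrix(rules[acmg_categories])
  fired <- apply(mins, 1, function(m) all(counts[acmg_categories] >= m))
  fired_classes <- unique(rules$class[fired])
  path_side <- intersect(c("pathogenic", "likely_pathogenic"), fired_classes)
  ben_side <- intersect(c("benign", "likely_benign"), fired_classes)
  if (length(path_side) && length(ben_side)) {
    return(list(class = "uncertain_significance", rationale = "conflicting"))
  }
  if (!length(path_side) && !length(ben_side)) {
    return(list(class = "uncertain_significance", rationale = "insufficient"))
  }
  cls <- c(path_side, ben_side)[1]
  rule <- rules$rule[fired & rules$class == cls][1]
  list(class = cls, rationale = rule)
}

#' Classify a variant from its ACMG evidence
#'
#' Combines active evidence codes into one of the five classes using a
#' data-driven rule table ([acmg_rule_table()] by default). If combinations
#' on both the pathogenic and the benign side are reached the result is
#' uncertain significance with rationale `"conflicting"`; if neither side
#' is reached, uncertain significance with `"insufficient"`. Classification
#' depends only on the per-category counts; per-code strength is fixed by
#' its category (no upgrading or downgrading).
#'
#' @param evidence A character vector of codes for one variant, or a list
#'   of such vectors for several.
#' @param rules A combining-rule table; see [acmg_rule_table()].
#' @return A tibble with one row per evidence set: `class` and `rationale`
#'   (the firing rule, or "conflicting"/"insufficient").
#' @export
#' @examples
#' classify_acmg(c("PVS1", "PS1"))
#' classify_acmg(list(character(), c("PVS1", "PM2")))
classify_acmg <- function(evidence, rules = acmg_rule_table()) {
  rules <- validate_rule_table(rules)
  if (!is.list(evidence)) evidence <- list(evidence)
  purrr::map(evidence, function(codes) {
    res <- classify_counts(evidence_counts(codes), rules)
    tibble(class = res$class, rationale = res$rationale)
  }) |>
    purrr::list_rbind()
}

# --- automatic evidence assignment ---------------------------------------

parse_hgvs_p <- function(hgvs_p) {
  m <- stringr::str_match(
    hgvs_p, "^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|Ter|\\*|=)$"
  )
  tibble(aa_ref = m[, 2], residue = suppressWarnings(as.integer(m[, 3])),
         aa_alt = m[, 4])
}

#' Auto-assign the mechanically computable ACMG codes
#'
#' Assigns, per record, only the codes that can be derived from the
#' annotation itself: `BA1` (maximum allele frequency above the stand-alone
#' benign threshold, default 0.05), `PM2` (absent from all sources or below
#' the ultra-rare threshold, default 1e-4), `PP3`/`BP4` (damaging /
#' benign-leaning [predictor_consensus()]), `PVS1` (explicit `null_variant`
#' flag on the record -- splice variants outside the canonical +/-1,2
#' positions are never auto-flagged), `PS1` (same amino-acid change as a
#' known pathogenic entry, via a different nucleotide change) and `PM5`
#' (different missense change at a residue carrying a known pathogenic
#' missense). `PS1` and `PM5` are mutually exclusive at a residue: only the
#' stronger is assigned. All other codes require expert input and must be
#' supplied by the user.
#'
#' @param records Annotated variant tibble (a `consensus` column, e.g. from
#'   [apply_filter_cascade()], is used when present and computed otherwise).
#' @param known_table Tibble of known pathogenic entries with `gene`,
#'   `hgvs_c`, `hgvs_p` and optionally `clinvar` (rows restricted to
#'   pathogenic / likely pathogenic when present).
#' @param config Full configuration list; uses its `acmg` and `filter`
#'   elements.
#' @return A tibble `variant_id`, `codes` (list-column of character
#'   vectors).
#' @export
auto_evidence <- function(records, known_table = NULL,
                          config = fh_default_config()) {
  records <- as_tibble(records)
  n <- nrow(records)
  af <- max_af(records)
  observed <- if (length(af_cols(records))) {
    rowSums(!is.na(as.matrix(records[af_cols(records)]))) > 0
  } else {
    rep(FALSE, n)
  }
  consensus <- if ("consensus" %in% names(records)) records$consensus else
    predictor_consensus(records, config$filter)

  kt <- NULL
  if (!is.null(known_table) && nrow(known_table)) {
    kt <- as_tibble(known_table)
    if ("clinvar" %in% names(kt)) {
      kt <- filter(kt, is.na(.data$clinvar) |
                     .data$clinvar %in% c("pathogenic", "likely_pathogenic"))
    }
    kt <- bind_cols(kt, parse_hgvs_p(kt$hgvs_p))
  }
  rec_p <- parse_hgvs_p(if ("hgvs_p" %in% names(records)) records$hgvs_p
                        else rep(NA_character_, n))

  codes <- purrr::map(seq_len(n), function(i) {
    out <- character()
    if (!is.null(records$null_variant) && isTRUE(records$null_variant[i])) {
      out <- c(out, "PVS1")
    }
    if (observed[i] && af[i] > config$acmg$ba1_af) out <- c(out, "BA1")
    if (af[i] < config$acmg$pm2_af) out <- c(out, "PM2")
    if (!is.null(kt) && !is.na(rec_p$residue[i])) {
      same_res <- !is.na(kt$residue) & kt$residue == rec_p$residue[i] &
        kt$aa_ref == rec_p$aa_ref[i] & kt$gene == records$gene[i]
      same_change <- same_res & kt$aa_alt == rec_p$aa_alt[i]
      diff_nt <- is.na(kt$hgvs_c) | is.na(records$hgvs_c[i]) |
        kt$hgvs_c != records$hgvs_c[i]
      if (any(same_change & diff_nt)) {
        out <- c(out, "PS1")
      } else if (any(same_res & kt$aa_alt != rec_p$aa_alt[i] &
                       kt$aa_alt != "Ter" & rec_p$aa_alt[i] != "Ter")) {
        out <- c(out, "PM5")
      }
    }
    if (!is.na(consensus[i])) {
      if (consensus[i] == "damaging") out <- c(out, "PP3")
      if (consensus[i] == "benign_leaning") out <- c(out, "BP4")
    }
    out
  })
  tibble(
    variant_id = if ("variant_id" %in% names(records)) records$variant_id
      else as.character(seq_len(n)),
    codes = codes
  )
}
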