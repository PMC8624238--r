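# Canonical subject-table schema. TSV, UTF-8, '.' decimal; "", "NA" and "."
# are all read as missing. One row per subject.

subject_required_cols <- c(
  "subject_id", "family_id", "role", "relation", "sex", "age"
)

subject_all_cols <- c(
  subject_required_cols,
  # lipid panel (mmol/L)
  "tc", "tg", "hdl", "ldl", "ldl_method", "on_lipid_lowering",
  # DLCN criteria inputs
  "fam_premature_cvd", "fam_ldl_above_p95", "fam_xanthoma_or_arcus",
  "fam_child_ldl_above_p95", "premature_cad",
  "premature_cerebral_or_peripheral", "tendon_xanthomata",
  "arcus_cornealis_before_45", "dlcn_ldl", "dna_functional_mutation",
  # genetic result
  "genetic_status", "gene", "variant_ids", "zygosity"
)

subject_col_types <- function(header = subject_all_cols) {
  spec <- readr::cols(
    subject_id = readr::col_character(),
    family_id = readr::col_character(),
    role = readr::col_character(),
    relation = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_integer(),
    tc = readr::col_double(),
    tg = readr::col_double(),
    hdl = readr::col_double(),
    ldl = readr::col_double(),
    ldl_method = readr::col_character(),
    on_lipid_lowering = readr::col_logical(),
    fam_premature_cvd = readr::col_logical(),
    fam_ldl_above_p95 = readr::col_logical(),
    fam_xanthoma_or_arcus = readr::col_logical(),
    fam_child_ldl_above_p95 = readr::col_logical(),
    premature_cad = readr::col_logical(),
    premature_cerebral_or_peripheral = readr::col_logical(),
    tendon_xanthomata = readr::col_logical(),
    arcus_cornealis_before_45 = readr::col_logical(),
    dlcn_ldl = readr::col_double(),
    dna_functional_mutation = readr::col_character(),
    genetic_status = readr::col_character(),
    gene = readr::col_character(),
    variant_ids = readr::col_character(),
    zygosity = readr::col_character(),
    .default = readr::col_character()
  )
  spec$cols <- spec$cols[intersect(names(spec$cols), header)]
  spec
}

#' Read a subject table
#'
#' Reads the canonical tab-separated subject table (one row per subject:
#' identifiers, demographics, lipid panel in mmol/L, DLCN criteria inputs and
#' the genetic result) and validates it. Missing optional values may be
#' written as `NA`, `.` or an empty field. Writing with
#' [write_subject_table()] and reading back is an identity.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with one row per subject.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) abort(paste0("subject table not found: ", path))
  header <- names(readr::read_tsv(
    path, n_max = 0, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  missing_cols <- setdiff(subject_required_cols, header)
  if (length(missing_cols)) {
    abort(paste0(
      "subject table format error: missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  subjects <- readr::read_tsv(
    path, col_types = subject_col_types(header), na = c("", "NA", "."),
    progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(subjects)
  if (nrow(prob)) {
    abort(sprintf(
      "subject table format error at data row %d, column '%s'",
      prob$row[1] - 1L, header[prob$col[1]]
    ))
  }
  validate_subjects(subjects)
}

#' Write a subject table
#'
#' @param subjects A subject tibble as returned by [read_subject_table()] or
#'   the generators.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  readr::write_tsv(subjects, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Validate a subject table
#'
#' Checks the structural invariants of the subject table: unique ids, legal
#' enum values, ages in 0--120, probands self-related, positive lipid
#' concentrations with LDL-C below total cholesterol, a gene for every
#' positive genetic result, and at least two variant ids for compound
#' heterozygotes. The first violated row is named in the error.
#'
#' @param subjects A subject tibble.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_subjects <- function(subjects) {
  subjects <- as_tibble(subjects)
  dup <- duplicated(subjects$subject_id)
  if (any(dup)) {
    abort(sprintf(
      "validation error: duplicate subject_id '%s' at row %d",
      subjects$subject_id[which(dup)[1]], which(dup)[1]
    ))
  }
  fail_row <- function(cond, what) {
    bad <- which(cond)
    if (length(bad)) {
      abort(sprintf("validation error at row %d: %s", bad[1], what))
    }
  }
  enum_ok <- function(x, levels) is.na(x) | x %in% levels
  fail_row(!enum_ok(subjects$role, c("proband", "relative")) |
             is.na(subjects$role), "role must be proband/relative")
  fail_row(
    !enum_ok(subjects$relation, c("self", "child", "parent", "sibling", "other")),
    "relation must be self/child/parent/sibling/other"
  )
  fail_row(!enum_ok(subjects$sex, c("F", "M")), "sex must be F/M")
  fail_row(
    subjects$role == "proband" & subjects$relation != "self",
    "a proband's relation_to_proband must be 'self'"
  )
  fail_row(
    !is.na(subjects$age) & (subjects$age < 0L | subjects$age > 120L),
    "age must be in 0..120"
  )
  for (col in intersect(c("tc", "tg", "hdl", "ldl"), names(subjects))) {
    fail_row(
      !is.na(subjects[[col]]) & subjects[[col]] <= 0,
      paste0(col, " must be > 0 when present")
    )
  }
  if (all(c("ldl", "tc") %in% names(subjects))) {
    fail_row(
      !is.na(subjects$ldl) & !is.na(subjects$tc) & subjects$ldl >= subjects$tc,
      "ldl must be < tc when both present"
    )
  }
  if ("genetic_status" %in% names(subjects)) {
    fail_row(
      !enum_ok(subjects$genetic_status, c("positive", "negative", "untested")),
      "genetic_status must be positive/negative/untested"
    )
    if ("gene" %in% names(subjects)) {
      fail_row(
        !is.na(subjects$genetic_status) & subjects$genetic_status == "positive" &
          (is.na(subjects$gene) | subjects$gene == ""),
        "a positive genetic result requires a gene"
      )
    }
    if (all(c("zygosity", "variant_ids") %in% names(subjects))) {
      n_var <- purrr::map_int(
        strsplit(dplyr::coalesce(subjects$variant_ids, ""), ",", fixed = TRUE),
        function(v) sum(nzchar(trimws(v)))
      )
      fail_row(
        !is.na(subjects$zygosity) & subjects$zygosity == "compound_het" & n_var < 2L,
        "compound_het requires at least two variant ids"
      )
    }
  }
  subjects
}

# --- pedigrees ------------------------------------------------------------

#' Read a pedigree file
#'
#' Reads a standard 6-column PED file (family id, individual id, father id,
#' mother id, sex, phenotype; whitespace- or tab-separated, no header).
#' Sex is coded 1 = male / 2 = female, phenotype 2 = affected / 1 =
#' unaffected / 0 or -9 = missing, and `0` denotes a missing parent.
#' Parent links must resolve within the family and the parentage graph must
#' be acyclic; founders are individuals with both parents missing.
#'
#' @param path Path to a PED file.
#' @return A tibble with columns `family_id`, `id`, `father_id`, `mother_id`
#'   (`NA` when missing), `sex` ("M"/"F"/`NA`) and `affected`
#'   (`TRUE`/`FALSE`/`NA`).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  raw <- utils::read.table(
    path, header = FALSE, colClasses = "character",
    col.names = c("family_id", "id", "father_id", "mother_id", "sex", "phenotype")
  )
  ped <- tibble(
    family_id = raw$family_id,
    id = raw$id,
    father_id = ifelse(raw$father_id %in% c("0", "-9", "NA", "."),
                       NA_character_, raw$father_id),
    mother_id = ifelse(raw$mother_id %in% c("0", "-9", "NA", "."),
                       NA_character_, raw$mother_id),
    sex = dplyr::case_match(raw$sex, "1" ~ "M", "2" ~ "F", .default = NA_character_),
    affected = dplyr::case_match(raw$phenotype, "2" ~ TRUE, "1" ~ FALSE,
                                 .default = NA)
  )
  validate_pedigree(ped)
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()]: writes the standard 6-column PED encoding
#' (missing parents as `0`, sex 1/2, phenotype 2/1/0).
#'
#' @param ped A pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    ped$family_id, ped$id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    dplyr::case_match(ped$sex, "M" ~ "1", "F" ~ "2", .default = "0"),
    dplyr::case_when(is.na(ped$affected) ~ "0", ped$affected ~ "2",
                     .default = "1")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a pedigree
#'
#' Enforces resolvable parent links (within the same family), uniqueness of
#' individual ids, no self-parentage and acyclicity of the parentage graph.
#'
#' @param ped A pedigree tibble (see [read_pedigree()] for columns).
#' @return The validated pedigree.
#' @export
validate_pedigree <- function(ped) {
  ped <- as_tibble(ped)
  key <- paste(ped$family_id, ped$id)
  if (anyDuplicated(key)) {
    abort(paste0(
      "pedigree validation error: duplicate individual id ",
      ped$id[which(duplicated(key))[1]]
    ))
  }
  for (fam in unique(ped$family_id)) {
    fp <- ped[ped$family_id == fam, ]
    for (pcol in c("father_id", "mother_id")) {
      par <- fp[[pcol]]
      unknown <- !is.na(par) & !(par %in% fp$id)
      if (any(unknown)) {
        abort(sprintf(
          "pedigree validation error: unknown parent id '%s' in family %s",
          par[which(unknown)[1]], fam
        ))
      }
      if (any(!is.na(par) & par == fp$id)) {
        abort(sprintf(
          "pedigree validation error: individual '%s' is its own parent",
          fp$id[which(!is.na(par) & par == fp$id)[1]]
        ))
      }
    }
    # Kahn-style founder stripping; leftovers imply a parentage cycle
    remaining <- fp$id
    repeat {
      fathers <- fp$father_id[match(remaining, fp$id)]
      mothers <- fp$mother_id[match(remaining, fp$id)]
      placed <- (is.na(fathers) | !(fathers %in% remaining)) &
        (is.na(mothers) | !(mothers %in% remaining))
      if (!any(placed)) break
      remaining <- remaining[!placed]
      if (!length(remaining)) break
    }
    if (length(remaining)) {
      abort(sprintf(
        "pedigree validation error: cyclic parentage in family %s involving %s",
        fam, paste(remaining, collapse = ", ")
      ))
    }
  }
  ped
}

#' Founders of a pedigree
#'
#' @param ped A pedigree tibble.
#' @return Character vector of ids whose parents are both missing.
#' @export
pedigree_founders <- function(ped) {
  ped$id[is.na(ped$father_id) & is.na(ped$mother_id)]
}
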