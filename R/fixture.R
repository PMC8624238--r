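# Deterministic reference fixture: a cohort whose aggregate counts equal
# the study's printed counts, used by the end-to-end acceptance checks.
# 80 subjects (60 probands, 14 children, 6 other first-degree relatives);
# DLCN bands 34 definite / 5 probable / 41 possible; 26 variant-positive
# probands split 19 LDLR / 3 APOB / 4 other genes; 12 of 14 children
# positive; definite band = 26 LDLR + 3 APOB + 5 negative; 38 positive
# subjects in total (47.5% of 80). Per-subject lipid values are synthetic
# (the study published only aggregates) and are derived from each
# subject's DLCN LDL-C input.

fixture_dlcn_inputs <- function(template) {
  # templates: definite18 / definite / probable / possible
  base <- tibble(
    fam_premature_cvd = FALSE, fam_ldl_above_p95 = FALSE,
    fam_xanthoma_or_arcus = FALSE, fam_child_ldl_above_p95 = FALSE,
    premature_cad = FALSE, premature_cerebral_or_peripheral = FALSE,
    tendon_xanthomata = FALSE, arcus_cornealis_before_45 = FALSE,
    dlcn_ldl = NA_real_, dna_functional_mutation = "untested"
  )
  out <- base[rep(1, length(template)), ]
  out$tendon_xanthomata <- template %in% c("definite18", "definite")
  out$premature_cad <- template == "definite18"
  out$fam_child_ldl_above_p95 <- template == "definite18"
  out$fam_premature_cvd <- template %in% c("probable", "possible")
  out$dlcn_ldl <- dplyr::case_match(
    template,
    "definite18" ~ 15.2, "definite" ~ 7.0, "probable" ~ 7.0,
    "possible" ~ 5.5
  )
  out
}

#' Build the deterministic reference cohort fixture
#'
#' Constructs, without any randomness in the subject/pedigree tables, a
#' cohort whose aggregate counts reproduce the study's printed numbers:
#' 80 subjects (60 probands, 20 first-degree relatives of whom 14 are
#' children), DLCN bands 34/5/41 (definite/probable/possible), 26
#' variant-positive probands (19 LDLR, 3 APOB, 4 in LPL/SREBF1/APOC3/ABCG5,
#' two of the LDLR probands compound heterozygous with DLCN score 18), 12
#' of 14 children positive, and a definite band containing 26 LDLR-positive
#' and 3 APOB-positive subjects and 5 negatives. Re-running yields
#' identical output.
#'
#' @return A list of tibbles: `subjects`, `pedigree` and `annotations`
#'   (the embedded variant spectrum plus deterministic decoys).
#' @export
build_paper_fixture <- function() {
  ldlr_ids <- c(
    "rs121908038", "rs137853964", "rs28942078", "rs539080792",
    "rs570942190", "rs755757866", "rs761954844", "rs879254566",
    "rs879254721", "rs879254980", "rs879255191"
  )
  pid <- sprintf("S%03d", 1:60)
  fam <- sprintf("F%03d", 1:60)

  proband_gene <- c(
    rep("LDLR", 19), rep("APOB", 3), "LPL", "SREBF1", "APOC3", "ABCG5",
    rep(NA_character_, 34)
  )
  proband_variants <- c(
    "rs875989907,rs879254769", "rs875989894,novel",
    rep_len(ldlr_ids, 17),
    rep("rs5742904", 3),
    "rs118204077", "rs115855236", "rs138326449", "rs145164937",
    rep(NA_character_, 34)
  )
  proband_zyg <- c(rep("compound_het", 2), rep("het", 24),
                   rep(NA_character_, 34))
  proband_band <- c(
    rep("definite18", 2), rep("definite", 14),       # S001-S016
    rep("probable", 2), "possible",                  # S017-S019
    rep("definite", 3),                              # S020-S022 APOB
    rep("possible", 4),                              # S023-S026 other genes
    rep("definite", 5),                              # S027-S031 negative
    rep("probable", 3),                              # S032-S034 negative
    rep("possible", 26)                              # S035-S060 negative
  )

  child_parent <- c(pid[1:10], "S020", "S024", "S027", "S028")
  child_id <- paste0("C", substr(child_parent, 2, 4))
  child_gene <- c(rep("LDLR", 10), "APOB", "SREBF1",
                  NA_character_, NA_character_)
  child_variants <- c(
    purrr::map_chr(strsplit(proband_variants[1:10], ","), 1),
    "rs5742904", "rs115855236", NA_character_, NA_character_
  )
  child_band <- c(rep("definite", 10), "possible", "possible",
                  "possible", "possible")

  rel_id <- c("R011S", "R011N", "R012S", "R013P", "R014P", "R001S")
  rel_fam <- c("F011", "F011", "F012", "F013", "F014", "F001")
  rel_relation <- c("sibling", "other", "sibling", "parent", "parent",
                    "sibling")
  rel_age <- c(45L, 20L, 47L, 71L, 69L, 44L)

  mk <- function(ids, fams, role, relation, sex, age, band_template,
                 status, gene, variants, zyg) {
    d <- fixture_dlcn_inputs(band_template)
    hdl <- 1.4
    tg <- 1.76
    ldl <- d$dlcn_ldl
    tibble(
      subject_id = ids, family_id = fams, role = role, relation = relation,
      sex = sex, age = as.integer(age),
      tc = ldl + hdl + tg / 2.2, tg = tg, hdl = hdl, ldl = ldl,
      ldl_method = ifelse(ldl > 4.5, "direct", "friedewald"),
      on_lipid_lowering = rep_len(c(TRUE, FALSE, FALSE), length(ids)),
      d,
      genetic_status = status, gene = gene, variant_ids = variants,
      zygosity = zyg
    )
  }

  subjects <- bind_rows(
    mk(pid, fam, "proband", "self",
       rep_len(c("F", "M"), 60), rep_len(c(44L, 51L, 38L, 57L), 60),
       proband_band,
       ifelse(is.na(proband_gene), "negative", "positive"),
       proband_gene, proband_variants, proband_zyg),
    mk(child_id, paste0("F", substr(child_parent, 2, 4)), "relative",
       "child", rep_len(c("M", "F"), 14), rep_len(c(8L, 13L, 16L, 11L), 14),
       child_band,
       ifelse(is.na(child_gene), "negative", "positive"),
       child_gene, child_variants,
       ifelse(is.na(child_gene), NA_character_, "het")),
    mk(rel_id, rel_fam, "relative", rel_relation,
       rep_len(c("M", "F"), 6), rel_age,
       rep("possible", 6), "negative",
       NA_character_, NA_character_, NA_character_)
  )

  pedigree <- fixture_pedigree(pid, fam, child_parent, child_id)
  list(
    subjects = validate_subjects(subjects),
    pedigree = validate_pedigree(pedigree),
    annotations = gen_annotation_table(fh_sim_params(), seed = 101L)
  )
}

fixture_pedigree <- function(pid, fam, child_parent, child_id) {
  proband_sex <- rep_len(c("F", "M"), 60)
  names(proband_sex) <- pid
  rows <- list()
  add <- function(family_id, id, father = NA_character_,
                  mother = NA_character_, sex = NA_character_,
                  affected = NA) {
    rows[[length(rows) + 1L]] <<- tibble(
      family_id = family_id, id = id, father_id = father,
      mother_id = mother, sex = sex, affected = affected
    )
  }
  # probands (S011-S014 are re-parented below to attach their relatives)
  for (i in seq_along(pid)) {
    if (pid[i] %in% c("S011", "S012", "S013", "S014")) next
    add(fam[i], pid[i], sex = proband_sex[i], affected = NA)
  }
  # families with a child subject: add a spouse founder and the child
  for (k in seq_along(child_parent)) {
    p <- child_parent[k]
    f <- paste0("F", substr(p, 2, 4))
    sp <- paste0(p, "-SP")
    add(f, sp, sex = ifelse(proband_sex[p] == "F", "M", "F"),
        affected = FALSE)
    fa <- if (proband_sex[p] == "M") p else sp
    mo <- if (proband_sex[p] == "F") p else sp
    add(f, child_id[k], father = fa, mother = mo,
        sex = rep_len(c("M", "F"), 14)[k], affected = NA)
  }
  # F011: proband + sibling (shared founder parents) + the sibling's child
  add("F011", "F011-FA", sex = "M"); add("F011", "F011-MO", sex = "F")
  add("F011", "S011", "F011-FA", "F011-MO", proband_sex["S011"])
  add("F011", "R011S", "F011-FA", "F011-MO", "M")
  add("F011", "R011S-SP", sex = "F", affected = FALSE)
  add("F011", "R011N", "R011S", "R011S-SP", "M")
  # F012: proband + sibling
  add("F012", "F012-FA", sex = "M"); add("F012", "F012-MO", sex = "F")
  add("F012", "S012", "F012-FA", "F012-MO", proband_sex["S012"])
  add("F012", "R012S", "F012-FA", "F012-MO", "F")
  # F013 / F014: proband + one parent subject (other parent is a founder
  # placeholder)
  add("F013", "R013P", sex = "M"); add("F013", "F013-MO", sex = "F")
  add("F013", "S013", "R013P", "F013-MO", proband_sex["S013"])
  add("F014", "R014P", sex = "F"); add("F014", "F014-FA", sex = "M")
  add("F014", "S014", "F014-FA", "R014P", proband_sex["S014"])
  # F001 also carries a sibling of the proband
  add("F001", "F001-FA", sex = "M"); add("F001", "F001-MO", sex = "F")
  add("F001", "R001S", "F001-FA", "F001-MO", "M")
  ped <- purrr::list_rbind(rows)
  # S001's row was added without parents; attach it to the F001 founders
  # so the sibling link resolves
  ped$father_id[ped$id == "S001"] <- "F001-FA"
  ped$mother_id[ped$id == "S001"] <- "F001-MO"
  ped
}

#' Write the reference fixture to a directory
#'
#' Writes `subjects.tsv`, `pedigree.ped` and `annotations.tsv` from
#' [build_paper_fixture()]. Re-running produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_paper_fixture <- function(dir) {
  fx <- build_paper_fixture()
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_subject_table(fx$subjects, file.path(dir, "subjects.tsv"))
  write_pedigree(fx$pedigree, file.path(dir, "pedigree.ped"))
  readr::write_tsv(fx$annotations, file.path(dir, "annotations.tsv"),
                   na = "NA", progress = FALSE)
  invisible(dir)
}
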