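# Synthetic-data generation: the embedded reference variant spectrum, a
# cohort generator emulating the study population's statistical structure,
# an annotation-table generator with common/benign decoys, and an MLPA run
# generator.

#' The embedded reference variant spectrum
#'
#' The 20 variant records of the study's printed spectrum, verbatim:
#' identifiers, GRCh38 1-based positions as printed, coding-DNA and protein
#' changes, gnomAD minor allele frequencies (absent = not observed, `NA`)
#' and clinical assertions mapped onto canonical tokens (`pathogenic`,
#' `likely_pathogenic`, `conflicting`, `uncertain`, `not_reported`). The
#' `pred_*` and `cons_*` columns are SYNTHETIC stand-ins for per-tool
#' annotations (the in-silico tools themselves are not run here);
#' `null_variant` flags protein-null alleles (nonsense, canonical +/-1,2
#' splice).
#'
#' @return An annotated variant tibble with one row per (variant, alt).
#' @export
table2_variants <- function() {
  v <- tibble::tribble(
    ~patient_ids, ~variant_id, ~chrom, ~pos, ~gene, ~hgvs_c, ~hgvs_p,
    ~af_gnomad, ~clinvar, ~hgmd_id, ~null_variant,
    "P28,P40,P41,P42,P55,P56", "rs121908038", "19", 11113293L, "LDLR",
      "c.1202T>A", "p.Leu401His", NA, "likely_pathogenic", NA, FALSE,
    "P45", "rs137853964", "19", 11129602L, "LDLR",
      "c.2479G>A", "p.Val827Ile", 0.001006, "likely_pathogenic", NA, FALSE,
    "P22,P36,P58", "rs28942078", "19", 11113376L, "LDLR",
      "c.1285G>A", "p.Val429Met", 0.000012, "likely_pathogenic", NA, FALSE,
    "P65", "rs539080792", "19", 11221396L, "LDLR",
      "c.1009G>A", "p.Glu337Lys", 0.000104, "uncertain", NA, FALSE,
    "P47", "rs570942190", "19", 11113337L, "LDLR",
      "c.1246C>T", "p.Arg416Trp", 0.000024, "not_reported", NA, FALSE,
    "P67,P68", "rs755757866", "19", 11110730L, "LDLR",
      "c.1019G>T", "p.Cys340Tyr", 0.000008, "likely_pathogenic", NA, FALSE,
    "P7", "rs761954844", "19", 11110697L, "LDLR",
      "c.986G>A", "p.Cys329Tyr", 0.000016, "likely_pathogenic", NA, FALSE,
    "P35", "rs879254566", "19", 11105440L, "LDLR",
      "c.534TT>G", "p.Asp178Glu", NA, "likely_pathogenic", NA, FALSE,
    "P38,P39", "rs879254721", "19", 11107496L, "LDLR",
      "c.922G>A", "p.Glu308Lys", NA, "pathogenic", NA, FALSE,
    "P2", "rs879254980", "19", 11116179L, "LDLR",
      "c.1672G>T", "p.Glu558Ter", NA, "pathogenic", NA, TRUE,
    "P24,P25,P26,P81,P82", "rs879255191", "19", 11128090L, "LDLR",
      "c.2389+5G>A", NA, NA, "conflicting", NA, FALSE,
    "P52", "rs875989907", "19", 11106666L, "LDLR",
      "c.796G>A", "p.Asp266Asn", 0.000012, "pathogenic", NA, FALSE,
    "P52", "rs879254769", "19", 11110765L, "LDLR",
      "c.1054T>C", "p.Cys352Ser", NA, "likely_pathogenic", NA, FALSE,
    "P10", "rs875989894", "19", 11213415L, "LDLR",
      "c.266G>C", "p.Cys89Ser", NA, "likely_pathogenic", NA, FALSE,
    "P10", "novel", "19", 11222252L, "LDLR",
      "c.1123T>G", "p.Tyr375Asp", NA, "not_reported", NA, FALSE,
    "P11,P15,P71", "rs5742904", "2", 21006288L, "APOB",
      "c.10580G>A", "p.Arg3527Gln", 0.000275, "pathogenic", NA, FALSE,
    "P74", "rs145164937", "2", 43832056L, "ABCG5",
      "c.293C>G", "p.Ala98Gly", 0.002223, "conflicting", "CM169023", FALSE,
    "P59", "rs138326449", "11", 116830638L, "APOC3",
      "c.55+1G>A", NA, 0.002244, "conflicting", NA, TRUE,
    "P9", "rs118204077", "8", 19955873L, "LPL",
      "c.808C>T", "p.Arg270Cys", 0.0001, "pathogenic", "CM941054", FALSE,
    "P83,P84", "rs115855236", "17", 17820281L, "SREBF1",
      "c.422C>T", "p.Pro141Leu", 0.001210, "not_reported", NA, FALSE
  )
  # ref/alt from the coding-DNA change (plumbing; strand bookkeeping is
  # not needed by any downstream step)
  m <- stringr::str_match(v$hgvs_c, "([ACGT]+)>([ACGT]+)$")
  v$ref <- m[, 2]
  v$alt <- m[, 3]
  v$zygosity <- "het"
  # synthetic in-silico columns: damaging/conserved for missense records,
  # unknown for the two splice-region records
  missense <- !is.na(v$hgvs_p)
  v$pred_sift <- ifelse(missense, "damaging", "unknown")
  v$pred_polyphen2 <- ifelse(missense, "damaging", "unknown")
  v$pred_mutation_taster <- ifelse(missense, "damaging", "unknown")
  v$cons_gerp <- ifelse(missense, 5.2, 4.8)
  v$cons_phastcons <- ifelse(missense, 0.98, 0.95)
  select(v, "variant_id", "chrom", "pos", "ref", "alt", "gene", "hgvs_c",
         "hgvs_p", "af_gnomad", "clinvar", "hgmd_id", "zygosity",
         "null_variant", "patient_ids", dplyr::starts_with("pred_"),
         dplyr::starts_with("cons_"))
}

# truncated normal via inverse-CDF sampling
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (!(lower < upper)) abort("unreachable truncation bounds")
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(p, mean, sd)
}

# log-normal with meanlog/sdlog matched to the target arithmetic moments
rlnorm_matched <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulation parameters for the synthetic cohort generator
#'
#' Defaults encode the emulated study conditions: 60 probands with ~14
#' children in total (rate 14/60 per proband), proband-level molecular
#' yield 26/60, 41% of subjects on lipid-lowering therapy, total
#' cholesterol 8.6 +/- 3.4 mmol/L and HDL-C 1.4 +/- 0.4 mmol/L (truncated
#' normal, symmetric +/- 2.5 SD bounds so the stated mean is preserved),
#' triglycerides log-normal with arithmetic moments 1.8 +/- 1.4 mmol/L,
#' variant spectrum weighted by the per-variant patient counts of the
#' embedded [table2_variants()] table, and a carrier total-cholesterol
#' shift of +3 mmol/L (a generator-only assumption; doubled for compound
#' heterozygotes).
#'
#' @param ... Overrides of the default elements.
#' @return Named list of parameters.
#' @export
fh_sim_params <- function(...) {
  t2 <- table2_variants()
  spectrum <- tibble(
    gene = t2$gene, variant_id = t2$variant_id,
    weight = purrr::map_int(strsplit(t2$patient_ids, ","), length)
  )
  p <- list(
    n_probands = 60L,
    children_rate = 14 / 60,
    p_positive = 26 / 60,
    pct_on_therapy = 0.41,
    pct_xanthomas = 0.42,
    tc_mean = 8.6, tc_sd = 3.4, tc_trunc_sd = 2.5,
    tg_mean = 1.8, tg_sd = 1.4,
    hdl_mean = 1.4, hdl_sd = 0.4, hdl_trunc_sd = 2.5,
    carrier_tc_shift = 3.0,
    spectrum = spectrum,
    n_background = 30L,
    n_benign_decoys = 10L,
    mlpa_event_rate = 0.15,
    noise_sd = 0.05,
    seed = 1L
  )
  modifyList(p, list(...))
}

empty_subjects <- function() {
  as_tibble(setNames(
    lapply(subject_all_cols, function(x) character(0)), subject_all_cols
  ))
}

#' Generate a synthetic cohort
#'
#' Draws a cohort emulating the study's statistical structure: probands
#' with lipid profiles from the configured distributions, molecular results
#' drawn from the embedded variant spectrum, children generated per
#' pedigree and genotyped by Mendelian gene dropping
#' ([simulate_transmission()]), carrier lipid shifts, DLCN criteria inputs
#' with realistic prevalence, and a matching annotation table. Fully
#' deterministic given `seed`.
#'
#' @param params Parameter list from [fh_sim_params()].
#' @param seed Integer seed (default `params$seed`).
#' @return A list with tibbles `subjects`, `pedigree` and `annotations`,
#'   all passing the package validators.
#' @export
gen_cohort <- function(params = fh_sim_params(), seed = params$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- as.integer(params$n_probands)
  if (n == 0L) {
    return(list(
      subjects = empty_subjects(),
      pedigree = tibble(family_id = character(), id = character(),
                        father_id = character(), mother_id = character(),
                        sex = character(), affected = logical()),
      annotations = gen_annotation_table(params, seed = seed + 1L)
    ))
  }
  pid <- sprintf("SIM%04d", seq_len(n))
  fam <- sprintf("FAM%04d", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  carrier <- rbinom(n, 1L, params$p_positive) == 1L
  spec <- params$spectrum
  vix <- sample(nrow(spec), n, replace = TRUE, prob = spec$weight)

  n_children <- rpois(n, params$children_rate)
  child_rows <- tibble(
    parent = rep(seq_len(n), n_children)
  ) |>
    mutate(
      id = sprintf("%s-C%d", pid[.data$parent],
                   sequence(n_children[n_children > 0])),
      family_id = fam[.data$parent],
      sex = sample(c("F", "M"), dplyr::n(), replace = TRUE)
    )

  # pedigree: proband + an unsampled spouse founder per family with
  # children; children link to both
  spouse_needed <- which(n_children > 0)
  ped <- bind_rows(
    tibble(family_id = fam, id = pid, father_id = NA_character_,
           mother_id = NA_character_, sex = sex, affected = carrier),
    tibble(family_id = fam[spouse_needed],
           id = paste0(pid[spouse_needed], "-SP"),
           father_id = NA_character_, mother_id = NA_character_,
           sex = as.character(ifelse(sex[spouse_needed] == "F", "M", "F")),
           affected = FALSE),
    tibble(family_id = child_rows$family_id, id = child_rows$id,
           father_id = as.character(ifelse(sex[child_rows$parent] == "M",
                                           pid[child_rows$parent],
                                           paste0(pid[child_rows$parent],
                                                  "-SP"))),
           mother_id = as.character(ifelse(sex[child_rows$parent] == "F",
                                           pid[child_rows$parent],
                                           paste0(pid[child_rows$parent],
                                                  "-SP"))),
           sex = child_rows$sex, affected = NA)
  )
  founder_carriers <- setNames(as.integer(carrier), pid)
  trans <- simulate_transmission(ped, founder_carriers, seed = seed + 17L)
  child_carrier <- trans$carrier[match(child_rows$id, trans$id)]

  make_lipids <- function(m, is_carrier) {
    tc <- rtrunc_norm(m, params$tc_mean, params$tc_sd,
                      params$tc_mean - params$tc_trunc_sd * params$tc_sd,
                      params$tc_mean + params$tc_trunc_sd * params$tc_sd)
    tc <- pmax(tc, 0.5)
    hdl <- rtrunc_norm(m, params$hdl_mean, params$hdl_sd,
                       params$hdl_mean - params$hdl_trunc_sd * params$hdl_sd,
                       params$hdl_mean + params$hdl_trunc_sd * params$hdl_sd)
    tg <- rlnorm_matched(m, params$tg_mean, params$tg_sd)
    tc <- tc + ifelse(is_carrier, params$carrier_tc_shift, 0)
    fried <- tc - hdl - tg / 2.2
    valid <- tg <= 4.5 & fried > 0.1
    # fallback "direct measurement" when the formula is invalid: a plausible
    # LDL fraction of TC, kept strictly inside (0, tc)
    ldl <- ifelse(valid, fried, pmax(pmin(0.6 * tc, tc - 0.1), 0.2 * tc))
    ldl_method <- ifelse(valid & fried <= 4.5, "friedewald", "direct")
    tibble(tc = tc, tg = tg, hdl = hdl, ldl = ldl, ldl_method = ldl_method)
  }

  build_rows <- function(ids, family_ids, role, relation, sex, age, carrier,
                         gene, variant_id) {
    m <- length(ids)
    lip <- make_lipids(m, carrier)
    tibble(
      subject_id = ids, family_id = family_ids, role = role,
      relation = relation, sex = sex, age = as.integer(age), lip,
      on_lipid_lowering = rbinom(m, 1L, params$pct_on_therapy) == 1L,
      fam_premature_cvd = rbinom(m, 1L, 0.45) == 1L,
      fam_ldl_above_p95 = rbinom(m, 1L, 0.5) == 1L,
      fam_xanthoma_or_arcus = rbinom(m, 1L, 0.15) == 1L,
      fam_child_ldl_above_p95 = rbinom(m, 1L, 0.2) == 1L,
      premature_cad = rbinom(m, 1L, 0.2) == 1L,
      premature_cerebral_or_peripheral = rbinom(m, 1L, 0.08) == 1L,
      tendon_xanthomata = rbinom(m, 1L, params$pct_xanthomas) == 1L,
      arcus_cornealis_before_45 = rbinom(m, 1L, 0.1) == 1L,
      dlcn_ldl = lip$ldl,
      dna_functional_mutation = "untested",
      genetic_status = ifelse(carrier, "positive", "negative"),
      gene = ifelse(carrier, gene, NA_character_),
      variant_ids = ifelse(carrier, variant_id, NA_character_),
      zygosity = ifelse(carrier, "het", NA_character_)
    )
  }

  probands <- build_rows(
    pid, fam, "proband", "self", sex,
    sample(20:73, n, replace = TRUE), carrier,
    spec$gene[vix], spec$variant_id[vix]
  )
  children <- if (nrow(child_rows)) {
    build_rows(
      child_rows$id, child_rows$family_id, "relative", "child",
      child_rows$sex, sample(5:17, nrow(child_rows), replace = TRUE),
      child_carrier, spec$gene[vix[child_rows$parent]],
      spec$variant_id[vix[child_rows$parent]]
    )
  } else {
    NULL
  }
  subjects <- bind_rows(probands, children)
  list(
    subjects = validate_subjects(subjects),
    pedigree = validate_pedigree(ped),
    annotations = gen_annotation_table(params, seed = seed + 1L)
  )
}

#' Generate an annotation table with embedded spectrum and decoys
#'
#' Emits the embedded [table2_variants()] records verbatim, plus
#' configurable common background variants (allele frequencies drawn in
#' 0.01--0.5) and rare benign / likely-benign decoys. At the default filter
#' configuration the cascade retains exactly the embedded records: the
#' backgrounds fail the rarity step and the decoys the assertion step.
#'
#' @param params Parameter list ([fh_sim_params()]); uses `n_background`
#'   and `n_benign_decoys`.
#' @param seed Integer seed.
#' @return An annotated variant tibble; duplicated (chrom, pos, alt) keys
#'   raise an error.
#' @export
gen_annotation_table <- function(params = fh_sim_params(),
                                 seed = params$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t2 <- select(table2_variants(), -"patient_ids")
  bases <- c("A", "C", "G", "T")
  mk_bg <- function(m, prefix, af_range, clinvar_pool) {
    if (m == 0L) return(NULL)
    ref <- sample(bases, m, replace = TRUE)
    alt <- purrr::map_chr(ref, function(r) sample(setdiff(bases, r), 1))
    tibble(
      variant_id = sprintf("%s%03d", prefix, seq_len(m)),
      chrom = as.character(sample(1:22, m, replace = TRUE)),
      pos = sample(5e7:6e7, m),
      ref = ref, alt = alt,
      gene = sprintf("GENE%02d", sample(1:40, m, replace = TRUE)),
      hgvs_c = NA_character_, hgvs_p = NA_character_,
      af_gnomad = runif(m, af_range[1], af_range[2]),
      clinvar = sample(clinvar_pool, m, replace = TRUE),
      hgmd_id = NA_character_, zygosity = "het", null_variant = FALSE,
      pred_sift = "tolerated", pred_polyphen2 = "tolerated",
      pred_mutation_taster = "tolerated",
      cons_gerp = runif(m, -2, 1), cons_phastcons = runif(m, 0, 0.3)
    )
  }
  bg <- mk_bg(as.integer(params$n_background), "common", c(0.01, 0.5),
              c("not_reported", "uncertain", "benign"))
  decoys <- mk_bg(as.integer(params$n_benign_decoys), "decoy",
                  c(1e-5, 0.004), c("benign", "likely_benign"))
  out <- bind_rows(t2, bg, decoys)
  key <- paste(out$chrom, out$pos, out$alt)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate variant record at %s",
                  key[which(duplicated(key))[1]]))
  }
  out
}

#' Generate a synthetic MLPA run
#'
#' Builds a probe set (one promoter probe, one probe per exon 1--18, eight
#' reference probes), control samples, and `n_samples` test samples.
#' Each peak is `baseline * copy_ratio * exp(N(0, noise_sd))`; reference
#' probes always have copy ratio 1, and target probes have the ratio of
#' any event covering their exon (heterozygous deletion 0.5, heterozygous
#' duplication 1.5). Deterministic given `seed`.
#'
#' @param n_samples Number of test samples (`S0001`, ...).
#' @param events Tibble with columns `sample_id`, `exon_start`, `exon_end`,
#'   `copy_ratio` (> 0). May be empty.
#' @param noise_sd Standard deviation of the multiplicative log-normal
#'   noise (0 = exact copy ratios).
#' @param seed Integer seed.
#' @param n_controls Number of control samples.
#' @param n_exons Number of exon target probes.
#' @return An MLPA run tibble for [normalize_run()].
#' @export
gen_mlpa_run <- function(n_samples, events = NULL, noise_sd = 0, seed = 1L,
                         n_controls = 6L, n_exons = 18L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  samples <- sprintf("S%04d", seq_len(n_samples))
  if (!is.null(events) && nrow(events)) {
    if (any(events$copy_ratio <= 0)) abort("copy_ratio must be > 0")
    unknown <- setdiff(events$sample_id, samples)
    if (length(unknown)) {
      abort(paste0("event references unknown sample(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  probes <- tibble(
    probe_id = c("pr_promoter", sprintf("pr_ex%02d", seq_len(n_exons)),
                 sprintf("pr_ref%02d", 1:8)),
    target = c("promoter", as.character(seq_len(n_exons)),
               rep(NA_character_, 8)),
    is_reference = c(rep(FALSE, n_exons + 1L), rep(TRUE, 8)),
    baseline = 500 + 37 * seq_len(n_exons + 9L)
  )
  all_samples <- tibble(
    sample_id = c(sprintf("CTRL%02d", seq_len(n_controls)), samples),
    role = c(rep("control", n_controls), rep("test", n_samples))
  )
  run <- tidyr::crossing(all_samples, probes) |>
    mutate(copy_ratio = 1)
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ex <- suppressWarnings(as.integer(run$target))
      hit <- run$sample_id == events$sample_id[i] & !run$is_reference &
        !is.na(ex) & ex >= events$exon_start[i] & ex <= events$exon_end[i]
      run$copy_ratio[hit] <- events$copy_ratio[i]
    }
  }
  noise <- if (noise_sd > 0) exp(rnorm(nrow(run), 0, noise_sd)) else 1
  run |>
    mutate(peak = .data$baseline * .data$copy_ratio * noise) |>
    select("sample_id", "role", "probe_id", "target", "is_reference",
           "peak")
}
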