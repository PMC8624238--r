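# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Hand-coded nested-if decision procedure for the evidence-combination
# rules: classification from the per-category counts.
oracle_acmg <- function(pvs, ps, pm, pp, ba, bs, bp) {
  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
    (ps >= 2) ||
    (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm >= 1) ||
    (ps >= 1 && pm >= 1) ||
    (ps >= 1 && pp >= 2) ||
    (pm >= 3) ||
    (pm >= 2 && pp >= 2) ||
    (pm >= 1 && pp >= 4)
  benign <- (ba >= 1) || (bs >= 2)
  likely_benign <- (bs >= 1 && bp >= 1) || (bp >= 2)

  path_side <- pathogenic || likely_pathogenic
  ben_side <- benign || likely_benign
  if (path_side && ben_side) return("uncertain_significance")
  if (!path_side && !ben_side) return("uncertain_significance")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  "likely_benign"
}

# bounded evidence grid shared by the unit and acceptance suites
acmg_grid <- function() {
  expand.grid(
    pvs = 0:1, ps = 0:3, pm = 0:4, pp = 0:5, ba = 0:1, bs = 0:3, bp = 0:3
  )
}

# distinct code names realizing a count vector (paste0 with a zero-length
# vector would yield a bare prefix, hence the guards)
codes_from_counts <- function(pvs, ps, pm, pp, ba, bs, bp) {
  lab <- function(prefix, k) if (k > 0) paste0(prefix, seq_len(k)) else NULL
  c(
    rep("PVS1", pvs), lab("PS", ps), lab("PM", pm), lab("PP", pp),
    rep("BA1", ba), lab("BS", bs), lab("BP", bp)
  )
}

# explicit DFS cycle detector over (id -> parents) edges
oracle_has_cycle <- function(ids, father, mother) {
  parents <- function(i) {
    p <- c(father[i], mother[i])
    p[!is.na(p)]
  }
  state <- setNames(rep(0L, length(ids)), ids)  # 0 new, 1 active, 2 done
  visit <- function(id) {
    if (state[id] == 1L) return(TRUE)
    if (state[id] == 2L) return(FALSE)
    state[id] <<- 1L
    for (p in parents(match(id, ids))) {
      if (p %in% ids && visit(p)) return(TRUE)
    }
    state[id] <<- 2L
    FALSE
  }
  any(vapply(ids, visit, logical(1)))
}

# brute-force re-binning of DLCN totals
oracle_band_counts <- function(totals) {
  band <- ifelse(totals > 8, "definite",
                 ifelse(totals >= 6, "probable",
                        ifelse(totals >= 3, "possible", "unlikely")))
  table(factor(band, levels = c("unlikely", "possible", "probable",
                                "definite")))
}

# random DLCN criteria inputs
random_dlcn_inputs <- function(n) {
  tibble::tibble(
    fam_premature_cvd = sample(c(TRUE, FALSE), n, replace = TRUE),
    fam_ldl_above_p95 = sample(c(TRUE, FALSE), n, replace = TRUE),
    fam_xanthoma_or_arcus = sample(c(TRUE, FALSE), n, replace = TRUE),
    fam_child_ldl_above_p95 = sample(c(TRUE, FALSE), n, replace = TRUE),
    premature_cad = sample(c(TRUE, FALSE), n, replace = TRUE),
    premature_cerebral_or_peripheral = sample(c(TRUE, FALSE), n, replace = TRUE),
    tendon_xanthomata = sample(c(TRUE, FALSE), n, replace = TRUE),
    arcus_cornealis_before_45 = sample(c(TRUE, FALSE), n, replace = TRUE),
    dlcn_ldl = ifelse(runif(n) < 0.1, NA_real_, runif(n, 0.5, 12)),
    dna_functional_mutation = sample(c("yes", "no", "untested"), n,
                                     replace = TRUE)
  )
}

# expected DLCN group subscores computed independently (max-of-satisfied)
oracle_dlcn_total <- function(row) {
  fam <- max(0, row$fam_premature_cvd * 1, row$fam_ldl_above_p95 * 1,
             row$fam_xanthoma_or_arcus * 2, row$fam_child_ldl_above_p95 * 2)
  cli <- max(0, row$premature_cad * 2,
             row$premature_cerebral_or_peripheral * 1)
  phy <- max(0, row$tendon_xanthomata * 6,
             row$arcus_cornealis_before_45 * 4)
  ldl <- if (is.na(row$dlcn_ldl)) 0
    else if (row$dlcn_ldl >= 8.5) 8
    else if (row$dlcn_ldl >= 6.5) 5
    else if (row$dlcn_ldl >= 5.0) 3
    else if (row$dlcn_ldl >= 4.0) 1
    else 0
  dna <- if (row$dna_functional_mutation == "yes") 8 else 0
  fam + cli + phy + ldl + dna
}

# small five-member pedigree mirroring a proband with two children, a
# sibling and the sibling's child
family_fixture_ped <- function() {
  tibble::tibble(
    family_id = "FAM1",
    id = c("GF", "GM", "PRO", "PRO-SP", "CH1", "CH2", "SIB", "SIB-SP", "NEP"),
    father_id = c(NA, NA, "GF", NA, "PRO", "PRO", "GF", NA, "SIB"),
    mother_id = c(NA, NA, "GM", NA, "PRO-SP", "PRO-SP", "GM", NA, "SIB-SP"),
    sex = c("M", "F", "M", "F", "F", "M", "M", "F", "M"),
    affected = NA
  )
}

write_ped_lines <- function(lines, path = tempfile(fileext = ".ped")) {
  writeLines(lines, path)
  path
}

# minimal annotated-record builder shared across files
make_record <- function(variant_id = "v1", chrom = "1", pos = 100L,
                        ref = "A", alt = "G", gene = "LDLR",
                        af_gnomad = NA_real_, clinvar = "not_reported",
                        pred = c("damaging", "damaging", "damaging"),
                        cons = 5, hgvs_c = NA, hgvs_p = NA,
                        null_variant = FALSE) {
  tibble::tibble(
    variant_id = variant_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = gene, hgvs_c = hgvs_c, hgvs_p = hgvs_p, af_gnomad = af_gnomad,
    clinvar = clinvar, zygosity = "het", null_variant = null_variant,
    pred_sift = pred[1], pred_polyphen2 = pred[2],
    pred_mutation_taster = pred[3], cons_gerp = cons
  )
}

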