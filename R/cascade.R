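# Cascade screening over pedigrees and cohort-level detection-yield
# summaries.

#' Round half-up to one decimal
#'
#' Percentage rounding used throughout the summaries (half-up, matching
#' clinical reporting convention, unlike base R's banker's rounding).
#'
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

pct <- function(num, denom) {
  denom <- rep_len(denom, length(num))
  out <- round_half_up(100 * num / denom)
  out[is.na(denom) | denom <= 0] <- NA_real_
  out
}

# first-degree relatives of `ids` within one family's pedigree:
# parents, children, and siblings (sharing >= 1 recorded parent)
first_degree <- function(ped, ids) {
  rows <- ped[ped$id %in% ids, , drop = FALSE]
  parents <- c(rows$father_id, rows$mother_id)
  children <- ped$id[ped$father_id %in% ids | ped$mother_id %in% ids]
  sibs <- character()
  for (i in seq_len(nrow(rows))) {
    ps <- c(rows$father_id[i], rows$mother_id[i])
    ps <- ps[!is.na(ps)]
    if (length(ps)) {
      sibs <- c(sibs, ped$id[ped$father_id %in% ps | ped$mother_id %in% ps])
    }
  }
  setdiff(unique(c(parents[!is.na(parents)], children, sibs)), ids)
}

#' Propose a cascade genetic screening plan
#'
#' Builds the testing waves for one family: wave 1 holds the untested
#' first-degree relatives (parents, siblings, children) of the proband;
#' each subsequent wave holds the untested first-degree relatives of the
#' individuals who tested positive in the previous wave. The plan
#' terminates when a wave would be empty; no individual is proposed twice
#' and the proband is never proposed.
#'
#' @param ped A pedigree tibble ([read_pedigree()]).
#' @param proband_id Id of the proband; must be present in the pedigree.
#' @param results Known genetic results: a tibble with columns
#'   `subject_id` and `genetic_status` ("positive"/"negative"/"untested"),
#'   or a named character vector. Individuals absent from `results` count
#'   as untested. The proband is assumed positive.
#' @return An object of class `fh_cascade_plan`: a tibble `wave`,
#'   `subject_id`, with attributes `proband_id`.
#' @export
propose_cascade <- function(ped, proband_id, results = NULL) {
  ped <- as_tibble(ped)
  if (!proband_id %in% ped$id) {
    abort(sprintf("proband '%s' is not in the pedigree", proband_id))
  }
  ped <- ped[ped$family_id == ped$family_id[match(proband_id, ped$id)], ]
  status <- rep("untested", nrow(ped))
  names(status) <- ped$id
  if (!is.null(results)) {
    if (is.data.frame(results)) {
      results <- setNames(results$genetic_status, results$subject_id)
    }
    hit <- intersect(names(results), names(status))
    status[hit] <- results[hit]
  }
  status[proband_id] <- "positive"

  proposed <- character()
  waves <- list()
  pos_frontier <- proband_id     # positives whose relatives seed this wave
  seen <- proband_id
  repeat {
    if (!length(pos_frontier)) break
    candidates <- setdiff(first_degree(ped, pos_frontier), seen)
    seen <- c(seen, candidates)
    wave <- sort(candidates[status[candidates] == "untested"])
    # relatives already known positive are not re-proposed but their own
    # first-degree relatives seed the next wave
    pos_frontier <- candidates[status[candidates] == "positive"]
    if (length(wave)) {
      waves[[length(waves) + 1L]] <- wave
      proposed <- c(proposed, wave)
    } else if (!length(pos_frontier)) {
      break
    }
  }
  plan <- if (length(waves)) {
    purrr::imap(waves, function(ids, w) tibble(wave = w, subject_id = ids)) |>
      purrr::list_rbind()
  } else {
    tibble(wave = integer(), subject_id = character())
  }
  structure(plan, class = c("fh_cascade_plan", class(plan)),
            proband_id = proband_id)
}

gene_group <- function(gene) {
  dplyr::case_when(
    gene %in% c("LDLR", "APOB") ~ gene,
    is.na(gene) ~ NA_character_,
    .default = "other"
  )
}

#' Summarize molecular detection yield of a cohort
#'
#' Computes the cohort-level detection yields from a subject table with
#' genetic results: overall subject-level yield, the per-gene split among
#' variant-positive probands (LDLR / APOB / other lipid-metabolism genes,
#' plus exact per-gene counts), and the yield among children of probands.
#' A subject is variant-positive when `genetic_status == "positive"`;
#' compound heterozygotes count once. Percentages are rounded half-up to
#' one decimal; a zero denominator yields `NA` (undefined, not 0) and is
#' flagged.
#'
#' @param subjects A validated subject tibble.
#' @return An `fh_cohort_summary` object (a list of tibbles plus headline
#'   counts). `glance()` gives a one-row headline tibble; `tidy()` a long
#'   table of every count/percentage.
#' @export
summarize_cohort <- function(subjects) {
  subjects <- as_tibble(subjects)
  pos <- !is.na(subjects$genetic_status) & subjects$genetic_status == "positive"
  is_proband <- subjects$role == "proband"
  is_child <- subjects$role == "relative" & subjects$relation == "child"

  n_subjects <- nrow(subjects)
  n_pos <- sum(pos)
  pos_probands <- subjects[pos & is_proband, , drop = FALSE]

  by_gene <- pos_probands |>
    count(gene = .data$gene, name = "n") |>
    mutate(percent = pct(.data$n, nrow(pos_probands)))
  by_group <- pos_probands |>
    count(gene_group = gene_group(.data$gene), name = "n") |>
    mutate(percent = pct(.data$n, nrow(pos_probands)))

  children <- tibble(
    n = sum(is_child),
    n_positive = sum(is_child & pos),
    percent = pct(sum(is_child & pos), sum(is_child))
  )

  structure(
    list(
      n_subjects = n_subjects,
      n_probands = sum(is_proband),
      n_variant_positive = n_pos,
      subject_yield_percent = pct(n_pos, n_subjects),
      n_positive_probands = nrow(pos_probands),
      by_gene = by_gene,
      by_gene_group = by_group,
      children = children,
      flags = c(
        if (n_subjects == 0) "subject yield undefined (empty cohort)",
        if (nrow(pos_probands) == 0) "per-gene split undefined (no positive probands)",
        if (sum(is_child) == 0) "children yield undefined (no children)"
      )
    ),
    class = "fh_cohort_summary"
  )
}

#' @export
print.fh_cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<fh_cohort_summary> %d subjects (%d probands); %d variant-positive (%.1f%%)\n",
    x$n_subjects, x$n_probands, x$n_variant_positive,
    x$subject_yield_percent
  ))
  cat("per-gene split among variant-positive probands:\n")
  print(x$by_gene_group)
  cat(sprintf("children of probands: %d/%d positive (%s%%)\n",
              x$children$n_positive, x$children$n,
              format(x$children$percent)))
  for (f in x$flags) cat("note:", f, "\n")
  invisible(x)
}

#' Cross-tabulate DLCN band against molecular result
#'
#' For subjects carrying both a DLCN band and a genetic result, counts
#' within each band the subjects positive in LDLR, in APOB, in another
#' gene, and the negatives, with within-band percentages (half-up, one
#' decimal). Subjects lacking a band are excluded with a warning naming
#' their number.
#'
#' @param subjects A subject tibble with columns `band`, `genetic_status`
#'   and `gene` (e.g. the subject table joined with [score_dlcn()] output).
#' @return A tibble `band`, `category` ("LDLR"/"APOB"/"other"/"negative"),
#'   `n`, `band_n`, `percent`.
#' @export
crosstab_dlcn_by_result <- function(subjects) {
  subjects <- as_tibble(subjects)
  no_band <- is.na(subjects$band)
  if (any(no_band)) {
    warn(sprintf("%d subject(s) lack a DLCN band and were excluded",
                 sum(no_band)))
    subjects <- subjects[!no_band, , drop = FALSE]
  }
  if (!nrow(subjects)) {
    return(tibble(band = character(), category = character(),
                  n = integer(), band_n = integer(), percent = numeric()))
  }
  subjects |>
    mutate(
      category = ifelse(
        !is.na(.data$genetic_status) & .data$genetic_status == "positive",
        gene_group(.data$gene), "negative"
      )
    ) |>
    count(.data$band, .data$category, name = "n") |>
    group_by(.data$band) |>
    mutate(band_n = sum(.data$n), percent = pct(.data$n, .data$band_n)) |>
    ungroup()
}

#' Simulate autosomal-dominant transmission through a pedigree
#'
#' Mendelian gene-dropping: founder carrier states are given; every other
#' individual receives, independently, each parent's variant allele with
#' probability one half per allele carried by that parent. A missing
#' parent is a non-carrier. With one heterozygous parent a child is a
#' carrier with probability 1/2; with two heterozygous parents, 3/4.
#'
#' @param ped A pedigree tibble.
#' @param founder_carriers Named vector over founder ids: logical
#'   (`TRUE` = heterozygous) or integer allele count 0/1/2. Ids must be
#'   founders of the pedigree; unlisted founders are non-carriers.
#' @param seed Integer seed; the simulation is deterministic given the
#'   seed.
#' @return A tibble `id`, `alleles` (0/1/2), `carrier` (logical).
#' @export
simulate_transmission <- function(ped, founder_carriers, seed = 1L) {
  ped <- as_tibble(ped)
  founders <- pedigree_founders(ped)
  ids <- names(founder_carriers)
  if (is.null(ids) && length(founder_carriers)) {
    abort("founder_carriers must be a named vector")
  }
  non_founder <- setdiff(ids, founders)
  if (length(non_founder)) {
    abort(paste0("carrier status supplied for non-founder(s): ",
                 paste(non_founder, collapse = ", ")))
  }
  alleles <- setNames(rep(NA_integer_, nrow(ped)), ped$id)
  alleles[founders] <- 0L
  alleles[ids] <- as.integer(founder_carriers)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fa_idx <- match(ped$father_id, ped$id)
  mo_idx <- match(ped$mother_id, ped$id)
  # resolve generation by generation (vectorized gene dropping)
  while (anyNA(alleles)) {
    fa_al <- ifelse(is.na(fa_idx), 0L, alleles[fa_idx])
    mo_al <- ifelse(is.na(mo_idx), 0L, alleles[mo_idx])
    ready <- is.na(alleles[ped$id]) & !is.na(fa_al) & !is.na(mo_al)
    if (!any(ready)) abort("unresolvable pedigree (cycle?)")
    n_ready <- sum(ready)
    got <- rbinom(n_ready, 1L, fa_al[ready] / 2) +
      rbinom(n_ready, 1L, mo_al[ready] / 2)
    alleles[ped$id[ready]] <- got
  }
  n_alleles <- unname(alleles[ped$id])
  tibble(id = ped$id, alleles = n_alleles, carrier = n_alleles > 0L)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
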