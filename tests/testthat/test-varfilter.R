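test_that("conservation percentile uses strict comparison with midrank ties", {
  expect_equal(conservation_percentile(0.9, seq(0.1, 0.8, by = 0.1)), 1.0)
  expect_equal(conservation_percentile(0.5, rep(0.5, 6)), 0.5)
  expect_equal(conservation_percentile(0.3, seq(0.4, 0.8, by = 0.1)), 0.0)
  expect_error(conservation_percentile(1, numeric()), "empty")
  # non-decreasing in the score for fixed references
  set.seed(5)
  refs <- rnorm(50)
  scores <- sort(rnorm(100))
  pct <- conservation_percentile(scores, refs)
  expect_true(all(diff(pct) >= 0))
  expect_true(all(pct >= 0 & pct <= 1))
})

test_that("predictor consensus combines tool calls and conservation", {
  cfg <- fh_default_config()$filter
  refs <- tibble::tibble(cons_gerp = seq(-2, 2, length.out = 20))
  # 4/4 damaging (3 pred tools here) and highly conserved -> damaging
  rec <- make_record(cons = 5)
  expect_equal(predictor_consensus(rec, cfg, refs), "damaging")
  # no tool reporting -> indeterminate
  rec2 <- make_record(pred = c("unknown", "unknown", "unknown"))
  expect_equal(predictor_consensus(rec2, cfg, refs), "indeterminate")
  # 1/4 damaging -> benign-leaning at the default fraction 0.5
  rec3 <- dplyr::bind_cols(
    make_record(pred = c("damaging", "tolerated", "tolerated"))[
      , c("variant_id", "pred_sift", "pred_polyphen2",
          "pred_mutation_taster", "cons_gerp")],
    tibble::tibble(pred_extra = "tolerated")
  )
  expect_equal(predictor_consensus(rec3, cfg, refs), "benign_leaning")
  # damaging calls without conservation support stay indeterminate
  rec4 <- make_record(cons = -2)
  expect_equal(predictor_consensus(rec4, cfg, refs), "indeterminate")
})

test_that("filter cascade drops common and benign-asserted records only", {
  records <- dplyr::bind_rows(
    make_record("rs145164937", "2", 43832056L, "C", "G", "ABCG5",
                af_gnomad = 0.002223, clinvar = "conflicting"),
    make_record("common1", af_gnomad = 0.12, pos = 1L),
    make_record("benign1", af_gnomad = 1e-4, clinvar = "benign", pos = 2L),
    make_record("novel1", pos = 3L)
  )
  rep <- apply_filter_cascade(records)
  expect_s3_class(rep, "fh_filter_report")
  expect_setequal(rep$surviving$variant_id, c("rs145164937", "novel1"))
  audit <- tidy(rep)
  expect_equal(audit$removed_at[audit$variant_id == "common1"], "rarity")
  expect_equal(audit$removed_at[audit$variant_id == "benign1"], "assertion")
  expect_true(all(is.na(audit$removed_at[audit$variant_id %in%
                                           rep$surviving$variant_id])))
  g <- glance(rep)
  expect_equal(g$input_count, 4L)
  expect_equal(g$removed_rarity, 1L)
  expect_equal(g$removed_assertion, 1L)
  expect_equal(g$surviving, 2L)

  # empty input: all counts zero
  rep0 <- apply_filter_cascade(records[0, ])
  expect_equal(rep0$input_count, 0L)
  expect_equal(nrow(rep0$surviving), 0L)
  expect_true(all(rep0$steps$n_removed == 0L))
})

test_that("cascade is idempotent, order-invariant, and audit counts add up", {
  g <- gen_cohort(fh_sim_params(n_probands = 5L), seed = 3L)
  rep <- apply_filter_cascade(g$annotations)

  # audit accounts for every input record
  expect_equal(nrow(tidy(rep)), rep$input_count)
  expect_equal(sum(!is.na(tidy(rep)$removed_at)) + nrow(rep$surviving),
               rep$input_count)
  expect_true(all(diff(c(rep$input_count, rep$steps$n_out)) <= 0))

  # idempotence: re-filtering the survivors keeps them all
  rep2 <- apply_filter_cascade(dplyr::select(rep$surviving, -"consensus"))
  expect_setequal(rep2$surviving$variant_id, rep$surviving$variant_id)

  # survivor set unaffected by input order
  set.seed(9)
  shuffled <- g$annotations[sample(nrow(g$annotations)), ]
  rep3 <- apply_filter_cascade(shuffled)
  expect_setequal(rep3$surviving$variant_id, rep$surviving$variant_id)
})

test_that("cascade equals brute-force per-record evaluation on small inputs", {
  g <- gen_cohort(fh_sim_params(n_probands = 2L, n_background = 8L,
                                n_benign_decoys = 4L), seed = 21L)
  records <- g$annotations[sample(nrow(g$annotations), 20), ]
  cfg <- fh_default_config()$filter
  rep <- apply_filter_cascade(records)
  survive <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    af <- max(r$af_gnomad, 0, na.rm = TRUE)
    af < cfg$rare_af_threshold &&
      !(r$clinvar %in% c("benign", "likely_benign"))
  }, logical(1))
  expect_setequal(rep$surviving$variant_id, records$variant_id[survive])
})

test_that("candidate prioritization orders tiers as documented", {
  records <- dplyr::bind_rows(
    make_record("novel_dmg", "19", 500L, "T", "G", cons = 8),
    make_record("asserted", "19", 400L, "G", "A",
                clinvar = "pathogenic"),
    make_record("bland", "19", 300L, "C", "T",
                pred = c("tolerated", "tolerated", "tolerated"), cons = -5)
  )
  rep <- apply_filter_cascade(records)
  ranked <- prioritize_candidates(rep)
  expect_equal(ranked$variant_id[1], "asserted")
  expect_equal(ranked$tier[ranked$variant_id == "novel_dmg"], 3L)
  expect_equal(ranked$tier[ranked$variant_id == "bland"], 4L)

  # a record at a position carrying a described pathogenic allele ranks
  # above an equally-novel record elsewhere: the compound-het pair
  t2 <- table2_variants()
  pair <- t2[t2$variant_id %in% c("rs875989894", "novel"), ]
  pair$clinvar <- "not_reported"  # suppress tier 1 to isolate tier 2
  known <- tibble::tibble(chrom = "19", pos = 11213415L, ref = "G",
                          alt = "A", clinvar = "pathogenic")
  repp <- apply_filter_cascade(pair)
  ranked2 <- prioritize_candidates(repp, known)
  expect_equal(ranked2$hgvs_c[1], "c.266G>C")
  expect_lt(ranked2$tier[ranked2$hgvs_c == "c.266G>C"],
            ranked2$tier[ranked2$hgvs_c == "c.1123T>G"])

  # empty survivors -> empty ranking
  rep0 <- apply_filter_cascade(records[0, ])
  expect_equal(nrow(prioritize_candidates(rep0)), 0L)
})
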