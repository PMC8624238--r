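test_that("generated cohorts are deterministic and pass validation", {
  g1 <- gen_cohort(fh_sim_params(n_probands = 40L), seed = 8L)
  g2 <- gen_cohort(fh_sim_params(n_probands = 40L), seed = 8L)
  expect_identical(g1$subjects, g2$subjects)
  expect_identical(g1$pedigree, g2$pedigree)
  expect_identical(g1$annotations, g2$annotations)
  expect_silent(validate_subjects(g1$subjects))
  expect_silent(validate_pedigree(g1$pedigree))

  # writing twice gives byte-identical files
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_subject_table(g1$subjects, file.path(d1, "s.tsv"))
  write_subject_table(g2$subjects, file.path(d2, "s.tsv"))
  expect_identical(readLines(file.path(d1, "s.tsv")),
                   readLines(file.path(d2, "s.tsv")))

  g0 <- gen_cohort(fh_sim_params(n_probands = 0L))
  expect_equal(nrow(g0$subjects), 0L)
  expect_true(all(c("subject_id", "tc", "genetic_status") %in%
                    names(g0$subjects)))
})

test_that("lipid moments match the configured distributions (CLT bounds)", {
  n <- 10000L
  g <- gen_cohort(fh_sim_params(n_probands = n, children_rate = 0,
                                carrier_tc_shift = 0), seed = 555L)
  s <- g$subjects
  expect_equal(nrow(s), n)
  expect_lt(abs(mean(s$tc) - 8.6), 3 * 3.4 / sqrt(n))
  expect_lt(abs(mean(s$hdl) - 1.4), 3 * 0.4 / sqrt(n))
  expect_lt(abs(mean(s$tg) - 1.8), 3 * 1.4 / sqrt(n))
  expect_lt(abs(sd(s$tg) - 1.4), 0.1)
  expect_true(all(s$tc > 0 & s$tg > 0 & s$hdl > 0 & s$ldl > 0))

  # under defaults the carrier TC shift is visible at its configured size
  gd <- gen_cohort(fh_sim_params(n_probands = 4000L, children_rate = 0),
                   seed = 556L)
  p <- gd$subjects
  shift <- mean(p$tc[p$genetic_status == "positive"]) -
    mean(p$tc[p$genetic_status == "negative"])
  expect_lt(abs(shift - 3.0), 0.3)
})

test_that("annotation generator embeds the printed spectrum verbatim", {
  ann <- gen_annotation_table(fh_sim_params(), seed = 4L)
  t2 <- table2_variants()
  expect_equal(nrow(t2), 20L)
  expect_true(all(t2$variant_id %in% ann$variant_id))

  # the printed APOB record is present with its printed position and MAF
  apo <- ann[ann$variant_id == "rs5742904", ]
  expect_equal(apo$chrom, "2")
  expect_equal(apo$pos, 21006288L)
  expect_equal(apo$af_gnomad, 0.000275)
  expect_equal(apo$clinvar, "pathogenic")

  # all printed frequencies are below the default rarity threshold
  expect_true(all(t2$af_gnomad < 0.005, na.rm = TRUE))
  expect_equal(max(t2$af_gnomad, na.rm = TRUE), 0.002244)

  # determinism
  expect_identical(ann, gen_annotation_table(fh_sim_params(), seed = 4L))
})

test_that("filtering the generated table retains the spectrum, drops decoys", {
  ann <- gen_annotation_table(fh_sim_params(), seed = 12L)
  rep <- apply_filter_cascade(ann)
  expect_setequal(rep$surviving$variant_id, table2_variants()$variant_id)
  audit <- tidy(rep)
  expect_true(all(audit$removed_at[grepl("^common", audit$variant_id)] ==
                    "rarity"))
  expect_true(all(audit$removed_at[grepl("^decoy", audit$variant_id)] %in%
                    c("rarity", "assertion")))

  # background-only table: nothing survives the default cascade
  bg_only <- ann[grepl("^common", ann$variant_id), ]
  expect_equal(nrow(apply_filter_cascade(bg_only)$surviving), 0L)
})

test_that("zero-noise MLPA generation is exact and seeded runs repeat", {
  events <- tibble::tibble(sample_id = "S0001", exon_start = 2L,
                           exon_end = 10L, copy_ratio = 0.5)
  run <- gen_mlpa_run(1, events, noise_sd = 0, seed = 6L)
  dq <- normalize_run(run)
  aff <- dq$sample_id == "S0001" & dq$target %in% as.character(2:10)
  expect_true(all(dq$dq[aff] == 0.5))
  expect_true(all(dq$dq[!aff & dq$sample_id == "S0001"] == 1))

  expect_identical(gen_mlpa_run(3, events, noise_sd = 0.05, seed = 9L),
                   gen_mlpa_run(3, events, noise_sd = 0.05, seed = 9L))
  expect_error(
    gen_mlpa_run(1, tibble::tibble(sample_id = "S9999", exon_start = 1L,
                                   exon_end = 1L, copy_ratio = 0.5)),
    "unknown sample"
  )
  expect_error(
    gen_mlpa_run(1, tibble::tibble(sample_id = "S0001", exon_start = 1L,
                                   exon_end = 1L, copy_ratio = 0)),
    "copy_ratio"
  )
})

test_that("the reference fixture is deterministic and internally consistent", {
  fx1 <- build_paper_fixture()
  fx2 <- build_paper_fixture()
  expect_identical(fx1, fx2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_paper_fixture(d1)
  write_paper_fixture(d2)
  for (f in c("subjects.tsv", "pedigree.ped", "annotations.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  s <- fx1$subjects
  expect_equal(nrow(s), 80L)
  expect_equal(sum(s$role == "proband"), 60L)
  expect_equal(sum(s$relation == "child"), 14L)
  expect_equal(sum(s$role == "relative"), 20L)
  bands <- table(score_dlcn(s)$band)
  expect_equal(as.integer(bands[c("definite", "probable", "possible")]),
               c(34L, 5L, 41L))
  # every family referenced by a subject resolves in the pedigree
  expect_true(all(s$subject_id %in% fx1$pedigree$id))
})
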