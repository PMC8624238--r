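test_that("cascade plan proposes first-degree relatives in waves", {
  ped <- family_fixture_ped()
  plan <- propose_cascade(ped, "PRO")
  w1 <- plan$subject_id[plan$wave == 1]
  expect_setequal(w1, c("GF", "GM", "CH1", "CH2", "SIB"))
  expect_false("PRO" %in% plan$subject_id)
  expect_false(any(duplicated(plan$subject_id)))

  # once the sibling is known positive, the next wave reaches the nephew
  plan2 <- propose_cascade(ped, "PRO",
                           c(SIB = "positive", GF = "negative"))
  expect_setequal(plan2$subject_id[plan2$wave == 1],
                  c("GM", "CH1", "CH2"))
  expect_true("NEP" %in% plan2$subject_id[plan2$wave == 2])
  expect_equal(glance(plan2)$n_waves, 2L)

  # solitary proband: empty plan; unknown proband: error
  solo <- tibble::tibble(family_id = "F", id = "X",
                         father_id = NA_character_,
                         mother_id = NA_character_,
                         sex = NA_character_, affected = NA)
  expect_equal(nrow(propose_cascade(solo, "X")), 0L)
  expect_error(propose_cascade(solo, "Y"), "not in the pedigree")
})

test_that("every proposed relative is one edge from a positive individual", {
  set.seed(31)
  for (rep in 1:10) {
    g <- gen_cohort(fh_sim_params(n_probands = 6L, children_rate = 1.5),
                    seed = rep)
    ped <- g$pedigree
    pro <- g$subjects$subject_id[g$subjects$role == "proband"][1]
    results <- setNames(g$subjects$genetic_status, g$subjects$subject_id)
    plan <- propose_cascade(ped, pro, results)
    expect_false(any(duplicated(plan$subject_id)))
    positives <- union(pro, names(results)[results == "positive"])
    fam_ped <- ped[ped$family_id == ped$family_id[match(pro, ped$id)], ]
    edge_ok <- vapply(plan$subject_id, function(id) {
      row <- fam_ped[match(id, fam_ped$id), ]
      pos_rows <- fam_ped[fam_ped$id %in% positives, ]
      is_parent <- any(positives %in% c(row$father_id, row$mother_id))
      is_child <- any(pos_rows$father_id %in% id | pos_rows$mother_id %in% id)
      shared <- any(!is.na(row$father_id) & pos_rows$father_id %in% row$father_id |
                      !is.na(row$mother_id) & pos_rows$mother_id %in% row$mother_id)
      is_parent || is_child || shared
    }, logical(1))
    expect_true(all(edge_ok))
  }
})

test_that("cohort summary reproduces the printed detection yields", {
  fx <- build_paper_fixture()
  s <- summarize_cohort(fx$subjects)
  expect_equal(s$n_subjects, 80L)
  expect_equal(s$n_probands, 60L)
  expect_equal(s$n_variant_positive, 38L)
  expect_equal(s$subject_yield_percent, 47.5)
  gg <- s$by_gene_group
  expect_equal(gg$n[gg$gene_group == "LDLR"], 19L)
  expect_equal(gg$percent[gg$gene_group == "LDLR"], 73.1)
  expect_equal(gg$percent[gg$gene_group == "APOB"], 11.5)
  expect_equal(gg$percent[gg$gene_group == "other"], 15.4)
  expect_equal(s$children$n, 14L)
  expect_equal(s$children$n_positive, 12L)
  expect_equal(s$children$percent, 85.7)
  # percentages recomputed by an independent one-liner agree to 0.1
  expect_true(all(abs(gg$percent - 100 * gg$n / sum(gg$n)) <= 0.1))
})

test_that("summary marks undefined percentages instead of reporting zero", {
  fx <- build_paper_fixture()
  neg <- fx$subjects
  neg$genetic_status <- "negative"
  neg$gene <- NA_character_
  neg$variant_ids <- NA_character_
  neg$zygosity <- NA_character_
  s <- summarize_cohort(neg)
  expect_equal(s$n_variant_positive, 0L)
  expect_equal(nrow(s$by_gene_group), 0L)
  expect_true(is.na(s$children$percent) || s$children$n_positive == 0L)
  expect_true(any(grepl("per-gene split undefined", s$flags)))
  s0 <- summarize_cohort(fx$subjects[0, ])
  expect_true(is.na(s0$subject_yield_percent))
})

test_that("DLCN band crosstab reproduces the definite-band percentages", {
  fx <- build_paper_fixture()
  sc <- score_dlcn(fx$subjects)
  joined <- dplyr::left_join(fx$subjects, sc[c("subject_id", "band")],
                             by = "subject_id")
  xt <- crosstab_dlcn_by_result(joined)
  def <- xt[xt$band == "definite", ]
  expect_equal(def$band_n[1], 34L)
  expect_equal(def$percent[def$category == "LDLR"], 76.5)
  expect_equal(def$percent[def$category == "APOB"], 8.8)
  expect_equal(def$percent[def$category == "negative"], 14.7)
  prob <- xt[xt$band == "probable", ]
  expect_equal(sum(prob$n[prob$category != "negative"]), 2L)
  expect_equal(prob$band_n[1], 5L)

  # subjects without a band are dropped with a warning
  joined2 <- joined
  joined2$band[1] <- NA
  expect_warning(crosstab_dlcn_by_result(joined2), "1 subject")
  expect_equal(nrow(crosstab_dlcn_by_result(joined[0, ])), 0L)
})

test_that("gene dropping recovers Mendelian expectations", {
  n <- 10000L
  ped <- tibble::tibble(
    family_id = "X",
    id = c("P", "SP", sprintf("K%05d", seq_len(n))),
    father_id = c(NA, NA, rep("P", n)),
    mother_id = c(NA, NA, rep("SP", n)),
    sex = NA_character_, affected = NA
  )
  tr <- simulate_transmission(ped, c(P = 1L), seed = 1234L)
  frac <- mean(tr$carrier[match(sprintf("K%05d", seq_len(n)), tr$id)])
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
  # deterministic under the seed
  tr2 <- simulate_transmission(ped, c(P = 1L), seed = 1234L)
  expect_identical(tr, tr2)
  # exact binomial test at alpha = 0.001 does not reject p = 1/2
  k <- sum(tr$carrier[-(1:2)])
  expect_gt(stats::binom.test(k, n, 0.5)$p.value, 0.001)

  # both parents heterozygous: carrier probability 3/4
  tr3 <- simulate_transmission(ped, c(P = 1L, SP = 1L), seed = 99L)
  frac3 <- mean(tr3$carrier[-(1:2)])
  expect_lt(abs(frac3 - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  # no carrier founders: nobody carries
  tr0 <- simulate_transmission(ped, c(P = 0L), seed = 5L)
  expect_equal(sum(tr0$carrier), 0L)

  # carrier status on a non-founder is rejected
  expect_error(simulate_transmission(ped, c(K00001 = 1L), seed = 1L),
               "non-founder")
})
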