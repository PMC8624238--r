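ldlr_order <- c("promoter", as.character(1:18))

test_that("dosage-quotient normalization has the expected algebra", {
  # no events, no noise: every dq exactly 1
  run <- gen_mlpa_run(2, noise_sd = 0, seed = 1)
  dq <- normalize_run(run)
  expect_true(all(dq$dq == 1))

  # halving one target probe's peak halves its dq only
  run2 <- run
  hit <- run2$sample_id == "S0001" & run2$probe_id == "pr_ex05"
  run2$peak[hit] <- run2$peak[hit] / 2
  dq2 <- normalize_run(run2)
  expect_equal(dq2$dq[dq2$sample_id == "S0001" & dq2$probe_id == "pr_ex05"],
               0.5)
  expect_true(all(dq2$dq[!(dq2$sample_id == "S0001" &
                             dq2$probe_id == "pr_ex05")] == 1))

  # a global per-sample scale factor cancels
  run3 <- run
  run3$peak[run3$sample_id == "S0002"] <- run3$peak[run3$sample_id == "S0002"] * 2
  expect_true(all(normalize_run(run3)$dq == 1))

  # probe row order is irrelevant
  set.seed(4)
  run4 <- run2[sample(nrow(run2)), ]
  dq4 <- normalize_run(run4)
  expect_equal(as.data.frame(dq4), as.data.frame(dq2))
})

test_that("normalization reports degenerate inputs", {
  run <- gen_mlpa_run(1, noise_sd = 0, seed = 1)
  run$peak[run$sample_id == "S0001" & run$is_reference] <- 0
  expect_error(normalize_run(run), "reference peaks are zero in sample S0001")
  run2 <- gen_mlpa_run(1, noise_sd = 0, seed = 1)
  expect_error(normalize_run(run2[run2$role == "test", ]), "control")
})

test_that("event calling recovers the two reference deletions exactly", {
  events <- tibble::tibble(
    sample_id = c("S0001", "S0002"),
    exon_start = c(2L, 15L), exon_end = c(10L, 15L), copy_ratio = 0.5
  )
  run <- gen_mlpa_run(2, events, noise_sd = 0, seed = 1)
  dq <- normalize_run(run)
  affected <- dq$sample_id == "S0001" & dq$target %in% as.character(2:10)
  expect_true(all(dq$dq[affected] == 0.5))
  calls <- call_exon_events(dplyr::filter(dq, role == "test"), ldlr_order)
  expect_equal(nrow(calls), 2L)
  multi <- calls[calls$sample_id == "S0001", ]
  expect_equal(multi$event, "deletion")
  expect_equal(c(multi$exon_start, multi$exon_end), c(2L, 10L))
  expect_equal(multi$n_probes, 9L)
  expect_equal(multi$mean_dq, 0.5)
  expect_false(multi$homozygous)
  single <- calls[calls$sample_id == "S0002", ]
  expect_equal(c(single$exon_start, single$exon_end), c(15L, 15L))

  # their HGVS names match the printed nomenclature
  expect_equal(format_deletion_hgvs(multi$exon_start, multi$exon_end),
               "NM_000527.4:c.(67+1_68-1)_(1586+1_1587-1)del")
  expect_equal(format_deletion_hgvs(single$exon_start, single$exon_end),
               "NM_000527.4:c.(2140+1_2141-1)_(2311+1_2312-1)del")

  # event-free run yields no calls
  run0 <- gen_mlpa_run(2, noise_sd = 0, seed = 2)
  expect_equal(nrow(call_exon_events(
    dplyr::filter(normalize_run(run0), role == "test"), ldlr_order
  )), 0L)
})

test_that("duplications, homozygous deletions and bad targets are handled", {
  events <- tibble::tibble(
    sample_id = c("S0001", "S0002"),
    exon_start = c(3L, 7L), exon_end = c(5L, 7L),
    copy_ratio = c(1.5, 0.05)
  )
  run <- gen_mlpa_run(2, events, noise_sd = 0, seed = 1)
  calls <- call_exon_events(dplyr::filter(normalize_run(run), role == "test"),
                            ldlr_order)
  dup <- calls[calls$sample_id == "S0001", ]
  expect_equal(dup$event, "duplication")
  expect_equal(c(dup$exon_start, dup$exon_end), c(3L, 5L))
  hom <- calls[calls$sample_id == "S0002", ]
  expect_equal(hom$event, "deletion")
  expect_true(hom$homozygous)

  dq <- normalize_run(run)
  expect_error(call_exon_events(dq, c("promoter", as.character(1:10))),
               "exon_order is missing")
  expect_error(format_deletion_hgvs(15, 15, boundaries = tibble::tibble(
    exon = 15L, cdna_end = 2311L
  )), "exon 14")
})

test_that("calling stays near-perfect under multiplicative noise", {
  set.seed(77)
  n_samples <- 200L
  n_events <- 30L
  ev_samples <- sample(sprintf("S%04d", 1:n_samples), n_events)
  starts <- sample(1:16, n_events, replace = TRUE)
  events <- tibble::tibble(
    sample_id = ev_samples,
    exon_start = starts,
    exon_end = pmin(starts + sample(0:8, n_events, replace = TRUE), 18L),
    copy_ratio = 0.5
  )
  run <- gen_mlpa_run(n_samples, events, noise_sd = 0.05, seed = 99)
  calls <- call_exon_events(dplyr::filter(normalize_run(run), role == "test"),
                            ldlr_order)
  key <- function(d, type_col) paste(
    d$sample_id,
    ifelse(d[[type_col]] == 0.5 | d[[type_col]] == "deletion",
           "deletion", "duplication"),
    d$exon_start, d$exon_end
  )
  truth <- key(events, "copy_ratio")
  called <- key(calls, "event")
  sensitivity <- mean(truth %in% called)
  event_free <- setdiff(sprintf("S%04d", 1:n_samples), events$sample_id)
  specificity <- mean(!(event_free %in% calls$sample_id))
  expect_gte(sensitivity, 0.99)
  expect_gte(specificity, 0.99)
})
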