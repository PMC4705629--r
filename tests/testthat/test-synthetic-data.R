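test_that("cohort generation is deterministic and validates its spec", {
  sp <- cohort_spec(n_cases = 10, n_controls = 6, n_genes = 20,
                    n_planted_genes = 2, seed = 7)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$variants$sites, b$variants$sites)
  expect_identical(a$variants$gt, b$variants$gt)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$manifest, b$manifest)

  expect_error(cohort_spec(n_cases = 0), "positive")
  expect_error(cohort_spec(n_planted_genes = 50, n_genes = 10), "exceeds")
  expect_error(cohort_spec(class_mix = c(stop_indel = 0.5,
                                         nonsynonymous = 0.5,
                                         synonymous = 0.5)), "sum to 1")
  expect_error(screen_spec(planted_interactions = numeric(0)), "non-empty")
})

test_that("planted_effect = 1 plants no case/control carriage difference", {
  sp <- cohort_spec(n_cases = 300, n_controls = 300, n_genes = 30,
                    n_planted_genes = 5, planted_effect = 1, seed = 21)
  co <- generate_cohort(sp)
  man <- co$manifest
  expect_equal(man$planted_genes$case_freq, man$planted_genes$control_freq)
  # empirical check on the planted sites themselves
  planted <- man$planted_deleterious_sites
  gt <- co$variants$gt[planted, , drop = FALSE]
  carr <- gt != "0/0"
  is_case <- co$phenotype == "susceptible"
  rate_case <- mean(carr[, is_case])
  rate_ctrl <- mean(carr[, !is_case])
  expect_lt(abs(rate_case - rate_ctrl), 0.015)
})

test_that("cohort manifest records every planted quality failure", {
  co <- generate_cohort(cohort_spec(n_cases = 20, n_controls = 10,
                                    n_genes = 40, n_planted_genes = 3,
                                    seed = 9))
  man <- co$manifest
  # manifest-listed VQSLOD failures are exactly the sub-threshold sites
  expect_setequal(man$vqslod_fail_sites,
                  co$variants$sites$site_id[co$variants$sites$vqslod < 2])
  # filtering removes exactly the sites the log blames, conserving counts
  filtered <- filter_sites(co$variants)
  log <- attr(filtered, "filter_log")
  expect_equal(sum(log$retained) + sum(!log$retained), man$n_sites)
  expect_setequal(log$site_id[grepl("low_vqslod", log$reason)],
                  man$vqslod_fail_sites)
  # planted deleterious sites carry the deleterious score structure
  ann <- co$annotations[co$annotations$site_id %in%
                          man$planted_deleterious_sites, ]
  ns <- ann$variant_class == "nonsynonymous"
  expect_true(all(ann$predictor_score[ns] <= -40))
  expect_true(all(ann$variant_class %in%
                    c("indel", "stop_gain", "stop_loss", "nonsynonymous")))
})

test_that("FPKM generation is deterministic with planted truth in manifest", {
  a <- generate_fpkm(n_transcripts = 50, n_donors = 5, seed = 13,
                     n_low_abundance = 8, n_high_var = 4)
  b <- generate_fpkm(n_transcripts = 50, n_donors = 5, seed = 13,
                     n_low_abundance = 8, n_high_var = 4)
  expect_identical(a$expression$fpkm, b$expression$fpkm)
  expect_length(a$manifest$low_abundance, 8L)
  expect_length(a$manifest$high_variability, 4L)
  expect_error(generate_fpkm(n_transcripts = 10, zero_rate = 1.5),
               "zero_rate")
  expect_error(generate_fpkm(n_transcripts = 10, n_donors = 1), "donors")
})

test_that("zero inflation feeds the two-zero exclusion rule", {
  gen <- generate_fpkm(n_transcripts = 400, n_donors = 5, zero_rate = 0.3,
                       seed = 17, n_low_abundance = 0, n_high_var = 0)
  vs <- variability_stats(gen$expression)
  n_zero <- gen$manifest$n_zero
  expect_equal(vs$per_transcript$n_zero,
               unname(n_zero[vs$per_transcript$transcript_id]))
  expect_equal(vs$per_transcript$excluded_zero_rule, unname(n_zero >= 2))
})

test_that("noiseless screens reproduce planted ratios exactly", {
  planted <- setNames(c(0.5, 1, 2), paste0("g", 1:3))
  scr <- toy_screen(planted, noise_cv = 0, seed = 1)
  expect_true(all(unlist(scr$plate[, c("rep1", "rep2", "rep3")]) > 0))
  coll_r <- screen_pipeline(scr$plate)
  # per-experiment ratios are exact, so the mean ratio equals the truth
  expect_equal(coll_r$interaction$ratio[match(names(planted),
                                              coll_r$interaction$gene_id)],
               unname(planted))
  # determinism
  scr2 <- toy_screen(planted, noise_cv = 0, seed = 1)
  expect_identical(scr$plate, scr2$plate)
})

test_that("estimated ratios preserve planted order at small noise", {
  planted <- setNames(c(0.2, 0.6, 1.0, 1.6), paste0("g", 1:4))
  for (s in 1:5) {
    scr <- toy_screen(planted, noise_cv = 0.05, seed = s)
    res <- screen_pipeline(scr$plate)
    est <- res$interaction$ratio[match(names(planted),
                                       res$interaction$gene_id)]
    expect_equal(order(est), 1:4)
  }
})

test_that("screen batches respect the 2-10 genes-per-experiment design", {
  scr <- generate_screen(screen_spec(seed = 5))
  batches <- scr$manifest$batches
  sizes <- table(batches$experiment_id)
  expect_true(all(sizes <= 10))
  # every gene appears in the default number of independent experiments
  expect_true(all(table(batches$gene_id) == 3))
  # shared scrambled control present once per experiment and condition
  plate <- scr$plate
  ctrl <- plate[plate$gene_id == "scrambled", ]
  expect_equal(nrow(ctrl), 2L * length(unique(plate$experiment_id)))
})
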