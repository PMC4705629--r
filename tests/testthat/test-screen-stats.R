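test_that("interaction and alone ratios follow the four-group formula", {
  mk <- function(a, b, cc, d)
    data.frame(condition = c("A", "B", "C", "D"),
               rep1 = c(a, b, cc, d), rep2 = c(a, b, cc, d),
               rep3 = c(a, b, cc, d))
  expect_equal(interaction_ratio(mk(1, 1, 1, 1)),
               c(interaction = 1, alone = 1))
  expect_equal(interaction_ratio(mk(1, 0.8, 1, 0.4)),
               c(interaction = 0.5, alone = 1))
  # scale invariance: a common factor cancels
  r1 <- interaction_ratio(mk(1.2, 0.7, 0.9, 0.5))
  r3 <- interaction_ratio(mk(3 * 1.2, 3 * 0.7, 3 * 0.9, 3 * 0.5))
  expect_equal(r1, r3)
  # replicate averaging happens before the ratio
  recs <- mk(1, 0.8, 1, 0.4)
  recs[recs$condition == "D", c("rep1", "rep2", "rep3")] <- c(0.3, 0.4, 0.5)
  expect_equal(unname(interaction_ratio(recs)["interaction"]), 0.5)
  bad <- mk(1, 1, 1, 1); bad[1, c("rep1", "rep2", "rep3")] <- c(0, 0, 0)
  expect_error(interaction_ratio(bad), "A")
})

test_that("pseudo-SD is IQR/1.35 with linear-interpolation quantiles", {
  expect_equal(pseudo_sd(c(1, 2, 3)), 1 / 1.35)
  # n = 3: IQR = (max - min) / 2 under type-7 quantiles
  expect_equal(pseudo_sd(c(0.5, 0.9, 1.7)), (1.7 - 0.5) / 2 / 1.35)
  expect_equal(pseudo_sd(c(2, 2, 2)), 0)
})

test_that("robust z maps to one-sided normal tails on both sides", {
  df <- robust_z(list(gA = c(0.55, 0.614, 0.68)), null_center = 1)
  expect_equal(df$z_score, (mean(c(0.55, 0.614, 0.68)) - 1) /
                             pseudo_sd(c(0.55, 0.614, 0.68)))
  # tail convention: lower tail for z < 0, upper for z > 0, 0.5 at z = 0
  expect_equal(round(pnorm(-2.924), 4), 0.0017)
  z0 <- robust_z(list(g = c(0.9, 1.0, 1.1)), null_center = 1)
  expect_equal(z0$z_score, 0)
  expect_equal(z0$p_one_sided, 0.5)
  # zero dispersion is flagged, not infinite
  flat <- robust_z(list(g = c(0.7, 0.7, 0.7)))
  expect_true(is.na(flat$z_score))
  # use_se divides the pseudo-SD by sqrt(n), scaling z up accordingly
  se <- robust_z(list(gA = c(0.55, 0.614, 0.68)), use_se = TRUE)
  expect_equal(se$z_score, df$z_score * sqrt(3))
})

test_that("global scope standardises against the gene population", {
  set.seed(2)
  ratios <- setNames(c(0.196, rnorm(30, 1, 0.1)), paste0("g", 0:30))
  df <- robust_z(ratios, scope = "global")
  expect_equal(df$z_score,
               (unname(ratios) - mean(ratios)) / pseudo_sd(ratios))
  # explicit centre/scale override
  df2 <- robust_z(c(x = 0.196), scope = "global", center = 1.000049,
                  scale = 0.1320278)
  expect_equal(df2$z_score, -6.090, tolerance = 1e-3)
})

test_that("BH thresholds are linear in rank and tails are exclusive", {
  set.seed(3)
  z <- c(seq(-5, -0.5, length.out = 50), seq(0.4, 4, length.out = 31))
  res <- data.frame(gene_id = sprintf("g%02d", seq_along(z)), z_score = z,
                    p_one_sided = ifelse(z < 0, pnorm(z), 1 - pnorm(z)))
  out <- bh_calls(res, alpha = 0.05)
  aug <- out[out$tail == "augmenting", ]
  pro <- out[out$tail == "protecting", ]
  expect_equal(nrow(aug), 50L); expect_equal(nrow(pro), 31L)
  expect_equal(sort(aug$bh_threshold), 0.05 * (1:50) / 50)
  expect_equal(sort(pro$bh_threshold), 0.05 * (1:31) / 31)
  expect_true(all(diff(aug$bh_threshold[order(aug$rank_in_tail)]) > 0))
  # every gene with defined z belongs to exactly one tail
  expect_equal(nrow(aug) + nrow(pro), nrow(out))
  # z = 0 is unassigned and logged
  res0 <- rbind(res, data.frame(gene_id = "gz", z_score = 0,
                                p_one_sided = 0.5))
  out0 <- bh_calls(res0)
  expect_true(is.na(out0$tail[out0$gene_id == "gz"]))
  expect_equal(attr(out0, "unassigned"), "gz")
})

test_that("pointwise rule matches row-wise printed-threshold logic; step-up is monotone", {
  p <- c(0.0001, 0.0017, 0.0192, 0.0363, 0.0622,
         seq(0.07, 0.49, length.out = 45))
  res <- data.frame(gene_id = sprintf("g%02d", 1:50),
                    z_score = -qnorm(1 - p), p_one_sided = p)
  out <- bh_calls(res, alpha = 0.05, rule = "pointwise")
  expect_equal(sum(out$significant), 2L)   # ranks 1 and 2 only
  expect_equal(out$gene_id[out$significant], c("g01", "g02"))

  # a vector where the pointwise rule is non-monotone in rank
  p2 <- c(0.013, 0.020, 0.040, 0.048)
  res2 <- data.frame(gene_id = paste0("h", 1:4), z_score = -qnorm(1 - p2),
                     p_one_sided = p2)
  pw <- bh_calls(res2, alpha = 0.05, rule = "pointwise")
  expect_equal(pw$significant[order(pw$rank_in_tail)],
               c(FALSE, TRUE, FALSE, TRUE))
  # step-up fills the gap: significant up to the largest qualifying rank
  su <- bh_calls(res2, alpha = 0.05, rule = "stepup")
  expect_equal(su$significant[order(su$rank_in_tail)],
               c(TRUE, TRUE, TRUE, TRUE))
})

test_that("screen pipeline recovers a strong planted augmenting gene", {
  planted <- setNames(c(0.5, rep(1, 9)), sprintf("g%02d", 1:10))
  scr <- toy_screen(planted, noise_cv = 0.02, seed = 4)
  res <- screen_pipeline(scr$plate)
  tab <- res$interaction
  expect_equal(tab$gene_id[which.min(tab$z_score)], "g01")
  expect_equal(tab$ratio[tab$gene_id == "g01"], 0.5, tolerance = 0.05)
  # gene order in the plate does not change results
  perm <- scr$plate[sample(nrow(scr$plate)), ]
  res_p <- screen_pipeline(perm)
  ord <- match(tab$gene_id, res_p$interaction$gene_id)
  expect_equal(res_p$interaction$z_score[ord], tab$z_score)
})

test_that("rescaling a whole batch changes no ratio, z or call", {
  planted <- setNames(c(0.4, 1, 1.5, 1), paste0("g", 1:4))
  scr <- toy_screen(planted, noise_cv = 0.03, seed = 9)
  plate <- scr$plate
  res1 <- screen_pipeline(plate)
  one_exp <- plate$experiment_id == plate$experiment_id[1]
  plate[one_exp, c("rep1", "rep2", "rep3")] <-
    plate[one_exp, c("rep1", "rep2", "rep3")] * 7.5
  res2 <- screen_pipeline(plate)
  expect_equal(res2$interaction$z_score, res1$interaction$z_score)
  expect_equal(res2$interaction$significant, res1$interaction$significant)
  expect_equal(res2$alone$z_score, res1$alone$z_score)
})

test_that("genes missing a condition are excluded with a reason", {
  planted <- setNames(rep(1, 4), paste0("g", 1:4))
  scr <- toy_screen(planted, noise_cv = 0.02, seed = 2)
  plate <- scr$plate
  drop <- which(plate$gene_id == "g2" & plate$condition == "D")[1]
  res <- screen_pipeline(plate[-drop, ])
  expect_true("g2" %in% res$excluded$gene_id)
  expect_false("g2" %in% res$interaction$gene_id)
  expect_equal(res$excluded$reason[res$excluded$gene_id == "g2"],
               "missing_condition")
})

test_that("alone analysis tests only the reduced-viability tail", {
  planted_alone <- setNames(c(0.5, 1, 1, 1.4), paste0("g", 1:4))
  planted <- setNames(rep(1, 4), paste0("g", 1:4))
  scr <- generate_screen(screen_spec(n_genes = 4,
                                     planted_interactions = planted,
                                     planted_alone = planted_alone,
                                     noise_cv = 0.02, seed = 6))
  res <- screen_pipeline(scr$plate)
  al <- res$alone
  expect_equal(al$ratio[al$gene_id == "g1"], 0.5, tolerance = 0.05)
  # the raised-viability gene is never assigned to the tested tail
  expect_true(is.na(al$tail[al$gene_id == "g4"]))
  tested <- al[!is.na(al$tail), ]
  expect_equal(sort(tested$bh_threshold),
               0.05 * seq_len(nrow(tested)) / nrow(tested))
})
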