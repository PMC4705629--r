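test_that("variability statistics apply the zero-exclusion and tenfold rules", {
  fpkm <- rbind(const = c(5, 5, 5, 5, 5),
                twozero = c(1, 0, 0, 3, 2),
                onezero = c(1, 0, 2, 3, 2),
                boundary = c(1, 1, 1, 10, 100),
                wild = c(0.01, 0.01, 10, 1000, 1000))
  em <- expression_matrix(fpkm, gene_ids = paste0("g", 1:5))
  vs <- variability_stats(em)
  per <- vs$per_transcript

  expect_equal(per$log10_iqr[per$transcript_id == "const"], 0)
  expect_true(per$within_tenfold[per$transcript_id == "const"])
  # >= 2 zeros: excluded from the denominator entirely
  expect_true(per$excluded_zero_rule[per$transcript_id == "twozero"])
  expect_false(per$in_denominator[per$transcript_id == "twozero"])
  # a single zero defeats log10: dropped from the variability statistic only
  expect_false(per$in_denominator[per$transcript_id == "onezero"])
  expect_false(per$excluded_zero_rule[per$transcript_id == "onezero"])
  # log10 = (0,0,0,1,2); linear-interpolation IQR = 1.0 -> inclusive boundary
  expect_equal(per$log10_iqr[per$transcript_id == "boundary"], 1.0)
  expect_true(per$within_tenfold[per$transcript_id == "boundary"])
  expect_false(per$within_tenfold[per$transcript_id == "wild"])
  # denominator = {const, boundary, wild}; 2 of 3 within tenfold
  expect_equal(vs$fraction_within_tenfold, 2 / 3)
})

test_that("variability flags are invariant to global rescaling", {
  gen <- generate_fpkm(n_transcripts = 60, n_donors = 5, seed = 5,
                       n_low_abundance = 10, n_high_var = 6)
  em <- gen$expression
  scaled <- expression_matrix(em$fpkm * 37, transcript_ids = em$transcript_id,
                              gene_ids = em$gene_id)
  expect_equal(variability_stats(scaled)$per_transcript$within_tenfold,
               variability_stats(em)$per_transcript$within_tenfold)
})

test_that("abundance filter is inclusive at the boundary and gene-level any", {
  fpkm <- rbind(t1 = rep(0.99, 5), t2 = rep(1.0, 5),
                t3 = rep(0.2, 5), t4 = rep(3.0, 5))
  em <- expression_matrix(fpkm, gene_ids = c("gA", "gB", "gC", "gC"))
  ab <- abundance_filter(em)
  expect_equal(ab$per_transcript$pass, c(FALSE, TRUE, FALSE, TRUE))
  expect_setequal(ab$expressed_genes, c("gB", "gC"))  # any-transcript rule
  # monotone: raising the threshold never grows the pass set
  stricter <- abundance_filter(em, min_mean_fpkm = 2)
  expect_true(all(stricter$expressed_genes %in% ab$expressed_genes))
})

test_that("planted expression violations are recovered exactly", {
  gen <- generate_fpkm(n_transcripts = 100, n_donors = 5, seed = 3,
                       n_low_abundance = 10, n_high_var = 7)
  em <- gen$expression
  ab <- abundance_filter(em)
  failing <- ab$per_transcript$transcript_id[!ab$per_transcript$pass]
  expect_setequal(failing, gen$manifest$low_abundance)
  vs <- variability_stats(em)
  over <- vs$per_transcript$transcript_id[
    vs$per_transcript$in_denominator & !vs$per_transcript$within_tenfold]
  expect_setequal(over, gen$manifest$high_variability)
  # zero_rate = 0: nothing excluded by the zero rule
  expect_false(any(vs$per_transcript$excluded_zero_rule))
})

test_that("rank-list intersection needs both 5% lists and rank < 300", {
  mk <- function(genes, ranks, inh, dir)
    data.frame(gene_id = genes, rank = ranks, p_value = 0.01,
               inheritance = inh, background = "freq5pct", direction = dir,
               stringsAsFactors = FALSE)
  lists <- rbind(
    mk(c("A", "B", "C", "D"), c(10, 299, 500, 301), "dominant", "sus"),
    mk(c("B", "C", "E", "D"), c(400, 500, 2, 302), "recessive", "sus"))
  got <- ranklist_intersect(lists, max_rank = 300)
  # A: dominant only -> out.  B: both, min rank 299 < 300 -> in.
  # C: both, min 500 -> out.  D: both, min 301 -> out.  E: recessive only.
  expect_equal(as.character(got), "B")
  # boundary is strict: rank exactly 300 fails
  lists2 <- rbind(mk("F", 300, "dominant", "sus"),
                  mk("F", 600, "recessive", "sus"))
  expect_length(ranklist_intersect(lists2), 0)
  # monotone in max_rank
  expect_true(all(as.character(ranklist_intersect(lists, max_rank = 300)) %in%
                  as.character(ranklist_intersect(lists, max_rank = 600))))
  # a missing required analysis is a hard error
  expect_error(ranklist_intersect(mk("A", 1, "dominant", "sus")),
               "missing a required")
})

test_that("rank-list intersection unions over comparison directions", {
  mk <- function(genes, ranks, inh, dir)
    data.frame(gene_id = genes, rank = ranks, p_value = 0.01,
               inheritance = inh, background = "freq5pct", direction = dir,
               stringsAsFactors = FALSE)
  lists <- rbind(
    mk(c("A"), 5, "dominant", "sus"), mk(c("A"), 8, "recessive", "sus"),
    mk(c("B"), 7, "dominant", "res"), mk(c("B"), 9, "recessive", "res"))
  got <- ranklist_intersect(lists)
  expect_setequal(as.character(got), c("A", "B"))
  expect_equal(attr(got, "detail")$sus, "A")
})

test_that("panel merge intersects with expression and tracks provenance", {
  panel <- merge_panel(vaast_genes = c("a", "d", "x"),
                       ttest_genes = c("b", "d"),
                       fcbf_genes = c("c", "d"),
                       expressed_genes = c("a", "b", "c", "d"))
  expect_equal(panel$gene_id, c("a", "b", "c", "d"))
  expect_equal(panel$n_sources, c(1L, 1L, 1L, 3L))
  expect_true(all(panel[panel$gene_id == "d",
                        c("in_vaast", "in_ttest", "in_fcbf")] == TRUE))
  expect_false("x" %in% panel$gene_id)  # not expressed
  counts <- attr(panel, "counts")
  expect_equal(unname(counts["n_union"]), 4)
  # the expert keep-list is an explicit input restricting the panel
  kept <- merge_panel(c("a", "d"), c("b", "d"), c("c", "d"),
                      expressed_genes = letters[1:4], keep_list = c("b", "d"))
  expect_equal(kept$gene_id, c("b", "d"))
})
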