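#' Synthetic cohort specification
#'
#' Parameters for simulating the extreme-phenotype exome design: a cohort of
#' susceptible cases and resistant controls, genes segregating background
#' variants, and a set of planted genes in which cases carry deleterious
#' variants at an elevated rate.  Defaults mirror the study design (62
#' susceptible cases, 30 resistant controls).
#'
#' Per-gene variant load is modelled as sites segregating at carrier
#' frequency \code{carrier_freq}; the number of background sites per gene is
#' Poisson with mean \code{per_gene_variant_rate / carrier_freq}, so the mean
#' variant count per gene per individual is \code{per_gene_variant_rate}.
#' Each planted gene receives, in addition, \code{planted_sites_per_gene}
#' deleterious sites (one indel/stop-class, the rest strongly non-neutral
#' nonsynonymous with predictor scores in [-100, -40]) carried at
#' \code{planted_effect * carrier_freq} in cases but \code{carrier_freq} in
#' controls.  Background nonsynonymous sites draw predictor scores from the
#' neutral region [0, 80].
#'
#' Quality fields are independent draws with configurable failure fractions:
#' a genotype fails DP (< 6) with probability \code{dp_fail_rate} (raised to
#' 0.5 at the \code{low_dp_site_rate} fraction of sites, which therefore fail
#' the 80\%-of-samples site rule), fails GQ (< 30) with \code{gq_fail_rate},
#' and a site draws VQSLOD below 2 with probability \code{vqslod_fail_rate}.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_genes total gene count.
#' @param n_planted_genes number of deleterious-enriched genes (first genes).
#' @param planted_effect case/control carriage enrichment factor (>= 1;
#'   1 plants no effect).
#' @param per_gene_variant_rate mean variants per gene per individual.
#' @param het_fraction probability a carried variant is heterozygous.
#' @param class_mix probabilities over variant classes, named
#'   \code{stop_indel}, \code{nonsynonymous}, \code{synonymous}; must sum
#'   to 1.
#' @param carrier_freq background per-site carrier frequency.
#' @param planted_sites_per_gene deleterious sites added per planted gene.
#' @param vqslod_fail_rate,dp_fail_rate,gq_fail_rate,low_dp_site_rate
#'   quality-failure fractions (see Details).
#' @param seed random seed (integer).
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_cases = 62L, n_controls = 30L, n_genes = 200L,
                        n_planted_genes = 5L, planted_effect = 8,
                        per_gene_variant_rate = 0.15, het_fraction = 0.8,
                        class_mix = c(stop_indel = 0.1, nonsynonymous = 0.5,
                                      synonymous = 0.4),
                        carrier_freq = 0.05, planted_sites_per_gene = 3L,
                        vqslod_fail_rate = 0.05, dp_fail_rate = 0.02,
                        gq_fail_rate = 0.02, low_dp_site_rate = 0.03,
                        seed = 1L) {
  counts <- c(n_cases = n_cases, n_controls = n_controls, n_genes = n_genes,
              n_planted_genes = n_planted_genes,
              planted_sites_per_gene = planted_sites_per_gene)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (n_planted_genes > n_genes) stop("n_planted_genes exceeds n_genes")
  if (planted_effect < 1) stop("planted_effect must be >= 1")
  probs <- c(het_fraction, carrier_freq, vqslod_fail_rate, dp_fail_rate,
             gq_fail_rate, low_dp_site_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!setequal(names(class_mix),
                c("stop_indel", "nonsynonymous", "synonymous")))
    stop("class_mix must be named stop_indel, nonsynonymous, synonymous")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must be non-negative and sum to 1")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_genes = as.integer(n_genes),
                 n_planted_genes = as.integer(n_planted_genes),
                 planted_effect = planted_effect,
                 per_gene_variant_rate = per_gene_variant_rate,
                 het_fraction = het_fraction,
                 class_mix = class_mix[c("stop_indel", "nonsynonymous",
                                         "synonymous")],
                 carrier_freq = carrier_freq,
                 planted_sites_per_gene = as.integer(planted_sites_per_gene),
                 vqslod_fail_rate = vqslod_fail_rate,
                 dp_fail_rate = dp_fail_rate, gq_fail_rate = gq_fail_rate,
                 low_dp_site_rate = low_dp_site_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic extreme-phenotype cohort
#'
#' Simulates every input the variant pipeline consumes: a multi-sample
#' variant table (writable as VCF 4.2 via \code{\link{write_variant_vcf}}),
#' a per-site annotation table, phenotype labels, and a ground-truth manifest
#' listing all planted structure.  Identical spec + seed reproduces the
#' output exactly.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return An object of class \code{copd_cohort}: list with \code{variants}
#'   (a \code{\link{variant_table}}), \code{annotations},
#'   \code{phenotype} (named vector, \code{"susceptible"} /
#'   \code{"resistant"}), \code{manifest} and \code{spec}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  samples <- c(sprintf("case%03d", seq_len(spec$n_cases)),
               sprintf("ctrl%03d", seq_len(spec$n_controls)))
  phenotype <- setNames(rep(c("susceptible", "resistant"),
                            c(spec$n_cases, spec$n_controls)), samples)
  is_case <- phenotype == "susceptible"
  genes <- sprintf("gene%04d", seq_len(spec$n_genes))
  planted <- genes[seq_len(spec$n_planted_genes)]

  lambda_sites <- spec$per_gene_variant_rate / spec$carrier_freq
  n_bg <- rpois(spec$n_genes, lambda_sites)

  sites <- list(); k <- 0L
  add_site <- function(gene, class, score, freq_case, freq_ctrl, planted_del) {
    k <<- k + 1L
    sites[[k]] <<- data.frame(gene_id = gene, variant_class = class,
                              predictor_score = score,
                              freq_case = freq_case, freq_ctrl = freq_ctrl,
                              planted_deleterious = planted_del,
                              stringsAsFactors = FALSE)
  }
  classes <- c("stop_indel", "nonsynonymous", "synonymous")
  for (g in seq_len(spec$n_genes)) {
    if (n_bg[g] > 0) {
      cls <- sample(classes, n_bg[g], replace = TRUE, prob = spec$class_mix)
      for (cl in cls) {
        cl_out <- if (cl == "stop_indel")
          sample(c("stop_gain", "stop_loss", "indel"), 1L) else cl
        score <- if (cl == "nonsynonymous") runif(1L, 0, 80) else NA_real_
        add_site(genes[g], cl_out, score,
                 spec$carrier_freq, spec$carrier_freq, FALSE)
      }
    }
    if (genes[g] %in% planted) {
      fc <- min(1, spec$planted_effect * spec$carrier_freq)
      for (s in seq_len(spec$planted_sites_per_gene)) {
        if (s == 1L)
          add_site(genes[g], "indel", NA_real_, fc, spec$carrier_freq, TRUE)
        else
          add_site(genes[g], "nonsynonymous", runif(1L, -100, -40),
                   fc, spec$carrier_freq, TRUE)
      }
    }
  }
  site_df <- do.call(rbind, sites)
  n_sites <- nrow(site_df)
  site_df$site_id <- sprintf("s%05d", seq_len(n_sites))
  site_df$chrom <- "1"
  site_df$pos <- seq_len(n_sites) * 100L
  site_df$ref <- "A"
  site_df$alt <- ifelse(site_df$variant_class == "indel", "AT", "G")

  n_samp <- length(samples)
  freq <- matrix(rep(site_df$freq_ctrl, n_samp), nrow = n_sites)
  freq[, is_case] <- site_df$freq_case
  carrier <- matrix(rbinom(n_sites * n_samp, 1L, freq) == 1L, nrow = n_sites)
  het <- matrix(runif(n_sites * n_samp) < spec$het_fraction, nrow = n_sites)
  gt <- matrix("0/0", nrow = n_sites, ncol = n_samp,
               dimnames = list(site_df$site_id, samples))
  gt[carrier & het] <- "0/1"
  gt[carrier & !het] <- "1/1"

  low_dp_site <- runif(n_sites) < spec$low_dp_site_rate
  dp_fail_prob <- matrix(ifelse(low_dp_site, 0.5, spec$dp_fail_rate),
                         nrow = n_sites, ncol = n_samp)
  dp_fail <- matrix(runif(n_sites * n_samp) < dp_fail_prob, nrow = n_sites)
  dp <- matrix(sample(20:80, n_sites * n_samp, replace = TRUE),
               nrow = n_sites)
  dp[dp_fail] <- sample(0:5, sum(dp_fail), replace = TRUE)
  gq_fail <- matrix(runif(n_sites * n_samp) < spec$gq_fail_rate,
                    nrow = n_sites)
  gq <- matrix(sample(30:99, n_sites * n_samp, replace = TRUE),
               nrow = n_sites)
  gq[gq_fail] <- sample(0:29, sum(gq_fail), replace = TRUE)
  vq_fail <- runif(n_sites) < spec$vqslod_fail_rate
  vqslod <- ifelse(vq_fail, runif(n_sites, -5, 1.99), runif(n_sites, 2, 15))

  vt <- variant_table(
    sites = site_df[, c("site_id", "chrom", "pos", "ref", "alt")] |>
      cbind(vqslod = vqslod),
    gt = gt,
    dp = matrix(as.integer(dp), nrow = n_sites, dimnames = dimnames(gt)),
    gq = matrix(as.integer(gq), nrow = n_sites, dimnames = dimnames(gt)))

  annotations <- site_df[, c("site_id", "gene_id", "variant_class",
                             "predictor_score")]
  rownames(annotations) <- NULL
  manifest <- list(
    planted_genes = data.frame(
      gene_id = planted, effect = spec$planted_effect,
      case_freq = min(1, spec$planted_effect * spec$carrier_freq),
      control_freq = spec$carrier_freq, stringsAsFactors = FALSE),
    planted_deleterious_sites =
      site_df$site_id[site_df$planted_deleterious],
    vqslod_fail_sites = site_df$site_id[vq_fail],
    low_dp_sites = site_df$site_id[low_dp_site],
    n_sites = n_sites)
  structure(list(variants = vt, annotations = annotations,
                 phenotype = phenotype, manifest = manifest, spec = spec),
            class = "copd_cohort")
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat(sprintf("copd_cohort: %d cases + %d controls, %d genes (%d planted), %d sites\n",
              x$spec$n_cases, x$spec$n_controls, x$spec$n_genes,
              x$spec$n_planted_genes, x$manifest$n_sites))
  invisible(x)
}

#' Generate a synthetic FPKM expression matrix
#'
#' Simulates a transcript x donor FPKM matrix with known counts of
#' transcripts violating each expression filter, recorded in a manifest.
#' Base transcripts draw log-normal expression and are rescaled, when needed,
#' so their mean FPKM is at least 1; \code{n_low_abundance} transcripts are
#' planted at mean FPKM below 1 (uniform in [0.05, 0.95]); \code{n_high_var}
#' transcripts are planted with an across-donor spread exceeding tenfold
#' (IQR of log10 FPKM > 1).  With \code{zero_rate > 0} every entry is
#' independently zeroed with that probability (base transcripts are rescaled
#' after zeroing, so planted abundance truth is preserved).  Default planted
#' fractions emulate bronchial-epithelium expression structure in which
#' roughly half of transcripts reach mean FPKM 1.0 and ~96\% lie within
#' tenfold variability.
#'
#' Transcripts are assigned to genes in pairs, so the any-transcript rule of
#' the gene-level abundance filter is exercised.
#'
#' @param n_transcripts,n_donors matrix dimensions (n_donors >= 2).
#' @param zero_rate per-entry zero-inflation probability in [0, 1].
#' @param meanlog,sdlog base log-normal parameters.
#' @param n_low_abundance,n_high_var planted violation counts (defaults
#'   49.6\% and 3.8\% of transcripts).
#' @param seed random seed.
#' @return list with \code{expression} (an \code{\link{expression_matrix}})
#'   and \code{manifest} (planted transcript ids and realised zero counts).
#' @export
generate_fpkm <- function(n_transcripts = 32457L, n_donors = 5L,
                          zero_rate = 0, meanlog = log(15), sdlog = 0.5,
                          n_low_abundance = round(0.496 * n_transcripts),
                          n_high_var = round(0.038 * n_transcripts),
                          seed = 1L) {
  if (n_donors < 2L) stop("n_donors must be >= 2")
  if (zero_rate < 0 || zero_rate > 1) stop("zero_rate must be in [0, 1]")
  if (n_low_abundance + n_high_var > n_transcripts)
    stop("planted counts exceed n_transcripts")
  set.seed(seed)
  m <- matrix(rlnorm(n_transcripts * n_donors, meanlog, sdlog),
              nrow = n_transcripts)
  ids <- sprintf("t%06d", seq_len(n_transcripts))
  hv <- seq_len(n_high_var)
  low <- n_high_var + seq_len(n_low_abundance)
  base <- setdiff(seq_len(n_transcripts), c(hv, low))

  if (n_high_var > 0) {
    # bimodal donor pattern: ~half the donors 200-fold above the rest
    n_lo <- max(1L, floor(n_donors / 2))
    for (i in hv) {
      lvl <- rep(200, n_donors)
      lvl[sample(n_donors, n_lo)] <- 1
      m[i, ] <- lvl * rlnorm(n_donors, 0, 0.1)
    }
  }
  if (n_low_abundance > 0) {
    target <- runif(n_low_abundance, 0.05, 0.95)
    m[low, ] <- m[low, , drop = FALSE] * target / rowMeans(m[low, , drop = FALSE])
  }
  if (zero_rate > 0)
    m[matrix(runif(length(m)) < zero_rate, nrow = n_transcripts)] <- 0
  # keep base transcripts above the abundance threshold (planted truth exact)
  if (length(base)) {
    mb <- rowMeans(m[base, , drop = FALSE])
    fix <- base[mb < 1 & mb > 0]
    if (length(fix))
      m[fix, ] <- m[fix, , drop = FALSE] * 1.01 / rowMeans(m[fix, , drop = FALSE])
  }
  gene_ids <- sprintf("g%06d", (seq_len(n_transcripts) + 1L) %/% 2L)
  em <- expression_matrix(m, transcript_ids = ids, gene_ids = gene_ids)
  manifest <- list(low_abundance = ids[low], high_variability = ids[hv],
                   n_zero = setNames(as.integer(rowSums(m == 0)), ids))
  list(expression = em, manifest = manifest)
}

#' Synthetic siRNA screen specification
#'
#' Parameters for simulating the viability screen: genes are tested in
#' batches of 2-10 per independent experiment, each experiment carrying a
#' shared scrambled control; every gene is tested in
#' \code{n_experiments_per_gene} independent experiments with
#' \code{n_replicates} wells per condition.  Expected condition means are
#' \code{baseline} (A), \code{baseline * cse_effect} (B),
#' \code{baseline * alone} (C) and
#' \code{baseline * alone * cse_effect * interaction} (D), so the expected
#' interaction ratio of each gene equals its planted value and the expected
#' alone ratio equals its planted alone value.  Well noise is multiplicative
#' log-normal with unit mean and coefficient of variation \code{noise_cv}
#' (absorbance is positive and scale-proportional), so all generated
#' absorbances are strictly positive.
#'
#' @param n_genes number of screened genes (default 81).
#' @param batch_sizes allowed genes per experiment (subset of 2:10).
#' @param n_experiments_per_gene independent experiments per gene.
#' @param n_replicates replicate wells per condition.
#' @param baseline_absorbance expected control absorbance (positive).
#' @param cse_effect multiplicative viability factor of smoke extract on
#'   control cells (in (0, 1] for a toxic exposure).
#' @param planted_interactions named vector gene -> true interaction ratio
#'   (> 0); default 1 for every gene.  Must be non-empty.
#' @param planted_alone named vector gene -> true siRNA-alone ratio;
#'   default 1.
#' @param noise_cv coefficient of variation of well noise (>= 0).
#' @param seed random seed.
#' @return An object of class \code{screen_spec}.
#' @export
screen_spec <- function(n_genes = 81L, batch_sizes = 2:10,
                        n_experiments_per_gene = 3L, n_replicates = 3L,
                        baseline_absorbance = 1.0, cse_effect = 0.6,
                        planted_interactions = NULL, planted_alone = NULL,
                        noise_cv = 0.05, seed = 1L) {
  if (any(c(n_genes, n_experiments_per_gene, n_replicates) <= 0))
    stop("all counts must be positive")
  if (!all(batch_sizes %in% 2:10)) stop("batch_sizes must lie in 2..10")
  if (baseline_absorbance <= 0) stop("baseline_absorbance must be positive")
  if (cse_effect <= 0) stop("cse_effect must be positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  genes <- sprintf("g%02d", seq_len(n_genes))
  if (is.null(planted_interactions))
    planted_interactions <- setNames(rep(1, n_genes), genes)
  if (!length(planted_interactions))
    stop("planted_interactions must be non-empty")
  if (is.null(names(planted_interactions)))
    stop("planted_interactions must be named by gene")
  genes <- names(planted_interactions)
  if (length(genes) != n_genes)
    stop("planted_interactions must cover the n_genes genes")
  if (any(planted_interactions <= 0)) stop("interaction ratios must be > 0")
  if (is.null(planted_alone))
    planted_alone <- setNames(rep(1, n_genes), genes)
  planted_alone <- planted_alone[genes]
  if (anyNA(planted_alone) || any(planted_alone <= 0))
    stop("planted_alone must cover every gene with positive ratios")
  structure(list(n_genes = as.integer(n_genes), batch_sizes = batch_sizes,
                 n_experiments_per_gene = as.integer(n_experiments_per_gene),
                 n_replicates = as.integer(n_replicates),
                 baseline_absorbance = baseline_absorbance,
                 cse_effect = cse_effect,
                 planted_interactions = planted_interactions,
                 planted_alone = planted_alone,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "screen_spec")
}

#' Generate a synthetic siRNA screen plate table
#'
#' Simulates the full screen layout of a \code{\link{screen_spec}}: for each
#' experimental round the genes are shuffled and partitioned into batches
#' (sizes drawn from \code{batch_sizes}); each batch becomes one experiment
#' with shared scrambled A/B rows and per-gene C/D rows.  Returns the
#' long-form plate table consumed by \code{\link{screen_pipeline}} together
#' with a truth manifest (planted ratios and batch assignment).
#'
#' @param spec a \code{\link{screen_spec}}.
#' @return list with \code{plate} (data.frame: \code{experiment_id},
#'   \code{gene_id}, \code{condition}, \code{rep1..repK}) and
#'   \code{manifest} (\code{truth} data.frame and \code{batches}).
#' @export
generate_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  set.seed(spec$seed)
  genes <- names(spec$planted_interactions)
  k <- spec$n_replicates
  sdlog <- sqrt(log1p(spec$noise_cv^2))
  noise <- function(n) if (sdlog == 0) rep(1, n) else
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  rows <- list(); r <- 0L
  add <- function(exp_id, gene, cond, expected) {
    r <<- r + 1L
    rows[[r]] <<- c(list(experiment_id = exp_id, gene_id = gene,
                         condition = cond),
                    as.list(setNames(expected * noise(k),
                                     paste0("rep", seq_len(k)))))
  }
  batches <- list(); bi <- 0L
  exp_counter <- 0L
  for (round in seq_len(spec$n_experiments_per_gene)) {
    remaining <- sample(genes)
    while (length(remaining)) {
      size <- sample(spec$batch_sizes, 1L)
      batch <- remaining[seq_len(min(size, length(remaining)))]
      remaining <- setdiff(remaining, batch)
      exp_counter <- exp_counter + 1L
      exp_id <- sprintf("E%04d", exp_counter)
      bi <- bi + 1L
      batches[[bi]] <- data.frame(experiment_id = exp_id, round = round,
                                  gene_id = batch, stringsAsFactors = FALSE)
      base <- spec$baseline_absorbance
      add(exp_id, "scrambled", "A", base)
      add(exp_id, "scrambled", "B", base * spec$cse_effect)
      for (g in batch) {
        alone <- spec$planted_alone[[g]]
        inter <- spec$planted_interactions[[g]]
        add(exp_id, g, "C", base * alone)
        add(exp_id, g, "D", base * alone * spec$cse_effect * inter)
      }
    }
  }
  plate <- do.call(rbind, lapply(rows, as.data.frame,
                                 stringsAsFactors = FALSE))
  manifest <- list(
    truth = data.frame(gene_id = genes,
                       interaction = unname(spec$planted_interactions),
                       alone = unname(spec$planted_alone),
                       stringsAsFactors = FALSE),
    batches = do.call(rbind, batches))
  list(plate = plate, manifest = manifest)
}
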