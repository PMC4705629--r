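#' Scoring constants for the gene functional deficit score
#'
#' Per-class variant weights: insertions/deletions and stop gain/loss score 1;
#' a nonsynonymous variant predicted non-neutral (raw predictor score < 0)
#' scores \code{|score|/100} (mode \code{"magnitude"}) or \code{score/100}
#' (mode \code{"literal"}); a predicted-neutral nonsynonymous variant scores
#' 0.055; a synonymous variant 0.05.  Heterozygous variants are down-weighted
#' by \code{het_factor} (0.25) to approximate the effect of one intact copy.
#'
#' The default \code{"magnitude"} mode makes damaging variants contribute a
#' positive deficit (a literal signed score would rank them below synonymous
#' ones); \code{"literal"} keeps the signed convention for exact-replication
#' work.  Neither sign convention of the upstream predictor is asserted
#' correct -- both are available.
#'
#' @param indel_stop_score weight for indel / stop gain / stop loss.
#' @param neutral_nonsyn_score weight for predicted-neutral nonsynonymous.
#' @param synonymous_score weight for synonymous.
#' @param het_factor multiplicative factor for heterozygous calls, in (0, 1].
#' @param nonneutral_mode \code{"magnitude"} or \code{"literal"} (see above).
#' @return An object of class \code{score_constants}.
#' @export
score_constants <- function(indel_stop_score = 1.0,
                            neutral_nonsyn_score = 0.055,
                            synonymous_score = 0.05,
                            het_factor = 0.25,
                            nonneutral_mode = c("magnitude", "literal")) {
  nonneutral_mode <- match.arg(nonneutral_mode)
  if (!(het_factor > 0 && het_factor <= 1))
    stop("het_factor must be in (0, 1]")
  if (nonneutral_mode == "magnitude" &&
      any(c(indel_stop_score, neutral_nonsyn_score, synonymous_score) < 0))
    stop("scores must be >= 0 under magnitude mode")
  structure(list(indel_stop_score = indel_stop_score,
                 neutral_nonsyn_score = neutral_nonsyn_score,
                 synonymous_score = synonymous_score,
                 het_factor = het_factor,
                 nonneutral_mode = nonneutral_mode),
            class = "score_constants")
}

#' Score individual variant calls
#'
#' Vectorised over a data.frame of annotated calls (see
#' \code{\link{join_annotations}}).  Each call receives its class weight,
#' multiplied by \code{het_factor} when heterozygous.
#'
#' @param calls data.frame with columns \code{variant_class}, \code{zygosity}
#'   and \code{predictor_score}.
#' @param constants a \code{\link{score_constants}}.
#' @return Numeric vector of per-call scores.
#' @examples
#' variant_score(data.frame(variant_class = "stop_gain",
#'                          zygosity = "homozygous",
#'                          predictor_score = NA_real_))  # 1
#' @export
variant_score <- function(calls, constants = score_constants()) {
  stopifnot(inherits(constants, "score_constants"))
  cls <- calls$variant_class
  ns <- cls == "nonsynonymous"
  if (any(ns & is.na(calls$predictor_score)))
    stop("nonsynonymous call without predictor_score")
  s <- numeric(nrow(calls))
  s[cls %in% c("indel", "stop_gain", "stop_loss")] <- constants$indel_stop_score
  s[cls == "synonymous"] <- constants$synonymous_score
  if (any(ns)) {
    raw <- calls$predictor_score[ns]
    nonneutral <- raw < 0   # predictor convention: >= 0 is neutral
    val <- ifelse(nonneutral,
                  if (constants$nonneutral_mode == "magnitude")
                    abs(raw) / 100 else raw / 100,
                  constants$neutral_nonsyn_score)
    s[ns] <- val
  }
  het <- calls$zygosity == "heterozygous"
  s[het] <- s[het] * constants$het_factor
  s
}

#' Gene functional deficit score matrix
#'
#' Sums per-call variant scores into a gene x individual matrix: entry (g, i)
#' is the total deficit score of gene g in individual i, and is 0 exactly when
#' the individual carries no (post-filter) variant in that gene.  Genes and
#' samples with no calls at all can be forced into the matrix via
#' \code{genes} / \code{samples} so downstream contrasts see explicit zeros.
#'
#' @param calls annotated call data.frame (\code{\link{join_annotations}}).
#' @param constants a \code{\link{score_constants}}.
#' @param genes,samples optional character vectors fixing row/column universe
#'   (defaults to those present in \code{calls}).
#' @return Numeric matrix (genes x samples).
#' @export
gene_scores <- function(calls, constants = score_constants(),
                        genes = NULL, samples = NULL) {
  key <- calls[, c("site_id", "sample_id", "gene_id")]
  if (anyDuplicated(key))
    stop("duplicate (site, sample, gene) call(s); decompose upstream")
  if (is.null(genes)) genes <- sort(unique(calls$gene_id))
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  if (!all(calls$gene_id %in% genes) || !all(calls$sample_id %in% samples))
    stop("calls reference genes/samples outside the supplied universe")
  s <- variant_score(calls, constants)
  m <- matrix(0, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(calls)) {
    i <- match(calls$gene_id, genes)
    j <- match(calls$sample_id, samples)
    for (k in seq_along(s)) m[i[k], j[k]] <- m[i[k], j[k]] + s[k]
  }
  m
}

#' Cohort contrast of gene deficit scores
#'
#' Compares, gene by gene, the deficit-score distribution of susceptible
#' individuals against resistant ones with a two-sample t-test (Welch by
#' default), over \emph{all} individuals of each cohort (zeros included).
#' Genes are only tested when affected (score != 0) in at least
#' \code{min_affected_per_cohort} individuals in \emph{both} cohorts; genes
#' failing the restriction, or with constant scores in both cohorts, are
#' reported in attribute \code{"excluded"} with a reason.  Positive t means a
#' higher mean deficit in the susceptible cohort.
#'
#' Bonferroni-adjusted p-values over the tested genes are returned alongside.
#'
#' @param scores gene x sample matrix from \code{\link{gene_scores}}.
#' @param phenotype character/factor over samples (values
#'   \code{"susceptible"} / \code{"resistant"}), named by sample or aligned
#'   with the matrix columns.
#' @param min_affected_per_cohort inclusion threshold (default 10).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame with \code{gene_id}, \code{t_statistic}, \code{p_value},
#'   \code{p_bonferroni}, \code{n_affected_susceptible},
#'   \code{n_affected_resistant}; excluded genes in attribute
#'   \code{"excluded"}.
#' @export
cohort_ttest <- function(scores, phenotype, min_affected_per_cohort = 10L,
                         var_equal = FALSE) {
  if (!is.null(names(phenotype)))
    phenotype <- phenotype[colnames(scores)]
  phenotype <- as.character(phenotype)
  if (length(phenotype) != ncol(scores))
    stop("phenotype must cover every sample")
  if (!all(phenotype %in% c("susceptible", "resistant")))
    stop("phenotype values must be 'susceptible' or 'resistant'")
  sus <- phenotype == "susceptible"
  res <- phenotype == "resistant"
  if (!any(sus) || !any(res)) stop("both cohorts must be non-empty")

  n_aff_s <- rowSums(scores[, sus, drop = FALSE] != 0)
  n_aff_r <- rowSums(scores[, res, drop = FALSE] != 0)
  eligible <- n_aff_s >= min_affected_per_cohort &
    n_aff_r >= min_affected_per_cohort

  genes <- rownames(scores)
  rows <- vector("list", sum(eligible))
  excluded <- data.frame(gene_id = genes[!eligible],
                         reason = rep("below_min_affected", sum(!eligible)),
                         stringsAsFactors = FALSE)
  k <- 0L
  for (g in which(eligible)) {
    tt <- tryCatch(
      t.test(scores[g, sus], scores[g, res], var.equal = var_equal),
      error = function(e) NULL)
    if (is.null(tt)) {
      excluded <- rbind(excluded,
                        data.frame(gene_id = genes[g],
                                   reason = "degenerate_variance",
                                   stringsAsFactors = FALSE))
      next
    }
    k <- k + 1L
    rows[[k]] <- data.frame(gene_id = genes[g],
                            t_statistic = unname(tt$statistic),
                            p_value = tt$p.value,
                            n_affected_susceptible = n_aff_s[g],
                            n_affected_resistant = n_aff_r[g],
                            stringsAsFactors = FALSE)
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(gene_id = character(), t_statistic = numeric(),
               p_value = numeric(), n_affected_susceptible = integer(),
               n_affected_resistant = integer(), stringsAsFactors = FALSE)
  out$p_bonferroni <- p.adjust(out$p_value, method = "bonferroni")
  out <- out[, c("gene_id", "t_statistic", "p_value", "p_bonferroni",
                 "n_affected_susceptible", "n_affected_resistant")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
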