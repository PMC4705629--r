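#' Transcript x donor FPKM expression matrix
#'
#' Container for RNA-Seq expression of bronchial epithelial cultures:
#' non-negative FPKM values per transcript and donor, with a gene identifier
#' per transcript (a gene may have several transcript isoforms).
#'
#' @param fpkm numeric matrix (transcripts x donors), values >= 0.
#' @param transcript_ids,gene_ids character vectors along the rows (default
#'   transcript ids from rownames; gene ids default to the transcript ids).
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(fpkm, transcript_ids = rownames(fpkm),
                              gene_ids = transcript_ids) {
  fpkm <- as.matrix(fpkm)
  if (is.null(transcript_ids))
    transcript_ids <- sprintf("t%05d", seq_len(nrow(fpkm)))
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  if (ncol(fpkm) < 2L) stop("need at least 2 donors")
  if (length(transcript_ids) != nrow(fpkm) || length(gene_ids) != nrow(fpkm))
    stop("transcript_ids and gene_ids must match the row count")
  if (anyDuplicated(transcript_ids)) stop("duplicated transcript_ids")
  rownames(fpkm) <- transcript_ids
  if (is.null(colnames(fpkm)))
    colnames(fpkm) <- sprintf("donor%d", seq_len(ncol(fpkm)))
  structure(list(fpkm = fpkm, transcript_id = transcript_ids,
                 gene_id = gene_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts (%d genes) x %d donors\n",
              nrow(x$fpkm), length(unique(x$gene_id)), ncol(x$fpkm)))
  invisible(x)
}

#' Expression-variability statistics across donors
#'
#' Flags each transcript as within tenfold variability when the interquartile
#' range of its log10 FPKM across donors is at most 1.0 (boundary inclusive),
#' and summarises the fraction of transcripts within tenfold.  Transcripts
#' with 2 or more zero FPKM values are excluded from the variability
#' denominator; transcripts with exactly one zero are likewise dropped from
#' the variability statistic only (log10 of zero is undefined) but remain
#' available to the abundance filter.  Quantiles use linear interpolation
#' between order statistics (\code{quantile} type 7); the within-tenfold
#' flags are invariant to rescaling all FPKM by a constant.
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param max_log10_iqr variability bound on the IQR of log10 FPKM.
#' @param max_zeros a transcript with this many zero values (or more) is
#'   excluded from the variability denominator.
#' @return list with \code{per_transcript} (data.frame: \code{transcript_id},
#'   \code{gene_id}, \code{n_zero}, \code{in_denominator},
#'   \code{log10_iqr}, \code{within_tenfold}) and
#'   \code{fraction_within_tenfold}.
#' @export
variability_stats <- function(x, max_log10_iqr = 1.0, max_zeros = 2L) {
  stopifnot(inherits(x, "expression_matrix"))
  n_zero <- rowSums(x$fpkm == 0)
  in_denom <- n_zero == 0L          # >= max_zeros excluded per design; a
  excluded_rule <- n_zero >= max_zeros   # single zero also defeats log10
  iqr <- rep(NA_real_, nrow(x$fpkm))
  if (any(in_denom)) {
    lx <- log10(x$fpkm[in_denom, , drop = FALSE])
    q <- t(apply(lx, 1L, quantile, probs = c(0.25, 0.75), type = 7,
                 names = FALSE))
    iqr[in_denom] <- q[, 2L] - q[, 1L]
  }
  within <- ifelse(in_denom, iqr <= max_log10_iqr, NA)
  per <- data.frame(transcript_id = x$transcript_id,
                    gene_id = x$gene_id,
                    n_zero = as.integer(n_zero),
                    excluded_zero_rule = excluded_rule,
                    in_denominator = in_denom,
                    log10_iqr = iqr,
                    within_tenfold = within,
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(per_transcript = per,
       fraction_within_tenfold = mean(within[in_denom]))
}

#' Expression-abundance filter
#'
#' A transcript passes when its mean FPKM across donors is at least
#' \code{min_mean_fpkm} (inclusive, "1.0 or more"); a gene counts as
#' expressed when any of its transcripts passes.
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param min_mean_fpkm abundance threshold (default 1.0).
#' @return list with \code{per_transcript} (data.frame:
#'   \code{transcript_id}, \code{gene_id}, \code{mean_fpkm}, \code{pass})
#'   and \code{expressed_genes} (character vector).
#' @export
abundance_filter <- function(x, min_mean_fpkm = 1.0) {
  stopifnot(inherits(x, "expression_matrix"))
  m <- rowMeans(x$fpkm)
  pass <- m >= min_mean_fpkm
  per <- data.frame(transcript_id = x$transcript_id, gene_id = x$gene_id,
                    mean_fpkm = m, pass = pass, stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(per_transcript = per,
       expressed_genes = sort(unique(x$gene_id[pass])))
}
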