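#' Variant filter configuration
#'
#' Thresholds for the site- and genotype-level quality filters.  Defaults are
#' the study design's values: sites are kept when VQSLOD >= 2 and DP >= 6 in
#' at least 80\% of samples; individual genotypes with DP < 6 or GQ < 30 are
#' set to no-call.  All ">=" bounds are inclusive and "<" bounds exclusive,
#' exactly as written.
#'
#' @param min_vqslod minimum site-level recalibrated quality (VQSLOD).
#' @param min_dp minimum per-genotype read depth.
#' @param min_gq minimum per-genotype quality.
#' @param min_dp_sample_fraction fraction of samples that must reach
#'   \code{min_dp} for a site to be kept; in (0, 1].
#' @return An object of class \code{filter_config}.
#' @export
filter_config <- function(min_vqslod = 2, min_dp = 6L, min_gq = 30L,
                          min_dp_sample_fraction = 0.80) {
  if (!(min_dp_sample_fraction > 0 && min_dp_sample_fraction <= 1))
    stop("min_dp_sample_fraction must be in (0, 1]")
  structure(list(min_vqslod = min_vqslod, min_dp = as.integer(min_dp),
                 min_gq = as.integer(min_gq),
                 min_dp_sample_fraction = min_dp_sample_fraction),
            class = "filter_config")
}

#' Site-level variant filtering
#'
#' Retains sites with \code{VQSLOD >= min_vqslod} and read depth
#' \code{DP >= min_dp} in at least \code{min_dp_sample_fraction} of samples.
#' Site order is preserved and a per-site filter-reason log is attached as
#' attribute \code{"filter_log"} (columns \code{site_id}, \code{retained},
#' \code{reason}; failing sites list every violated rule, separated by
#' \code{";"}).  Missing DP counts as below threshold.
#'
#' @param x a \code{\link{variant_table}}.
#' @param config a \code{\link{filter_config}}.
#' @return The filtered \code{variant_table}, with the filter log attached.
#' @export
filter_sites <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "variant_table"), inherits(config, "filter_config"))
  if (anyNA(x$sites$vqslod))
    stop("missing VQSLOD at site(s): ",
         paste(x$sites$site_id[is.na(x$sites$vqslod)], collapse = ", "))
  vq_ok <- x$sites$vqslod >= config$min_vqslod
  dp_ok_mat <- !is.na(x$dp) & x$dp >= config$min_dp
  dp_frac <- rowMeans(dp_ok_mat)
  dp_ok <- dp_frac >= config$min_dp_sample_fraction
  keep <- vq_ok & dp_ok
  reason <- character(nrow(x$sites))
  reason[!vq_ok] <- "low_vqslod"
  reason[!dp_ok] <- ifelse(reason[!dp_ok] == "", "low_dp_fraction",
                           paste(reason[!dp_ok], "low_dp_fraction", sep = ";"))
  log <- data.frame(site_id = x$sites$site_id, retained = keep,
                    reason = reason, stringsAsFactors = FALSE)
  out <- variant_table(x$sites[keep, , drop = FALSE],
                       x$gt[keep, , drop = FALSE],
                       x$dp[keep, , drop = FALSE],
                       x$gq[keep, , drop = FALSE])
  attr(out, "filter_log") <- log
  out
}

#' Genotype-level no-call masking
#'
#' Sets individual genotypes with \code{DP < min_dp} or \code{GQ < min_gq} to
#' no-call (\code{NA}); all other genotypes are untouched.  A genotype with
#' missing GQ fails the filter (conservative) and is counted separately in the
#' log attached as attribute \code{"nocall_log"}.
#'
#' @inheritParams filter_sites
#' @return The masked \code{variant_table} with a no-call count log attached.
#' @export
apply_genotype_nocalls <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "variant_table"), inherits(config, "filter_config"))
  called <- !is.na(x$gt)
  low_dp <- is.na(x$dp) | x$dp < config$min_dp
  missing_gq <- is.na(x$gq)
  low_gq <- missing_gq | x$gq < config$min_gq
  mask <- called & (low_dp | low_gq)
  out <- x
  out$gt[mask] <- NA_character_
  attr(out, "nocall_log") <- c(
    n_called_in = sum(called),
    n_masked = sum(mask),
    n_low_dp = sum(called & low_dp),
    n_low_gq = sum(called & low_gq & !missing_gq),
    n_missing_gq = sum(called & missing_gq))
  out
}

# Count alternate alleles in a genotype string ("0/1", "1|1", ...).
alt_dosage <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) sum(a != "0" & a != "."), integer(1L))
}

#' Join filtered genotypes with per-site gene annotations
#'
#' Produces one annotated variant call per (called, non-reference) genotype
#' per annotated gene.  A variant annotated to several genes (overlapping
#' loci) contributes one call per gene; annotation tables are expected to
#' already be reduced to the primary isoform per gene, so a site appears at
#' most once per gene.  Sites absent from the annotation table are dropped
#' with a warning and counted in attribute \code{"join_log"}.
#'
#' @param x a \code{\link{variant_table}} (after filtering / no-call masking).
#' @param annotations data.frame with columns \code{site_id}, \code{gene_id},
#'   \code{variant_class} (one of \code{stop_gain}, \code{stop_loss},
#'   \code{indel}, \code{nonsynonymous}, \code{synonymous}) and
#'   \code{predictor_score} (raw protein-effect predictor score in
#'   [-100, 100]; required for nonsynonymous variants, \code{NA} otherwise).
#' @return data.frame of calls: \code{sample_id}, \code{gene_id},
#'   \code{site_id}, \code{variant_class}, \code{zygosity}
#'   (\code{heterozygous}/\code{homozygous}), \code{predictor_score},
#'   \code{dp}, \code{gq}, \code{vqslod}.
#' @export
join_annotations <- function(x, annotations) {
  stopifnot(inherits(x, "variant_table"))
  req <- c("site_id", "gene_id", "variant_class", "predictor_score")
  if (!all(req %in% names(annotations)))
    stop("annotations must have columns: ", paste(req, collapse = ", "))
  classes <- c("stop_gain", "stop_loss", "indel", "nonsynonymous", "synonymous")
  bad <- setdiff(unique(annotations$variant_class), classes)
  if (length(bad)) stop("unknown variant_class: ", paste(bad, collapse = ", "))
  ns <- annotations$variant_class == "nonsynonymous"
  if (any(ns & is.na(annotations$predictor_score)))
    stop("nonsynonymous annotation without predictor_score at site(s): ",
         paste(annotations$site_id[ns & is.na(annotations$predictor_score)],
               collapse = ", "))
  if (anyDuplicated(annotations[, c("site_id", "gene_id")]))
    stop("duplicated (site_id, gene_id) in annotations")

  unannotated <- setdiff(x$sites$site_id, annotations$site_id)
  if (length(unannotated))
    warning(length(unannotated), " site(s) without annotation excluded")

  dosage <- matrix(0L, nrow = nrow(x$gt), ncol = ncol(x$gt),
                   dimnames = dimnames(x$gt))
  called <- !is.na(x$gt)
  dosage[called] <- alt_dosage(x$gt[called])
  idx <- which(called & dosage > 0L, arr.ind = TRUE)
  if (nrow(idx)) {
    carriers <- data.frame(
      site_id = rownames(x$gt)[idx[, 1L]],
      sample_id = colnames(x$gt)[idx[, 2L]],
      zygosity = ifelse(dosage[idx] >= 2L, "homozygous", "heterozygous"),
      dp = x$dp[idx], gq = x$gq[idx],
      stringsAsFactors = FALSE)
    calls <- merge(carriers, annotations, by = "site_id")
    calls <- merge(calls, x$sites[, c("site_id", "vqslod")], by = "site_id")
  } else {
    calls <- data.frame(site_id = character(), sample_id = character(),
                        zygosity = character(), dp = integer(), gq = integer(),
                        gene_id = character(), variant_class = character(),
                        predictor_score = numeric(), vqslod = numeric(),
                        stringsAsFactors = FALSE)
  }
  calls <- calls[order(calls$gene_id, calls$site_id, calls$sample_id),
                 c("sample_id", "gene_id", "site_id", "variant_class",
                   "zygosity", "predictor_score", "dp", "gq", "vqslod")]
  rownames(calls) <- NULL
  attr(calls, "join_log") <- c(n_sites_unannotated = length(unannotated),
                               n_calls = nrow(calls))
  calls
}
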