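#' Robust pseudo standard deviation
#'
#' Nonparametric scale estimate: interquartile range divided by 1.35 (the
#' normal-consistency factor).  Quantiles use linear interpolation between
#' order statistics (\code{quantile} type 7); with triplicate values this
#' convention is consequential, giving IQR = (max - min) / 2 for n = 3.
#'
#' @param x numeric vector (length >= 2).
#' @return pseudo-SD (>= 0).
#' @export
pseudo_sd <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values for the IQR")
  IQR(x, type = 7) / 1.35
}

# Replicate columns of a plate table.
.rep_cols <- function(plate) grep("^rep", names(plate), value = TRUE)

#' siRNA screen interaction and alone ratios
#'
#' For one gene in one experiment, given the four condition groups
#' (A: scrambled control without smoke extract, B: scrambled with extract,
#' C: gene siRNA without extract, D: gene siRNA with extract), replicate
#' absorbances are averaged per group and the multiplicative
#' gene-environment interaction ratio \eqn{(\bar D / \bar C) /
#' (\bar B / \bar A)} and the siRNA-alone ratio \eqn{\bar C / \bar A} are
#' returned.  An interaction ratio below 1 means knockdown augments
#' smoke-induced cytotoxicity; above 1, protects against it.  Both ratios
#' are invariant to rescaling all absorbances by a constant.
#'
#' @param records data.frame with columns \code{condition} (exactly the four
#'   values A-D) and replicate absorbance columns \code{rep1}, \code{rep2},
#'   ... (positive).
#' @return named numeric vector \code{c(interaction, alone)}.
#' @examples
#' recs <- data.frame(condition = c("A", "B", "C", "D"),
#'                    rep1 = c(1, 0.8, 1, 0.4),
#'                    rep2 = c(1, 0.8, 1, 0.4),
#'                    rep3 = c(1, 0.8, 1, 0.4))
#' interaction_ratio(recs)  # interaction 0.5, alone 1
#' @export
interaction_ratio <- function(records) {
  rc <- .rep_cols(records)
  if (!length(rc)) stop("no replicate (rep*) columns found")
  if (!setequal(records$condition, c("A", "B", "C", "D")) ||
      nrow(records) != 4L)
    stop("records must contain exactly one row per condition A, B, C, D")
  vals <- as.matrix(records[, rc, drop = FALSE])
  means <- rowMeans(vals)
  names(means) <- records$condition
  if (any(!is.finite(means)) || any(means <= 0))
    stop("non-positive mean absorbance in group(s): ",
         paste(records$condition[means <= 0 | !is.finite(means)],
               collapse = ", "))
  c(interaction = unname((means["D"] / means["C"]) /
                           (means["B"] / means["A"])),
    alone = unname(means["C"] / means["A"]))
}

#' Robust one-sample Z-scores for screen ratios
#'
#' Default \code{scope = "per_gene"}: for every gene, the mean of its
#' per-experiment ratios is compared against \code{null_center} (1 = no
#' effect), scaled by the pseudo-SD (IQR / 1.35) of those ratios -- a
#' one-sample Z-test per gene.  \code{scope = "global"} instead standardises
#' each gene's single summary ratio against the centre and pseudo-SD of the
#' whole gene population.  The one-sided p-value takes the lower normal tail
#' for negative z and the upper tail otherwise, so both response directions
#' are detected.
#'
#' A gene whose pseudo-SD is zero gets \code{NA} z (flagged), never a silent
#' infinity.  No \eqn{\sqrt n} divisor is applied by default (the statistic
#' uses the dispersion itself, not a standard error); \code{use_se = TRUE}
#' switches it on.
#'
#' @param ratios for \code{"per_gene"}: a named list of per-experiment ratio
#'   vectors (one element per gene, each length >= 2); for \code{"global"}: a
#'   named numeric vector of per-gene ratios.
#' @param scope \code{"per_gene"} or \code{"global"}.
#' @param null_center null hypothesis centre for the per-gene test.
#' @param use_se divide the per-gene pseudo-SD by \eqn{\sqrt n}.
#' @param center,scale optional explicit centre/scale for the global scope
#'   (both must be given together), e.g. parameters recovered by
#'   \code{\link{infer_z_parameters}}.
#' @return data.frame with \code{gene_id}, \code{ratio} (per-gene mean or the
#'   supplied value), \code{n}, \code{z_score}, \code{p_one_sided}.
#' @export
robust_z <- function(ratios, scope = c("per_gene", "global"),
                     null_center = 1, use_se = FALSE,
                     center = NULL, scale = NULL) {
  scope <- match.arg(scope)
  if (scope == "per_gene") {
    if (!is.list(ratios)) stop("per_gene scope expects a list of vectors")
    gene <- names(ratios)
    mean_r <- vapply(ratios, mean, numeric(1))
    n <- lengths(ratios)
    psd <- vapply(ratios, pseudo_sd, numeric(1))
    if (use_se) psd <- psd / sqrt(n)
    z <- ifelse(psd > 0, (mean_r - null_center) / psd, NA_real_)
  } else {
    if (!is.numeric(ratios)) stop("global scope expects a numeric vector")
    gene <- names(ratios)
    if (is.null(center) != is.null(scale))
      stop("supply center and scale together")
    if (is.null(center)) {
      if (length(ratios) < 2L) stop("need >= 2 genes for the global scale")
      center <- mean(ratios)
      scale <- pseudo_sd(ratios)
    }
    if (scale <= 0) stop("global pseudo-SD must be positive")
    mean_r <- unname(ratios)
    n <- rep(1L, length(ratios))
    z <- (mean_r - center) / scale
  }
  p <- ifelse(z < 0, pnorm(z), pnorm(z, lower.tail = FALSE))
  out <- data.frame(gene_id = gene, ratio = unname(mean_r), n = unname(n),
                    z_score = unname(z), p_one_sided = unname(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Recover a global centre and scale from (ratio, z) pairs
#'
#' Given ratios and the Z-scores they map to under a common standardisation
#' \eqn{z = (r - center) / scale}, solves for the centre and scale by linear
#' regression of ratio on z (exact for two pairs).  Useful as a cross-check
#' that a published Z column is (or is not) consistent with one global
#' centre/scale.
#'
#' @param ratio,z_score numeric vectors (length >= 2).
#' @return named vector \code{c(center, pseudo_sd)}.
#' @export
infer_z_parameters <- function(ratio, z_score) {
  if (length(ratio) < 2L || length(ratio) != length(z_score))
    stop("need >= 2 (ratio, z) pairs of equal length")
  fit <- lm(ratio ~ z_score)
  c(center = unname(coef(fit)[1L]), pseudo_sd = unname(coef(fit)[2L]))
}

#' Two-tailed Benjamini-Hochberg significance calls
#'
#' Partitions genes by the sign of z into an \emph{augmenting} tail (z < 0:
#' knockdown augments cytotoxicity) and a \emph{protecting} tail (z > 0);
#' genes with z exactly 0 or undefined are left unassigned and logged.
#' Within each tail, p-values are sorted ascending and compared against
#' \eqn{BH(j) = \alpha j / n} with n the tail size.  The default
#' \code{"pointwise"} rule marks gene j significant iff
#' \eqn{p(j) \le BH(j)} row by row, exactly as the threshold formula is
#' written; the standard step-up rule (significant up to the largest j
#' satisfying the inequality) is available via \code{rule = "stepup"}.
#'
#' @param results data.frame with \code{gene_id}, \code{z_score},
#'   \code{p_one_sided} (e.g. from \code{\link{robust_z}}).
#' @param alpha FDR level (default 0.05).
#' @param rule \code{"pointwise"} or \code{"stepup"}.
#' @return \code{results} with added \code{tail}, \code{rank_in_tail},
#'   \code{bh_threshold} and \code{significant}; unassigned genes carry
#'   \code{NA} in these columns and are listed in attribute
#'   \code{"unassigned"}.
#' @export
bh_calls <- function(results, alpha = 0.05,
                     rule = c("pointwise", "stepup")) {
  rule <- match.arg(rule)
  stopifnot(all(c("gene_id", "z_score", "p_one_sided") %in% names(results)))
  z <- results$z_score
  tail <- rep(NA_character_, nrow(results))
  tail[!is.na(z) & z < 0] <- "augmenting"
  tail[!is.na(z) & z > 0] <- "protecting"
  results$tail <- tail
  results$rank_in_tail <- NA_integer_
  results$bh_threshold <- NA_real_
  results$significant <- NA
  for (tl in c("augmenting", "protecting")) {
    idx <- which(!is.na(tail) & tail == tl)
    if (!length(idx)) next
    n_tail <- length(idx)
    ord <- idx[order(results$p_one_sided[idx], results$gene_id[idx])]
    j <- seq_len(n_tail)
    bh <- alpha * j / n_tail
    pj <- results$p_one_sided[ord]
    sig <- if (rule == "pointwise") pj <= bh else {
      jmax <- suppressWarnings(max(which(pj <= bh)))
      if (is.finite(jmax)) j <= jmax else rep(FALSE, n_tail)
    }
    results$rank_in_tail[ord] <- j
    results$bh_threshold[ord] <- bh
    results$significant[ord] <- sig
  }
  attr(results, "unassigned") <- results$gene_id[is.na(tail)]
  results
}

# Gather per-gene, per-experiment (interaction, alone) ratios from a plate
# table; genes missing a condition in any of their experiments are excluded
# with a reason.
.collect_ratios <- function(plate, scrambled_id = "scrambled") {
  rc <- .rep_cols(plate)
  if (!length(rc)) stop("no replicate (rep*) columns found")
  vals <- as.matrix(plate[, rc, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all absorbances must be positive")
  plate$.mean <- rowMeans(vals)
  ctrl <- plate[plate$gene_id == scrambled_id, ]
  genes <- setdiff(unique(plate$gene_id), scrambled_id)
  inter <- list(); alone <- list(); excluded <- character(0)
  reasons <- character(0)
  for (g in genes) {
    sub <- plate[plate$gene_id == g, ]
    exps <- unique(sub$experiment_id)
    iv <- numeric(0); av <- numeric(0)
    ok <- TRUE
    for (e in exps) {
      se <- sub[sub$experiment_id == e, ]
      ce <- ctrl[ctrl$experiment_id == e, ]
      a <- ce$.mean[ce$condition == "A"]
      b <- ce$.mean[ce$condition == "B"]
      cc <- se$.mean[se$condition == "C"]
      d <- se$.mean[se$condition == "D"]
      if (length(a) != 1L || length(b) != 1L || length(cc) != 1L ||
          length(d) != 1L) { ok <- FALSE; break }
      iv <- c(iv, (d / cc) / (b / a))
      av <- c(av, cc / a)
    }
    if (!ok || length(iv) < 2L) {
      excluded <- c(excluded, g)
      reasons <- c(reasons, if (!ok) "missing_condition"
                   else "fewer_than_2_experiments")
      next
    }
    inter[[g]] <- iv
    alone[[g]] <- av
  }
  list(interaction = inter, alone = alone,
       excluded = data.frame(gene_id = excluded, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Full siRNA screen analysis
#'
#' Runs the complete screen statistic on a plate table: per-gene,
#' per-experiment interaction and siRNA-alone ratios; robust Z-scores and
#' one-sided p-values; tail assignment and Benjamini-Hochberg calls for the
#' gene-environment interaction (both tails); and the siRNA-alone analysis
#' restricted to its lower tail (genes whose knockdown alone reduced
#' viability).  Genes missing a condition in any experiment are excluded
#' with a logged reason.
#'
#' The plate table is long-form with one row per condition per experiment:
#' columns \code{experiment_id}, \code{gene_id} (the shared scrambled
#' control rows carry \code{gene_id = "scrambled"}), \code{condition}
#' (A/B/C/D) and replicate absorbances \code{rep1}, \code{rep2}, ...
#'
#' @param plate plate table (see \code{\link{generate_screen}} for the
#'   generated form).
#' @param alpha FDR level.
#' @param scope,null_center,use_se passed to \code{\link{robust_z}}.
#' @param rule passed to \code{\link{bh_calls}}.
#' @param scrambled_id gene_id of the scrambled-control rows.
#' @return An object of class \code{screen_result}: list with
#'   \code{interaction} and \code{alone} result tables (gene, ratio, z, p,
#'   tail, BH threshold, significance, replicate provenance),
#'   \code{excluded}, and the analysis settings.
#' @export
screen_pipeline <- function(plate, alpha = 0.05,
                            scope = "per_gene", rule = "pointwise",
                            null_center = 1, use_se = FALSE,
                            scrambled_id = "scrambled") {
  coll <- .collect_ratios(plate, scrambled_id = scrambled_id)
  if (!length(coll$interaction))
    stop("no analysable genes in the plate table")
  if (scope == "per_gene") {
    zint <- robust_z(coll$interaction, scope = "per_gene",
                     null_center = null_center, use_se = use_se)
    zalo <- robust_z(coll$alone, scope = "per_gene",
                     null_center = null_center, use_se = use_se)
  } else {
    zint <- robust_z(vapply(coll$interaction, mean, numeric(1)),
                     scope = "global")
    zalo <- robust_z(vapply(coll$alone, mean, numeric(1)), scope = "global")
  }
  interaction <- bh_calls(zint, alpha = alpha, rule = rule)

  # siRNA-alone analysis: lower tail only (reduced viability).
  alone <- zalo
  lower <- !is.na(alone$z_score) & alone$z_score < 0
  alone$tail <- ifelse(lower, "augmenting", NA_character_)
  alone$rank_in_tail <- NA_integer_
  alone$bh_threshold <- NA_real_
  alone$significant <- NA
  if (any(lower)) {
    idx <- which(lower)
    n_tail <- length(idx)
    ord <- idx[order(alone$p_one_sided[idx], alone$gene_id[idx])]
    j <- seq_len(n_tail)
    bh <- alpha * j / n_tail
    pj <- alone$p_one_sided[ord]
    sig <- if (rule == "pointwise") pj <= bh else {
      jmax <- suppressWarnings(max(which(pj <= bh)))
      if (is.finite(jmax)) j <= jmax else rep(FALSE, n_tail)
    }
    alone$rank_in_tail[ord] <- j
    alone$bh_threshold[ord] <- bh
    alone$significant[ord] <- sig
  }
  structure(list(interaction = interaction, alone = alone,
                 excluded = coll$excluded,
                 alpha = alpha, scope = scope, rule = rule,
                 null_center = null_center),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  n <- nrow(x$interaction)
  cat(sprintf("screen_result: %d genes analysed (alpha = %g, %s scope, %s rule)\n",
              n, x$alpha, x$scope, x$rule))
  tl <- table(factor(x$interaction$tail, c("augmenting", "protecting")))
  cat(sprintf("  interaction tails: %d augmenting, %d protecting\n",
              tl[["augmenting"]], tl[["protecting"]]))
  cat(sprintf("  significant: %d augmenting, %d protecting, %d alone-effect\n",
              sum(x$interaction$significant & x$interaction$tail == "augmenting",
                  na.rm = TRUE),
              sum(x$interaction$significant & x$interaction$tail == "protecting",
                  na.rm = TRUE),
              sum(x$alone$significant, na.rm = TRUE)))
  if (nrow(x$excluded))
    cat(sprintf("  excluded genes: %d\n", nrow(x$excluded)))
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  fmt <- function(df, p_digits) {
    df <- df[!is.na(df$significant) & df$significant, ]
    df <- df[order(df$tail, df$rank_in_tail), ]
    df$ratio <- round(df$ratio, 3)
    df$z_score <- round(df$z_score, 3)
    df$p_one_sided <- round(df$p_one_sided, p_digits)
    df
  }
  out <- list(interaction = fmt(object$interaction, 4L),
              alone = fmt(object$alone, 5L),
              excluded = object$excluded)
  class(out) <- "summary.screen_result"
  out
}

#' @export
print.summary.screen_result <- function(x, ...) {
  cat("Significant gene-environment interactions:\n")
  print(x$interaction[, c("gene_id", "ratio", "z_score", "p_one_sided",
                          "tail", "bh_threshold")], row.names = FALSE)
  cat("\nSignificant siRNA-alone effects (reduced viability):\n")
  print(x$alone[, c("gene_id", "ratio", "z_score", "p_one_sided",
                    "bh_threshold")], row.names = FALSE)
  invisible(x)
}

#' Published screen summary tables (example data)
#'
#' Top-five gene summaries from a published siRNA viability screen of
#' cigarette-smoke-extract-exposed human bronchial epithelial cells, as
#' printed: the gene-environment interaction tails (augmenting, tail size
#' 50; protecting, tail size 31) and the siRNA-alone analysis (lower tail,
#' size 46).  Each table carries the reported ratio, Z-score, one-sided
#' p-value and BH FDR threshold at the published print precision, plus the
#' reported significance mark.  Used as worked examples and as a cross-check
#' fixture for the Z/p/BH machinery.
#'
#' @return Named list of three data.frames (\code{augmenting},
#'   \code{protecting}, \code{alone}), each with attribute \code{"n_tail"}.
#' @export
cse_screen_examples <- function() {
  dir <- system.file("extdata", package = "copdexome")
  read1 <- function(f, n_tail) {
    d <- read.table(file.path(dir, f), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    attr(d, "n_tail") <- n_tail
    d
  }
  list(augmenting = read1("cse_screen_augmenting_top5.tsv", 50L),
       protecting = read1("cse_screen_protecting_top5.tsv", 31L),
       alone = read1("cse_screen_alone_top5.tsv", 46L))
}
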