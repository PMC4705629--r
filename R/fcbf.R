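# Shannon entropy (bits) of a discrete vector.
entropy_bits <- function(x) {
  p <- tabulate(match(x, unique(x)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

# Entropy (bits) of rows of a count matrix, each row summing to n.
.row_entropy <- function(counts, n) {
  p <- counts / n
  h <- p * log2(p)
  h[!is.finite(h)] <- 0
  -rowSums(h)
}

#' Symmetrical uncertainty between two discrete vectors
#'
#' \eqn{SU(X, Y) = 2 I(X; Y) / (H(X) + H(Y))}, with Shannon entropies in
#' bits and plug-in probability estimates.  SU is a normalised mutual
#' information in [0, 1]; by convention SU = 0 when \eqn{H(X) + H(Y) = 0}
#' (both vectors constant).  SU is symmetric and invariant to relabelling of
#' the category codes.
#'
#' @param x,y discrete vectors (integer/character/factor) of equal length.
#' @return SU in [0, 1].
#' @examples
#' symmetrical_uncertainty(c(0, 1, 0, 1), c(0, 1, 0, 1))  # 1
#' symmetrical_uncertainty(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!length(x)) stop("x and y must be non-empty")
  hx <- entropy_bits(x)
  hy <- entropy_bits(y)
  if (hx + hy == 0) return(0)
  hxy <- entropy_bits(paste(x, y, sep = "\r"))
  mi <- hx + hy - hxy
  min(1, max(0, 2 * mi / (hx + hy)))
}

# Fayyad-Irani MDL-principle supervised cut points for one numeric attribute.
# Returns a (possibly empty) sorted vector of cut points (bin boundaries at
# midpoints between adjacent distinct values).
mdlp_cuts <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]
  ys <- match(y, unique(y))[ord]
  k_all <- max(ys)
  cuts <- numeric(0)

  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L) return(invisible())
    xs_ <- xs[lo:hi]; ys_ <- ys[lo:hi]
    cand <- which(diff(xs_) > 0)          # boundaries between distinct values
    if (!length(cand)) return(invisible())
    counts <- matrix(0L, nrow = n, ncol = k_all)
    counts[cbind(seq_len(n), ys_)] <- 1L
    cum <- apply(counts, 2L, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
    tot <- cum[n, ]
    left <- cum[cand, , drop = FALSE]
    right <- rep(tot, each = length(cand)) - left
    nl <- cand; nr <- n - cand
    h_left <- .row_entropy(left, nl)
    h_right <- .row_entropy(right, nr)
    h_s <- .row_entropy(matrix(tot, nrow = 1L), n)
    e <- (nl / n) * h_left + (nr / n) * h_right
    b <- which.min(e)
    gain <- h_s - e[b]
    k <- sum(tot > 0)
    k1 <- sum(left[b, ] > 0); k2 <- sum(right[b, ] > 0)
    delta <- log2(3^k - 2) - (k * h_s - k1 * h_left[b] - k2 * h_right[b])
    if (gain > (log2(n - 1) + delta) / n) {
      pos <- cand[b]
      cuts <<- c(cuts, (xs_[pos] + xs_[pos + 1L]) / 2)
      recurse(lo, lo + pos - 1L)
      recurse(lo + pos, hi)
    }
    invisible()
  }
  recurse(1L, length(xs))
  sort(cuts)
}

#' Discretize a gene-score matrix
#'
#' Bins every gene's score profile into integer codes, a prerequisite for the
#' entropy-based SU/FCBF machinery.  The default is Fayyad-Irani MDL
#' supervised discretization (requires class \code{labels}); unsupervised
#' equal-frequency and equal-width binnings are available as fallbacks.
#' Genes that collapse to a single bin are flagged (their SU with any vector
#' is 0 by construction).
#'
#' @param scores gene x sample numeric matrix.
#' @param method \code{"mdl"}, \code{"equal_frequency"} or
#'   \code{"equal_width"}.
#' @param labels class labels over samples (required for \code{"mdl"}).
#' @param n_bins bin count for the unsupervised methods.
#' @return An object of class \code{discretized_matrix}: list with integer
#'   \code{codes} (gene x sample, values in \code{0:(n_bins_g - 1)}),
#'   per-gene \code{edges} (strictly increasing interior cut points),
#'   \code{single_bin} flags and the \code{method} tag.
#' @export
discretize <- function(scores, method = c("mdl", "equal_frequency",
                                          "equal_width"),
                       labels = NULL, n_bins = 2L) {
  method <- match.arg(method)
  if (method == "mdl") {
    if (is.null(labels)) stop("MDL discretization requires class labels")
    if (length(labels) != ncol(scores))
      stop("labels must cover every sample")
  }
  if (ncol(scores) < 2L) stop("need at least 2 samples")
  genes <- rownames(scores)
  codes <- matrix(0L, nrow = nrow(scores), ncol = ncol(scores),
                  dimnames = dimnames(scores))
  edges <- vector("list", nrow(scores))
  names(edges) <- genes
  for (g in seq_len(nrow(scores))) {
    x <- scores[g, ]
    cuts <- switch(method,
      mdl = mdlp_cuts(x, labels),
      equal_frequency = {
        q <- quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                      type = 7, names = FALSE)
        unique(q[-c(1L, n_bins + 1L)])
      },
      equal_width = {
        if (max(x) > min(x))
          seq(min(x), max(x), length.out = n_bins + 1L)[-c(1L, n_bins + 1L)]
        else numeric(0)
      })
    cuts <- sort(unique(cuts))
    edges[[g]] <- cuts
    codes[g, ] <- findInterval(x, cuts)
  }
  structure(list(codes = codes, edges = edges,
                 single_bin = lengths(edges) == 0L, method = method),
            class = "discretized_matrix")
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat(sprintf("discretized_matrix (%s): %d genes x %d samples; %d single-bin\n",
              x$method, nrow(x$codes), ncol(x$codes), sum(x$single_bin)))
  invisible(x)
}

#' Fast correlation-based filter (FCBF) selection
#'
#' Ranks genes by symmetrical uncertainty with the class label (descending,
#' ties broken by gene identifier), then walks the ranking keeping a gene
#' only if no already-kept gene f is more predictive of it than the class is,
#' i.e. pruning g when \eqn{SU(f, g) \ge SU(g, class)}.  Genes with
#' \eqn{SU(g, class) \le su_threshold} are never considered; the default
#' threshold 0 keeps every positive-SU gene (no cap on count), mirroring a
#' no-threshold configuration.
#'
#' @param disc a \code{\link{discretize}}d matrix.
#' @param labels binary class labels over samples.
#' @param su_threshold keep only genes with SU(gene, class) strictly above
#'   this value.
#' @return Character vector of kept genes in rank order, with the SU-with-
#'   class values of all candidate genes attached as attribute
#'   \code{"su_with_class"}.
#' @export
fcbf <- function(disc, labels, su_threshold = 0) {
  stopifnot(inherits(disc, "discretized_matrix"))
  if (length(labels) != ncol(disc$codes))
    stop("labels must cover every sample")
  if (length(unique(labels)) > 2L) stop("labels must be binary")
  genes <- rownames(disc$codes)
  su_class <- vapply(seq_along(genes), function(g)
    symmetrical_uncertainty(disc$codes[g, ], labels), numeric(1))
  names(su_class) <- genes
  cand <- genes[su_class > su_threshold]
  cand <- cand[order(-su_class[cand], cand)]
  kept <- character(0)
  for (g in cand) {
    redundant <- FALSE
    for (f in kept) {
      if (symmetrical_uncertainty(disc$codes[f, ], disc$codes[g, ]) >=
          su_class[g]) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, g)
  }
  attr(kept, "su_with_class") <- su_class
  kept
}

#' Leave-one-out FCBF with merit aggregation
#'
#' Runs FCBF on every leave-one-out subsample (n folds for n samples; the
#' procedure is fully deterministic).  A gene is \emph{relevant} when
#' selected in at least one fold.  Its merit is the SU with the class label
#' within the folds where it was selected: \code{average_merit} is the mean,
#' \code{merit_se} the sample SD over those folds divided by the square root
#' of the fold count (\code{NA} when selected once), and \code{strong_flag}
#' marks \code{average_merit - merit_se > 0}.  Setting
#' \code{merit = "all_folds"} averages over every fold instead, counting 0
#' for folds where the gene was not selected.
#'
#' Under MDL discretization, binning is re-fit inside each fold so no
#' information from the held-out sample leaks into the selection.
#'
#' @param scores gene x sample matrix (\code{\link{gene_scores}}).
#' @param labels binary class labels over samples.
#' @param method,n_bins passed to \code{\link{discretize}}.
#' @param su_threshold passed to \code{\link{fcbf}}.
#' @param merit \code{"selected_folds"} (default) or \code{"all_folds"}.
#' @return data.frame with \code{gene_id}, \code{su_with_class} (full-data
#'   SU), \code{selected_fold_count}, \code{average_merit}, \code{merit_se},
#'   \code{relevant_flag}, \code{strong_flag}.
#' @export
loo_fcbf <- function(scores, labels, method = "mdl", n_bins = 2L,
                     su_threshold = 0,
                     merit = c("selected_folds", "all_folds")) {
  merit <- match.arg(merit)
  n <- ncol(scores)
  if (n < 3L) stop("need at least 3 samples for leave-one-out")
  genes <- rownames(scores)
  su_folds <- matrix(NA_real_, nrow = length(genes), ncol = n,
                     dimnames = list(genes, NULL))
  for (i in seq_len(n)) {
    sub <- scores[, -i, drop = FALSE]
    lab <- labels[-i]
    disc <- discretize(sub, method = method, labels = lab, n_bins = n_bins)
    sel <- fcbf(disc, lab, su_threshold = su_threshold)
    if (length(sel))
      su_folds[sel, i] <- attr(sel, "su_with_class")[sel]
  }
  count <- rowSums(!is.na(su_folds))
  if (merit == "selected_folds") {
    avg <- ifelse(count > 0, rowMeans(su_folds, na.rm = TRUE), NA_real_)
    sdv <- apply(su_folds, 1L, function(v) sd(v[!is.na(v)]))
  } else {
    filled <- su_folds
    filled[is.na(filled)] <- 0
    avg <- ifelse(count > 0, rowMeans(filled), NA_real_)
    sdv <- ifelse(count > 0, apply(filled, 1L, sd), NA_real_)
  }
  se <- sdv / sqrt(pmax(count, 1L))
  disc_full <- discretize(scores, method = method, labels = labels,
                          n_bins = n_bins)
  su_full <- vapply(seq_along(genes), function(g)
    symmetrical_uncertainty(disc_full$codes[g, ], labels), numeric(1))
  out <- data.frame(gene_id = genes,
                    su_with_class = su_full,
                    selected_fold_count = as.integer(count),
                    average_merit = avg,
                    merit_se = se,
                    relevant_flag = count >= 1L,
                    strong_flag = !is.na(avg) & !is.na(se) & (avg - se) > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
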