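#' Intersect prioritizer rank lists
#'
#' Filters candidate genes from the external prioritizer's per-analysis rank
#' lists.  The analyses form a grid over inheritance model (dominant /
#' recessive), background-frequency setting (\code{freq5pct} /
#' \code{complete_penetrance}) and comparison direction (e.g. susceptible
#' vs resistant background and vice versa).  For each direction, a gene
#' qualifies when it is (1) present in \emph{both} the dominant and the
#' recessive list under the 5\% background-frequency setting and (2) ranked
#' strictly below \code{max_rank} in at least one of those analyses; the
#' union over directions is returned.  With
#' \code{all_backgrounds = TRUE}, criterion (2) considers the gene's rank in
#' every analysis of that direction (complete-penetrance included).
#'
#' @param lists data.frame with columns \code{gene_id}, \code{rank},
#'   \code{p_value}, \code{inheritance} (\code{"dominant"} /
#'   \code{"recessive"}), \code{background} (\code{"freq5pct"} /
#'   \code{"complete_penetrance"}) and \code{direction}.
#' @param max_rank strict rank cutoff (default 300, i.e. rank < 300).
#' @param all_backgrounds widen criterion (2) to every background setting.
#' @return Sorted character vector of qualifying genes; a per-direction
#'   breakdown is attached as attribute \code{"detail"}.
#' @export
ranklist_intersect <- function(lists, max_rank = 300L,
                               all_backgrounds = FALSE) {
  req <- c("gene_id", "rank", "inheritance", "background", "direction")
  if (!all(req %in% names(lists)))
    stop("lists must have columns: ", paste(req, collapse = ", "))
  key <- interaction(lists$inheritance, lists$background, lists$direction,
                     drop = TRUE)
  for (k in levels(key)) {
    r <- lists$rank[key == k]
    if (anyDuplicated(r)) stop("duplicated ranks within analysis ", k)
  }
  detail <- list()
  out <- character(0)
  for (dir in unique(lists$direction)) {
    dom <- lists[lists$direction == dir & lists$inheritance == "dominant" &
                   lists$background == "freq5pct", ]
    rec <- lists[lists$direction == dir & lists$inheritance == "recessive" &
                   lists$background == "freq5pct", ]
    if (!nrow(dom) || !nrow(rec))
      stop("direction '", dir,
           "' is missing a required freq5pct dominant/recessive analysis")
    both <- intersect(dom$gene_id, rec$gene_id)
    pool <- if (all_backgrounds) lists[lists$direction == dir, ]
            else rbind(dom, rec)
    min_rank <- tapply(pool$rank, pool$gene_id, min)
    qual <- both[min_rank[both] < max_rank]
    detail[[dir]] <- qual
    out <- union(out, qual)
  }
  out <- sort(out)
  attr(out, "detail") <- detail
  out
}

#' Merge candidate-gene sets into a screening panel
#'
#' Intersects each candidate source (prioritizer rank-list genes, t-test
#' genes, FCBF genes) with the expressed-gene set, then unions them with
#' per-gene source provenance.  An optional user-supplied keep-list restricts
#' the final panel (the expert-curation step is an explicit input, not an
#' algorithm).
#'
#' @param vaast_genes,ttest_genes,fcbf_genes character vectors of candidate
#'   genes from the three sources (same identifier namespace).
#' @param expressed_genes character vector from
#'   \code{\link{abundance_filter}}.
#' @param keep_list optional character vector; when supplied, only these
#'   genes are retained in the panel.
#' @return data.frame with \code{gene_id}, logical provenance columns
#'   \code{in_vaast}, \code{in_ttest}, \code{in_fcbf} and \code{n_sources};
#'   per-source expressed counts are attached as attribute \code{"counts"}.
#' @export
merge_panel <- function(vaast_genes, ttest_genes, fcbf_genes,
                        expressed_genes, keep_list = NULL) {
  v <- intersect(vaast_genes, expressed_genes)
  t <- intersect(ttest_genes, expressed_genes)
  f <- intersect(fcbf_genes, expressed_genes)
  all_genes <- sort(unique(c(v, t, f)))
  panel <- data.frame(gene_id = all_genes,
                      in_vaast = all_genes %in% v,
                      in_ttest = all_genes %in% t,
                      in_fcbf = all_genes %in% f,
                      stringsAsFactors = FALSE)
  panel$n_sources <- panel$in_vaast + panel$in_ttest + panel$in_fcbf
  counts <- c(n_vaast_expressed = length(v),
              n_ttest_expressed = length(t),
              n_fcbf_expressed = length(f),
              n_union = length(all_genes))
  if (!is.null(keep_list))
    panel <- panel[panel$gene_id %in% keep_list, , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "counts") <- counts
  panel
}
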