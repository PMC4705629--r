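#' Multi-sample variant table
#'
#' In-memory container for a joint-called, bi-allelic variant set: one row of
#' site metadata per variant (with the site-level recalibrated quality VQSLOD)
#' plus genotype (GT), read-depth (DP) and genotype-quality (GQ) matrices over
#' samples.  This is the working representation behind the VCF reader/writer
#' and the site and genotype filters.
#'
#' Multi-allelic records are expected to have been decomposed into bi-allelic
#' ones upstream; coordinates are 1-based as in VCF.
#'
#' @param sites data.frame with columns \code{site_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{vqslod}.
#' @param gt character matrix (sites x samples) of genotype strings such as
#'   \code{"0/0"}, \code{"0/1"}, \code{"1/1"}; \code{NA} marks a no-call.
#' @param dp,gq integer matrices (sites x samples) of per-genotype read depth
#'   and genotype quality.  \code{gq} may contain \code{NA}.
#' @return An object of class \code{variant_table}.
#' @examples
#' sites <- data.frame(site_id = "s1", chrom = "1", pos = 100L,
#'                     ref = "A", alt = "T", vqslod = 5)
#' vt <- variant_table(sites,
#'                     gt = matrix("0/1", 1, 2, dimnames = list("s1", c("a", "b"))),
#'                     dp = matrix(40L, 1, 2), gq = matrix(99L, 1, 2))
#' vt
#' @export
variant_table <- function(sites, gt, dp, gq) {
  required <- c("site_id", "chrom", "pos", "ref", "alt", "vqslod")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols))
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sites$site_id))
    stop("duplicated site_id in sites")
  gt <- as.matrix(gt); dp <- as.matrix(dp); gq <- as.matrix(gq)
  n <- nrow(sites)
  for (m in list(gt, dp, gq))
    if (nrow(m) != n) stop("genotype matrices must have one row per site")
  if (!identical(dim(gt), dim(dp)) || !identical(dim(gt), dim(gq)))
    stop("gt, dp and gq must share dimensions")
  if (is.null(colnames(gt))) stop("gt must carry sample names as colnames")
  rownames(gt) <- rownames(dp) <- rownames(gq) <- sites$site_id
  colnames(dp) <- colnames(gq) <- colnames(gt)
  structure(list(sites = sites, gt = gt, dp = dp, gq = gq),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples\n",
              nrow(x$sites), ncol(x$gt)))
  ncalled <- sum(!is.na(x$gt))
  cat(sprintf("  called genotypes: %d / %d\n", ncalled, length(x$gt)))
  if (!is.null(attr(x, "filter_log")))
    cat(sprintf("  site filter log attached (%d sites assessed)\n",
                nrow(attr(x, "filter_log"))))
  invisible(x)
}

#' Number of samples / sites in a variant table
#' @param x a \code{\link{variant_table}}.
#' @return integer count.
#' @export
n_samples <- function(x) ncol(x$gt)

#' @rdname n_samples
#' @export
n_sites <- function(x) nrow(x$sites)

#' Write a variant table as a minimal VCF 4.2 file
#'
#' Emits one bi-allelic record per site with \code{VQSLOD} in INFO and
#' \code{GT:DP:GQ} genotype fields.  No-call genotypes are written as
#' \code{./.}; missing GQ as \code{.}.
#'
#' @param x a \code{\link{variant_table}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_variant_vcf <- function(x, path) {
  stopifnot(inherits(x, "variant_table"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VQSLOD,Number=1,Type=Float,Description=\"Recalibrated variant quality log-odds\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x$gt)), collapse = "\t"))
  gt <- ifelse(is.na(x$gt), "./.", x$gt)
  gq <- ifelse(is.na(x$gq), ".", as.character(x$gq))
  dp <- ifelse(is.na(x$dp), ".", as.character(x$dp))
  cells <- matrix(paste(gt, dp, gq, sep = ":"),
                  nrow = nrow(x$sites))
  body <- paste(x$sites$chrom, x$sites$pos, x$sites$site_id,
                x$sites$ref, x$sites$alt, ".", ".",
                sprintf("VQSLOD=%.10g", x$sites$vqslod), "GT:DP:GQ",
                apply(cells, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF file into a variant table
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) carrying \code{INFO/VQSLOD} and
#' \code{GT:DP:GQ} genotype fields into a \code{\link{variant_table}}.
#' Records lacking an ID are keyed as \code{chrom_pos}.
#'
#' @param path VCF file path.
#' @return A \code{\link{variant_table}}.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  vqslod <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = "VQSLOD")))
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(id) | id == "."]
  sites <- data.frame(site_id = id, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                      vqslod = vqslod, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  mode(dp) <- "integer"; mode(gq) <- "integer"
  variant_table(sites, gt = gt, dp = dp, gq = gq)
}
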