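# In-code fixtures shared across test files.

# 10 sites x 4 samples with 3 planted site-filter failures:
#   s08 fails VQSLOD (1.9), s09 fails the DP-in-80%-of-samples rule,
#   s10 fails both.  Everything else passes comfortably.
toy_variant_table <- function() {
  samples <- c("w", "x", "y", "z")
  ids <- sprintf("s%02d", 1:10)
  vqslod <- c(rep(8, 7), 1.9, 9, 1.0)
  sites <- data.frame(site_id = ids, chrom = "1", pos = seq(100, 1000, 100),
                      ref = "A", alt = "G", vqslod = vqslod,
                      stringsAsFactors = FALSE)
  gt <- matrix("0/1", 10, 4, dimnames = list(ids, samples))
  dp <- matrix(60L, 10, 4, dimnames = list(ids, samples))
  dp["s09", c("w", "x")] <- 3L   # DP >= 6 in only 50% of samples
  dp["s10", c("w", "x", "y")] <- 2L
  gq <- matrix(99L, 10, 4, dimnames = list(ids, samples))
  variant_table(sites, gt, dp, gq)
}

# 5 sites x 4 samples yielding exactly 9 annotated calls (site s3 overlaps
# two genes; s4 has no carriers).
toy_join_fixture <- function() {
  samples <- c("w", "x", "y", "z")
  ids <- sprintf("s%d", 1:5)
  sites <- data.frame(site_id = ids, chrom = "1", pos = 1:5 * 10,
                      ref = "A", alt = "G", vqslod = 10,
                      stringsAsFactors = FALSE)
  gt <- matrix("0/0", 5, 4, dimnames = list(ids, samples))
  gt["s1", c("w", "y")] <- c("0/1", "1/1")
  gt["s2", "x"] <- "0/1"
  gt["s3", c("w", "z")] <- c("0/1", "1/1")
  gt["s5", c("y", "z")] <- c("0/1", "1/1")
  dp <- matrix(50L, 5, 4, dimnames = list(ids, samples))
  gq <- matrix(90L, 5, 4, dimnames = list(ids, samples))
  ann <- data.frame(
    site_id = c("s1", "s2", "s3", "s3", "s4", "s5"),
    gene_id = c("GA", "GA", "GB", "GC", "GB", "GC"),
    variant_class = c("nonsynonymous", "synonymous", "nonsynonymous",
                      "nonsynonymous", "stop_gain", "indel"),
    predictor_score = c(-80, NA, 10, 10, NA, NA),
    stringsAsFactors = FALSE)
  list(vt = variant_table(sites, gt, dp, gq), annotations = ann)
}

# Hand-built discretized matrix for tracing the FCBF walk (8 samples,
# class = 4 zeros then 4 ones).
toy_disc_fixture <- function() {
  codes <- rbind(
    g1 = c(0, 0, 0, 1, 1, 1, 1, 1),
    g2 = c(0, 0, 0, 0, 0, 1, 1, 1),
    g3 = c(0, 0, 0, 1, 1, 1, 1, 1),  # duplicate of g1
    g4 = c(0, 1, 0, 1, 0, 1, 0, 1))  # independent of the class
  storage.mode(codes) <- "integer"
  disc <- structure(list(codes = codes,
                         edges = rep(list(0.5), 4),
                         single_bin = rep(FALSE, 4), method = "manual"),
                    class = "discretized_matrix")
  list(disc = disc, labels = c(0, 0, 0, 0, 1, 1, 1, 1))
}

# Independent plug-in SU oracle used against the implementation: builds the
# joint contingency table and works in natural logs.
su_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) / log(2) }
  hx <- h(rowSums(tab) / n)
  hy <- h(colSums(tab) / n)
  if (hx + hy == 0) return(0)
  hxy <- h(as.vector(tab) / n)
  2 * (hx + hy - hxy) / (hx + hy)
}

# Brute-force FCBF reference: explicit SU matrix, iterative deletion.
fcbf_oracle <- function(codes, labels, su_threshold = 0) {
  genes <- rownames(codes)
  su_c <- vapply(genes, function(g) su_oracle(codes[g, ], labels), numeric(1))
  cand <- genes[su_c > su_threshold]
  cand <- cand[order(-su_c[cand], cand)]
  if (!length(cand)) return(character(0))
  su_m <- outer(cand, cand, Vectorize(function(a, b)
    su_oracle(codes[a, ], codes[b, ])))
  dimnames(su_m) <- list(cand, cand)
  alive <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    if (!alive[i]) next
    for (j in seq_along(cand)) {
      if (j <= i || !alive[j]) next
      if (su_m[i, j] >= su_c[cand[j]]) alive[j] <- FALSE
    }
  }
  cand[alive]
}

# Default-size plate with a given planted configuration.
toy_screen <- function(planted, noise_cv = 0.02, seed = 1, ...) {
  n <- length(planted)
  generate_screen(screen_spec(n_genes = n, planted_interactions = planted,
                              noise_cv = noise_cv, seed = seed, ...))
}
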