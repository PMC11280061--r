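# Independent oracles and tiny builders shared across the test files.

# Exact one-sided hypergeometric upper tail by brute-force rational sum.
# All choose() values are exact integers in doubles for N <= 30 (the largest,
# C(30,15) ~ 1.55e8, is far below 2^53), so the sum is exact up to the final
# division.
oracle_fisher_tail <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  hi <- min(K, n)
  if (a > hi) return(0)
  ks <- a:hi
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Naive Benjamini-Hochberg step-up straight from the definition:
# q_(k) = min_{j >= k} min(1, p_(j) * m / j), reported in input order.
oracle_bh <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  o <- order(p)
  sorted <- p[o]
  q <- vapply(seq_len(m),
              function(k) min(1, min(sorted[k:m] * m / (k:m))),
              numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# small manual promoter table
mk_promoters <- function(gene_id, start, end, chrom = "chr1", strand = "+") {
  data.frame(gene_id = gene_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, stringsAsFactors = FALSE)
}

# peak_set from bare coordinates
mk_peakset <- function(tf, start, end, chrom = "chr1", label = "col",
                       set_id = tf) {
  peaks <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end), score = NA_real_,
                      stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  structure(list(tf_gene_id = tf, library_label = label, set_id = set_id,
                 peaks = peaks), class = "peak_set")
}

# fresh scratch directory for fixtures
fixture_dir <- function() {
  d <- tempfile("tfrnet-fixture-")
  dir.create(d)
  d
}

# the planted fixture run end to end with the standard defaults
run_fixture_pipeline <- function(fx) {
  suppressMessages(tfrnet::run_tfrn_files(
    fx$paths$annotation, "tsv", fx$paths$manifest,
    deg_table_path = fx$paths$degs))
}
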