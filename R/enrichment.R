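# Step 1: per (TF peak set x DEG direction) promoter-binding enrichment via a
# one-sided Fisher exact test with Benjamini-Hochberg FDR control.

#' Genes whose promoter carries at least one binding peak
#'
#' Overlap is binarized: a gene is "bound" when any peak of the set overlaps
#' its promoter by at least `min_overlap_bp` bases, regardless of how many
#' peaks do. Coordinates are 0-based half-open, so a peak starting exactly at
#' a promoter's `end` does not overlap it.
#'
#' @param promoters promoter `data.frame` from [extract_promoters()].
#' @param peakset a `peak_set` (or a bare peak `data.frame` with `chrom`,
#'   `start`, `end`).
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @return character vector of bound `gene_id`s (sorted, unique).
#' @export
genes_bound <- function(promoters, peakset, min_overlap_bp = 1L) {
  peaks <- if (inherits(peakset, "peak_set")) peakset$peaks else peakset
  .assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  .assert_cols(promoters, c("gene_id", "chrom", "start", "end"), "promoters")
  min_overlap_bp <- .as_count(min_overlap_bp, "min_overlap_bp")
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  if (!nrow(peaks) || !nrow(promoters)) return(character())
  orphan <- setdiff(unique(peaks$chrom), unique(promoters$chrom))
  if (length(orphan)) {
    tally <- table(peaks$chrom[peaks$chrom %in% orphan])
    warning("peak chromosome(s) absent from the annotation (check naming ",
            "dialects): ",
            paste(sprintf("%s (%d peaks)", names(tally), as.integer(tally)),
                  collapse = ", "))
  }
  hits <- GenomicRanges::findOverlaps(.gr_halfopen(peaks),
                                      .gr_halfopen(promoters),
                                      minoverlap = min_overlap_bp)
  sort(unique(promoters$gene_id[S4Vectors::subjectHits(hits)]))
}

#' Build the 2x2 contingency table of DEG status against promoter binding
#'
#' Cells: `a` = DEGs with a bound promoter, `b` = DEGs without,
#' `c` = non-DEG universe genes with a bound promoter, `d` = the rest, so
#' `a + b + c + d = |universe|`. DEG ids outside the universe are dropped
#' with a message.
#'
#' @param deg_genes character vector of DEG gene ids (one direction).
#' @param bound_genes character vector from [genes_bound()].
#' @param universe character vector of all background gene ids.
#' @return named integer vector `c(a=, b=, c=, d=)`.
#' @export
build_contingency <- function(deg_genes, bound_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  outside <- setdiff(deg_genes, universe)
  if (length(outside))
    message(length(outside), " DEG id(s) outside the universe dropped: ",
            paste(head(outside, 5L), collapse = ", "))
  deg <- intersect(unique(deg_genes), universe)
  bound <- intersect(unique(bound_genes), universe)
  a <- length(intersect(deg, bound))
  b <- length(deg) - a
  cc <- length(bound) - a
  d <- length(universe) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided (greater) Fisher exact p-value for a 2x2 table
#'
#' The enrichment p-value is the upper tail of the hypergeometric
#' distribution: with `N = a+b+c+d` genes of which `K = a+c` are bound and
#' `n = a+b` are DEGs, `p = P(X >= a)` for `X ~ Hypergeom(N, K, n)`. The
#' test is one-sided because only over-representation of binding among DEG
#' promoters is interpretable downstream; depletion is not. Degenerate
#' margins give `p = 1`.
#'
#' @param a,b,c,d cell counts (vectorized).
#' @return p-value(s) in (0, 1].
#' @export
fisher_pvalue <- function(a, b, c, d) {
  a <- .as_count(a, "a"); b <- .as_count(b, "b")
  c <- .as_count(c, "c"); d <- .as_count(d, "d")
  # P(X >= a) = upper tail at a-1
  stats::phyper(a - 1L, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up BH with monotonicity enforcement; output order matches
#' input order. Thin, validated wrapper around [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values in \[0, 1\].
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the enrichment step over a peak-set library
#'
#' Tests every peak set of one library against both DEG directions and pools
#' all tests of the run for BH adjustment (`bh_pool = "run"`, the default) or
#' adjusts within each direction separately (`"per-direction"`). Peak-set
#' libraries (e.g. `"col"` vs `"colamp"`) are processed separately: pass a
#' single-library `peaksets` list or select one with `library_label`.
#'
#' @param promoters promoter `data.frame` from [extract_promoters()].
#' @param peaksets list of `peak_set` objects.
#' @param deg_table DEG `data.frame` from [load_deg_lists()].
#' @param universe background gene ids; defaults to all genes with a mappable
#'   promoter.
#' @param library_label optional label used to filter `peaksets`.
#' @param alpha FDR level for the `enriched` flag (default 0.001).
#' @param min_overlap_bp minimum promoter/peak overlap (default 1).
#' @param bh_pool `"run"` or `"per-direction"`.
#' @return `data.frame` with one row per (peak set, direction):
#'   `tf_gene_id`, `library_label`, `set_id`, `direction`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `p_value`, `q_value`, `enriched`.
#' @export
run_enrichment <- function(promoters, peaksets, deg_table, universe = NULL,
                           library_label = NULL, alpha = 0.001,
                           min_overlap_bp = 1L,
                           bh_pool = c("run", "per-direction")) {
  bh_pool <- match.arg(bh_pool)
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  if (!is.null(library_label))
    peaksets <- Filter(function(ps) ps$library_label == library_label, peaksets)
  labs <- unique(vapply(peaksets, `[[`, character(1), "library_label"))
  if (length(labs) > 1L)
    stop("one library per run: found labels ", paste(labs, collapse = ", "),
         "; select one with library_label")
  if (!length(peaksets)) stop("no peak sets to test")
  universe <- unique(universe %||% promoters$gene_id)
  deg_dir <- list(up = unique(deg_table$gene_id[deg_table$direction == "up"]),
                  down = unique(deg_table$gene_id[deg_table$direction == "down"]))

  rows <- lapply(peaksets, function(ps) {
    bound <- genes_bound(promoters, ps, min_overlap_bp)
    do.call(rbind, lapply(c("up", "down"), function(dir) {
      tb <- build_contingency(deg_dir[[dir]], bound, universe)
      data.frame(tf_gene_id = ps$tf_gene_id, library_label = ps$library_label,
                 set_id = ps$set_id, direction = dir,
                 a = tb[["a"]], b = tb[["b"]], c = tb[["c"]], d = tb[["d"]],
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$tf_gene_id, res$set_id, res$direction), , drop = FALSE]
  res$odds_ratio <- with(res, (a * d) / (b * c))
  res$p_value <- fisher_pvalue(res$a, res$b, res$c, res$d)
  res$q_value <- if (bh_pool == "run") bh_adjust(res$p_value) else
    stats::ave(res$p_value, res$direction, FUN = bh_adjust)
  res$enriched <- res$q_value <= alpha
  rownames(res) <- NULL
  res
}
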