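# Convenience wrapper chaining the three steps with the standard defaults
# (1 kb promoters, one-sided Fisher, BH-FDR at 0.001).

#' Run the whole network-inference pipeline
#'
#' Chains [extract_promoters()], [run_enrichment()], [classify_all()],
#' [retain_network_classes()] and [build_tfrn()]. The defaults reproduce
#' the standard run parameters: 1000 bp promoters upstream of the TSS and
#' FDR controlled at 0.001 with Benjamini-Hochberg.
#'
#' @param tss annotation `data.frame` from [load_tss_annotation()].
#' @param peaksets list of `peak_set` objects.
#' @param deg_table DEG `data.frame` from [load_deg_lists()].
#' @param library_label which peak-set library to use (`NULL` = the single
#'   label present).
#' @param upstream_len promoter length in bp.
#' @param alpha FDR level.
#' @param min_overlap_bp minimum promoter/peak overlap in bases.
#' @param universe optional explicit background gene universe.
#' @param bh_pool BH pooling, see [run_enrichment()].
#' @param tier2_rule tier-2 membership rule, see [assign_tiers()].
#' @param chrom_sizes optional chromosome sizes for promoter clipping.
#' @return list with `promoters`, `enrichment`, `classifications`,
#'   `network_tfs` and `network` (a `tfrn`).
#' @export
run_tfrn <- function(tss, peaksets, deg_table, library_label = NULL,
                     upstream_len = 1000L, alpha = 0.001,
                     min_overlap_bp = 1L, universe = NULL,
                     bh_pool = c("run", "per-direction"),
                     tier2_rule = c("any-parent", "all-parents"),
                     chrom_sizes = NULL) {
  bh_pool <- match.arg(bh_pool)
  tier2_rule <- match.arg(tier2_rule)
  promoters <- extract_promoters(tss, upstream_len, chrom_sizes)
  enrichment <- run_enrichment(promoters, peaksets, deg_table, universe,
                               library_label, alpha, min_overlap_bp, bh_pool)
  classifications <- classify_all(enrichment, deg_table)
  network_tfs <- retain_network_classes(classifications)
  network <- build_tfrn(network_tfs, promoters, peaksets, library_label,
                        min_overlap_bp, tier2_rule)
  list(promoters = promoters, enrichment = enrichment,
       classifications = classifications, network_tfs = network_tfs,
       network = network)
}

#' Run the pipeline from files
#'
#' File-path front end over [run_tfrn()]: loads the annotation, the peak
#' manifest and the DEG input, then delegates.
#'
#' @param annotation_path,annotation_format see [load_tss_annotation()].
#' @param manifest_path peak-set manifest TSV, see [load_peak_manifest()].
#' @param deg_table_path combined DEG CSV (or use `deg_up_path` +
#'   `deg_down_path`).
#' @param deg_up_path,deg_down_path plain per-direction gene lists.
#' @param tss_rule representative-TSS rule, see [load_tss_annotation()].
#' @param ... further arguments passed to [run_tfrn()].
#' @return see [run_tfrn()].
#' @export
run_tfrn_files <- function(annotation_path, annotation_format = "tsv",
                           manifest_path, deg_table_path = NULL,
                           deg_up_path = NULL, deg_down_path = NULL,
                           tss_rule = "most-upstream", ...) {
  tss <- load_tss_annotation(annotation_path, annotation_format, tss_rule)
  peaksets <- load_peak_manifest(manifest_path)
  degs <- load_deg_lists(up_path = deg_up_path, down_path = deg_down_path,
                         table_path = deg_table_path)
  run_tfrn(tss, peaksets, degs, ...)
}
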