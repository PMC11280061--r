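# Overlay the network's regulators onto arbitrary gene lists, and report the
# co-binding structure of regulator peaks within one target promoter.

#' Map regulators onto a gene list
#'
#' For every gene in the list that resolves to a promoter, reports which
#' regulators have a binding peak in it, the fraction of genes targeted by
#' each regulator class, and per-regulator target counts. With
#' `direction_filter = "down"` only DA and US regulators are considered
#' (the classes that repress, actively or passively, the downregulated
#' genes); with `"up"` only UA and DS (the activating classes). This mirrors
#' overlaying the network on process-specific DEG sublists.
#'
#' @param gene_ids character vector of target gene ids (deduplicated).
#' @param regulators classification `data.frame` (`tf_gene_id`, `tf_class`),
#'   network classes only.
#' @param promoters promoter `data.frame`.
#' @param peaksets list of `peak_set` objects.
#' @param library_label optional filter applied to `peaksets`.
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @param direction_filter `NULL` (all classes), `"up"` or `"down"`.
#' @param gene_list_name label carried into the report.
#' @return object of class `target_report`: list with `gene_list_name`,
#'   `genes` (id + resolvable flag), `hits` (gene, regulator, class),
#'   `class_fractions` and `regulator_counts`.
#' @export
tf_targets_for_genes <- function(gene_ids, regulators, promoters, peaksets,
                                 library_label = NULL, min_overlap_bp = 1L,
                                 direction_filter = NULL,
                                 gene_list_name = "gene_list") {
  gene_ids <- unique(gene_ids[nzchar(gene_ids)])
  if (!length(gene_ids)) stop("empty gene list")
  .assert_cols(regulators, c("tf_gene_id", "tf_class"), "regulators")
  if (!is.null(direction_filter)) {
    direction_filter <- match.arg(direction_filter, c("up", "down"))
    keep_cls <- if (direction_filter == "down") c("DA", "US") else c("UA", "DS")
    regulators <- regulators[regulators$tf_class %in% keep_cls, , drop = FALSE]
  }
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  if (!is.null(library_label))
    peaksets <- Filter(function(ps) ps$library_label == library_label, peaksets)
  prom <- promoters[promoters$gene_id %in% gene_ids, , drop = FALSE]
  unresolved <- setdiff(gene_ids, prom$gene_id)
  if (length(unresolved))
    message(length(unresolved), " gene id(s) not resolvable to a promoter: ",
            paste(head(unresolved, 5L), collapse = ", "))
  cls <- stats::setNames(regulators$tf_class, regulators$tf_gene_id)
  hits <- do.call(rbind, lapply(peaksets, function(ps) {
    if (!ps$tf_gene_id %in% names(cls)) return(NULL)
    bound <- genes_bound(prom, ps, min_overlap_bp)
    if (!length(bound)) return(NULL)
    data.frame(gene_id = bound, tf_gene_id = ps$tf_gene_id,
               tf_class = unname(cls[ps$tf_gene_id]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits))
    hits <- data.frame(gene_id = character(), tf_gene_id = character(),
                       tf_class = character(), stringsAsFactors = FALSE)
  hits <- hits[!duplicated(hits), , drop = FALSE]
  hits <- hits[order(hits$gene_id, hits$tf_gene_id), , drop = FALSE]
  rownames(hits) <- NULL
  n_res <- nrow(prom)
  frac <- do.call(rbind, lapply(sort(unique(regulators$tf_class)), function(cl) {
    n <- length(unique(hits$gene_id[hits$tf_class == cl]))
    data.frame(tf_class = cl, n_genes = n,
               fraction = if (n_res) n / n_res else NA_real_,
               stringsAsFactors = FALSE)
  })) %||% data.frame(tf_class = character(), n_genes = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE)
  cnt <- regulators[order(regulators$tf_gene_id),
                    c("tf_gene_id", "tf_class"), drop = FALSE]
  cnt$n_targets <- vapply(cnt$tf_gene_id, function(tf)
    length(unique(hits$gene_id[hits$tf_gene_id == tf])), integer(1))
  rownames(cnt) <- NULL
  structure(list(gene_list_name = gene_list_name,
                 genes = data.frame(gene_id = sort(gene_ids),
                                    resolvable = sort(gene_ids) %in%
                                      prom$gene_id,
                                    stringsAsFactors = FALSE),
                 hits = hits, class_fractions = frac,
                 regulator_counts = cnt),
            class = "target_report")
}

#' @export
print.target_report <- function(x, ...) {
  cat("<target_report>", x$gene_list_name, "|",
      sum(x$genes$resolvable), "of", nrow(x$genes), "genes resolvable\n")
  if (nrow(x$class_fractions)) {
    for (i in seq_len(nrow(x$class_fractions)))
      cat(sprintf("  %s targets %d gene(s) (%.0f%%)\n",
                  x$class_fractions$tf_class[i], x$class_fractions$n_genes[i],
                  100 * x$class_fractions$fraction[i]))
  }
  invisible(x)
}

#' Co-binding structure of regulator peaks in one promoter
#'
#' Intersects every regulator's peaks with the target gene's promoter and
#' converts them to TSS-relative coordinates (negative upstream: positions
#' in `[-upstream_len, 0)`, minus-strand genes mirrored so upstream is
#' always negative). Peaks are then grouped by the transitive closure of
#' pairwise interval overlap — stacked peaks betray regulators competing for
#' or sharing a promoter element. A regulator with several peaks enters the
#' grouping once per peak.
#'
#' @param target_gene gene id whose promoter is inspected.
#' @param regulators classification `data.frame` (`tf_gene_id`, `tf_class`).
#' @param promoters promoter `data.frame`.
#' @param peaksets list of `peak_set` objects.
#' @param library_label optional filter applied to `peaksets`.
#' @return object of class `co_binding`: list with `target_gene_id`,
#'   `intervals` (`tf_gene_id`, `tf_class`, `rel_start`, `rel_end`,
#'   `group`) and `groups` (list of regulator-id vectors, one per overlap
#'   group).
#' @export
co_binding_report <- function(target_gene, regulators, promoters, peaksets,
                              library_label = NULL) {
  prom <- promoters[promoters$gene_id == target_gene, , drop = FALSE]
  if (!nrow(prom)) stop("no promoter for target gene ", target_gene)
  prom <- prom[1L, ]
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  if (!is.null(library_label))
    peaksets <- Filter(function(ps) ps$library_label == library_label, peaksets)
  cls <- stats::setNames(regulators$tf_class, regulators$tf_gene_id)
  # 0-based TSS position implied by the promoter window
  tss <- if (prom$strand == "+") prom$end else prom$start - 1L
  ivs <- do.call(rbind, lapply(peaksets, function(ps) {
    if (!ps$tf_gene_id %in% names(cls)) return(NULL)
    pk <- ps$peaks[ps$peaks$chrom == prom$chrom, , drop = FALSE]
    s <- pmax(pk$start, prom$start); e <- pmin(pk$end, prom$end)
    keep <- s < e
    if (!any(keep)) return(NULL)
    s <- s[keep]; e <- e[keep]
    if (prom$strand == "+") {
      rs <- s - tss; re <- e - tss
    } else {                      # mirror: upstream stays negative
      rs <- tss - e + 1L; re <- tss - s + 1L
    }
    data.frame(tf_gene_id = ps$tf_gene_id,
               tf_class = unname(cls[ps$tf_gene_id]),
               rel_start = as.integer(rs), rel_end = as.integer(re),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ivs))
    return(structure(list(target_gene_id = target_gene,
                          intervals = data.frame(tf_gene_id = character(),
                                                 tf_class = character(),
                                                 rel_start = integer(),
                                                 rel_end = integer(),
                                                 group = integer(),
                                                 stringsAsFactors = FALSE),
                          groups = list()),
                     class = "co_binding"))
  ivs <- ivs[order(ivs$rel_start, ivs$rel_end, ivs$tf_gene_id), , drop = FALSE]
  # sweep: overlap components of half-open intervals sorted by start
  grp <- integer(nrow(ivs)); g <- 0L; reach <- -Inf
  for (i in seq_len(nrow(ivs))) {
    if (ivs$rel_start[i] >= reach) { g <- g + 1L; reach <- ivs$rel_end[i] }
    else reach <- max(reach, ivs$rel_end[i])
    grp[i] <- g
  }
  ivs$group <- grp
  rownames(ivs) <- NULL
  groups <- lapply(split(ivs$tf_gene_id, ivs$group),
                   function(x) sort(unique(x)))
  names(groups) <- NULL
  structure(list(target_gene_id = target_gene, intervals = ivs,
                 groups = groups),
            class = "co_binding")
}

#' @export
print.co_binding <- function(x, ...) {
  cat("<co_binding>", x$target_gene_id, "|", nrow(x$intervals),
      "peak interval(s) in", length(x$groups), "overlap group(s)\n")
  invisible(x)
}
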