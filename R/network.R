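# Step 3: signed regulator->target link inference among classified TFs,
# subnetwork partition, tier assignment on the DA-DA core, and export.

#' Is an ordered (regulator, target) class pair sign-consistent?
#'
#' Of the 16 ordered pairs over \{DA, DS, US, UA\} exactly eight are
#' mechanistically meaningful: an activator (DA, UA) may regulate targets
#' whose coding gene moves in the same direction as its own, a suppressor
#' (DS, US) targets genes moving in the opposite direction. That rule admits
#' UA-UA, UA-US, DS-UA, DS-US, US-DA, US-DS, DA-DA and DA-DS.
#'
#' @param regulator_class,target_class classes in DA/DS/US/UA (vectorized).
#' @return logical vector.
#' @export
is_meaningful_pair <- function(regulator_class, target_class) {
  bad <- setdiff(unique(c(regulator_class, target_class)), NETWORK_CLASSES)
  if (length(bad))
    stop("class outside the four network classes: ",
         paste(bad, collapse = ", "))
  role <- .class_role[regulator_class]
  same <- .class_gene_dir[regulator_class] == .class_gene_dir[target_class]
  unname(ifelse(role == "activator", same, !same))
}

#' Infer signed regulator-to-target links
#'
#' A link runs from regulator to target when a regulator binding peak
#' overlaps the promoter of the target TF's coding gene by at least
#' `min_overlap_bp` bases and the (regulator, target) class pair is
#' sign-consistent ([is_meaningful_pair()]). Self-links arise only for DA-DA
#' and UA-UA (the only meaningful same-class pairs). Link sign follows the
#' regulator's role: activation for DA/UA, inhibition for DS/US. Multiple
#' supporting peaks collapse onto one unweighted link with the evidence kept
#' in the `support` list-column.
#'
#' @param classified network-class TFs from [retain_network_classes()].
#' @param promoters promoter `data.frame`; must cover the target TF genes
#'   (TFs without a promoter receive no incoming links, reported).
#' @param peaksets list of `peak_set` objects (one library).
#' @param library_label optional filter applied to `peaksets`.
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @return `data.frame` with `regulator`, `target`, `sign`, `n_support` and
#'   list-column `support` (data.frames of supporting peaks), sorted by
#'   (regulator, target).
#' @export
infer_links <- function(classified, promoters, peaksets,
                        library_label = NULL, min_overlap_bp = 1L) {
  .assert_cols(classified, c("tf_gene_id", "tf_class"), "classified TFs")
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  if (!is.null(library_label))
    peaksets <- Filter(function(ps) ps$library_label == library_label, peaksets)
  cls <- stats::setNames(classified$tf_class, classified$tf_gene_id)
  tprom <- promoters[promoters$gene_id %in% classified$tf_gene_id, , drop = FALSE]
  missing <- setdiff(classified$tf_gene_id, tprom$gene_id)
  if (length(missing))
    message("TF gene(s) without a mappable promoter receive no incoming ",
            "links: ", paste(missing, collapse = ", "))
  empty <- data.frame(regulator = character(), target = character(),
                      sign = character(), n_support = integer(),
                      stringsAsFactors = FALSE)
  empty$support <- list()
  if (!nrow(tprom)) return(empty)

  pieces <- list()
  for (ps in peaksets) {
    reg <- ps$tf_gene_id
    if (!reg %in% names(cls) || !nrow(ps$peaks)) next
    hits <- GenomicRanges::findOverlaps(.gr_halfopen(ps$peaks),
                                        .gr_halfopen(tprom),
                                        minoverlap = .as_count(min_overlap_bp,
                                                               "min_overlap_bp"))
    if (!length(hits)) next
    pk <- ps$peaks[S4Vectors::queryHits(hits), c("chrom", "start", "end")]
    pieces[[length(pieces) + 1L]] <- data.frame(
      regulator = reg, target = tprom$gene_id[S4Vectors::subjectHits(hits)],
      library_label = ps$library_label, set_id = ps$set_id, pk,
      stringsAsFactors = FALSE)
  }
  if (!length(pieces)) return(empty)
  cand <- do.call(rbind, pieces)
  keep <- is_meaningful_pair(cls[cand$regulator], cls[cand$target])
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  key <- paste(cand$regulator, cand$target, sep = "\r")
  ord <- order(cand$regulator, cand$target, cand$chrom, cand$start)
  cand <- cand[ord, , drop = FALSE]
  key <- key[ord]
  uk <- unique(key)
  support <- lapply(uk, function(k) {
    s <- cand[key == k, c("library_label", "set_id", "chrom", "start", "end")]
    s <- s[!duplicated(s), , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  out <- cand[!duplicated(key), c("regulator", "target"), drop = FALSE]
  out$sign <- unname(ifelse(.class_role[cls[out$regulator]] == "activator",
                            "activation", "inhibition"))
  out$n_support <- vapply(support, nrow, integer(1))
  out$support <- support
  rownames(out) <- NULL
  out
}

.subnetwork_of <- function(tf_class) {
  unname(c(DA = "R", DS = "R", US = "A", UA = "A")[tf_class])
}

#' Partition a link set into subnetworks and label edge scope
#'
#' Nodes split by class: the stimulus-repressed subnetwork R holds DA and DS
#' (active before the stimulus, switched off by it), the stimulus-activated
#' subnetwork A holds UA and US. Each edge is labeled `within-R`,
#' `within-A`, `A-to-R` (US regulating DA/DS) or `R-to-A` (DS regulating
#' UA/US).
#'
#' @param classified network-class TFs.
#' @param links link `data.frame` from [infer_links()].
#' @return list with `nodes` (adds `subnetwork`) and `edges` (adds `scope`).
#' @export
partition_subnetworks <- function(classified, links) {
  nodes <- classified
  nodes$subnetwork <- .subnetwork_of(nodes$tf_class)
  edges <- links
  if (nrow(edges)) {
    sub <- stats::setNames(nodes$subnetwork, nodes$tf_gene_id)
    rs <- sub[edges$regulator]
    ts <- sub[edges$target]
    edges$scope <- unname(ifelse(rs == ts, paste0("within-", rs),
                                 paste0(rs, "-to-", ts)))
  } else edges$scope <- character()
  list(nodes = nodes, edges = edges)
}

#' Assign tiers within the DA-DA core
#'
#' Considering only DA-to-DA edges (the core of the repressed subnetwork):
#' tier 1 holds the nodes with no incoming core edge other than
#' self-regulation (only outgoing arcs), tier 2 the remaining nodes
#' triggered by a tier-1 node, and tier 3 the rest. "Triggered by" is read
#' inclusively by default (`tier2_rule = "any-parent"`: at least one parent
#' in tier 1); `"all-parents"` demands every non-self parent be tier 1.
#' Nodes outside the core (non-DA, or DA without any DA-DA edge) get
#' `NA`. A core made only of cycles has no tier-1 seed; all its nodes go to
#' tier 3 with a warning.
#'
#' @param classified network-class TFs (`tf_gene_id`, `tf_class`).
#' @param links link `data.frame`.
#' @param tier2_rule `"any-parent"` (default) or `"all-parents"`.
#' @return integer vector of tiers (1/2/3 or `NA`) named by `tf_gene_id`.
#' @export
assign_tiers <- function(classified, links, tier2_rule = c("any-parent",
                                                           "all-parents")) {
  tier2_rule <- match.arg(tier2_rule)
  cls <- stats::setNames(classified$tf_class, classified$tf_gene_id)
  tier <- stats::setNames(rep(NA_integer_, length(cls)), names(cls))
  core_e <- links[cls[links$regulator] == "DA" & cls[links$target] == "DA", ,
                  drop = FALSE]
  core_nodes <- unique(c(core_e$regulator, core_e$target))
  if (!length(core_nodes)) return(tier)
  nonself <- core_e[core_e$regulator != core_e$target, , drop = FALSE]
  indeg0 <- setdiff(core_nodes, nonself$target)
  if (!length(indeg0)) {
    warning("DA-DA core has no source node (cycle); all core nodes put in ",
            "tier 3")
    tier[core_nodes] <- 3L
    return(tier)
  }
  tier[indeg0] <- 1L
  rest <- setdiff(core_nodes, indeg0)
  t2 <- vapply(rest, function(v) {
    parents <- unique(nonself$regulator[nonself$target == v])
    if (tier2_rule == "any-parent") any(parents %in% indeg0)
    else length(parents) > 0L && all(parents %in% indeg0)
  }, logical(1))
  tier[rest[t2]] <- 2L
  tier[rest[!t2]] <- 3L
  tier
}

#' Build the full TF regulatory network
#'
#' Runs [infer_links()], [partition_subnetworks()] and [assign_tiers()] and
#' assembles a `tfrn` object.
#'
#' @inheritParams infer_links
#' @param tier2_rule see [assign_tiers()].
#' @return object of class `tfrn`: list with `nodes` (`tf_gene_id`,
#'   `tf_class`, `subnetwork`, `tier`), `edges` (`regulator`, `target`,
#'   `sign`, `scope`, `n_support`, `support`) and `isolated` (TFs with no
#'   links).
#' @export
build_tfrn <- function(classified, promoters, peaksets, library_label = NULL,
                       min_overlap_bp = 1L,
                       tier2_rule = c("any-parent", "all-parents")) {
  tier2_rule <- match.arg(tier2_rule)
  links <- infer_links(classified, promoters, peaksets, library_label,
                       min_overlap_bp)
  parts <- partition_subnetworks(classified, links)
  tiers <- assign_tiers(classified, links, tier2_rule)
  nodes <- parts$nodes
  nodes$tier <- unname(tiers[nodes$tf_gene_id])
  nodes <- nodes[order(nodes$tf_gene_id),
                 c("tf_gene_id", "tf_class", "subnetwork", "tier")]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = parts$edges,
                 isolated = sort(setdiff(nodes$tf_gene_id,
                                         c(links$regulator, links$target)))),
            class = "tfrn")
}

#' @export
print.tfrn <- function(x, ...) {
  cat("<tfrn>", nrow(x$nodes), "TFs,", nrow(x$edges), "links,",
      length(x$isolated), "isolated\n")
  if (nrow(x$nodes)) {
    tb <- table(x$nodes$tf_class)
    cat("  classes:", paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                            collapse = " "), "\n")
    cat("  R-subnetwork:", sum(x$nodes$subnetwork == "R"),
        "| A-subnetwork:", sum(x$nodes$subnetwork == "A"), "\n")
  }
  invisible(x)
}

#' Audit a TFRN against its structural invariants
#'
#' Checks that every edge joins network-class nodes through a meaningful
#' pair with the sign implied by the regulator class, that subnetwork labels
#' follow node class, and that tiers partition the DA-DA core with tier-1
#' non-self in-degree zero.
#'
#' @param tfrn a `tfrn` object.
#' @return invisibly `TRUE`; violations raise an error.
#' @export
validate_tfrn <- function(tfrn) {
  nodes <- tfrn$nodes; edges <- tfrn$edges
  stopifnot(all(nodes$tf_class %in% NETWORK_CLASSES))
  if (!all(nodes$subnetwork == .subnetwork_of(nodes$tf_class)))
    stop("subnetwork label inconsistent with class")
  if (nrow(edges)) {
    cls <- stats::setNames(nodes$tf_class, nodes$tf_gene_id)
    if (!all(is_meaningful_pair(cls[edges$regulator], cls[edges$target])))
      stop("edge violating the meaningful-pair rule")
    want <- ifelse(.class_role[cls[edges$regulator]] == "activator",
                   "activation", "inhibition")
    if (!all(edges$sign == want)) stop("edge sign inconsistent with class")
    core <- edges[cls[edges$regulator] == "DA" & cls[edges$target] == "DA" &
                    edges$regulator != edges$target, , drop = FALSE]
    t1 <- nodes$tf_gene_id[!is.na(nodes$tier) & nodes$tier == 1L]
    if (any(core$target %in% t1)) stop("tier-1 node with incoming core edge")
    core_nodes <- unique(c(
      edges$regulator[cls[edges$regulator] == "DA" & cls[edges$target] == "DA"],
      edges$target[cls[edges$regulator] == "DA" & cls[edges$target] == "DA"]))
    tiered <- nodes$tf_gene_id[!is.na(nodes$tier)]
    if (!setequal(core_nodes, tiered))
      stop("tiers do not partition the DA-DA core node set")
  }
  invisible(TRUE)
}

#' Convert a TFRN to an igraph graph
#'
#' Vertices carry `class`, `subnetwork` and `tier` (`"none"` outside the
#' DA-DA core); edges carry `sign`, `scope` and `n_support`. Vertices are
#' sorted by id and edges by (regulator, target) so serializations are
#' deterministic.
#'
#' @param tfrn a `tfrn` object.
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(tfrn) {
  nodes <- tfrn$nodes[order(tfrn$nodes$tf_gene_id), , drop = FALSE]
  v <- data.frame(name = nodes$tf_gene_id, class = nodes$tf_class,
                  subnetwork = nodes$subnetwork,
                  tier = ifelse(is.na(nodes$tier), "none",
                                as.character(nodes$tier)),
                  stringsAsFactors = FALSE)
  e <- tfrn$edges[order(tfrn$edges$regulator, tfrn$edges$target),
                  c("regulator", "target", "sign", "scope", "n_support"),
                  drop = FALSE]
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}

#' Export a TFRN to a file
#'
#' @param tfrn a `tfrn` object.
#' @param path output file path.
#' @param format `"graphml"`, `"dot"`, `"json"` (node-link) or `"tsv"`
#'   (edge list: regulator, target, sign, n_supporting_peaks).
#' @return `path`, invisibly.
#' @export
export_graph <- function(tfrn, path,
                         format = c("graphml", "dot", "json", "tsv")) {
  format <- match.arg(format)
  if (format %in% c("graphml", "dot")) {
    igraph::write_graph(as_igraph(tfrn), path, format = format)
  } else if (format == "json") {
    nodes <- tfrn$nodes[order(tfrn$nodes$tf_gene_id), , drop = FALSE]
    nodes$tier <- ifelse(is.na(nodes$tier), "none", as.character(nodes$tier))
    edges <- tfrn$edges[order(tfrn$edges$regulator, tfrn$edges$target),
                        c("regulator", "target", "sign", "scope", "n_support"),
                        drop = FALSE]
    jsonlite::write_json(list(nodes = nodes, edges = edges,
                              isolated = tfrn$isolated),
                         path, dataframe = "rows", pretty = TRUE)
  } else {
    edges <- tfrn$edges[order(tfrn$edges$regulator, tfrn$edges$target),
                        c("regulator", "target", "sign", "n_support"),
                        drop = FALSE]
    names(edges)[4L] <- "n_supporting_peaks"
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Compare two link sets
#'
#' Links are compared as unordered collections of ordered (regulator,
#' target) pairs, ignoring signs and supporting evidence — the comparison
#' used to contrast networks built from different peak-set libraries.
#'
#' @param links_a,links_b `data.frame`s with `regulator` and `target`.
#' @return list of `data.frame`s `only_a`, `only_b`, `common`.
#' @export
compare_link_sets <- function(links_a, links_b) {
  pairify <- function(l) {
    p <- unique(data.frame(regulator = l$regulator, target = l$target,
                           stringsAsFactors = FALSE))
    p[order(p$regulator, p$target), , drop = FALSE]
  }
  a <- pairify(links_a); b <- pairify(links_b)
  ka <- paste(a$regulator, a$target, sep = "\r")
  kb <- paste(b$regulator, b$target, sep = "\r")
  res <- list(only_a = a[!(ka %in% kb), , drop = FALSE],
              only_b = b[!(kb %in% ka), , drop = FALSE],
              common = a[ka %in% kb, , drop = FALSE])
  lapply(res, function(d) { rownames(d) <- NULL; d })
}

#' Node persistence as the fold-change threshold of DEG calling increases
#'
#' For each threshold `t` the DEG table is refiltered to `|log2fc| >= t`,
#' the whole enrichment-classification pipeline re-runs, and presence of
#' each TF among the network classes is recorded. Robust network nodes are
#' those persisting at higher thresholds.
#'
#' @param deg_table DEG `data.frame` with a complete `log2fc` column.
#' @param fc_thresholds numeric vector of |log2fc| thresholds.
#' @inheritParams run_enrichment
#' @return `data.frame`: `tf_gene_id`, `tf_class` (at the lowest threshold
#'   at which the TF appears) and one logical column `t<threshold>` per
#'   threshold.
#' @export
robustness_sweep <- function(deg_table, fc_thresholds, promoters, peaksets,
                             universe = NULL, library_label = NULL,
                             alpha = 0.001, min_overlap_bp = 1L,
                             bh_pool = c("run", "per-direction")) {
  bh_pool <- match.arg(bh_pool)
  if (!"log2fc" %in% names(deg_table) || any(is.na(deg_table$log2fc)))
    stop("robustness_sweep() needs a complete log2fc column in the DEG table")
  fc_thresholds <- sort(unique(as.numeric(fc_thresholds)))
  members <- lapply(fc_thresholds, function(t) {
    sub <- deg_table[abs(deg_table$log2fc) >= t, , drop = FALSE]
    if (!nrow(sub)) {
      warning("threshold ", t, " removes every DEG")
      return(data.frame(tf_gene_id = character(), tf_class = character(),
                        stringsAsFactors = FALSE))
    }
    enr <- run_enrichment(promoters, peaksets, sub, universe, library_label,
                          alpha, min_overlap_bp, bh_pool)
    retain_network_classes(classify_all(enr, sub))[, c("tf_gene_id",
                                                       "tf_class")]
  })
  tfs <- sort(unique(unlist(lapply(members, `[[`, "tf_gene_id"))))
  out <- data.frame(tf_gene_id = tfs, stringsAsFactors = FALSE)
  first_class <- rep(NA_character_, length(tfs))
  for (i in seq_along(fc_thresholds)) {
    m <- members[[i]]
    out[[paste0("t", fc_thresholds[i])]] <- tfs %in% m$tf_gene_id
    need <- is.na(first_class) & tfs %in% m$tf_gene_id
    first_class[need] <- m$tf_class[match(tfs[need], m$tf_gene_id)]
  }
  out <- cbind(out[1L], tf_class = first_class, out[-1L])
  rownames(out) <- NULL
  out
}
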