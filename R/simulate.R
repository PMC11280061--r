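# Planted-network synthetic data generator. Emits exactly the formats the
# readers consume (TSS TSV, BED peak sets + manifest, DEG CSV) plus a
# ground-truth JSON, so every pipeline stage is testable without downloads.
#
# Construction guarantees:
#   * gene slots are 3 kb apart on one synthetic chromosome, so promoters
#     (<= 1 kb) can never overlap and no peak can ambiguously support two
#     genes — the ground truth stays exact;
#   * every planted edge is realized as a peak inside the target promoter;
#   * the number of additional ("salt") DEG promoters bound per TF is the
#     smallest count whose one-sided hypergeometric tail satisfies
#     p * n_tests <= alpha (a Bonferroni-style margin that implies the BH
#     q-value passes too) — computed, never guessed — and verified with
#     fisher_pvalue() before any file is written;
#   * salt and noise peaks never touch TF-coding promoters, so no spurious
#     links can arise; promoter noise lands in neutral (non-DEG) promoters
#     and only weakens the planted tests, which the salt count accounts for.

#' Describe a planted ground-truth network
#'
#' @param tfs `data.frame` with `tf_gene_id` and `planted_class`
#'   (DA/DS/US/UA/DR/UR/NTR).
#' @param edges `data.frame` with `regulator`, `target`; both must be
#'   network-class TFs and every pair must satisfy [is_meaningful_pair()].
#' @param n_up,n_down,n_neutral background (non-TF) gene counts per
#'   expression status.
#' @param expected_tiers optional named integer vector of hand-derived tiers
#'   for the DA-DA core, carried into the ground truth.
#' @return object of class `planted_network`.
#' @export
planted_network <- function(tfs, edges, n_up = 50L, n_down = 60L,
                            n_neutral = 80L, expected_tiers = NULL) {
  .assert_cols(tfs, c("tf_gene_id", "planted_class"), "planted TFs")
  if (anyDuplicated(tfs$tf_gene_id)) stop("duplicate TF ids")
  if (!all(tfs$planted_class %in% ALL_CLASSES))
    stop("unknown planted class")
  cls <- stats::setNames(tfs$planted_class, tfs$tf_gene_id)
  if (nrow(edges)) {
    .assert_cols(edges, c("regulator", "target"), "planted edges")
    ends <- c(edges$regulator, edges$target)
    if (!all(ends %in% tfs$tf_gene_id)) stop("edge endpoint not a planted TF")
    if (!all(cls[ends] %in% NETWORK_CLASSES))
      stop("planted edges must join network-class TFs")
    if (!all(is_meaningful_pair(cls[edges$regulator], cls[edges$target])))
      stop("planted edge violating the meaningful-pair rule")
  }
  structure(list(tfs = tfs, edges = edges,
                 n_up = .as_count(n_up, "n_up"),
                 n_down = .as_count(n_down, "n_down"),
                 n_neutral = .as_count(n_neutral, "n_neutral"),
                 expected_tiers = expected_tiers),
            class = "planted_network")
}

#' Default 10-TF planted network
#'
#' Four DAs forming a tiered core with one self-activation, one DS
#' redundantly wired to the core, two USes attacking the repressed side, two
#' UAs forming the activated side, and one NTR decoy that the
#' classification step must filter out. Tiers of the DA-DA core are derived
#' by hand: TF01 (only outgoing arcs, self-loop excluded) is tier 1, TF02
#' and TF03 (triggered by TF01) are tier 2, TF04 is tier 3.
#'
#' @return a [planted_network()].
#' @export
default_planted_network <- function() {
  tfs <- data.frame(
    tf_gene_id = sprintf("TF%02d", 1:10),
    planted_class = c("DA", "DA", "DA", "DA", "DS", "US", "US", "UA", "UA",
                      "NTR"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    regulator = c("TF01", "TF01", "TF02", "TF03", "TF01", "TF02", "TF06",
                  "TF07", "TF05", "TF08", "TF09"),
    target    = c("TF02", "TF03", "TF04", "TF04", "TF01", "TF05", "TF02",
                  "TF05", "TF08", "TF09", "TF06"),
    stringsAsFactors = FALSE)
  planted_network(tfs, edges,
                  expected_tiers = c(TF01 = 1L, TF02 = 2L, TF03 = 2L,
                                     TF04 = 3L))
}

# enrichment direction(s) implied by a planted class
.enrichment_dirs <- function(cl) {
  switch(cl,
         DA = "down", US = "down", DS = "up", UA = "up",
         DR = c("up", "down"), UR = c("up", "down"), NTR = "down")
}

# smallest bound-DEG count a (>= n_targets) with tail * n_tests <= alpha
.required_bound <- function(n_targets, n_deg, n_other_bound, n_universe,
                            alpha, n_tests) {
  for (a in seq.int(max(n_targets, 1L), n_deg)) {
    p <- fisher_pvalue(a, n_deg - a, n_other_bound,
                       n_universe - n_deg - n_other_bound)
    if (p * n_tests <= alpha) return(a)
  }
  # search the smallest universe that would make the demand feasible
  n_min <- n_universe
  repeat {
    n_min <- n_min * 2L
    p <- fisher_pvalue(n_deg, 0L, n_other_bound,
                       n_min - n_deg - n_other_bound)
    if (p * n_tests <= alpha || n_min > 1e9) break
  }
  stop("infeasible planted enrichment: binding all ", n_deg,
       " DEGs in a universe of ", n_universe, " genes gives p*m > ", alpha,
       "; a universe of at least ~", n_min, " genes would be required",
       call. = FALSE)
}

#' Generate a synthetic fixture from a planted network
#'
#' Lays the genes on one synthetic chromosome (3 kb slots, shuffled order,
#' random strands), makes each TF-coding gene a DEG of the direction its
#' planted class implies, realizes every planted edge as a binding peak in
#' the target's promoter, salts each TF's peak set with enough additional
#' background-DEG promoters for the planted enrichment to pass `alpha`
#' (see the file header for the calculation), adds configurable noise, and
#' writes the annotation TSV, one BED per TF plus a manifest, the DEG CSV
#' and a ground-truth JSON under `dir`. Fully reproducible: the same
#' planted network and seed give byte-identical files.
#'
#' @param planted a [planted_network()].
#' @param dir output directory (created).
#' @param seed integer RNG seed.
#' @param upstream_len promoter length (default 1000).
#' @param alpha target FDR level the planted tests must pass (default 0.001).
#' @param peak_width width of generated peaks in bp (default 200).
#' @param noise_intergenic background peaks per TF placed in a promoter-free
#'   zone (default 5).
#' @param noise_promoter_hits spurious peaks per TF placed in neutral
#'   (non-DEG, non-TF) gene promoters (default 0); the salt calculation
#'   compensates so planted calls still pass `alpha` while the spurious
#'   hits stay sub-threshold.
#' @param library_label manifest library label (default `"col"`).
#' @return invisibly, a list with `dir`, the file `paths` and the `truth`
#'   record (also serialized as `truth.json`).
#' @export
generate_fixture <- function(planted = default_planted_network(), dir,
                             seed = 1L, upstream_len = 1000L, alpha = 0.001,
                             peak_width = 200L, noise_intergenic = 5L,
                             noise_promoter_hits = 0L,
                             library_label = "col") {
  stopifnot(inherits(planted, "planted_network"))
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)

  tf_ids <- planted$tfs$tf_gene_id
  cls <- stats::setNames(planted$tfs$planted_class, tf_ids)
  bg <- c(sprintf("BGd%03d", seq_len(planted$n_down)),
          sprintf("BGu%03d", seq_len(planted$n_up)),
          sprintf("BGn%03d", seq_len(planted$n_neutral)))
  gene_dir <- c(.class_gene_dir[cls],
                rep(c("down", "up", "none"),
                    c(planted$n_down, planted$n_up, planted$n_neutral)))
  names(gene_dir) <- c(tf_ids, bg)
  genes <- names(gene_dir)
  n_genes <- length(genes)
  if (n_genes < length(tf_ids) + 2L) stop("too few genes")

  # layout: shuffled 3 kb slots, TSS mid-slot, promoter strictly inside
  ord <- sample(genes)
  slot <- stats::setNames(seq_len(n_genes) - 1L, ord)[genes]
  tss <- unname(slot) * 3000L + 1500L
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  ann <- data.frame(gene_id = genes, chrom = "chrS1", tss = tss,
                    strand = strand, stringsAsFactors = FALSE)
  prom <- extract_promoters(ann, upstream_len)
  prom_by_gene <- stats::setNames(seq_len(nrow(prom)), prom$gene_id)
  noise_lo <- n_genes * 3000L + 1000L
  noise_hi <- n_genes * 3000L + 50000L

  deg_genes <- genes[gene_dir[genes] != "none"]
  n_dir <- c(up = sum(gene_dir == "up"), down = sum(gene_dir == "down"))
  n_tests <- 2L * length(tf_ids)
  neutral_bg <- bg[gene_dir[bg] == "none"]

  support <- list()
  peak_files <- character()
  bound_all <- list()
  for (tf in tf_ids) {
    dirs <- .enrichment_dirs(cls[[tf]])
    targets <- lapply(dirs, function(d) {
      if (nrow(planted$edges))
        unique(planted$edges$target[planted$edges$regulator == tf &
                                      gene_dir[planted$edges$target] == d])
      else character()
    })
    names(targets) <- dirs
    # bound counts per direction: genes bound for one direction fall into
    # cell c of the other direction's table, so solve the coupled demands by
    # fixed-point iteration (monotone, bounded by the DEG counts)
    a_req <- stats::setNames(integer(length(dirs)), dirs)
    repeat {
      a_new <- vapply(dirs, function(d)
        .required_bound(length(targets[[d]]), n_dir[[d]],
                        noise_promoter_hits + sum(a_req[setdiff(dirs, d)]),
                        n_genes, alpha, n_tests),
        integer(1))
      if (identical(a_new, a_req)) break
      a_req <- a_new
    }
    bound <- character()
    supp <- list()
    for (d in dirs) {
      pool <- setdiff(bg[gene_dir[bg] == d], targets[[d]])
      n_salt <- a_req[[d]] - length(targets[[d]])
      if (n_salt > length(pool))
        stop("infeasible planted enrichment for ", tf, " (", d, "): needs ",
             n_salt, " background ", d, "-DEGs but only ", length(pool),
             " exist; enlarge n_", d, call. = FALSE)
      salt <- if (n_salt > 0L) sort(sample(pool, n_salt)) else character()
      supp[[d]] <- salt
      bound <- c(bound, targets[[d]], salt)
    }
    support[[tf]] <- supp
    bound <- unique(bound)
    bound_all[[tf]] <- bound
    noise_prom <- if (noise_promoter_hits > 0L)
      sample(neutral_bg, noise_promoter_hits) else character()
    rows <- lapply(c(bound, noise_prom), function(g) {
      p <- prom[prom_by_gene[[g]], ]
      off <- sample.int(upstream_len - peak_width + 1L, 1L) - 1L
      data.frame(chrom = p$chrom, start = p$start + off,
                 end = p$start + off + peak_width, stringsAsFactors = FALSE)
    })
    if (noise_intergenic > 0L) {
      st <- sort(sample.int(noise_hi - noise_lo - peak_width,
                            noise_intergenic)) + noise_lo
      rows <- c(rows, list(data.frame(chrom = "chrS1", start = st,
                                      end = st + peak_width,
                                      stringsAsFactors = FALSE)))
    }
    pk <- do.call(rbind, rows)
    pk <- pk[order(pk$chrom, pk$start, pk$end), , drop = FALSE]
    f <- file.path(dir, "peaks", paste0(tf, ".bed"))
    write.table(pk, f, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    peak_files[tf] <- f
  }

  # prove every planted (TF, direction) test passes before shipping files
  for (tf in tf_ids) for (d in .enrichment_dirs(cls[[tf]])) {
    deg_d <- genes[gene_dir[genes] == d]
    a <- length(intersect(bound_all[[tf]], deg_d))
    cc <- length(bound_all[[tf]]) - a + noise_promoter_hits
    p <- fisher_pvalue(a, length(deg_d) - a, cc,
                       n_genes - length(deg_d) - cc)
    if (p * n_tests > alpha)
      stop("internal: planted test ", tf, "/", d, " fails alpha (p=", p, ")")
  }

  ann_path <- file.path(dir, "annotation.tsv")
  write.table(ann[order(ann$gene_id), ], ann_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  man <- data.frame(path = file.path("peaks", paste0(tf_ids, ".bed")),
                    tf_gene_id = tf_ids,
                    library_label = library_label, stringsAsFactors = FALSE)
  man_path <- file.path(dir, "manifest.tsv")
  write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  degs <- data.frame(gene_id = deg_genes,
                     direction = unname(gene_dir[deg_genes]),
                     stringsAsFactors = FALSE)
  degs <- degs[order(degs$gene_id), ]
  deg_path <- file.path(dir, "degs.csv")
  write.table(degs, deg_path, sep = ",", quote = FALSE, row.names = FALSE)

  net_tfs <- tf_ids[cls %in% NETWORK_CLASSES]
  truth <- list(seed = seed, alpha = alpha, upstream_len = upstream_len,
                library_label = library_label, n_genes = n_genes,
                tfs = data.frame(tf_gene_id = tf_ids,
                                 planted_class = unname(cls),
                                 gene_direction = unname(gene_dir[tf_ids]),
                                 stringsAsFactors = FALSE),
                edges = planted$edges,
                network_tfs = net_tfs,
                subnetworks = stats::setNames(.subnetwork_of(cls[net_tfs]),
                                              net_tfs),
                expected_tiers = planted$expected_tiers,
                support = support)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(dir = dir,
                 paths = list(annotation = ann_path, manifest = man_path,
                              degs = deg_path, peaks = unname(peak_files),
                              truth = file.path(dir, "truth.json")),
                 truth = truth))
}

#' Default fold-change strata for the robustness fixture
#'
#' The repressed-side TFs (the DAs and the DS) form a strong-effect stratum
#' (|log2fc| in 2.5-3.5) and the activated-side TFs (USes and UAs) a weak
#' one (1.2-1.8), so that a sweep at thresholds 1 and 2 retains the full
#' network at 1 and exactly the repressed side at 2.
#'
#' @return a strata list for [generate_fc_strata()].
#' @export
default_fc_strata <- function() {
  list(core = list(tfs = sprintf("TF%02d", 1:5), range = c(2.5, 3.5)),
       peripheral = list(tfs = sprintf("TF%02d", 6:9), range = c(1.2, 1.8)))
}

#' Add stratified log2 fold changes to a fixture's DEG table
#'
#' Every DEG gets a |log2fc| drawn uniformly within its stratum's range and
#' signed by its direction. TF-coding DEGs take their own stratum (each DEG
#' TF must belong to exactly one); a background DEG inherits the strongest
#' stratum among the TFs whose enrichment support it provides (so
#' high-threshold refiltering never starves a strong TF of its evidence),
#' and unsupporting background DEGs fall to the weakest stratum.
#'
#' @param fixture result of [generate_fixture()].
#' @param strata list of `list(tfs = <ids>, range = c(lo, hi))`.
#' @param seed integer RNG seed.
#' @return the DEG `data.frame` with `log2fc`, also rewritten to the
#'   fixture's `degs.csv`.
#' @export
generate_fc_strata <- function(fixture, strata = default_fc_strata(),
                               seed = 1L) {
  set.seed(seed)
  truth <- fixture$truth
  all_tfs <- unlist(lapply(strata, `[[`, "tfs"))
  if (anyDuplicated(all_tfs))
    stop("TF(s) assigned to more than one stratum: ",
         paste(unique(all_tfs[duplicated(all_tfs)]), collapse = ", "))
  deg_tfs <- truth$tfs$tf_gene_id[truth$tfs$gene_direction != "none"]
  uncovered <- setdiff(deg_tfs, all_tfs)
  if (length(uncovered))
    stop("strata must cover all planted DEG TFs; missing: ",
         paste(uncovered, collapse = ", "))

  degs <- utils::read.csv(fixture$paths$degs, stringsAsFactors = FALSE)
  lo <- vapply(strata, function(s) s$range[1L], numeric(1))
  weakest <- which.min(lo)
  # stratum index per gene
  stratum_of_tf <- stats::setNames(
    rep(seq_along(strata), vapply(strata, function(s) length(s$tfs),
                                  integer(1))),
    unlist(lapply(strata, `[[`, "tfs")))
  gene_stratum <- rep(weakest, nrow(degs))
  names(gene_stratum) <- degs$gene_id
  for (tf in names(truth$support)) {
    si <- stratum_of_tf[tf]
    if (is.na(si)) next
    salted <- unlist(truth$support[[tf]], use.names = FALSE)
    salted <- intersect(salted, names(gene_stratum))
    upgrade <- lo[si] > lo[gene_stratum[salted]]
    gene_stratum[salted[upgrade]] <- si
  }
  tf_in <- intersect(degs$gene_id, names(stratum_of_tf))
  gene_stratum[tf_in] <- stratum_of_tf[tf_in]

  mags <- vapply(seq_len(nrow(degs)), function(i) {
    r <- strata[[gene_stratum[degs$gene_id[i]]]]$range
    stats::runif(1L, r[1L], r[2L])
  }, numeric(1))
  degs$log2fc <- round(ifelse(degs$direction == "up", mags, -mags), 4L)
  write.table(degs, fixture$paths$degs, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(degs)
}
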