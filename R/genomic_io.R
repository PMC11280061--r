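# Readers for the standard inputs (TSS annotation, BED peak sets, DEG lists)
# and strand-aware promoter extraction.
#
# Coordinate conventions, used everywhere in this package:
#   * internal coordinates are 0-based half-open [start, end), i.e. BED-native;
#   * GFF3 (1-based closed) is converted on read;
#   * `tss` is the 0-based position of the first transcribed base;
#   * plus-strand promoter  = [max(0, tss - upstream_len), tss)
#     minus-strand promoter = [tss + 1, tss + 1 + upstream_len)
#     so the TSS base itself is never part of the promoter.

#' Load a TSS annotation
#'
#' Reads one transcription start site (plus strand) per gene from either a
#' GFF3 annotation or a simple 4-column TSV (`gene_id`, `chrom`, `tss`,
#' `strand`; `tss` 0-based). For multi-isoform genes in GFF3 the
#' representative TSS is, by default, the most upstream transcription start
#' (smallest coordinate on `+`, largest on `-`), which maximizes promoter
#' coverage; `tss_rule = "first-listed"` keeps the first transcript in file
#' order instead.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @param tss_rule representative-TSS rule for multi-isoform genes:
#'   `"most-upstream"` (default) or `"first-listed"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `tss` (0-based
#'   integer), `strand` (`"+"`/`"-"`), sorted by `gene_id`.
#' @export
load_tss_annotation <- function(path, format = c("tsv", "gff3"),
                                tss_rule = c("most-upstream", "first-listed")) {
  format <- match.arg(format)
  tss_rule <- match.arg(tss_rule)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- if (format == "tsv") .read_tss_tsv(path) else .read_tss_gff3(path)

  bad <- !(tab$strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " gene(s) without a usable strand rejected: ",
            paste(head(tab$gene_id[bad], 5L), collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (any(tab$tss < 0))
    stop("negative TSS coordinate for gene(s): ",
         paste(head(tab$gene_id[tab$tss < 0], 5L), collapse = ", "))

  # collapse to one representative TSS per gene
  if (anyDuplicated(tab$gene_id)) {
    pick <- function(d) {
      if (nrow(d) == 1L || tss_rule == "first-listed") return(d[1L, ])
      i <- if (d$strand[1L] == "+") which.min(d$tss) else which.max(d$tss)
      d[i, ]
    }
    tab <- do.call(rbind, lapply(split(tab, tab$gene_id), pick))
  }
  tab <- tab[order(tab$gene_id), c("gene_id", "chrom", "tss", "strand")]
  rownames(tab) <- NULL
  tab
}

.read_tss_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^gene_id\\b", first)
  tab <- read.delim(path, header = has_header, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = "character", blank.lines.skip = TRUE)
  if (!has_header) {
    if (ncol(tab) < 4L) stop("TSS TSV needs 4 columns (gene_id, chrom, tss, strand)")
    names(tab)[1:4] <- c("gene_id", "chrom", "tss", "strand")
  }
  .assert_cols(tab, c("gene_id", "chrom", "tss", "strand"), "TSS TSV")
  tss_num <- suppressWarnings(as.numeric(tab$tss))
  if (any(is.na(tss_num))) {
    line <- which(is.na(tss_num))[1L] + has_header
    stop("malformed TSS value at line ", line, " of ", path)
  }
  data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
             tss = as.integer(tss_num), strand = tab$strand,
             stringsAsFactors = FALSE)
}

.read_tss_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("gene", "mRNA", "transcript")
  if (!any(keep)) stop("GFF3 has no gene/mRNA features: ", path)
  gr <- gr[keep]
  type <- type[keep]
  strand <- as.character(GenomicRanges::strand(gr))
  # 0-based first transcribed base: start-1 on '+', end-1 on '-'
  tss0 <- ifelse(strand == "+",
                 GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr) - 1L)
  id <- as.character(gr$ID)
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  gene_id <- ifelse(type == "gene", id, parent)
  no_id <- is.na(gene_id) | gene_id == ""
  if (any(no_id)) {
    warning(sum(no_id), " GFF3 feature(s) without ID/Parent skipped")
    gene_id <- gene_id[!no_id]; type <- type[!no_id]
    strand <- strand[!no_id]; tss0 <- tss0[!no_id]
    gr <- gr[!no_id]
  }
  # transcript-level records take precedence over the gene extent
  has_tx <- gene_id[type != "gene"]
  drop <- type == "gene" & gene_id %in% has_tx
  data.frame(gene_id = gene_id[!drop],
             chrom = as.character(GenomicRanges::seqnames(gr))[!drop],
             tss = tss0[!drop], strand = strand[!drop],
             stringsAsFactors = FALSE)
}

#' Extract strand-aware promoter regions
#'
#' The promoter is the `upstream_len` bases immediately 5' of the TSS,
#' excluding the TSS base itself: `[max(0, tss - upstream_len), tss)` on the
#' plus strand and `[tss + 1, tss + 1 + upstream_len)` on the minus strand
#' (0-based half-open). Promoters are clipped at position 0 and, when
#' `chrom_sizes` is supplied, at the chromosome end; genes whose promoter
#' clips to zero length are dropped and reported in `attr(, "dropped")`.
#'
#' @param tss annotation `data.frame` from [load_tss_annotation()].
#' @param upstream_len promoter length in bp (default 1000).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
extract_promoters <- function(tss, upstream_len = 1000L, chrom_sizes = NULL) {
  .assert_cols(tss, c("gene_id", "chrom", "tss", "strand"), "TSS annotation")
  upstream_len <- .as_count(upstream_len, "upstream_len")
  if (upstream_len <= 0L) stop("upstream_len must be > 0")
  plus <- tss$strand == "+"
  start <- ifelse(plus, pmax(0L, tss$tss - upstream_len), tss$tss + 1L)
  end <- ifelse(plus, tss$tss, tss$tss + 1L + upstream_len)
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(tss$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("chromosome(s) absent from chrom_sizes: ",
           paste(unknown, collapse = ", "))
    end <- pmin(end, unname(chrom_sizes[tss$chrom]))
    start <- pmin(start, end)
  }
  out <- data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
                    start = as.integer(start), end = as.integer(end),
                    strand = tss$strand, stringsAsFactors = FALSE)
  empty <- out$start >= out$end
  dropped <- out$gene_id[empty]
  if (length(dropped))
    message(length(dropped), " gene(s) with zero-length promoter dropped: ",
            paste(head(dropped, 5L), collapse = ", "))
  out <- out[!empty, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Load one BED peak set for a TF
#'
#' Reads a BED3+ file of binding peaks (0-based half-open, BED-native).
#' `track`/`browser`/comment lines are skipped. Records with
#' `start >= end` are dropped with a warning (count kept in
#' `attr(peaks, "n_dropped")`), duplicate intervals are deduplicated, and
#' peaks are sorted by (chrom, start, end).
#'
#' @param path BED file path.
#' @param tf_gene_id id of the gene encoding the TF this peak set profiles.
#' @param library_label peak-set library label (e.g. `"col"`, `"colamp"`).
#' @param set_id optional identifier distinguishing multiple peak sets of the
#'   same TF; defaults to the file base name.
#' @return object of class `peak_set`: a list with `tf_gene_id`,
#'   `library_label`, `set_id` and `peaks` (data.frame `chrom`, `start`,
#'   `end`, `score`).
#' @export
load_peak_bed <- function(path, tf_gene_id, library_label = "col",
                          set_id = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (!nzchar(tf_gene_id)) stop("tf_gene_id must be non-empty")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "[ \t]+")
    nf <- lengths(parts)
    if (any(nf < 3L))
      stop("malformed BED record (fewer than 3 fields) at data line ",
           which(nf < 3L)[1L], " of ", path)
    chrom <- vapply(parts, `[[`, character(1), 1L)
    start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
    end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
    if (any(is.na(start) | is.na(end)))
      stop("non-numeric BED coordinates at data line ",
           which(is.na(start) | is.na(end))[1L], " of ", path)
    score <- rep(NA_real_, length(chrom))
    has5 <- nf >= 5L
    score[has5] <- suppressWarnings(as.numeric(
      vapply(parts[has5], `[[`, character(1), 5L)))
    peaks <- data.frame(chrom = chrom, start = start, end = end,
                        score = score, stringsAsFactors = FALSE)
  } else {
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), score = numeric(),
                        stringsAsFactors = FALSE)
  }
  bad <- peaks$start >= peaks$end
  if (any(bad))
    warning(sum(bad), " zero-length or inverted peak(s) dropped from ", path)
  peaks <- peaks[!bad, , drop = FALSE]
  peaks <- peaks[!duplicated(peaks[c("chrom", "start", "end")]), , drop = FALSE]
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  attr(peaks, "n_dropped") <- sum(bad)
  structure(list(tf_gene_id = tf_gene_id,
                 library_label = library_label,
                 set_id = set_id %||% sub("\\.bed$", "", basename(path)),
                 peaks = peaks),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> TF", x$tf_gene_id, "| library", x$library_label,
      "| set", x$set_id, "|", nrow(x$peaks), "peaks\n")
  invisible(x)
}

#' Load a peak-set manifest
#'
#' The manifest is a TSV with header columns `path`, `tf_gene_id`,
#' `library_label` (one row per BED peak set). Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest TSV path.
#' @return list of [load_peak_bed()] `peak_set` objects.
#' @export
load_peak_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  .assert_cols(man, c("path", "tf_gene_id", "library_label"), "peak manifest")
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    load_peak_bed(p, man$tf_gene_id[i], man$library_label[i])
  })
}

.validate_degs <- function(deg) {
  bad_dir <- !(deg$direction %in% c("up", "down"))
  if (any(bad_dir))
    stop("invalid DEG direction(s): ",
         paste(unique(deg$direction[bad_dir]), collapse = ", "))
  deg <- deg[!duplicated(deg[c("gene_id", "direction")]), , drop = FALSE]
  both <- intersect(deg$gene_id[deg$direction == "up"],
                    deg$gene_id[deg$direction == "down"])
  if (length(both))
    stop("gene(s) present in both the up and the down DEG list: ",
         paste(head(both, 10L), collapse = ", "))
  if ("log2fc" %in% names(deg)) {
    fc <- suppressWarnings(as.numeric(deg$log2fc))
    wrong <- !is.na(fc) &
      ((deg$direction == "up" & fc < 0) | (deg$direction == "down" & fc > 0))
    if (any(wrong))
      stop("log2fc sign inconsistent with direction for gene(s): ",
           paste(head(deg$gene_id[wrong], 10L), collapse = ", "))
    deg$log2fc <- fc
  }
  rownames(deg) <- NULL
  deg
}

#' Load DEG lists
#'
#' Either two plain gene-id lists (one id per line) via `up_path` /
#' `down_path`, or one combined CSV via `table_path` with header columns
#' `gene_id`, `direction` (`"up"`/`"down"`) and optionally `log2fc`,
#' `adj_p`. A gene appearing in both directions is a hard error; duplicate
#' (gene, direction) rows collapse to one.
#'
#' @param up_path,down_path paths to plain up-/downregulated gene-id lists.
#' @param table_path path to a combined CSV DEG table.
#' @return `data.frame` with `gene_id`, `direction` and, when available,
#'   `log2fc`, `adj_p`.
#' @export
load_deg_lists <- function(up_path = NULL, down_path = NULL,
                           table_path = NULL) {
  if (!is.null(table_path)) {
    deg <- utils::read.csv(table_path, stringsAsFactors = FALSE)
    .assert_cols(deg, c("gene_id", "direction"), "DEG table")
  } else {
    if (is.null(up_path) || is.null(down_path))
      stop("supply either table_path or both up_path and down_path")
    read_ids <- function(p) {
      ids <- trimws(readLines(p))
      unique(ids[nzchar(ids)])
    }
    up <- read_ids(up_path)
    down <- read_ids(down_path)
    deg <- data.frame(gene_id = c(up, down),
                      direction = rep(c("up", "down"), c(length(up), length(down))),
                      stringsAsFactors = FALSE)
  }
  if (any(!nzchar(deg$gene_id))) stop("empty gene id in DEG input")
  .validate_degs(deg)
}
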