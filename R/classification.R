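# Step 2: classify each enriched TF from (enrichment directions, own-gene
# DEG direction) and keep only the four classes the network step can use.

#' Classify one TF from its enrichment pattern and own-gene direction
#'
#' The seven classes are read off a 3 x 3 grid (enriched in up-DEG promoters
#' only / down only / both, crossed with the TF's own coding gene being an
#' up-DEG / down-DEG / not a DEG):
#' \itemize{
#'   \item up-only + gene up = \strong{UA} (upregulated activator),
#'   \item up-only + gene down = \strong{DS} (downregulated suppressor),
#'   \item down-only + gene up = \strong{US} (upregulated suppressor),
#'   \item down-only + gene down = \strong{DA} (downregulated activator),
#'   \item both directions = \strong{UR} / \strong{DR} for gene up / down,
#'   \item gene not a DEG = \strong{NTR} (non-transcriptionally regulated).
#' }
#' A TF with no enrichment at all has no class (error).
#'
#' @param enriched_up,enriched_down logicals (vectorized).
#' @param gene_direction `"up"`, `"down"` or `"none"` (vectorized).
#' @return character vector of classes.
#' @export
classify_tf <- function(enriched_up, enriched_down, gene_direction) {
  n <- max(length(enriched_up), length(enriched_down), length(gene_direction))
  enriched_up <- rep_len(as.logical(enriched_up), n)
  enriched_down <- rep_len(as.logical(enriched_down), n)
  gene_direction <- rep_len(as.character(gene_direction), n)
  if (any(!enriched_up & !enriched_down))
    stop("classify_tf() requires enrichment in at least one direction")
  if (any(!gene_direction %in% c("up", "down", "none")))
    stop("gene_direction must be one of up, down, none")
  out <- character(n)
  out[gene_direction == "none"] <- "NTR"
  both <- enriched_up & enriched_down & gene_direction != "none"
  out[both & gene_direction == "up"] <- "UR"
  out[both & gene_direction == "down"] <- "DR"
  up_only <- enriched_up & !enriched_down & gene_direction != "none"
  out[up_only & gene_direction == "up"] <- "UA"
  out[up_only & gene_direction == "down"] <- "DS"
  down_only <- !enriched_up & enriched_down & gene_direction != "none"
  out[down_only & gene_direction == "up"] <- "US"
  out[down_only & gene_direction == "down"] <- "DA"
  out
}

#' Classify all enriched TFs of an enrichment run
#'
#' Aggregates over a TF's peak sets first (the TF counts as enriched in a
#' direction if any of its peak sets is), then applies [classify_tf()]. The
#' TF's own direction comes from the DEG table; a TF-coding gene absent from
#' both DEG lists is `"none"` (NTR path).
#'
#' @param records enrichment `data.frame` from [run_enrichment()].
#' @param deg_table DEG `data.frame`.
#' @return `data.frame` with `tf_gene_id`, `tf_class`, `enriched_up`,
#'   `enriched_down`, `gene_direction`, sorted by `tf_gene_id`.
#' @export
classify_all <- function(records, deg_table) {
  .assert_cols(records, c("tf_gene_id", "direction", "enriched"),
               "enrichment records")
  enr <- records[records$enriched, , drop = FALSE]
  tfs <- sort(unique(enr$tf_gene_id))
  if (!length(tfs))
    return(data.frame(tf_gene_id = character(), tf_class = character(),
                      enriched_up = logical(), enriched_down = logical(),
                      gene_direction = character(), stringsAsFactors = FALSE))
  up <- tfs %in% enr$tf_gene_id[enr$direction == "up"]
  down <- tfs %in% enr$tf_gene_id[enr$direction == "down"]
  dir_map <- c(stats::setNames(deg_table$direction, deg_table$gene_id))
  gene_dir <- unname(dir_map[tfs])
  gene_dir[is.na(gene_dir)] <- "none"
  data.frame(tf_gene_id = tfs,
             tf_class = classify_tf(up, down, gene_dir),
             enriched_up = up, enriched_down = down,
             gene_direction = gene_dir, stringsAsFactors = FALSE)
}

#' Keep only the four network classes
#'
#' DR, UR and NTR TFs cannot be univocally characterized as activators or
#' suppressors of the response, so they are filtered out before network
#' construction; removals are reported per class.
#'
#' @param classifications `data.frame` from [classify_all()].
#' @return the subset with `tf_class` in DA, DS, US, UA.
#' @export
retain_network_classes <- function(classifications) {
  .assert_cols(classifications, c("tf_gene_id", "tf_class"), "classifications")
  drop <- !(classifications$tf_class %in% NETWORK_CLASSES)
  if (any(drop)) {
    tally <- table(classifications$tf_class[drop])
    message("filtered out ", sum(drop), " TF(s) outside the network classes: ",
            paste(sprintf("%s=%d", names(tally), as.integer(tally)),
                  collapse = ", "))
  }
  out <- classifications[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
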