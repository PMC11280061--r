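test_that("TSV annotation parses, validates and sorts", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("g2\tchr1\t9000\t-", "g1\tchr1\t5000\t+"), f)
  tss <- load_tss_annotation(f, "tsv")
  expect_equal(tss$gene_id, c("g1", "g2"))
  expect_equal(tss$tss, c(5000L, 9000L))
  expect_equal(tss$strand, c("+", "-"))

  # header dialect
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand", "g1\tchr1\t5000\t+"), f2)
  expect_equal(load_tss_annotation(f2, "tsv")$tss, 5000L)

  # malformed coordinate names its line
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tchr1\t5000\t+", "g2\tchr1\toops\t+"), f3)
  expect_error(load_tss_annotation(f3, "tsv"), "line 2")

  # strand-less genes are rejected with a report
  f4 <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tchr1\t5000\t+", "g2\tchr1\t100\t."), f4)
  expect_warning(tss4 <- load_tss_annotation(f4, "tsv"), "g2")
  expect_equal(tss4$gene_id, "g1")
})

test_that("GFF3 annotation applies the representative-TSS rule", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t4801\t6000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t5001\t6000\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\tsrc\tmRNA\t4801\t6000\t.\t+\t.\tID=g1.2;Parent=g1",
    "chr1\tsrc\tgene\t7001\t8000\t.\t-\t.\tID=g2",
    "chr1\tsrc\tgene\t9001\t9500\t.\t+\t.\tID=g3"), f)
  tss <- load_tss_annotation(f, "gff3")
  expect_equal(tss$gene_id, c("g1", "g2", "g3"))
  # most-upstream: + strand takes the smallest start (1-based 4801 -> 0-based 4800)
  expect_equal(tss$tss[tss$gene_id == "g1"], 4800L)
  # minus strand gene extent: TSS at the right end (1-based 8000 -> 0-based 7999)
  expect_equal(tss$tss[tss$gene_id == "g2"], 7999L)
  # first-listed keeps the first transcript in file order
  tss_fl <- load_tss_annotation(f, "gff3", tss_rule = "first-listed")
  expect_equal(tss_fl$tss[tss_fl$gene_id == "g1"], 5000L)
})

test_that("promoter extraction follows the strand conventions and clips", {
  tss <- data.frame(gene_id = c("p1", "p2", "m1"),
                    chrom = "chr1",
                    tss = c(5000L, 300L, 5000L),
                    strand = c("+", "+", "-"),
                    stringsAsFactors = FALSE)
  pr <- extract_promoters(tss, 1000L)
  expect_equal(pr$start[pr$gene_id == "p1"], 4000L)
  expect_equal(pr$end[pr$gene_id == "p1"], 5000L)
  # clipped at the chromosome start
  expect_equal(pr$start[pr$gene_id == "p2"], 0L)
  expect_equal(pr$end[pr$gene_id == "p2"], 300L)
  # minus strand: the kilobase genomically right of the TSS, TSS base excluded
  expect_equal(pr$start[pr$gene_id == "m1"], 5001L)
  expect_equal(pr$end[pr$gene_id == "m1"], 6001L)

  # clipping at the chromosome end, and empty promoters dropped with report
  pr2 <- suppressMessages(
    extract_promoters(tss, 1000L, chrom_sizes = c(chr1 = 5500L)))
  expect_equal(pr2$end[pr2$gene_id == "m1"], 5500L)
  tss3 <- data.frame(gene_id = "m2", chrom = "chr1", tss = 5499L,
                     strand = "-", stringsAsFactors = FALSE)
  expect_message(
    pr3 <- extract_promoters(tss3, 1000L, chrom_sizes = c(chr1 = 5500L)),
    "m2")
  expect_equal(nrow(pr3), 0L)
  expect_equal(attr(pr3, "dropped"), "m2")
  expect_error(extract_promoters(tss, 1000L, chrom_sizes = c(chrX = 1e6)),
               "chr1")
})

test_that("promoter reflection symmetry maps + promoters onto - promoters", {
  set.seed(42)
  L <- 100000L
  n <- 50L
  tss_plus <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                         chrom = "chr1",
                         tss = sample(2000:90000, n),
                         strand = "+", stringsAsFactors = FALSE)
  # reflect x -> L - 1 - x and flip the strand
  tss_minus <- tss_plus
  tss_minus$tss <- L - 1L - tss_plus$tss
  tss_minus$strand <- "-"
  pp <- extract_promoters(tss_plus, 1000L)
  pm <- extract_promoters(tss_minus, 1000L)
  # reflecting the + promoter [s, e) gives [L - e, L - s)
  expect_equal(pm$start, L - pp$end)
  expect_equal(pm$end, L - pp$start)
})

test_that("BED peak sets load with filtering, dedup and sorting", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t500\t700", "chr1\t900\t800", "chr1\t100\t300\tpk\t7.5",
               "chr1\t100\t300"), f)
  expect_warning(ps <- load_peak_bed(f, "TFX"), "inverted")
  expect_s3_class(ps, "peak_set")
  expect_equal(nrow(ps$peaks), 2L)            # inverted dropped, dup collapsed
  expect_equal(ps$peaks$start, c(100L, 500L)) # sorted
  expect_equal(attr(ps$peaks, "n_dropped"), 1L)

  fe <- tempfile(fileext = ".bed")
  file.create(fe)
  expect_equal(nrow(load_peak_bed(fe, "TFY")$peaks), 0L)

  # read -> write -> read round-trips the retained records
  f2 <- tempfile(fileext = ".bed")
  write.table(ps$peaks[c("chrom", "start", "end")], f2, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  ps2 <- load_peak_bed(f2, "TFX", set_id = ps$set_id)
  expect_equal(ps2$peaks[c("chrom", "start", "end")],
               ps$peaks[c("chrom", "start", "end")])
})

test_that("peak manifests resolve relative paths", {
  d <- fixture_dir()
  writeLines("chr1\t10\t60", file.path(d, "a.bed"))
  writeLines(c("path\ttf_gene_id\tlibrary_label", "a.bed\tTFA\tcol"),
             file.path(d, "manifest.tsv"))
  sets <- load_peak_manifest(file.path(d, "manifest.tsv"))
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$tf_gene_id, "TFA")
  expect_equal(sets[[1]]$library_label, "col")
})

test_that("DEG lists validate directions, overlaps and fold-change signs", {
  up <- tempfile(); down <- tempfile()
  writeLines(c("a", "b", "b"), up)
  writeLines("c", down)
  deg <- load_deg_lists(up, down)
  expect_equal(nrow(deg), 3L)                 # duplicate collapsed
  expect_setequal(deg$gene_id[deg$direction == "up"], c("a", "b"))

  writeLines("a", down)
  expect_error(load_deg_lists(up, down), "a")

  f <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,direction,log2fc", "a,up,2.5", "b,down,-1.2"), f)
  deg2 <- load_deg_lists(table_path = f)
  expect_equal(deg2$log2fc, c(2.5, -1.2))
  writeLines(c("gene_id,direction,log2fc", "a,up,-2.5"), f)
  expect_error(load_deg_lists(table_path = f), "a")
})
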