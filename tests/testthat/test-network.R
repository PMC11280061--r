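PAIRS8 <- data.frame(
  regulator = c("UA", "UA", "DS", "DS", "US", "US", "DA", "DA"),
  target    = c("UA", "US", "UA", "US", "DA", "DS", "DA", "DS"),
  stringsAsFactors = FALSE)

test_that("exactly the eight sign-consistent class pairs are meaningful", {
  expect_true(is_meaningful_pair("UA", "US"))
  expect_false(is_meaningful_pair("UA", "DA"))
  expect_error(is_meaningful_pair("UA", "NTR"), "network classes")
  grid <- expand.grid(regulator = c("DA", "DS", "US", "UA"),
                      target = c("DA", "DS", "US", "UA"),
                      stringsAsFactors = FALSE)
  grid$ok <- is_meaningful_pair(grid$regulator, grid$target)
  expect_equal(sum(grid$ok), 8L)
  got <- grid[grid$ok, c("regulator", "target")]
  key <- function(d) sort(paste(d$regulator, d$target, sep = "-"))
  expect_equal(key(got), key(PAIRS8))
})

test_that("links require a promoter peak and a meaningful pair", {
  cls <- data.frame(tf_gene_id = c("A1", "A2", "S1", "U1"),
                    tf_class = c("DA", "DA", "US", "UA"),
                    stringsAsFactors = FALSE)
  prom <- mk_promoters(c("A1", "A2", "S1", "U1"),
                       c(0L, 3000L, 6000L, 9000L),
                       c(1000L, 4000L, 7000L, 10000L))
  ps <- list(
    mk_peakset("A1", c(3100L, 100L), c(3300L, 300L)),  # A2 + self promoter
    mk_peakset("S1", c(100L, 9100L), c(300L, 9300L)))  # A1 + U1 promoters
  links <- infer_links(cls, prom, ps)
  expect_equal(nrow(links), 3L)
  # DA with a peak in another DA's promoter -> activation link
  expect_true(any(links$regulator == "A1" & links$target == "A2" &
                    links$sign == "activation"))
  # DA-DA self-link is kept
  expect_true(any(links$regulator == "A1" & links$target == "A1"))
  # US peak in a DA promoter -> inhibition; US-UA is not meaningful -> no link
  expect_true(any(links$regulator == "S1" & links$target == "A1" &
                    links$sign == "inhibition"))
  expect_false(any(links$target == "U1"))

  # removing peaks never adds links (monotonicity)
  ps_less <- list(ps[[1]], mk_peakset("S1", 100L, 300L))
  links_less <- infer_links(cls, prom, ps_less)
  k <- function(l) paste(l$regulator, l$target)
  expect_true(all(k(links_less) %in% k(links)))
})

test_that("multiple supporting peaks collapse onto one evidenced edge", {
  cls <- data.frame(tf_gene_id = c("A1", "A2"), tf_class = c("DA", "DA"),
                    stringsAsFactors = FALSE)
  prom <- mk_promoters(c("A1", "A2"), c(0L, 3000L), c(1000L, 4000L))
  ps <- list(mk_peakset("A1", c(3100L, 3500L), c(3300L, 3700L)),
             mk_peakset("A1", 3600L, 3800L, set_id = "rep2"))
  links <- infer_links(cls, prom, ps)
  expect_equal(nrow(links), 1L)
  expect_equal(links$n_support, 3L)
  expect_equal(nrow(links$support[[1]]), 3L)
})

test_that("subnetwork partition labels nodes and edge scopes", {
  cls <- data.frame(tf_gene_id = c("d1", "d2", "s1", "u1"),
                    tf_class = c("DA", "DS", "US", "UA"),
                    stringsAsFactors = FALSE)
  links <- data.frame(regulator = c("d1", "s1", "d2", "u1"),
                      target = c("d2", "d1", "u1", "u1"),
                      stringsAsFactors = FALSE)
  parts <- partition_subnetworks(cls, links)
  expect_equal(parts$nodes$subnetwork, c("R", "R", "A", "A"))
  expect_equal(parts$edges$scope,
               c("within-R", "A-to-R", "R-to-A", "within-A"))
  # empty A side still partitions
  cls_r <- cls[cls$tf_class %in% c("DA", "DS"), ]
  parts_r <- partition_subnetworks(cls_r, links[1, , drop = FALSE])
  expect_equal(unique(parts_r$nodes$subnetwork), "R")
})

test_that("tier assignment follows the source/triggered/rest rule", {
  cls <- data.frame(tf_gene_id = c("a", "b", "c", "s1"),
                    tf_class = c("DA", "DA", "DA", "US"),
                    stringsAsFactors = FALSE)
  chain <- data.frame(regulator = c("a", "b", "s1"),
                      target = c("b", "c", "a"), stringsAsFactors = FALSE)
  # the US->a edge is outside the DA-DA core and must not affect in-degree
  tiers <- assign_tiers(cls, chain)
  expect_equal(tiers[c("a", "b", "c")], c(a = 1L, b = 2L, c = 3L))
  expect_true(is.na(tiers[["s1"]]))

  # a self-loop alone leaves the node in tier 1
  solo <- data.frame(regulator = "a", target = "a", stringsAsFactors = FALSE)
  expect_equal(assign_tiers(cls, solo)[["a"]], 1L)

  # a pure 2-cycle has no tier-1 seed: both nodes to tier 3 with a warning
  cyc <- data.frame(regulator = c("a", "b"), target = c("b", "a"),
                    stringsAsFactors = FALSE)
  expect_warning(t3 <- assign_tiers(cls, cyc), "no source")
  expect_equal(unname(t3[c("a", "b")]), c(3L, 3L))

  # strict rule: a node fed by tier-1 and tier-2 parents drops to tier 3
  dag <- data.frame(regulator = c("a", "a", "b"), target = c("b", "c", "c"),
                    stringsAsFactors = FALSE)
  t_any <- assign_tiers(cls, dag, "any-parent")
  t_all <- assign_tiers(cls, dag, "all-parents")
  expect_equal(t_any[["c"]], 2L)
  expect_equal(t_all[["c"]], 3L)
})

test_that("graph export round-trips and preserves attributes", {
  fx <- generate_fixture(dir = fixture_dir(), seed = 31)
  res <- run_fixture_pipeline(fx)
  net <- res$network
  expect_silent(validate_tfrn(net))

  f <- tempfile(fileext = ".graphml")
  export_graph(net, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(sort(igraph::V(g)$name), sort(net$nodes$tf_gene_id))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(unique(igraph::E(g)$sign), unique(net$edges$sign))
  nd <- net$nodes[match(igraph::V(g)$name, net$nodes$tf_gene_id), ]
  expect_equal(igraph::V(g)$class, nd$tf_class)
  expect_equal(igraph::V(g)$tier,
               ifelse(is.na(nd$tier), "none", as.character(nd$tier)))

  ftsv <- tempfile(fileext = ".tsv")
  export_graph(net, ftsv, "tsv")
  el <- read.delim(ftsv)
  expect_equal(names(el), c("regulator", "target", "sign",
                            "n_supporting_peaks"))
  expect_equal(nrow(el), nrow(net$edges))

  fjson <- tempfile(fileext = ".json")
  export_graph(net, fjson, "json")
  j <- jsonlite::read_json(fjson, simplifyVector = TRUE)
  expect_equal(nrow(j$nodes), nrow(net$nodes))

  # empty graph exports a valid document
  empty <- build_tfrn(res$network_tfs[0, ], res$promoters, list())
  fdot <- tempfile(fileext = ".dot")
  expect_silent(export_graph(empty, fdot, "dot"))
  expect_true(file.exists(fdot))
  expect_error(export_graph(net, tempfile(), "xml"), "'arg'")
})

test_that("link-set comparison is plain set arithmetic on pairs", {
  a <- data.frame(regulator = c("a", "b"), target = c("b", "c"),
                  stringsAsFactors = FALSE)
  b <- data.frame(regulator = "b", target = "c", stringsAsFactors = FALSE)
  cmp <- compare_link_sets(a, b)
  expect_equal(cmp$only_a, data.frame(regulator = "a", target = "b",
                                      stringsAsFactors = FALSE))
  expect_equal(nrow(cmp$only_b), 0L)
  expect_equal(cmp$common$target, "c")
  expect_equal(nrow(cmp$only_a) + nrow(cmp$common), nrow(unique(a)))

  same <- compare_link_sets(a, a)
  expect_equal(nrow(same$only_a) + nrow(same$only_b), 0L)
  disj <- compare_link_sets(a, data.frame(regulator = "x", target = "y"))
  expect_equal(nrow(disj$common), 0L)
})
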