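test_that("TSV edge tables parse, normalize and deduplicate", {
  net <- read_edge_table(ffl_fixture_tsv(), "tsv")
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$nodes$symbol, c("MIR155", "SOX10", "MITF"))
  expect_equal(node_class_of(net, "MIR155")[[1]], "MIRNA")

  # same edge under two provenances collapses with provenance union
  dup <- ffl_fixture_tsv(extra_rows = paste(
    "SOX10", "MITF", "+1", "transcriptional", "TF", "TF", "pluripotency",
    sep = "\t"))
  net2 <- read_edge_table(dup, "tsv")
  expect_equal(nrow(net2$edges), 3)
  e <- net2$edges[net2$edges$source == "SOX10", ]
  expect_setequal(e$provenance[[1]], c("melanoma", "pluripotency"))

  # header-only file: empty network
  empty <- tempfile(fileext = ".tsv")
  writeLines(paste(c("source", "target", "sign", "mechanism",
                     "node_class_source", "node_class_target",
                     "provenance"), collapse = "\t"), empty)
  net3 <- read_edge_table(empty, "tsv")
  expect_equal(nrow(net3$nodes), 0)
  expect_equal(nrow(net3$edges), 0)
})

test_that("malformed rows and unknown sign tokens are rejected with context", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("source", "target", "sign", "mechanism",
                       "node_class_source", "node_class_target",
                       "provenance"), collapse = "\t"),
               "A\tB"), bad)
  expect_error(read_edge_table(bad, "tsv"), "line 2")

  badsign <- ffl_fixture_tsv(extra_rows = paste(
    "SOX10", "TYR", "up", "transcriptional", "TF", "PCG", "melanoma",
    sep = "\t"))
  expect_error(read_edge_table(badsign, "tsv"), "sign token 'up' at line 5")
})

test_that("symbol normalization unifies miRNA spellings and uppercases genes", {
  expect_equal(normalize_symbol(c("miR-155-5p", "hsa-miR-155", "MIR155")),
               rep("MIR155", 3))
  expect_equal(normalize_symbol("sox10"), "SOX10")
  expect_equal(normalize_symbol("miR-200a-3p"), "MIR200A")
  net <- reg_network(
    nodes = data.frame(symbol = c("miR-155", "MIR155", "sox10"),
                       node_class = c("MIRNA", "MIRNA", "TF")))
  expect_equal(nrow(net$nodes), 2)
})

test_that("network invariants are enforced", {
  nodes <- data.frame(symbol = c("A", "B"), node_class = c("TF", "PCG"))
  expect_error(reg_network(nodes, data.frame(
    source = "A", target = "A", sign = 1,
    mechanism = "transcriptional")), "self-loop")
  expect_error(reg_network(nodes, data.frame(
    source = "A", target = "B", sign = 2,
    mechanism = "transcriptional")), "sign")
  expect_error(reg_network(nodes, data.frame(
    source = "A", target = "C", sign = 1,
    mechanism = "transcriptional")), "not in node table")
  mir <- data.frame(symbol = c("MIR1", "B"),
                    node_class = c("MIRNA", "PCG"))
  expect_error(reg_network(mir, data.frame(
    source = "MIR1", target = "B", sign = -1,
    mechanism = "transcriptional")), "post_transcriptional")
})

test_that("merging unions nodes/edges and tracks origins", {
  n1 <- two_node_net("A", "B", "melanoma")
  n2 <- two_node_net("C", "D", "astrocyte")
  m <- merge_networks(list(n1, n2))
  expect_equal(nrow(m$nodes), 4)
  expect_true(all(lengths(m$nodes$origins) == 1))

  n3 <- two_node_net("SOX10", "MITF", "pluripotency")
  n4 <- two_node_net("SOX10", "TYR", "melanoma")
  m2 <- merge_networks(list(n3, n4))
  expect_setequal(
    m2$nodes$origins[[which(m2$nodes$symbol == "SOX10")]],
    c("pluripotency", "melanoma"))

  # idempotence: merging a network with itself changes nothing
  m3 <- merge_networks(list(n1, n1), name = n1$name)
  expect_same_network(m3, n1)
})

test_that("merge resolves node-class conflicts by priority with a message", {
  n1 <- two_node_net("A", "B", "x", class_b = "PCG")
  n2 <- two_node_net("C", "B", "y", class_b = "TF")
  expect_message(m <- merge_networks(list(n1, n2)), "conflict")
  expect_equal(node_class_of(m, "B")[[1]], "TF")
})

test_that("focal subnetwork extraction is an induced ego graph", {
  net <- read_edge_table(ffl_fixture_tsv(), "tsv")
  ego <- extract_focal_subnetwork(net, "SOX10", 1)
  # MITF and miR-155 are both adjacent to SOX10; the miR-155 -> MITF edge
  # between neighbours must be retained (induced subgraph)
  expect_same_network(ego, net)
  expect_equal(nrow(extract_focal_subnetwork(net, "SOX10", 0)$nodes), 1)
  expect_equal(nrow(extract_focal_subnetwork(net, "SOX10", 0)$edges), 0)
  expect_error(extract_focal_subnetwork(net, "NOPE"), "not present")

  lone <- reg_network(nodes = data.frame(symbol = "X", node_class = "PCG"))
  expect_equal(nrow(extract_focal_subnetwork(lone, "X", 1)$nodes), 1)
})

test_that("ego radius is monotone and saturates at the weak component", {
  net <- generate_random_network(6, 2, 8, edge_prob = 0.15, seed = 42)
  focal <- net$nodes$symbol[1]
  sizes <- vapply(0:8, function(r)
    nrow(extract_focal_subnetwork(net, focal, r)$nodes), 0L)
  expect_true(all(diff(sizes) >= 0))
  # past the diameter the ego equals the focal node's weak component
  expect_equal(sizes[8], sizes[9])
})

test_that("miRNA-target integration adds repressive edges and dedups", {
  net <- read_edge_table(ffl_fixture_tsv(), "tsv")
  tbl <- data.frame(miRNA = "miR-340", target_gene = "MITF",
                    evidence = "luciferase assay")
  out <- integrate_mirna_targets(net, tbl)
  expect_equal(nrow(out$nodes), 4)
  e <- out$edges[out$edges$source == "MIR340", ]
  expect_equal(e$sign, -1L)
  expect_equal(e$mechanism, "post_transcriptional")
  expect_equal(e$evidence, "luciferase assay")

  # absent target skipped under restrict_to_existing
  skip_tbl <- data.frame(miRNA = "miR-1", target_gene = "ABSENT",
                         evidence = "qPCR")
  out2 <- integrate_mirna_targets(net, skip_tbl)
  expect_equal(attr(out2, "n_skipped"), 1L)
  expect_equal(nrow(out2$edges), nrow(net$edges))

  # duplicate rows collapse with evidence concatenation
  dup <- data.frame(miRNA = c("miR-340", "miR-340"),
                    target_gene = c("MITF", "MITF"),
                    evidence = c("qPCR", "western_blot"))
  out3 <- integrate_mirna_targets(net, dup)
  e3 <- out3$edges[out3$edges$source == "MIR340", ]
  expect_equal(nrow(e3), 1)
  expect_equal(e3$evidence, "qPCR;western_blot")

  expect_error(integrate_mirna_targets(net, data.frame(
    miRNA = "", target_gene = "MITF", evidence = "")), "empty")
  expect_warning(integrate_mirna_targets(net, data.frame(
    miRNA = "miR-9", target_gene = "MITF", evidence = "", sign = 1)),
    "override")
})

test_that("TF annotation reclassifies non-miRNA nodes only", {
  net <- fixture_melanoma_circuits()
  suppressMessages({
    ann <- annotate_tfs(net, c("SOX10", "MITF", "ATF2"))
  })
  expect_equal(unname(node_class_of(ann, c("SOX10", "MITF", "ATF2"))),
               rep("TF", 3))
  expect_equal(unname(node_class_of(ann, c("MIR155", "MIR204"))),
               rep("MIRNA", 2))

  suppressMessages(none <- annotate_tfs(net, character()))
  expect_true(all(none$nodes$node_class[
    none$nodes$symbol %in% c("SOX10", "MITF", "ATF2")] == "PCG"))

  expect_warning(suppressMessages(annotate_tfs(net, c("SOX10", "MIR155"))),
                 "miRNA")
})

test_that("degree summary counts incident edges and sorts hubs first", {
  net <- read_edge_table(ffl_fixture_tsv(), "tsv")
  ds <- degree_summary(net)
  expect_equal(sort(ds$total_degree), c(2, 2, 2))
  expect_equal(sum(ds$total_degree), 2 * nrow(net$edges))

  hub <- reg_network(
    nodes = data.frame(symbol = c("H", paste0("T", 1:5)),
                       node_class = c("TF", rep("PCG", 5))),
    edges = data.frame(source = "H", target = paste0("T", 1:5), sign = 1,
                       mechanism = "transcriptional"))
  ds2 <- degree_summary(hub)
  expect_equal(ds2$symbol[1], "H")
  expect_equal(ds2$total_degree[1], 5)
  expect_equal(ds2$out_degree[1], 5)

  lone <- reg_network(nodes = data.frame(symbol = "X", node_class = "PCG"))
  expect_equal(degree_summary(lone)$total_degree, 0L)
})

test_that("degree totals sum to twice the edge count on random networks", {
  for (seed in 1:5) {
    net <- random_test_network(seed)
    expect_equal(sum(degree_summary(net)$total_degree),
                 2 * nrow(net$edges))
  }
})

test_that("tidy and glance summarize networks", {
  net <- fixture_melanoma_circuits()
  td <- tidy(net)
  expect_equal(nrow(td), 6)
  expect_true(all(c("source_class", "target_class") %in% names(td)))
  gl <- glance(net)
  expect_equal(gl$n_nodes, 5)
  expect_equal(gl$n_mirna, 2)
  expect_equal(gl$n_repressing, 4)
})
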