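ffl_fixture_tsv <- function(path = tempfile(fileext = ".tsv"),
                            extra_rows = character()) {
  writeLines(c(
    paste("source", "target", "sign", "mechanism", "node_class_source",
          "node_class_target", "provenance", sep = "\t"),
    paste("miR-155", "SOX10", "-1", "post_transcriptional", "MIRNA", "TF",
          "melanoma", sep = "\t"),
    paste("miR-155", "MITF", "-1", "post_transcriptional", "MIRNA", "TF",
          "melanoma", sep = "\t"),
    paste("SOX10", "MITF", "+1", "transcriptional", "TF", "TF",
          "melanoma", sep = "\t"),
    extra_rows), path)
  path
}

two_node_net <- function(a, b, name, sign = 1L, class_a = "TF",
                         class_b = "PCG") {
  reg_network(
    nodes = tibble::tibble(symbol = c(a, b),
                           node_class = c(class_a, class_b)),
    edges = tibble::tibble(source = a, target = b, sign = sign,
                           mechanism = "transcriptional"),
    name = name)
}

expect_same_network <- function(a, b) {
  na <- dplyr::arrange(a$nodes, symbol)
  nb <- dplyr::arrange(b$nodes, symbol)
  expect_equal(na$symbol, nb$symbol)
  expect_equal(na$node_class, nb$node_class)
  expect_equal(lapply(na$origins, sort), lapply(nb$origins, sort))
  ea <- dplyr::arrange(a$edges, source, target, mechanism)
  eb <- dplyr::arrange(b$edges, source, target, mechanism)
  expect_equal(ea$source, eb$source)
  expect_equal(ea$target, eb$target)
  expect_equal(ea$sign, eb$sign)
  expect_equal(ea$mechanism, eb$mechanism)
  expect_equal(lapply(ea$provenance, sort), lapply(eb$provenance, sort))
  expect_equal(ea$evidence, eb$evidence)
}
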