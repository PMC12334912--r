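test_that("the melanoma fixture yields its two canonical circuits", {
  net <- fixture_melanoma_circuits()
  ffl <- enumerate_ffls(net, require_member = "SOX10", require_mirna = TRUE)
  expect_equal(nrow(ffl), 1)
  expect_equal(ffl$m1, "MIR155")
  expect_equal(ffl$m2, "SOX10")
  expect_equal(ffl$m3, "MITF")
  expect_equal(c(ffl$s1, ffl$s2, ffl$s3), c(-1L, 1L, -1L))
  expect_equal(ffl$sign_class, "coherent")

  fbl <- enumerate_fbls(net, 3, require_member = "SOX10",
                        require_mirna = TRUE)
  expect_equal(nrow(fbl), 1)
  expect_equal(fbl$kind, "FBL3")
  # canonical rotation starts at ATF2 (lexicographically smallest)
  expect_equal(c(fbl$m1, fbl$m2, fbl$m3), c("ATF2", "SOX10", "MIR204"))
  expect_equal(c(fbl$s1, fbl$s2, fbl$s3), c(-1L, 1L, -1L))
  expect_equal(fbl$sign_class, "positive")
})

test_that("edgeless and empty networks give empty motif sets", {
  lone <- reg_network(nodes = data.frame(symbol = c("A", "B", "C"),
                                         node_class = "TF"))
  expect_equal(nrow(enumerate_ffls(lone)), 0)
  expect_equal(nrow(enumerate_fbls(lone)), 0)
  census <- motif_census(lone)
  expect_equal(sum(census$n), 0)
})

test_that("FFL coherence follows the sign-product rule on all 8 patterns", {
  patterns <- expand.grid(s1 = c(-1L, 1L), s2 = c(-1L, 1L),
                          s3 = c(-1L, 1L))
  m <- tibble::tibble(kind = "FFL", m1 = "A", m2 = "B", m3 = "C",
                      s1 = patterns$s1, s2 = patterns$s2, s3 = patterns$s3,
                      mech1 = "transcriptional", mech2 = "transcriptional",
                      mech3 = "transcriptional",
                      sign_class = NA_character_, subtype = NA_integer_)
  out <- classify_ffl(m)
  # independent evaluation of the rule: direct sign equals indirect product
  expected <- ifelse(patterns$s3 == patterns$s1 * patterns$s2,
                     "coherent", "incoherent")
  expect_equal(out$sign_class, expected)
  expect_equal(sum(out$sign_class == "coherent"), 4)
  # subtypes 1-4 each appear exactly once per coherence class
  expect_equal(sort(out$subtype[out$sign_class == "coherent"]), 1:4)
  expect_equal(sort(out$subtype[out$sign_class == "incoherent"]), 1:4)
  # the canonical all-activation loop is coherent type 1
  c1 <- out[out$s1 == 1 & out$s2 == 1 & out$s3 == 1, ]
  expect_equal(c1$sign_class, "coherent")
  expect_equal(c1$subtype, 1L)
})

test_that("FBL polarity is the cycle sign product on all 8 patterns", {
  patterns <- expand.grid(s1 = c(-1L, 1L), s2 = c(-1L, 1L),
                          s3 = c(-1L, 1L))
  m <- tibble::tibble(kind = "FBL3", m1 = "A", m2 = "B", m3 = "C",
                      s1 = patterns$s1, s2 = patterns$s2, s3 = patterns$s3,
                      mech1 = "transcriptional", mech2 = "transcriptional",
                      mech3 = "transcriptional",
                      sign_class = NA_character_, subtype = NA_integer_)
  out <- classify_fbl(m)
  expect_equal(out$sign_class,
               ifelse(patterns$s1 * patterns$s2 * patterns$s3 > 0,
                      "positive", "negative"))
  # double repression closed by activation is positive
  expect_equal(out$sign_class[out$s1 == -1 & out$s2 == -1 & out$s3 == 1],
               "positive")
  # two-node loops
  m2 <- tibble::tibble(kind = "FBL2", m1 = "A", m2 = "B", m3 = NA,
                       s1 = c(1L, -1L), s2 = c(-1L, -1L), s3 = NA_integer_,
                       mech1 = "transcriptional", mech2 = "transcriptional",
                       mech3 = NA_character_,
                       sign_class = NA_character_, subtype = NA_integer_)
  out2 <- classify_fbl(m2)
  expect_equal(out2$sign_class, c("negative", "positive"))
  expect_equal(nrow(classify_fbl(m2[0, ])), 0)  # empty passthrough
  expect_error(classify_ffl(m2), "FFL")
  expect_error(classify_fbl(dplyr::mutate(m2, kind = "FFL")), "FBL")
})

test_that("flipping every edge sign flips odd-cycle polarity and coherence",
{
  for (seed in 1:3) {
    net <- random_test_network(seed, max_nodes = 20)
    flipped <- net
    flipped$edges$sign <- -flipped$edges$sign
    # re-validate since miRNA edges are sign-flipped too; bypass the
    # class-constraint by comparing classifications only
    f1 <- enumerate_ffls(net)
    f2 <- classify_ffl(within_signs_flipped(f1))
    if (nrow(f1)) {
      expect_equal(f2$sign_class,
                   ifelse(f1$sign_class == "coherent", "incoherent",
                          "coherent"))
    }
    b1 <- enumerate_fbls(net, 3)
    if (nrow(b1)) {
      b2 <- classify_fbl(within_signs_flipped(b1))
      odd <- b1$kind == "FBL3"
      expect_equal(b2$sign_class[odd],
                   ifelse(b1$sign_class[odd] == "positive", "negative",
                          "positive"))
      expect_equal(b2$sign_class[!odd], b1$sign_class[!odd])
    }
  }
})

test_that("two-node mutual repression is a single positive FBL2", {
  net <- reg_network(
    nodes = data.frame(symbol = c("A", "B"), node_class = "TF"),
    edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                       sign = -1, mechanism = "transcriptional"))
  fbl <- enumerate_fbls(net, 2)
  expect_equal(nrow(fbl), 1)
  expect_equal(fbl$kind, "FBL2")
  expect_equal(fbl$sign_class, "positive")
  # max_len = 2 excludes 3-cycles
  tri <- fixture_melanoma_circuits()
  expect_equal(nrow(enumerate_fbls(tri, 2)), 0)
})

test_that("parallel mechanism arms yield distinct motif instances", {
  net2 <- reg_network(
    nodes = data.frame(symbol = c("TFX", "B", "C"),
                       node_class = c("TF", "TF", "PCG")),
    edges = data.frame(
      source = c("TFX", "TFX", "B", "TFX"),
      target = c("B", "B", "C", "C"),
      sign = c(1, 1, 1, 1),
      mechanism = c("transcriptional", "post_transcriptional",
                    "transcriptional", "transcriptional")))
  ffl <- enumerate_ffls(net2)
  expect_equal(nrow(ffl), 2)
  expect_setequal(ffl$mech1, c("transcriptional", "post_transcriptional"))
})

test_that("enumeration equals the exhaustive oracle on random networks", {
  for (seed in 1:8) {
    net <- random_test_network(seed, max_nodes = 30)
    oracle <- oracle_motifs(net)
    expect_equal(motif_strings(enumerate_ffls(net)), oracle$ffl)
    fbl <- enumerate_fbls(net, 3)
    expect_equal(motif_strings(fbl[fbl$kind == "FBL2", ]), oracle$fbl2)
    expect_equal(motif_strings(fbl[fbl$kind == "FBL3", ]), oracle$fbl3)
  }
})

test_that("enumeration is deterministic and filters are sound", {
  net <- random_test_network(11, max_nodes = 30)
  a <- enumerate_ffls(net)
  b <- enumerate_ffls(net)
  expect_identical(a, b)
  expect_error(enumerate_ffls(net, require_member = "ZZZ"), "not present")

  cls <- setNames(net$nodes$node_class, net$nodes$symbol)
  member <- net$nodes$symbol[which.max(degree_summary(net)$total_degree)]
  member <- degree_summary(net)$symbol[1]
  f <- enumerate_ffls(net, require_member = member, require_mirna = TRUE)
  if (nrow(f)) {
    expect_true(all(f$m1 == member | f$m2 == member | f$m3 == member))
    expect_true(all(cls[f$m1] == "MIRNA" | cls[f$m2] == "MIRNA" |
                      cls[f$m3] == "MIRNA"))
  }
})

test_that("the census matches enumeration counts and writes TSV", {
  net <- fixture_melanoma_circuits()
  census <- motif_census(net)
  expect_equal(census$n[census$kind == "FFL" &
                          census$sign_class == "coherent"], 1L)
  expect_equal(census$n[census$kind == "FBL3" &
                          census$sign_class == "positive"], 1L)
  f <- tempfile(fileext = ".tsv")
  write_motif_table(census, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(census))
})
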