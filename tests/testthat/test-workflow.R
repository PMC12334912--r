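build_workflow_inputs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mel <- file.path(dir, "melanoma.tsv")
  write_network(fixture_melanoma_circuits(), mel, "tsv")
  astro <- file.path(dir, "astro.tsv")
  write_network(generate_random_network(3, 1, 2, edge_prob = 0.4, seed = 2,
                                        name = "astrocyte"), astro, "tsv")
  targets <- file.path(dir, "targets.tsv")
  readr::write_tsv(tibble::tibble(miRNA = "miR-155",
                                  target_gene = "SOX10",
                                  evidence = "reporter_assay"), targets)
  tfs <- file.path(dir, "tfs.txt")
  writeLines(c("SOX10", "MITF", "ATF2", "# comment"), tfs)
  list(
    out_dir = file.path(dir, "out"), seed = 11L, log_level = "quiet",
    networks = list(list(path = mel, label = "melanoma"),
                    list(path = astro, label = "astrocyte")),
    focal = "SOX10", radius = 1L,
    mirna_targets = targets, tf_list = tfs)
}

test_that("the build-network command runs the full assembly chain", {
  cfg <- build_workflow_inputs(withr::local_tempdir())
  res <- run_build_network(cfg)
  net <- res$network
  expect_equal(nrow(net$nodes), 5)  # the SOX10-centered fixture circuit
  expect_setequal(net$nodes$symbol,
                  c("SOX10", "MITF", "ATF2", "MIR155", "MIR204"))
  expect_true(file.exists(res$paths$graphml))
  expect_true(file.exists(res$paths$degrees))
  manifest <- jsonlite::read_json(file.path(cfg$out_dir, "manifest.json"))
  expect_equal(manifest$seed, 11L)

  # reruns are byte-identical
  first <- readLines(res$paths$tsv)
  res2 <- run_build_network(cfg)
  expect_identical(readLines(res2$paths$tsv), first)
})

test_that("a missing focal gene raises a user-input error", {
  cfg <- build_workflow_inputs(withr::local_tempdir())
  cfg$focal <- "NOSUCHGENE"
  expect_error(run_build_network(cfg), "NOSUCHGENE",
               class = "mirloops_user_error")
})

test_that("the find-motifs command reproduces planted ground truth", {
  dir <- withr::local_tempdir()
  pm <- plant_motifs(reg_network(), k_coherent_ffl = 2,
                     k_incoherent_ffl = 1, k_positive_fbl3 = 1, seed = 4)
  netfile <- file.path(dir, "planted.tsv")
  write_network(pm$network, netfile, "tsv")
  res <- run_find_motifs(list(out_dir = file.path(dir, "out"),
                              network = netfile, log_level = "quiet"))
  expect_equal(motif_strings(res$motifs), motif_strings(pm$ground_truth))
  expect_true(file.exists(res$paths$census))

  # fixture network census through the same command
  netfile2 <- file.path(dir, "mel.tsv")
  write_network(fixture_melanoma_circuits(), netfile2, "tsv")
  res2 <- run_find_motifs(list(out_dir = file.path(dir, "out2"),
                               network = netfile2,
                               require_member = "SOX10",
                               require_mirna = TRUE, log_level = "quiet"))
  expect_equal(sum(res2$census$n), 2)
})

test_that("simulate scenarios write summaries and honour overrides", {
  dir <- withr::local_tempdir()
  res <- run_simulate(list(out_dir = dir, log_level = "quiet",
                           params = list(n_grid = 51)),
                      "input_functions")
  expect_equal(res$summary$sigmoidal_midpoint, 0.5)
  js <- jsonlite::read_json(file.path(dir, "input_functions_summary.json"))
  expect_equal(js$saturated_initial_sensitivity, 2)
  curves <- readr::read_tsv(res$paths$curves, show_col_types = FALSE)
  expect_equal(nrow(curves), 3 * 51)
  expect_error(run_simulate(list(out_dir = dir), "no_such_scenario"))
})
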