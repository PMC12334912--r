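#' Generate a random typed regulatory network
#'
#' Draws a directed network over `n_tf` TF, `n_mirna` miRNA and `n_pcg`
#' protein-coding-gene nodes. Only TFs and miRNAs regulate (PCGs are
#' sinks); each allowed ordered pair receives an edge independently with
#' probability `edge_prob`; TF edges are transcriptional with sign +1 with
#' probability `p_activation`, miRNA edges are always post-transcriptional
#' repressions (sign -1). Self-loops are never drawn. Deterministic for a
#' fixed seed.
#'
#' @param n_tf,n_mirna,n_pcg Node counts per class.
#' @param edge_prob Edge probability in `[0, 1]`.
#' @param p_activation Probability that a TF edge activates.
#' @param seed RNG seed (required for reproducibility).
#' @param name Network name.
#' @return A `reg_network`.
#' @export
generate_random_network <- function(n_tf, n_mirna, n_pcg, edge_prob = 0.1,
                                    p_activation = 0.6, seed,
                                    name = "synthetic") {
  stopifnot(n_tf >= 0, n_mirna >= 0, n_pcg >= 0,
            edge_prob >= 0, edge_prob <= 1,
            p_activation >= 0, p_activation <= 1)
  withr::local_seed(seed)
  nodes <- tibble::tibble(
    symbol = c(sprintf("TF%d", seq_len(n_tf)),
               sprintf("MIR%d", seq_len(n_mirna)),
               sprintf("PCG%d", seq_len(n_pcg))),
    node_class = rep(c("TF", "MIRNA", "PCG"), c(n_tf, n_mirna, n_pcg)))
  regulators <- nodes$symbol[nodes$node_class != "PCG"]
  pairs <- expand.grid(source = regulators, target = nodes$symbol,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  # fixed iteration order so the draw is reproducible
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  keep <- runif(nrow(pairs)) < edge_prob
  pairs <- pairs[keep, , drop = FALSE]
  edges <- NULL
  if (nrow(pairs)) {
    mir_src <- startsWith(pairs$source, "MIR")
    sign <- ifelse(mir_src, -1L,
                   ifelse(runif(nrow(pairs)) < p_activation, 1L, -1L))
    edges <- tibble::tibble(
      source = pairs$source, target = pairs$target, sign = sign,
      mechanism = ifelse(mir_src, "post_transcriptional", "transcriptional"),
      provenance = replicate(nrow(pairs), name, simplify = FALSE),
      evidence = "")
  }
  reg_network(nodes = nodes, edges = edges, name = name)
}

#' Plant feedforward/feedback motifs with known ground truth
#'
#' Adds fresh nodes and edges realizing the requested counts of coherent
#' and incoherent feedforward loops and positive and negative three-node
#' feedback loops. Planted motifs use TF regulators/intermediates and PCG
#' targets (FFLs) or all-TF cycles (FBLs) on nodes disjoint from the
#' existing network, so planting itself cannot create cross-motifs. With
#' `collision_free = TRUE` the emitted network is verified by an
#' independent brute-force census to contain exactly the planted motif
#' counts (re-drawn up to `max_retries` times, e.g. when the base network
#' already contains motifs of its own; a capacity error is raised
#' otherwise).
#'
#' @param net Base `reg_network` to plant into.
#' @param k_coherent_ffl,k_incoherent_ffl Numbers of FFLs to plant.
#' @param k_positive_fbl3,k_negative_fbl3 Numbers of 3-node FBLs to plant.
#' @param seed RNG seed.
#' @param collision_free Verify the total census equals the planted counts.
#' @param max_retries Redraw budget for `collision_free`.
#' @return A list with `network` (the augmented `reg_network`) and
#'   `ground_truth` (tibble of planted instances in the motif-table
#'   layout, plus generator parameters in the `params` attribute).
#' @export
plant_motifs <- function(net, k_coherent_ffl = 0, k_incoherent_ffl = 0,
                         k_positive_fbl3 = 0, k_negative_fbl3 = 0,
                         seed, collision_free = TRUE, max_retries = 1000) {
  stopifnot(inherits(net, "reg_network"))
  withr::local_seed(seed)

  draw <- function(attempt) {
    prefix <- sprintf("PL%d", attempt)
    truth <- list(); nodes <- list(); edges <- list()
    idx <- 0
    add_node <- function(sym, cls) {
      nodes[[length(nodes) + 1]] <<- tibble::tibble(
        symbol = sym, node_class = cls)
    }
    add_edge <- function(src, tgt, sgn) {
      edges[[length(edges) + 1]] <<- tibble::tibble(
        source = src, target = tgt, sign = as.integer(sgn),
        mechanism = "transcriptional",
        provenance = list("planted"), evidence = "")
    }
    plant_ffl <- function(coherent) {
      idx <<- idx + 1
      ms <- sprintf("%sF%d%s", prefix, idx, c("A", "B", "C"))
      add_node(ms[1], "TF"); add_node(ms[2], "TF"); add_node(ms[3], "PCG")
      s1 <- sample(c(-1L, 1L), 1); s2 <- sample(c(-1L, 1L), 1)
      s3 <- if (coherent) s1 * s2 else -s1 * s2
      add_edge(ms[1], ms[2], s1); add_edge(ms[2], ms[3], s2)
      add_edge(ms[1], ms[3], s3)
      cl <- ffl_sign_class(s1, s2, s3)
      truth[[length(truth) + 1]] <<- tibble::tibble(
        kind = "FFL", m1 = ms[1], m2 = ms[2], m3 = ms[3],
        s1 = s1, s2 = s2, s3 = s3,
        mech1 = "transcriptional", mech2 = "transcriptional",
        mech3 = "transcriptional",
        sign_class = cl$sign_class, subtype = cl$subtype)
    }
    plant_fbl <- function(positive) {
      idx <<- idx + 1
      ms <- sprintf("%sB%d%s", prefix, idx, c("A", "B", "C"))
      for (m in ms) add_node(m, "TF")
      s1 <- sample(c(-1L, 1L), 1); s2 <- sample(c(-1L, 1L), 1)
      s3 <- if (positive) s1 * s2 else -s1 * s2  # product = s1*s2*s3
      add_edge(ms[1], ms[2], s1); add_edge(ms[2], ms[3], s2)
      add_edge(ms[3], ms[1], s3)
      truth[[length(truth) + 1]] <<- tibble::tibble(
        kind = "FBL3", m1 = ms[1], m2 = ms[2], m3 = ms[3],
        s1 = s1, s2 = s2, s3 = s3,
        mech1 = "transcriptional", mech2 = "transcriptional",
        mech3 = "transcriptional",
        sign_class = fbl_sign_class(s1 * s2 * s3), subtype = NA_integer_)
    }
    for (i in seq_len(k_coherent_ffl)) plant_ffl(TRUE)
    for (i in seq_len(k_incoherent_ffl)) plant_ffl(FALSE)
    for (i in seq_len(k_positive_fbl3)) plant_fbl(TRUE)
    for (i in seq_len(k_negative_fbl3)) plant_fbl(FALSE)
    list(nodes = dplyr::bind_rows(nodes), edges = dplyr::bind_rows(edges),
         truth = dplyr::bind_rows(truth))
  }

  target_counts <- c(ffl = k_coherent_ffl + k_incoherent_ffl,
                     fbl3 = k_positive_fbl3 + k_negative_fbl3)
  for (attempt in seq_len(max_retries)) {
    d <- draw(attempt)
    if (!nrow(d$nodes)) {
      return(list(network = net, ground_truth = empty_motif_table()))
    }
    nodes <- dplyr::bind_rows(
      net$nodes, dplyr::mutate(d$nodes, origins = list("planted")))
    edges <- dplyr::bind_rows(net$edges, d$edges)
    out <- validate_reg_network(
      structure(list(nodes = nodes, edges = edges, name = net$name),
                class = "reg_network"))
    if (!collision_free) {
      gt <- canonicalize_truth(d$truth)
      attr(gt, "params") <- list(seed = seed, attempt = attempt)
      return(list(network = out, ground_truth = gt))
    }
    census <- brute_force_census(out)
    if (census["ffl"] == target_counts["ffl"] &&
        census["fbl3"] == target_counts["fbl3"] &&
        census["fbl2"] == 0) {
      gt <- canonicalize_truth(d$truth)
      attr(gt, "params") <- list(seed = seed, attempt = attempt)
      return(list(network = out, ground_truth = gt))
    }
  }
  stop("could not plant motifs collision-free within ", max_retries,
       " attempts; the base network already contains motifs", call. = FALSE)
}

canonicalize_truth <- function(truth) {
  if (!nrow(truth)) return(empty_motif_table())
  # rotate FBL3 cycles so the lexicographically smallest member leads,
  # matching the enumerator's canonical form
  rot <- function(row) {
    if (row$kind != "FBL3") return(row)
    ms <- c(row$m1, row$m2, row$m3); ss <- c(row$s1, row$s2, row$s3)
    k <- which(ms == min(ms))[1]
    ord <- ((seq_len(3) + k - 2) %% 3) + 1
    row$m1 <- ms[ord[1]]; row$m2 <- ms[ord[2]]; row$m3 <- ms[ord[3]]
    row$s1 <- ss[ord[1]]; row$s2 <- ss[ord[2]]; row$s3 <- ss[ord[3]]
    row
  }
  out <- purrr::map_dfr(seq_len(nrow(truth)), ~ rot(truth[.x, ]))
  order_motifs(out)
}

# Independent brute-force motif census over sign/multiplicity matrices;
# deliberately not sharing code with the enumerators so it can vouch for
# them.
brute_force_census <- function(net) {
  syms <- net$nodes$symbol
  n <- length(syms)
  P <- matrix(0, n, n, dimnames = list(syms, syms))
  N <- P
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    if (e$sign[i] > 0) P[e$source[i], e$target[i]] <-
        P[e$source[i], e$target[i]] + 1
    else N[e$source[i], e$target[i]] <- N[e$source[i], e$target[i]] + 1
  }
  M <- P + N
  ffl <- sum((M %*% M) * M)
  fbl3 <- sum(diag(M %*% M %*% M)) / 3
  fbl2 <- sum(M * t(M)) / 2
  coh <- sum((P %*% P) * P + (N %*% N) * P +
               (P %*% N) * N + (N %*% P) * N)
  pos3 <- (sum(diag(P %*% P %*% P)) +
             sum(diag(P %*% N %*% N)) + sum(diag(N %*% P %*% N)) +
             sum(diag(N %*% N %*% P))) / 3
  pos2 <- (sum(P * t(P)) + sum(N * t(N))) / 2
  c(ffl = ffl, ffl_coherent = coh, fbl3 = fbl3, fbl3_positive = pos3,
    fbl2 = fbl2, fbl2_positive = pos2)
}

#' Five-node fixture containing the two named melanoma circuits
#'
#' The canonical miR-155--SOX10--MITF coherent feedforward loop
#' (miR-155 represses SOX10 and MITF; SOX10 activates MITF) and the
#' miR-204--SOX10--ATF2 positive feedback loop (miR-204 represses ATF2,
#' ATF2 represses SOX10, SOX10 activates miR-204 transcription), sharing
#' SOX10.
#'
#' @return A `reg_network` with nodes SOX10, MITF, ATF2 (TF), MIR155,
#'   MIR204 (miRNA) and six edges.
#' @export
fixture_melanoma_circuits <- function() {
  reg_network(
    nodes = tibble::tibble(
      symbol = c("SOX10", "MITF", "ATF2", "MIR155", "MIR204"),
      node_class = c("TF", "TF", "TF", "MIRNA", "MIRNA")),
    edges = tibble::tibble(
      source = c("MIR155", "MIR155", "SOX10", "MIR204", "ATF2", "SOX10"),
      target = c("SOX10", "MITF", "MITF", "ATF2", "SOX10", "MIR204"),
      sign = c(-1, -1, 1, -1, -1, 1),
      mechanism = c("post_transcriptional", "post_transcriptional",
                    "transcriptional", "post_transcriptional",
                    "transcriptional", "transcriptional")),
    name = "melanoma_circuits")
}

#' Generate a synthetic miRNA-target interaction table
#'
#' Emits records in the miRTarBase-like layout (`miRNA`, `target_gene`,
#' `evidence`) with evidence tags drawn from a small fixed vocabulary, for
#' exercising integration and deduplication logic. Deterministic for a
#' fixed seed.
#'
#' @param mirnas Character vector of miRNA symbols.
#' @param targets_per_mirna Targets drawn for each miRNA.
#' @param target_pool Pool of target gene symbols (defaults to generic
#'   gene names `G1..G50`).
#' @param seed RNG seed.
#' @param path Optional file; when given the table is also written as TSV.
#' @return A tibble (invisibly also written to `path` if given).
#' @export
generate_mirna_target_table <- function(mirnas, targets_per_mirna, seed,
                                        target_pool = sprintf("G%d", 1:50),
                                        path = NULL) {
  withr::local_seed(seed)
  vocab <- c("reporter_assay", "western_blot", "qPCR")
  rows <- purrr::map_dfr(mirnas, function(m) {
    tibble::tibble(
      miRNA = m,
      target_gene = sample(target_pool, targets_per_mirna,
                           replace = FALSE),
      evidence = sample(vocab, targets_per_mirna, replace = TRUE))
  })
  if (!nrow(rows))
    rows <- tibble::tibble(miRNA = character(), target_gene = character(),
                           evidence = character())
  if (!is.null(path)) readr::write_tsv(rows, path)
  rows
}
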