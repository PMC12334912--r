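#' Construct a signed, typed regulatory network
#'
#' A `reg_network` bundles a node table and a signed, mechanism-tagged edge
#' table describing transcriptional (TF on DNA) and post-transcriptional
#' (miRNA on mRNA) regulation. Nodes are typed as transcription factors
#' (`"TF"`), microRNAs (`"MIRNA"`) or other protein-coding genes (`"PCG"`)
#' and carry a set of provenance labels (`origins`) recording which source
#' networks (e.g. melanoma, astrocyte, pluripotency, oligodendrocyte) they
#' came from.
#'
#' Symbols are normalized on construction: gene symbols are uppercased
#' HGNC-style; miRNA names written in any of the common styles
#' (`"miR-155"`, `"miR-155-5p"`, `"hsa-miR-155"`, `"MIR155"`) collapse to a
#' single canonical `"MIR155"` node so that mixed-style inputs cannot split
#' one regulator across several nodes.
#'
#' @param nodes Data frame with columns `symbol`, `node_class` (one of
#'   `"TF"`, `"MIRNA"`, `"PCG"`) and optionally `origins` (list column of
#'   character vectors, or a character column). Missing `origins` default to
#'   the network `name`.
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (+1/-1), `mechanism` (`"transcriptional"` or `"post_transcriptional"`),
#'   and optionally `provenance` (list or character column) and `evidence`
#'   (character). Duplicate `(source, target, mechanism)` rows are collapsed
#'   with provenance union and evidence concatenation.
#' @param name Label for the network.
#' @param allow_self_loops Keep self-regulating edges? Default `FALSE`
#'   (rows with `source == target` raise an error).
#' @return An object of class `reg_network`: a list with tibbles `nodes`
#'   and `edges` and the `name`.
#' @examples
#' net <- reg_network(
#'   nodes = data.frame(symbol = c("miR-155", "SOX10", "MITF"),
#'                      node_class = c("MIRNA", "TF", "TF")),
#'   edges = data.frame(source = c("miR-155", "miR-155", "SOX10"),
#'                      target = c("SOX10", "MITF", "MITF"),
#'                      sign = c(-1, -1, 1),
#'                      mechanism = c("post_transcriptional",
#'                                    "post_transcriptional",
#'                                    "transcriptional")))
#' net
#' @export
reg_network <- function(nodes = NULL, edges = NULL, name = "network",
                        allow_self_loops = FALSE) {
  nodes <- as_node_tibble(nodes, default_origin = name)
  edges <- as_edge_tibble(edges, default_provenance = name)

  nodes$symbol <- normalize_symbol(nodes$symbol)
  if (nrow(edges)) {
    edges$source <- normalize_symbol(edges$source)
    edges$target <- normalize_symbol(edges$target)
  }

  # collapse duplicate symbols (e.g. "miR-155" and "MIR155" rows)
  if (anyDuplicated(nodes$symbol)) {
    nodes <- nodes |>
      dplyr::group_by(.data$symbol) |>
      dplyr::summarise(
        node_class = resolve_node_class(unique(.data$node_class)),
        origins = list(sort(unique(unlist(.data$origins)))),
        .groups = "drop"
      )
  }
  edges <- collapse_duplicate_edges(edges)

  net <- structure(
    list(nodes = nodes, edges = edges, name = name),
    class = "reg_network"
  )
  validate_reg_network(net, allow_self_loops = allow_self_loops)
}

#' @export
print.reg_network <- function(x, ...) {
  cls <- table(factor(x$nodes$node_class, levels = node_classes()))
  cat(sprintf("<reg_network> '%s': %d nodes (%s), %d edges\n",
              x$name, nrow(x$nodes),
              paste(sprintf("%s %d", names(cls), cls), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

node_classes <- function() c("TF", "MIRNA", "PCG")
mechanisms   <- function() c("transcriptional", "post_transcriptional")

as_node_tibble <- function(nodes, default_origin) {
  if (is.null(nodes) || !nrow(as.data.frame(nodes))) {
    return(tibble::tibble(symbol = character(), node_class = character(),
                          origins = list()))
  }
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("symbol", "node_class") %in% names(nodes)))
  if (!"origins" %in% names(nodes)) {
    nodes$origins <- replicate(nrow(nodes), default_origin, simplify = FALSE)
  } else if (!is.list(nodes$origins)) {
    nodes$origins <- as.list(as.character(nodes$origins))
  }
  nodes[c("symbol", "node_class", "origins")]
}

as_edge_tibble <- function(edges, default_provenance = "network") {
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    return(tibble::tibble(source = character(), target = character(),
                          sign = integer(), mechanism = character(),
                          provenance = list(), evidence = character()))
  }
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "target", "sign", "mechanism") %in% names(edges)))
  if (!"provenance" %in% names(edges)) {
    edges$provenance <- replicate(nrow(edges), character(), simplify = FALSE)
  } else if (!is.list(edges$provenance)) {
    edges$provenance <- as.list(as.character(edges$provenance))
  }
  edges$provenance <- purrr::map(edges$provenance, function(v) {
    v <- setdiff(v, "")
    if (length(v)) v else default_provenance
  })
  if (!"evidence" %in% names(edges)) edges$evidence <- ""
  edges$evidence[is.na(edges$evidence)] <- ""
  edges$sign <- as.integer(edges$sign)
  edges[c("source", "target", "sign", "mechanism", "provenance", "evidence")]
}

collapse_duplicate_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  key <- paste(edges$source, edges$target, edges$mechanism, sep = "\r")
  if (!anyDuplicated(key)) return(edges)
  edges |>
    dplyr::group_by(.data$source, .data$target, .data$mechanism) |>
    dplyr::summarise(
      sign = {
        s <- unique(.data$sign)
        if (length(s) > 1)
          stop("conflicting signs for edge ", .data$source[1], " -> ",
               .data$target[1], call. = FALSE)
        s
      },
      provenance = list(sort(unique(unlist(.data$provenance)))),
      evidence = paste(unique(.data$evidence[nzchar(.data$evidence)]),
                       collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::select("source", "target", "sign", "mechanism", "provenance",
                  "evidence")
}

resolve_node_class <- function(classes, report = FALSE) {
  classes <- unique(classes)
  if (length(classes) == 1) return(classes)
  # priority TF > MIRNA > PCG on conflict
  for (cl in node_classes()) if (cl %in% classes) return(cl)
  stop("unknown node_class values: ", paste(classes, collapse = ", "),
       call. = FALSE)
}

#' Normalize gene and miRNA symbols to canonical form
#'
#' Gene symbols are uppercased and trimmed. miRNA names lose the species
#' prefix (`hsa-`), hyphens and a trailing arm suffix (`-5p`/`-3p`), so
#' `"miR-155-5p"`, `"hsa-miR-155"` and `"MIR155"` all map to `"MIR155"`.
#'
#' @param x Character vector of symbols.
#' @return Character vector of canonical symbols.
#' @export
normalize_symbol <- function(x) {
  x <- trimws(as.character(x))
  up <- toupper(x)
  mir <- grepl("^(HSA[-_]?)?MIR[-_]?[0-9]", up)
  up[mir] <- sub("^HSA[-_]?", "", up[mir])
  up[mir] <- sub("[-_]?[53]P$", "", up[mir])
  up[mir] <- gsub("[-_]", "", up[mir])
  up
}

is_mirna_symbol <- function(x) {
  grepl("^(HSA[-_]?)?MIR[-_]?[0-9]", toupper(trimws(x)))
}

validate_reg_network <- function(net, allow_self_loops = FALSE) {
  nodes <- net$nodes; edges <- net$edges
  if (anyDuplicated(nodes$symbol))
    stop("duplicate node symbols after normalization: ",
         paste(unique(nodes$symbol[duplicated(nodes$symbol)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(nodes$symbol)))
    stop("empty node symbol", call. = FALSE)
  bad_class <- setdiff(unique(nodes$node_class), node_classes())
  if (length(bad_class))
    stop("invalid node_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  if (nrow(edges)) {
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge sign must be +1 or -1", call. = FALSE)
    bad_mech <- setdiff(unique(edges$mechanism), mechanisms())
    if (length(bad_mech))
      stop("invalid mechanism: ", paste(bad_mech, collapse = ", "),
           call. = FALSE)
    missing_ep <- setdiff(c(edges$source, edges$target), nodes$symbol)
    if (length(missing_ep))
      stop("edge endpoint(s) not in node table: ",
           paste(missing_ep, collapse = ", "), call. = FALSE)
    if (!allow_self_loops && any(edges$source == edges$target))
      stop("self-loops not allowed: ",
           paste(unique(edges$source[edges$source == edges$target]),
                 collapse = ", "), call. = FALSE)
    key <- paste(edges$source, edges$target, edges$mechanism)
    if (anyDuplicated(key))
      stop("duplicate (source, target, mechanism) edges", call. = FALSE)
    cls <- stats::setNames(nodes$node_class, nodes$symbol)
    mirna_src <- cls[edges$source] == "MIRNA"
    if (any(mirna_src & edges$mechanism != "post_transcriptional"))
      stop("miRNA-source edges must be post_transcriptional", call. = FALSE)
  }
  net
}

node_class_of <- function(net, symbols) {
  stats::setNames(net$nodes$node_class, net$nodes$symbol)[symbols]
}

#' Merge several regulatory networks into one multi-origin network
#'
#' Performs the network-assembly union step: nodes and edges are unioned;
#' each node's `origins` becomes the union of its existing origins and the
#' labels of the input networks that contain it (the basis of the
#' origin-ring summary, where a node's border width encodes how many source
#' networks it belongs to). Node-class conflicts between inputs are resolved
#' by priority TF > MIRNA > PCG with a message.
#'
#' @param nets List of `reg_network` objects.
#' @param labels Character vector of provenance labels, one per network.
#'   Defaults to each network's `name`.
#' @param name Name of the merged network.
#' @return A `reg_network`.
#' @export
merge_networks <- function(nets, labels = NULL, name = "merged") {
  stopifnot(length(nets) >= 1, all(vapply(nets, inherits, TRUE, "reg_network")))
  if (is.null(labels)) labels <- vapply(nets, `[[`, "", "name")
  stopifnot(length(labels) == length(nets))

  node_rows <- purrr::map2(nets, labels, function(n, lab) {
    dplyr::mutate(n$nodes,
                  origins = purrr::map(.data$origins, ~ union(.x, lab)))
  })
  nodes <- dplyr::bind_rows(node_rows)
  conflicted <- nodes |>
    dplyr::distinct(.data$symbol, .data$node_class) |>
    dplyr::count(.data$symbol) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicted))
    message("node_class conflicts resolved by priority TF > MIRNA > PCG: ",
            paste(conflicted$symbol, collapse = ", "))
  nodes <- nodes |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(
      node_class = resolve_node_class(unique(.data$node_class)),
      origins = list(sort(unique(unlist(.data$origins)))),
      .groups = "drop"
    )

  edges <- dplyr::bind_rows(purrr::map2(nets, labels, function(n, lab) {
    dplyr::mutate(n$edges,
                  provenance = purrr::map(.data$provenance, ~ union(.x, lab)))
  }))
  edges <- collapse_duplicate_edges(edges)

  validate_reg_network(
    structure(list(nodes = nodes, edges = edges, name = name),
              class = "reg_network"))
}

#' Extract the focal (ego) subnetwork around a gene
#'
#' Returns the subnetwork induced by all nodes within `radius` hops of the
#' focal gene, following edges in either direction, keeping *all* edges
#' among the retained nodes (induced subgraph). With `radius = 1` this is
#' the focal gene plus its direct regulators and targets -- the extraction
#' step that produces a SOX10-centered network from the full assembly.
#' Edges between the focal gene's neighbours are retained because
#' downstream motif search needs them.
#'
#' @param net A `reg_network`.
#' @param focal Gene symbol (normalized internally).
#' @param radius Non-negative integer hop count; `0` returns the focal node
#'   alone.
#' @return A `reg_network`.
#' @export
extract_focal_subnetwork <- function(net, focal, radius = 1L) {
  stopifnot(inherits(net, "reg_network"), radius >= 0)
  focal <- normalize_symbol(focal)
  if (!focal %in% net$nodes$symbol)
    stop("focal gene '", focal, "' not present in network", call. = FALSE)
  keep <- focal
  frontier <- focal
  r <- 0L
  while (r < radius && length(frontier)) {
    nb <- c(net$edges$target[net$edges$source %in% frontier],
            net$edges$source[net$edges$target %in% frontier])
    frontier <- setdiff(unique(nb), keep)
    keep <- union(keep, frontier)
    r <- r + 1L
  }
  induced_subnetwork(net, keep, name = paste0(net$name, ":", focal))
}

induced_subnetwork <- function(net, symbols, name = net$name) {
  nodes <- dplyr::filter(net$nodes, .data$symbol %in% symbols)
  edges <- dplyr::filter(net$edges,
                         .data$source %in% symbols & .data$target %in% symbols)
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "reg_network")
}

#' Integrate experimentally validated miRNA-target interactions
#'
#' Expands a network with miRNA-target records in a miRTarBase-like layout
#' (columns `miRNA`, `target_gene`, `evidence`, optional `sign`). Each
#' record adds a post-transcriptional edge with sign -1 (canonical
#' repression) from the miRNA to the target, creating the miRNA node when
#' absent. A per-record `sign` override is honoured with a warning, since
#' non-canonical (e.g. 5'-UTR) binding can activate.
#'
#' @param net A `reg_network`.
#' @param table Data frame of records with columns `miRNA`, `target_gene`,
#'   `evidence` (optional `sign`).
#' @param restrict_to_existing Only add records whose target gene is
#'   already in the network (default `TRUE`, matching expansion of an
#'   existing ego network); skipped records are reported in the
#'   `"n_skipped"` attribute of the result.
#' @param provenance Provenance label for the added edges.
#' @return A `reg_network` with attribute `n_skipped`.
#' @export
integrate_mirna_targets <- function(net, table, restrict_to_existing = TRUE,
                                    provenance = "mirna_target_db") {
  stopifnot(inherits(net, "reg_network"))
  table <- tibble::as_tibble(table)
  stopifnot(all(c("miRNA", "target_gene") %in% names(table)))
  if (!"evidence" %in% names(table)) table$evidence <- ""
  if (nrow(table) &&
      (any(is.na(table$miRNA) | !nzchar(trimws(table$miRNA))) ||
       any(is.na(table$target_gene) | !nzchar(trimws(table$target_gene)))))
    stop("miRNA-target record with empty miRNA or target field",
         call. = FALSE)

  table$miRNA <- normalize_symbol(table$miRNA)
  table$target_gene <- normalize_symbol(table$target_gene)
  if ("sign" %in% names(table)) {
    if (any(table$sign != -1))
      warning("non-repressive miRNA-target sign override accepted for ",
              sum(table$sign != -1), " record(s)", call. = FALSE)
  } else {
    table$sign <- -1L
  }

  n_skipped <- 0L
  if (restrict_to_existing) {
    keep <- table$target_gene %in% net$nodes$symbol
    n_skipped <- sum(!keep)
    table <- table[keep, ]
  }

  new_mirnas <- setdiff(unique(table$miRNA), net$nodes$symbol)
  nodes <- dplyr::bind_rows(
    net$nodes,
    tibble::tibble(symbol = new_mirnas, node_class = "MIRNA",
                   origins = replicate(length(new_mirnas), provenance,
                                       simplify = FALSE)))
  new_edges <- tibble::tibble(
    source = table$miRNA, target = table$target_gene,
    sign = as.integer(table$sign), mechanism = "post_transcriptional",
    provenance = replicate(nrow(table), provenance, simplify = FALSE),
    evidence = as.character(table$evidence))
  edges <- collapse_duplicate_edges(dplyr::bind_rows(net$edges, new_edges))

  out <- validate_reg_network(
    structure(list(nodes = nodes, edges = edges, name = net$name),
              class = "reg_network"))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Annotate network nodes with a known-TF list
#'
#' Reclassifies every non-miRNA node whose symbol is in `tf_symbols` as
#' `"TF"`; all other non-miRNA nodes become `"PCG"`. miRNA nodes are never
#' reclassified (a warning is issued if the TF list names one).
#'
#' @param net A `reg_network`.
#' @param tf_symbols Character vector of known TF symbols.
#' @return A `reg_network`.
#' @export
annotate_tfs <- function(net, tf_symbols) {
  stopifnot(inherits(net, "reg_network"))
  tf_symbols <- normalize_symbol(tf_symbols)
  nodes <- net$nodes
  mirna <- nodes$node_class == "MIRNA"
  clash <- intersect(tf_symbols, nodes$symbol[mirna])
  if (length(clash))
    warning("TF list names miRNA node(s), left unchanged: ",
            paste(clash, collapse = ", "), call. = FALSE)
  new_class <- ifelse(nodes$symbol %in% tf_symbols, "TF", "PCG")
  changed <- !mirna & new_class != nodes$node_class
  nodes$node_class[!mirna] <- new_class[!mirna]
  message(sum(changed), " node(s) reclassified by TF annotation")
  validate_reg_network(
    structure(list(nodes = nodes, edges = net$edges, name = net$name),
              class = "reg_network"))
}

#' Per-node degree summary
#'
#' Tabulates in-, out- and total degree (count of incident edges, the
#' node-size statistic of the network diagrams) plus the number of origin
#' networks per node, sorted by decreasing total degree so the head of the
#' table is the hub report.
#'
#' @param net A `reg_network`.
#' @return A tibble with columns `symbol`, `node_class`, `in_degree`,
#'   `out_degree`, `total_degree`, `n_origins`.
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  ind <- table(factor(net$edges$target, levels = net$nodes$symbol))
  outd <- table(factor(net$edges$source, levels = net$nodes$symbol))
  tibble::tibble(
    symbol = net$nodes$symbol,
    node_class = net$nodes$node_class,
    in_degree = as.integer(ind[net$nodes$symbol]),
    out_degree = as.integer(outd[net$nodes$symbol]),
    total_degree = in_degree + out_degree,
    n_origins = lengths(net$nodes$origins)
  ) |>
    dplyr::arrange(dplyr::desc(.data$total_degree), .data$symbol)
}
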