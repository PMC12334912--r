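#' Read a regulatory network from an edge-table file
#'
#' Supported dialects:
#' \describe{
#'   \item{`"tsv"`}{Tab-separated, UTF-8, mandatory header
#'     `source target sign mechanism node_class_source node_class_target
#'     provenance` (optional `evidence`). Lines starting `#` are comments;
#'     lines starting `#%node` carry node metadata (symbol, class,
#'     `|`-joined origins) written by [write_network()] so that isolated
#'     nodes and origin sets survive a round trip.}
#'   \item{`"sif"`}{Simple interaction format
#'     `source<TAB>relation<TAB>target` with relation `activates` or
#'     `represses`. Node classes, origins, mechanisms, provenance and
#'     evidence do not fit the 3-column body, so [write_network()] adds
#'     `#%node`/`#%edge` comment lines that this reader consumes and any
#'     other SIF reader ignores; without them, classes are inferred from
#'     symbols (miRNA pattern, else PCG) and miRNA-source edges are tagged
#'     post-transcriptional.}
#'   \item{`"graphml"`}{GraphML with node attributes `node_class`/`origins`
#'     and edge attributes `sign`/`mechanism`/`provenance`/`evidence`.}
#' }
#'
#' Sign tokens accepted in TSV: `+1`, `1`, `-1`, `+`, `-`, `activates`,
#' `represses`, `activation`, `repression`.
#'
#' @param path File to read.
#' @param dialect `"tsv"`, `"sif"` or `"graphml"`; default inferred from the
#'   file extension (falling back to `"tsv"`).
#' @param name Network name; defaults to the file stem.
#' @return A `reg_network`.
#' @export
read_edge_table <- function(path, dialect = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      sif = "sif", graphml = "graphml", xml = "graphml",
                      "tsv")
  }
  dialect <- match.arg(tolower(dialect), c("tsv", "sif", "graphml"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  switch(dialect,
         tsv = read_network_tsv(path, name),
         sif = read_network_sif(path, name),
         graphml = read_network_graphml(path, name))
}

#' Write a regulatory network to file
#'
#' Inverse of [read_edge_table()]: for every dialect,
#' `read_edge_table(write_network(net, path, d), d)` reproduces `net`
#' exactly (node set, edge set, all attributes). See [read_edge_table()]
#' for how the SIF and TSV dialects carry node metadata in comment lines.
#'
#' @param net A `reg_network`.
#' @param path Output file.
#' @param dialect `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = NULL) {
  stopifnot(inherits(net, "reg_network"))
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      sif = "sif", graphml = "graphml", xml = "graphml",
                      "tsv")
  }
  dialect <- match.arg(tolower(dialect), c("tsv", "sif", "graphml"))
  switch(dialect,
         tsv = write_network_tsv(net, path),
         sif = write_network_sif(net, path),
         graphml = write_network_graphml(net, path))
  invisible(path)
}

# ---- TSV ------------------------------------------------------------------

tsv_header <- function() {
  c("source", "target", "sign", "mechanism", "node_class_source",
    "node_class_target", "provenance", "evidence")
}

parse_sign_token <- function(tok, line_no) {
  out <- dplyr::case_match(
    tolower(trimws(tok)),
    c("+1", "1", "+", "activates", "activation") ~ 1L,
    c("-1", "−1", "-", "represses", "repression") ~ -1L,
    .default = NA_integer_)
  if (anyNA(out))
    stop("unknown sign token '", tok[which(is.na(out))[1]], "' at line ",
         line_no[which(is.na(out))[1]], call. = FALSE)
  out
}

parse_node_meta <- function(lines) {
  meta <- lines[startsWith(lines, "#%node\t")]
  if (!length(meta)) return(NULL)
  parts <- strsplit(meta, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed #%node metadata line", call. = FALSE)
  tibble::tibble(
    symbol = vapply(parts, `[`, "", 2),
    node_class = vapply(parts, `[`, "", 3),
    origins = purrr::map(parts, ~ {
      o <- if (length(.x) >= 4) .x[4] else ""
      if (nzchar(o)) strsplit(o, "|", fixed = TRUE)[[1]] else character()
    }))
}

read_network_tsv <- function(path, name) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  node_meta <- parse_node_meta(lines)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  body <- lines[keep]
  if (!length(body)) stop("no header line in ", path, call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  required <- tsv_header()[1:7]
  if (!all(required %in% header))
    stop("TSV header must contain columns: ",
         paste(setdiff(required, header), collapse = ", "), call. = FALSE)
  rows <- body[-1]; row_no <- line_no[-1]
  edges <- NULL
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    bad <- lengths(parts) < length(header) - 1L |
      lengths(parts) > length(header)
    if (any(bad))
      stop("malformed row at line ", row_no[which(bad)[1]],
           ": expected ", length(header), " tab-separated fields",
           call. = FALSE)
    get_col <- function(col) {
      i <- match(col, header)
      vapply(parts, function(p) if (i <= length(p)) p[i] else "", "")
    }
    edges <- tibble::tibble(
      source = get_col("source"),
      target = get_col("target"),
      sign = parse_sign_token(get_col("sign"), row_no),
      mechanism = get_col("mechanism"),
      provenance = purrr::map(get_col("provenance"), ~
        if (nzchar(.x)) strsplit(.x, "|", fixed = TRUE)[[1]] else character()),
      evidence = if ("evidence" %in% header) get_col("evidence") else "",
      src_class = get_col("node_class_source"),
      tgt_class = get_col("node_class_target"))
  }
  assemble_network(edges, node_meta, name)
}

assemble_network <- function(edges, node_meta, name) {
  nodes <- node_meta
  if (!is.null(edges) && nrow(edges)) {
    from_edges <- dplyr::bind_rows(
      tibble::tibble(symbol = edges$source, node_class = edges$src_class),
      tibble::tibble(symbol = edges$target, node_class = edges$tgt_class))
    from_edges$origins <- replicate(nrow(from_edges), character(),
                                    simplify = FALSE)
    nodes <- if (is.null(nodes)) from_edges else
      dplyr::bind_rows(nodes, dplyr::anti_join(
        from_edges, nodes, by = "symbol"))
    edges <- dplyr::select(edges, -"src_class", -"tgt_class")
  }
  if (is.null(nodes)) nodes <- tibble::tibble(symbol = character(),
                                              node_class = character(),
                                              origins = list())
  net <- reg_network(nodes = nodes, edges = edges, name = name)
  # origins from metadata are authoritative; empty origins fall back to name
  net$nodes$origins <- purrr::map(net$nodes$origins, ~
    if (length(.x)) setdiff(.x, character()) else name)
  net
}

write_network_tsv <- function(net, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(node_meta_lines(net), con)
  writeLines(paste(tsv_header(), collapse = "\t"), con)
  if (nrow(net$edges)) {
    cls <- setNames(net$nodes$node_class, net$nodes$symbol)
    e <- net$edges
    writeLines(paste(
      e$source, e$target, sprintf("%+d", e$sign), e$mechanism,
      cls[e$source], cls[e$target],
      vapply(e$provenance, paste, "", collapse = "|"),
      e$evidence, sep = "\t"), con)
  }
}

node_meta_lines <- function(net) {
  if (!nrow(net$nodes)) return(character())
  paste("#%node", net$nodes$symbol, net$nodes$node_class,
        vapply(net$nodes$origins, paste, "", collapse = "|"), sep = "\t")
}

# ---- SIF ------------------------------------------------------------------

read_network_sif <- function(path, name) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  node_meta <- parse_node_meta(lines)
  edge_meta <- lines[startsWith(lines, "#%edge\t")]
  edges <- NULL
  if (length(edge_meta)) {
    parts <- strsplit(edge_meta, "\t", fixed = TRUE)
    if (any(lengths(parts) < 6))
      stop("malformed #%edge metadata line", call. = FALSE)
    edges <- tibble::tibble(
      source = vapply(parts, `[`, "", 2),
      target = vapply(parts, `[`, "", 3),
      sign = as.integer(vapply(parts, `[`, "", 4)),
      mechanism = vapply(parts, `[`, "", 5),
      provenance = purrr::map(parts, ~ {
        o <- .x[6]
        if (nzchar(o)) strsplit(o, "|", fixed = TRUE)[[1]] else character()
      }),
      evidence = vapply(parts, function(p) if (length(p) >= 7) p[7] else "",
                        ""))
  } else {
    keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
    body <- lines[keep]; line_no <- which(keep)
    if (length(body)) {
      parts <- strsplit(body, "\t", fixed = TRUE)
      bad <- lengths(parts) != 3
      if (any(bad))
        stop("malformed SIF row at line ", line_no[which(bad)[1]],
             call. = FALSE)
      src <- vapply(parts, `[`, "", 1)
      rel <- vapply(parts, `[`, "", 2)
      tgt <- vapply(parts, `[`, "", 3)
      sgn <- parse_sign_token(rel, line_no)
      mech <- ifelse(is_mirna_symbol(src), "post_transcriptional",
                     "transcriptional")
      edges <- tibble::tibble(
        source = src, target = tgt, sign = sgn, mechanism = mech,
        provenance = replicate(length(src), character(), simplify = FALSE),
        evidence = "")
    }
  }
  if (!is.null(edges) && nrow(edges)) {
    guess_class <- function(sym) ifelse(is_mirna_symbol(sym), "MIRNA", "PCG")
    edges$src_class <- guess_class(edges$source)
    edges$tgt_class <- guess_class(edges$target)
  }
  assemble_network(edges, node_meta, name)
}

write_network_sif <- function(net, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(node_meta_lines(net), con)
  if (nrow(net$edges)) {
    e <- net$edges
    writeLines(paste("#%edge", e$source, e$target, sprintf("%+d", e$sign),
                     e$mechanism,
                     vapply(e$provenance, paste, "", collapse = "|"),
                     e$evidence, sep = "\t"), con)
    rel <- ifelse(e$sign > 0, "activates", "represses")
    writeLines(paste(e$source, rel, e$target, sep = "\t"), con)
  }
}

# ---- GraphML --------------------------------------------------------------

graphml_keys <- function() {
  tibble::tibble(
    id = c("d_class", "d_origins", "d_sign", "d_mech", "d_prov", "d_evid"),
    domain = c("node", "node", "edge", "edge", "edge", "edge"),
    attr_name = c("node_class", "origins", "sign", "mechanism", "provenance",
                  "evidence"),
    attr_type = c("string", "string", "int", "string", "string", "string"))
}

write_network_graphml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- graphml_keys()
  for (i in seq_len(nrow(keys))) {
    xml2::xml_add_child(doc, "key", id = keys$id[i], `for` = keys$domain[i],
                        attr.name = keys$attr_name[i],
                        attr.type = keys$attr_type[i])
  }
  g <- xml2::xml_add_child(doc, "graph", id = net$name,
                           edgedefault = "directed")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = net$nodes$symbol[i])
    xml2::xml_add_child(nd, "data", net$nodes$node_class[i], key = "d_class")
    xml2::xml_add_child(nd, "data",
                        paste(net$nodes$origins[[i]], collapse = "|"),
                        key = "d_origins")
  }
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    ed <- xml2::xml_add_child(g, "edge", source = e$source, target = e$target)
    xml2::xml_add_child(ed, "data", sprintf("%+d", e$sign), key = "d_sign")
    xml2::xml_add_child(ed, "data", e$mechanism, key = "d_mech")
    xml2::xml_add_child(ed, "data",
                        paste(e$provenance[[1]], collapse = "|"),
                        key = "d_prov")
    xml2::xml_add_child(ed, "data", e$evidence, key = "d_evid")
  }
  xml2::write_xml(doc, path)
}

read_network_graphml <- function(path, name) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  key_nodes <- xml2::xml_find_all(doc, ".//key")
  key_map <- setNames(xml2::xml_attr(key_nodes, "attr.name"),
                      xml2::xml_attr(key_nodes, "id"))
  data_attrs <- function(x) {
    d <- xml2::xml_find_all(x, "./data")
    setNames(xml2::xml_text(d), key_map[xml2::xml_attr(d, "key")])
  }
  nd <- xml2::xml_find_all(doc, ".//graph/node")
  node_meta <- NULL
  if (length(nd)) {
    attrs <- lapply(nd, data_attrs)
    node_meta <- tibble::tibble(
      symbol = xml2::xml_attr(nd, "id"),
      node_class = vapply(attrs, function(a)
        if ("node_class" %in% names(a)) a[["node_class"]] else "PCG", ""),
      origins = purrr::map(attrs, function(a) {
        o <- if ("origins" %in% names(a)) a[["origins"]] else ""
        if (nzchar(o)) strsplit(o, "|", fixed = TRUE)[[1]] else character()
      }))
  }
  ed <- xml2::xml_find_all(doc, ".//graph/edge")
  edges <- NULL
  if (length(ed)) {
    attrs <- lapply(ed, data_attrs)
    src <- xml2::xml_attr(ed, "source")
    tgt <- xml2::xml_attr(ed, "target")
    known <- if (is.null(node_meta)) character() else node_meta$symbol
    dangling <- setdiff(c(src, tgt), known)
    if (length(dangling))
      stop("GraphML edge references undeclared node(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    pick <- function(a, k, default = "") {
      if (k %in% names(a)) a[[k]] else default
    }
    edges <- tibble::tibble(
      source = src, target = tgt,
      sign = as.integer(vapply(attrs, pick, "", k = "sign", default = "1")),
      mechanism = vapply(attrs, pick, "", k = "mechanism",
                         default = "transcriptional"),
      provenance = purrr::map(attrs, function(a) {
        o <- pick(a, "provenance")
        if (nzchar(o)) strsplit(o, "|", fixed = TRUE)[[1]] else character()
      }),
      evidence = vapply(attrs, pick, "", k = "evidence"))
    cls <- setNames(node_meta$node_class, node_meta$symbol)
    edges$src_class <- unname(cls[src])
    edges$tgt_class <- unname(cls[tgt])
  }
  assemble_network(edges, node_meta, name)
}
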