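#' Tidy a regulatory network into an edge tibble
#'
#' @param x A `reg_network`.
#' @param ... Unused.
#' @return A tibble with one row per edge: `source`, `target`, `sign`,
#'   `mechanism`, `provenance` (collapsed to a `|`-joined string),
#'   `evidence`, plus the endpoint classes.
#' @export
tidy.reg_network <- function(x, ...) {
  cls <- setNames(x$nodes$node_class, x$nodes$symbol)
  e <- x$edges
  tibble::tibble(
    source = e$source, target = e$target, sign = e$sign,
    mechanism = e$mechanism,
    source_class = unname(cls[e$source]),
    target_class = unname(cls[e$target]),
    provenance = vapply(e$provenance, paste, "", collapse = "|"),
    evidence = e$evidence)
}

#' One-row summary of a regulatory network
#'
#' @param x A `reg_network`.
#' @param ... Unused.
#' @return A one-row tibble: node/edge counts overall and per class/sign.
#' @export
glance.reg_network <- function(x, ...) {
  cls <- table(factor(x$nodes$node_class, levels = node_classes()))
  tibble::tibble(
    name = x$name,
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_tf = as.integer(cls[["TF"]]), n_mirna = as.integer(cls[["MIRNA"]]),
    n_pcg = as.integer(cls[["PCG"]]),
    n_activating = sum(x$edges$sign > 0),
    n_repressing = sum(x$edges$sign < 0))
}

#' Tidy a circuit trajectory into long format
#'
#' @param x A `circuit_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `species`, `level`.
#' @export
tidy.circuit_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "species", values_to = "level")
}

#' Tidy a bifurcation diagram into its fixed-point table
#'
#' @param x A `bifurcation_diagram`.
#' @param ... Unused.
#' @return The `points` tibble (`param`, species columns, `stable`).
#' @export
tidy.bifurcation_diagram <- function(x, ...) x$points

#' One-row summary of a bifurcation diagram
#'
#' @param x A `bifurcation_diagram`.
#' @param ... Unused.
#' @return A one-row tibble with fold count and locations, the bistable
#'   window and the reversibility verdict.
#' @export
glance.bifurcation_diagram <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    n_folds = length(x$folds),
    fold_left = if (length(x$folds)) min(x$folds) else NA_real_,
    fold_right = if (length(x$folds)) max(x$folds) else NA_real_,
    bistable_lo = if (!is.null(x$bistable_range)) x$bistable_range[1]
                  else NA_real_,
    bistable_hi = if (!is.null(x$bistable_range)) x$bistable_range[2]
                  else NA_real_,
    reversibility = x$reversibility)
}
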