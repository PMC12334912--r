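#' Enumerate three-node feedforward loops
#'
#' Finds every ordered triple of distinct nodes (regulator, intermediate,
#' target) with edges regulator->intermediate, intermediate->target and
#' regulator->target, the composite-motif pattern in which a TF and a miRNA
#' co-regulate a common target. Each distinct `(source, target, mechanism)`
#' edge combination yields its own instance, so a pair regulated both
#' transcriptionally and post-transcriptionally contributes parallel
#' instances (their dynamics differ). Output order is deterministic:
#' lexicographic by member symbols, then mechanisms.
#'
#' @param net A `reg_network`.
#' @param require_member Optional symbol every returned motif must contain
#'   (e.g. `"SOX10"`); error if absent from the network.
#' @param require_mirna If `TRUE`, keep only motifs containing at least one
#'   miRNA node.
#' @return A tibble of motif instances with columns `kind` (`"FFL"`),
#'   members `m1` (regulator), `m2` (intermediate), `m3` (target), edge
#'   signs `s1` (m1->m2), `s2` (m2->m3), `s3` (m1->m3), mechanisms
#'   `mech1`..`mech3`, `sign_class` (`"coherent"`/`"incoherent"`) and
#'   `subtype` (1-4, standard coherent/incoherent type numbering).
#' @export
enumerate_ffls <- function(net, require_member = NULL, require_mirna = FALSE) {
  stopifnot(inherits(net, "reg_network"))
  check_member(net, require_member)
  e <- net$edges
  if (!nrow(e)) return(empty_motif_table())
  e1 <- dplyr::rename(e[c("source", "target", "sign", "mechanism")],
                      m1 = "source", m2 = "target", s1 = "sign",
                      mech1 = "mechanism")
  e2 <- dplyr::rename(e[c("source", "target", "sign", "mechanism")],
                      m2 = "source", m3 = "target", s2 = "sign",
                      mech2 = "mechanism")
  e3 <- dplyr::rename(e[c("source", "target", "sign", "mechanism")],
                      m1 = "source", m3 = "target", s3 = "sign",
                      mech3 = "mechanism")
  out <- e1 |>
    dplyr::inner_join(e2, by = "m2", relationship = "many-to-many") |>
    dplyr::inner_join(e3, by = c("m1", "m3"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$m1 != .data$m2, .data$m2 != .data$m3,
                  .data$m1 != .data$m3)
  if (!nrow(out)) return(empty_motif_table())
  out$kind <- "FFL"
  cl <- ffl_sign_class(out$s1, out$s2, out$s3)
  out$sign_class <- cl$sign_class
  out$subtype <- cl$subtype
  out <- apply_motif_filters(out, net, require_member, require_mirna)
  order_motifs(out)
}

#' Enumerate two- and three-node feedback loops
#'
#' Finds all directed simple cycles of length 2 (`"FBL2"`, mutual
#' regulation) and 3 (`"FBL3"`), reported once each in canonical rotation:
#' the cycle starts at its lexicographically smallest member and follows
#' edge direction. As in [enumerate_ffls()], parallel mechanism arms yield
#' distinct instances.
#'
#' @inheritParams enumerate_ffls
#' @param max_len Maximum cycle length, 2 or 3.
#' @return A tibble of motif instances; for `FBL3` the edges are
#'   `m1->m2` (`s1`), `m2->m3` (`s2`), `m3->m1` (`s3`); for `FBL2`,
#'   `m1->m2` (`s1`) and `m2->m1` (`s2`) with `m3`, `s3`, `mech3` `NA`.
#'   `sign_class` is `"positive"` or `"negative"` by the cycle sign
#'   product.
#' @export
enumerate_fbls <- function(net, max_len = 3, require_member = NULL,
                           require_mirna = FALSE) {
  stopifnot(inherits(net, "reg_network"), max_len %in% c(2, 3))
  check_member(net, require_member)
  e <- net$edges
  if (!nrow(e)) return(empty_motif_table())
  ecols <- e[c("source", "target", "sign", "mechanism")]

  # 2-cycles: m1 -> m2 -> m1 with m1 < m2 (canonical start)
  a <- dplyr::rename(ecols, m1 = "source", m2 = "target", s1 = "sign",
                     mech1 = "mechanism")
  b <- dplyr::rename(ecols, m2 = "source", m1 = "target", s2 = "sign",
                     mech2 = "mechanism")
  fbl2 <- dplyr::inner_join(a, b, by = c("m1", "m2"),
                            relationship = "many-to-many") |>
    dplyr::filter(.data$m1 < .data$m2)
  if (nrow(fbl2)) {
    fbl2$kind <- "FBL2"
    fbl2$m3 <- NA_character_
    fbl2$s3 <- NA_integer_
    fbl2$mech3 <- NA_character_
    fbl2$sign_class <- fbl_sign_class(fbl2$s1 * fbl2$s2)
    fbl2$subtype <- NA_integer_
  } else fbl2 <- NULL

  fbl3 <- NULL
  if (max_len >= 3) {
    e1 <- dplyr::rename(ecols, m1 = "source", m2 = "target", s1 = "sign",
                        mech1 = "mechanism")
    e2 <- dplyr::rename(ecols, m2 = "source", m3 = "target", s2 = "sign",
                        mech2 = "mechanism")
    e3 <- dplyr::rename(ecols, m3 = "source", m1 = "target", s3 = "sign",
                        mech3 = "mechanism")
    fbl3 <- e1 |>
      dplyr::inner_join(e2, by = "m2", relationship = "many-to-many") |>
      dplyr::inner_join(e3, by = c("m3", "m1"),
                        relationship = "many-to-many") |>
      dplyr::filter(.data$m1 != .data$m2, .data$m2 != .data$m3,
                    .data$m1 != .data$m3,
                    # canonical rotation: smallest symbol first
                    .data$m1 < .data$m2, .data$m1 < .data$m3)
    if (nrow(fbl3)) {
      fbl3$kind <- "FBL3"
      fbl3$sign_class <- fbl_sign_class(fbl3$s1 * fbl3$s2 * fbl3$s3)
      fbl3$subtype <- NA_integer_
    } else fbl3 <- NULL
  }

  out <- dplyr::bind_rows(fbl2, fbl3)
  if (is.null(out) || !nrow(out)) return(empty_motif_table())
  out <- apply_motif_filters(out, net, require_member, require_mirna)
  order_motifs(out)
}

#' Sign-classify a feedforward loop
#'
#' A feedforward loop is *coherent* when the sign of the direct edge
#' (regulator->target) equals the product of the signs along the indirect
#' path (regulator->intermediate->target); otherwise *incoherent*. The
#' subtype index 1-4 follows the standard convention keyed on
#' (sign(regulator->intermediate), sign(intermediate->target)): coherent
#' `(+,+)`->1, `(-,-)`->2, `(+,-)`->3, `(-,+)`->4; incoherent `(+,-)`->1,
#' `(-,-)`->2, `(+,+)`->3, `(-,+)`->4.
#'
#' @param m Motif table rows of kind `"FFL"` (as returned by
#'   [enumerate_ffls()]).
#' @return `m` with recomputed `sign_class` and `subtype`.
#' @export
classify_ffl <- function(m) {
  m <- tibble::as_tibble(m)
  if (!nrow(m)) return(m)
  if (any(m$kind != "FFL"))
    stop("classify_ffl() expects motif rows of kind 'FFL'", call. = FALSE)
  cl <- ffl_sign_class(m$s1, m$s2, m$s3)
  m$sign_class <- cl$sign_class
  m$subtype <- cl$subtype
  m
}

#' Sign-classify a feedback loop
#'
#' A feedback loop is *positive* when the product of its cycle edge signs
#' is +1 (even number of repressions; capable of bistable switching) and
#' *negative* otherwise (homeostasis/oscillation).
#'
#' @param m Motif table rows of kind `"FBL2"` or `"FBL3"`.
#' @return `m` with recomputed `sign_class`.
#' @export
classify_fbl <- function(m) {
  m <- tibble::as_tibble(m)
  if (!nrow(m)) return(m)
  if (!all(m$kind %in% c("FBL2", "FBL3")))
    stop("classify_fbl() expects motif rows of kind 'FBL2' or 'FBL3'",
         call. = FALSE)
  prod <- ifelse(m$kind == "FBL2", m$s1 * m$s2, m$s1 * m$s2 * m$s3)
  m$sign_class <- fbl_sign_class(prod)
  m
}

ffl_sign_class <- function(s1, s2, s3) {
  coherent <- s3 == s1 * s2
  subtype <- dplyr::case_when(
    coherent  & s1 == 1  & s2 == 1  ~ 1L,
    coherent  & s1 == -1 & s2 == -1 ~ 2L,
    coherent  & s1 == 1  & s2 == -1 ~ 3L,
    coherent  & s1 == -1 & s2 == 1  ~ 4L,
    !coherent & s1 == 1  & s2 == -1 ~ 1L,
    !coherent & s1 == -1 & s2 == -1 ~ 2L,
    !coherent & s1 == 1  & s2 == 1  ~ 3L,
    !coherent & s1 == -1 & s2 == 1  ~ 4L)
  list(sign_class = ifelse(coherent, "coherent", "incoherent"),
       subtype = subtype)
}

fbl_sign_class <- function(sign_product) {
  ifelse(sign_product > 0, "positive", "negative")
}

check_member <- function(net, member) {
  if (is.null(member)) return(invisible(NULL))
  member <- normalize_symbol(member)
  if (!member %in% net$nodes$symbol)
    stop("require_member '", member, "' not present in network",
         call. = FALSE)
  invisible(member)
}

apply_motif_filters <- function(out, net, require_member, require_mirna) {
  if (!is.null(require_member)) {
    member <- normalize_symbol(require_member)
    out <- dplyr::filter(out, .data$m1 == member | .data$m2 == member |
                           (!is.na(.data$m3) & .data$m3 == member))
  }
  if (isTRUE(require_mirna)) {
    cls <- setNames(net$nodes$node_class, net$nodes$symbol)
    m3_mir <- !is.na(out$m3) & !is.na(cls[out$m3]) & cls[out$m3] == "MIRNA"
    has_mir <- cls[out$m1] == "MIRNA" | cls[out$m2] == "MIRNA" | m3_mir
    out <- out[has_mir, ]
  }
  out
}

motif_columns <- function() {
  c("kind", "m1", "m2", "m3", "s1", "s2", "s3",
    "mech1", "mech2", "mech3", "sign_class", "subtype")
}

empty_motif_table <- function() {
  tibble::tibble(kind = character(), m1 = character(), m2 = character(),
                 m3 = character(), s1 = integer(), s2 = integer(),
                 s3 = integer(), mech1 = character(), mech2 = character(),
                 mech3 = character(), sign_class = character(),
                 subtype = integer())
}

order_motifs <- function(out) {
  out |>
    dplyr::select(dplyr::all_of(motif_columns())) |>
    dplyr::arrange(.data$kind, .data$m1, .data$m2, .data$m3,
                   .data$mech1, .data$mech2, .data$mech3)
}

#' Motif census of a network
#'
#' Counts feedforward and feedback loop instances per kind, sign class and
#' subtype, applying the same membership/miRNA constraints as the
#' enumerators. Counts equal the row counts of the corresponding
#' enumeration outputs.
#'
#' @inheritParams enumerate_fbls
#' @return A tibble with columns `kind`, `sign_class`, `subtype`, `n`.
#' @export
motif_census <- function(net, require_member = NULL, require_mirna = FALSE,
                         max_len = 3) {
  motifs <- dplyr::bind_rows(
    enumerate_ffls(net, require_member, require_mirna),
    enumerate_fbls(net, max_len, require_member, require_mirna))
  motifs |>
    dplyr::count(.data$kind, .data$sign_class, .data$subtype) |>
    dplyr::arrange(.data$kind, .data$sign_class, .data$subtype)
}

#' Write a motif table or census to TSV
#'
#' Flattens list-free motif columns to a plain tab-separated file.
#'
#' @param motifs Tibble from [enumerate_ffls()], [enumerate_fbls()] or
#'   [motif_census()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(motifs, path) {
  readr::write_tsv(motifs, path)
  invisible(path)
}
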