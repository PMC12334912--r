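#' Specify a SOX10->MITF input function
#'
#' Three alternative models for how steady-state MITF output depends on
#' SOX10 level: `linear` (proportional, slope `a`), `saturated`
#' (Michaelis-Menten-like, `v_max * S / (k_half + S)`, diminishing returns
#' as promoter sites fill) and `sigmoidal` (Hill,
#' `v_max * S^n / (k_half^n + S^n)`, cooperative binding at multiple
#' promoter sites giving sharp transitions at intermediate SOX10).
#'
#' @param model `"linear"`, `"saturated"` or `"sigmoidal"`.
#' @param a Slope of the linear model (output per input unit).
#' @param v_max Maximal output (saturated/sigmoidal).
#' @param k_half Input level giving half-maximal output.
#' @param hill_n Hill coefficient (cooperativity, >= 1); used only by the
#'   sigmoidal model. `hill_n = 1` reduces the sigmoidal model to the
#'   saturated one exactly.
#' @return An object of class `input_function_spec`.
#' @export
input_function_spec <- function(model = c("linear", "saturated", "sigmoidal"),
                                a = 1, v_max = 1, k_half = 0.5, hill_n = 4) {
  model <- match.arg(model)
  stopifnot(a > 0, v_max > 0, k_half > 0, hill_n >= 1)
  structure(list(model = model, a = a, v_max = v_max, k_half = k_half,
                 hill_n = hill_n),
            class = "input_function_spec")
}

#' Steady MITF output for given SOX10 levels
#'
#' Evaluates the chosen input-function model on a scalar or grid of
#' non-negative SOX10 levels.
#'
#' @param spec An [input_function_spec()].
#' @param sox10_level Non-negative numeric vector.
#' @return Numeric vector of MITF output levels.
#' @export
input_response <- function(spec, sox10_level) {
  stopifnot(inherits(spec, "input_function_spec"))
  if (any(sox10_level < 0)) stop("sox10_level must be >= 0", call. = FALSE)
  S <- sox10_level
  switch(spec$model,
         linear = spec$a * S,
         saturated = spec$v_max * S / (spec$k_half + S),
         sigmoidal = {
           n <- spec$hill_n
           spec$v_max * S^n / (spec$k_half^n + S^n)
         })
}

#' Sensitivity of MITF output to SOX10 level
#'
#' Closed-form derivative of [input_response()] with respect to the SOX10
#' level. For the linear model it is the constant slope; for the saturated
#' model it is maximal at 0; for the sigmoidal model with `hill_n > 1` it
#' peaks at the interior level `k_half * ((n-1)/(n+1))^(1/n)`.
#'
#' @inheritParams input_response
#' @return Numeric vector of derivatives.
#' @export
response_sensitivity <- function(spec, sox10_level) {
  stopifnot(inherits(spec, "input_function_spec"))
  if (any(sox10_level < 0)) stop("sox10_level must be >= 0", call. = FALSE)
  S <- sox10_level
  switch(spec$model,
         linear = rep(spec$a, length(S)),
         saturated = spec$v_max * spec$k_half / (spec$k_half + S)^2,
         sigmoidal = {
           n <- spec$hill_n
           k <- spec$k_half
           spec$v_max * n * k^n * S^(n - 1) / (k^n + S^n)^2
         })
}

#' Define a phenotype map over MITF levels
#'
#' The rheostat reading of MITF: graded MITF levels map onto ordered
#' phenotype zones separated by boundaries, with a gray transition band of
#' half-width `gray_width` around each boundary (zone edges blur between
#' individual cells). The default four-zone map is, in increasing MITF
#' order, senescence, invasion, proliferation, differentiation; the
#' three-state map used for toggle-switch readouts is mesenchymal,
#' intermediate, melanocytic.
#'
#' @param boundaries Strictly increasing numeric vector of zone boundaries
#'   on the MITF axis (length = number of zones - 1).
#' @param labels Zone labels in increasing-MITF order
#'   (length = `length(boundaries) + 1`).
#' @param gray_width Half-width of the transition band around each
#'   boundary; must be small enough that bands do not overlap.
#' @return An object of class `phenotype_map`.
#' @export
phenotype_map <- function(boundaries = c(0.25, 0.5, 0.75),
                          labels = c("senescence", "invasion",
                                     "proliferation", "differentiation"),
                          gray_width = 0.02) {
  if (length(boundaries) > 1 && any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing", call. = FALSE)
  stopifnot(length(labels) == length(boundaries) + 1, gray_width >= 0)
  if (length(boundaries) > 1 && any(diff(boundaries) <= 2 * gray_width))
    stop("gray zones overlap: decrease gray_width", call. = FALSE)
  structure(list(boundaries = boundaries, labels = labels,
                 gray_width = gray_width),
            class = "phenotype_map")
}

#' Three-state melanoma phenotype map
#'
#' Convenience [phenotype_map()] with zones mesenchymal, intermediate,
#' melanocytic, scaled to a given MITF dynamic range.
#'
#' @param mitf_range Numeric length-2: the MITF levels spanned by the
#'   circuit (low, high).
#' @param gray_frac Gray half-width as a fraction of the range.
#' @return A `phenotype_map`.
#' @export
melanoma_state_map <- function(mitf_range = c(0, 1), gray_frac = 0.05) {
  span <- diff(mitf_range)
  phenotype_map(
    boundaries = mitf_range[1] + span * c(1 / 3, 2 / 3),
    labels = c("mesenchymal", "intermediate", "melanocytic"),
    gray_width = gray_frac * span)
}

#' Classify MITF levels into phenotype zones
#'
#' Returns the zone containing each level, or `"transition"` when the
#' level lies within `gray_width` of a zone boundary.
#'
#' @param mitf_level Non-negative numeric vector.
#' @param map A [phenotype_map()].
#' @return Character vector of zone labels (ordered factor levels are the
#'   map's labels plus `"transition"`).
#' @export
classify_phenotype <- function(mitf_level, map = phenotype_map()) {
  stopifnot(inherits(map, "phenotype_map"))
  zone_idx <- findInterval(mitf_level, map$boundaries) + 1L
  out <- map$labels[zone_idx]
  if (map$gray_width > 0) {
    near <- vapply(mitf_level, function(x)
      any(abs(x - map$boundaries) <= map$gray_width), TRUE)
    out[near] <- "transition"
  }
  out
}

#' Numeric zone index of phenotype calls
#'
#' Maps zone labels back to their position in the map's increasing-MITF
#' order (transition calls get the half-index between their neighbours),
#' handy for monotonicity checks along an MITF sweep.
#'
#' @param labels Character vector of calls from [classify_phenotype()].
#' @param map The `phenotype_map` that produced them.
#' @param mitf_level The levels that were classified (needed to place
#'   `"transition"` calls).
#' @return Numeric vector of zone indices.
#' @export
phenotype_zone_index <- function(labels, map, mitf_level) {
  idx <- match(labels, map$labels)
  trans <- labels == "transition"
  if (any(trans)) {
    b <- vapply(mitf_level[trans], function(x)
      which.min(abs(x - map$boundaries)), 1L)
    idx[trans] <- b + 0.5
  }
  idx
}
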