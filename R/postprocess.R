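## Outcome metrics computed from a converged state: indentation depth,
## regional stress aggregates, gel-transmitted stress, nucleus shape and
## effective-strain summaries.

check_converged <- function(state) {
  stopifnot(inherits(state, "fe_state"))
  if (!isTRUE(state$converged))
    stop("state is not converged; refusing to post-process")
  invisible(state)
}

qp_measure <- function(state, measure) {
  s <- state$sigma
  switch(measure,
         total = s[, "rr"] + s[, "zz"] + s[, "tt"],
         von_mises = sqrt(0.5 * ((s[, "rr"] - s[, "zz"])^2 +
                                   (s[, "zz"] - s[, "tt"])^2 +
                                   (s[, "tt"] - s[, "rr"])^2) +
                            3 * s[, "rz"]^2),
         stop(sprintf("unknown stress measure '%s'", measure)))
}

qp_region_sel <- function(state, region) {
  if (region == "cell") {
    sel <- state$region_qp %in% c("nucleus", "cytoplasm")
  } else {
    sel <- state$region_qp == region
  }
  if (!any(sel)) stop(sprintf("unknown or empty region '%s'", region))
  sel
}

#' Indentation depth of the gel surface
#'
#' Maximum downward vertical displacement over the gel top-surface nodes,
#' the primary invasiveness proxy. Non-negative by construction.
#'
#' @param state A converged `fe_state`.
#' @param mesh Mesh used for the solve (defaults to the one stored in the
#'   state).
#' @return Depth in micrometres.
#' @export
indentation_depth <- function(state, mesh = state$mesh) {
  check_converged(state)
  ids <- mesh$surface_sets$gel_top_free
  max(0, max(-state$u[2 * ids]))
}

#' Regional stress aggregate
#'
#' Aggregates a pointwise stress measure over the revolved (deformed) volume
#' of a region. `total` is the signed trace of the Cauchy stress (sum of the
#' three directional stresses); `von_mises` the effective stress. Modes:
#' `volume_mean` (default reported scalar), `max` (peak magnitude) and
#' `volume_sum` (volume integral, kPa um^3).
#'
#' @param state A converged `fe_state`.
#' @param region `"nucleus"`, `"cytoplasm"`, `"gel"` or `"cell"`
#'   (nucleus + cytoplasm).
#' @param measure `"total"` or `"von_mises"`.
#' @param mode `"volume_mean"`, `"max"` or `"volume_sum"`.
#' @return Scalar aggregate (kPa, or kPa um^3 for `volume_sum`).
#' @export
region_stress_aggregate <- function(state, region,
                                    measure = c("total", "von_mises"),
                                    mode = c("volume_mean", "max",
                                             "volume_sum")) {
  check_converged(state)
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  sel <- qp_region_sel(state, region)
  m <- qp_measure(state, measure)[sel]
  w <- (state$wq_ref * state$Jq)[sel]
  switch(mode,
         volume_mean = sum(w * m) / sum(w),
         max = if (measure == "total") m[which.max(abs(m))] else max(m),
         volume_sum = sum(w * m))
}

#' Stress transmitted to the gel
#'
#' Default: volume-mean von Mises stress over the gel within a radius of
#' twice the cell radius of the axis, localising the metric to the region
#' beneath the cell where the transmitted stress concentrates. Alternatives:
#' the whole-gel mean and the peak (maximum) value in the near-cell region.
#'
#' @param state A converged `fe_state`.
#' @param mode `"near_cell"` (default), `"whole_gel"` or `"peak"`.
#' @param radius_factor Multiple of the cell radius delimiting the near-cell
#'   region.
#' @return Stress in kPa.
#' @export
gel_transmitted_stress <- function(state,
                                   mode = c("near_cell", "whole_gel", "peak"),
                                   radius_factor = 2) {
  check_converged(state)
  mode <- match.arg(mode)
  sel <- state$region_qp == "gel"
  if (mode != "whole_gel") {
    Rc <- state$mesh$geom$Rc
    if (is.na(Rc)) stop("mesh has no cell; near-cell gel region undefined")
    sel <- sel & state$Rq_qp <= radius_factor * Rc
  }
  m <- qp_measure(state, "von_mises")[sel]
  if (mode == "peak") return(max(m))
  w <- (state$wq_ref * state$Jq)[sel]
  sum(w * m) / sum(w)
}

#' Signed percentage difference
#'
#' `100 * (top - bottom) / bottom`. Gel-stress differences come out negative
#' when the bottom-applied configuration transmits more stress.
#'
#' @param top_value,bottom_value Scalars; `bottom_value` must be nonzero.
#' @return Percentage (signed).
#' @export
percent_difference <- function(top_value, bottom_value) {
  if (any(bottom_value == 0))
    stop("undefined percentage difference: zero baseline")
  100 * (top_value - bottom_value) / bottom_value
}

#' Deformed nucleus aspect ratio
#'
#' Ratio of the deformed vertical extent to the deformed planar extent
#' (diameter) of the nucleus, from the displaced positions of its nodes.
#' The undeformed reference value is `nucleus_diam_vertical /
#' nucleus_diam_planar`; compression toward a rounded shape drives the ratio
#' toward 1.
#'
#' @param state A converged `fe_state`.
#' @param mesh Mesh used for the solve.
#' @return Dimensionless ratio.
#' @export
nucleus_aspect_ratio <- function(state, mesh = state$mesh) {
  check_converged(state)
  sel <- mesh$region == "nucleus"
  if (!any(sel)) stop("mesh has no nucleus region")
  ids <- unique(as.vector(mesh$tri6[sel, ]))
  r <- mesh$nodes[ids, 1] + state$u[2 * ids - 1]
  z <- mesh$nodes[ids, 2] + state$u[2 * ids]
  (max(z) - min(z)) / (2 * max(r))
}

#' Volume-averaged effective (von Mises equivalent) strain
#'
#' Effective strain of the logarithmic (Hencky) strain tensor,
#' `sqrt(2/3 dev(eps) : dev(eps))` with `eps = ln V` from the principal
#' stretches, volume-averaged over a region.
#'
#' @inheritParams region_stress_aggregate
#' @return Dimensionless strain.
#' @export
average_effective_strain <- function(state, region = "cell") {
  check_converged(state)
  sel <- qp_region_sel(state, region)
  Fq <- state$Fq[sel, , drop = FALSE]
  B11 <- Fq[, 1]^2 + Fq[, 2]^2
  B22 <- Fq[, 3]^2 + Fq[, 4]^2
  B12 <- Fq[, 1] * Fq[, 3] + Fq[, 2] * Fq[, 4]
  mid <- (B11 + B22) / 2
  rad <- sqrt(((B11 - B22) / 2)^2 + B12^2)
  e1 <- 0.5 * log(mid + rad)
  e2 <- 0.5 * log(mid - rad)
  e3 <- log(Fq[, 5])
  em <- (e1 + e2 + e3) / 3
  eff <- sqrt((2 / 3) * ((e1 - em)^2 + (e2 - em)^2 + (e3 - em)^2))
  w <- (state$wq_ref * state$Jq)[sel]
  sum(w * eff) / sum(w)
}

#' Scalar outcome summary of one run
#'
#' Collects the outcome metrics of a converged state into a one-row data
#' frame: indentation depth, nucleus/cytoplasm total and von Mises stress
#' aggregates (volume means), gel-transmitted stress, nucleus aspect ratio
#' and the cell-average effective strain, plus run metadata.
#'
#' @param state A converged `fe_state`.
#' @param F Applied normal force (nN), metadata.
#' @param E_cyto Cytoplasm stiffness (kPa), metadata.
#' @param config Force configuration (`"top"`/`"bottom"`), metadata.
#' @param model Material model label, metadata.
#' @return One-row `data.frame`.
#' @export
result_summary <- function(state, F = NA_real_, E_cyto = NA_real_,
                           config = NA_character_, model = NA_character_) {
  check_converged(state)
  data.frame(
    F = F, E_cyto = E_cyto, config = config, model = model,
    converged = TRUE,
    load_factor = if (is.null(state$load_factor)) 1 else state$load_factor,
    indentation_depth = indentation_depth(state),
    nucleus_total_stress = region_stress_aggregate(state, "nucleus", "total"),
    nucleus_vm_stress = region_stress_aggregate(state, "nucleus", "von_mises"),
    nucleus_peak_total = region_stress_aggregate(state, "nucleus", "total",
                                                 "max"),
    cytoplasm_total_stress = region_stress_aggregate(state, "cytoplasm",
                                                     "total"),
    cytoplasm_vm_stress = region_stress_aggregate(state, "cytoplasm",
                                                  "von_mises"),
    gel_transmitted_stress = gel_transmitted_stress(state),
    nucleus_aspect_ratio = nucleus_aspect_ratio(state),
    avg_effective_strain_cell = average_effective_strain(state, "cell"),
    stringsAsFactors = FALSE)
}
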