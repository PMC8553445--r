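.muffle_beyond_max <- function(expr) {
  withCallingHandlers(expr, mlcoffset_beyond_max_field = function(w)
    invokeRestart("muffleWarning"))
}

.table_row <- function(h, material, geom, paper_rounding) {
  sol <- solve_edge(leaf_setting(h), material, geom)
  x50 <- sol$x50
  alpha <- sol$alpha
  if (paper_rounding) {
    # forensic emulation of a pipeline that carried radians at 4 decimals:
    # quantize the 50%-ray angle before projecting; geometry columns
    # (which the source tables carry at full precision) stay exact
    alpha <- round(alpha, 4)
    x50 <- geom$sad * tan(alpha)
  }
  data.frame(
    half_field_cm = h,
    theta_deg = sol$theta * 180 / pi,
    theta_rad = sol$theta,
    theta_prime_rad = sol$theta_prime,
    theta_dprime_rad = sol$theta_dprime,
    alpha_rad = alpha,
    x50_cm = x50,
    x_tang_cm = sol$x_tang,
    x_mlc_cm = sol$x_mlc,
    offset_mm = (x50 - sol$x_mlc) * 10,
    light_rad_mm = (sol$x_tang - x50) * 10,
    model_penumbra_mm = sol$model_penumbra_mm)
}

#' Regenerate the tungsten per-field offset table
#'
#' One row per half-field: divergence angles, the 50%-ray angle, the
#' three axis projections, the planning offset, the light-radiation
#' agreement, and the model penumbra.
#'
#' @param material an [mlc_material()]; pure tungsten by default.
#' @param half_fields nominal half-fields, cm.
#' @param geom a [beamline_geometry()].
#' @param paper_rounding emulate a pipeline carrying radians rounded to
#'   4 decimals: the 50%-ray angle is quantized before projection, which
#'   injects step jitter of up to ~0.13 mm into the offset columns.
#'   Geometry columns are unaffected. Off by default.
#' @param digits if non-`NULL`, round for display: 4 decimals for
#'   degrees/radians/cm, 5 for mm. `NULL` keeps full precision.
#' @return data.frame with columns `half_field_cm`, `theta_deg`,
#'   `theta_rad`, `theta_prime_rad`, `theta_dprime_rad`, `alpha_rad`,
#'   `x50_cm`, `x_tang_cm`, `x_mlc_cm`, `offset_mm`, `light_rad_mm`,
#'   `model_penumbra_mm`.
#' @export
generate_table2 <- function(material = mlc_materials()$W100,
                            half_fields = seq(0.5, 9, by = 0.5),
                            geom = beamline_geometry(),
                            paper_rounding = FALSE,
                            digits = NULL) {
  stopifnot(inherits(material, "mlc_material"), length(half_fields) >= 1L)
  rows <- .muffle_beyond_max(
    lapply(half_fields, .table_row, material = material, geom = geom,
           paper_rounding = paper_rounding))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(digits)) {
    cm_cols <- c("theta_deg", "theta_rad", "theta_prime_rad",
                 "theta_dprime_rad", "alpha_rad", "x50_cm", "x_tang_cm",
                 "x_mlc_cm")
    mm_cols <- c("offset_mm", "light_rad_mm", "model_penumbra_mm")
    out[cm_cols] <- lapply(out[cm_cols], round, digits = 4)
    out[mm_cols] <- lapply(out[mm_cols], round, digits = 5)
  }
  out
}

#' Regenerate the nine-material offset matrix
#'
#' Planning offsets (mm) for every material at every half-field; rows
#' are materials, columns half-fields. All entries are negative: the
#' 50%-dose point always falls between the light-field edge and the
#' planning position.
#'
#' @param materials named list of [mlc_material()]s.
#' @param half_fields nominal half-fields, cm.
#' @param geom a [beamline_geometry()].
#' @param paper_rounding as in [generate_table2()].
#' @return numeric matrix of offsets, mm.
#' @export
generate_table3 <- function(materials = mlc_materials(),
                            half_fields = 1:9,
                            geom = beamline_geometry(),
                            paper_rounding = FALSE) {
  stopifnot(length(materials) >= 1L)
  out <- .muffle_beyond_max(
    t(vapply(materials, function(m) {
      vapply(half_fields, function(h) {
        sol <- solve_edge(leaf_setting(h), m, geom)
        x50 <- if (paper_rounding) geom$sad * tan(round(sol$alpha, 4)) else sol$x50
        (x50 - sol$x_mlc) * 10
      }, numeric(1))
    }, numeric(length(half_fields)))))
  colnames(out) <- sprintf("hf_%g_cm", half_fields)
  out
}
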