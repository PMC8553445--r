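#' Axis position of the p-survival ray through the leaf end
#'
#' Finds the diverging ray whose slant chord through the rectangular
#' leaf end equals the material path that attenuates the beam to the
#' survival fraction `p`, and projects it onto the isocenter axis. The
#' ray enters the vertical end face at depth `z_enter` and exits through
#' the leaf bottom, so its chord is
#' `(z_bottom - x_leaf / tan t) / cos t`; the solve is the fixed-point
#' iteration `z_enter <- z_bottom - d_p * cos(atan(x_leaf / z_enter))`,
#' which contracts in a few iterations at these sub-2-degree divergence
#' angles. With `p = 0.5` the result is the radiation field edge X50.
#'
#' @inheritParams x_mlc
#' @param p survival fraction in (0, 1); 0.5 gives X50.
#' @return signed axis position, cm. `half_field = 0` returns 0 (the
#'   degenerate on-axis limit).
#' @export
solve_x_p <- function(setting, material, geom = beamline_geometry(), p = 0.5) {
  setting <- .as_setting(setting)
  .check_setting(setting, geom)
  .check_material_geom(material, geom)
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("survival fraction p must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (setting$half_field == 0) return(0)

  d_p <- path_for_survival(p, material)
  z_b <- geom$source_to_leaf_bottom
  x_leaf <- abs(leaf_lateral_position(setting, geom))
  theta_dprime <- atan(x_leaf / (z_b - material$thickness))
  max_chord <- material$thickness / cos(theta_dprime)
  if (d_p >= max_chord) {
    stop(sprintf("insufficient leaf thickness: material '%s' cannot attenuate to p = %.4g (needs %.4g cm, max chord %.4g cm)",
                 material$name, p, d_p, max_chord), call. = FALSE)
  }

  z_enter <- z_b - d_p  # small-angle start; exact at zero divergence
  for (i in 1:100) {
    z_new <- z_b - d_p * cos(atan(x_leaf / z_enter))
    if (abs(z_new - z_enter) < 1e-12) {
      z_enter <- z_new
      break
    }
    z_enter <- z_new
  }
  t_star <- atan(x_leaf / z_enter)
  chord <- (z_b - x_leaf / tan(t_star)) / cos(t_star)
  if (abs(chord - d_p) > 1e-8) {
    stop("chord solve failed to meet residual tolerance", call. = FALSE)  # nocov
  }
  setting$direction_sign * geom$sad * tan(t_star)
}

#' Planning offset of the leaf end
#'
#' The correction the planning system must apply to its stored leaf
#' position: the 50%-dose position minus the leaf-end midpoint
#' projection, `(X50 - Xmlc) * 10` mm. Negative for every shipped
#' material at positive half-fields, because X50 always falls between
#' the light-field edge and the planning position.
#'
#' @inheritParams x_mlc
#' @return offset in mm.
#' @export
leaf_offset <- function(setting, material, geom = beamline_geometry()) {
  setting <- .as_setting(setting)
  (solve_x_p(setting, material, geom, p = 0.5) -
     x_mlc(setting, material, geom)) * 10
}

#' Light-radiation agreement
#'
#' Mismatch between the visible light-field edge and the radiation
#' field edge: `(Xtang - X50) * 10` mm. Negative at positive
#' half-fields (the 50%-dose point lies beyond the light edge).
#'
#' @inheritParams x_mlc
#' @return agreement in mm.
#' @export
light_radiation_agreement <- function(setting, material,
                                      geom = beamline_geometry()) {
  setting <- .as_setting(setting)
  (x_tang(setting, geom) - solve_x_p(setting, material, geom, p = 0.5)) * 10
}

#' Model 20--80% penumbra of the leaf edge
#'
#' Lateral distance between the 20% and 80% survival rays,
#' `(X20 - X80) * 10` mm. This is the penumbra of the pure attenuation
#' model only -- no source size, scatter or secondary particles -- so it
#' is narrower than a measured film penumbra.
#'
#' @inheritParams x_mlc
#' @return model penumbra in mm; 0 in the degenerate `half_field = 0`
#'   limit.
#' @export
model_penumbra <- function(setting, material, geom = beamline_geometry()) {
  setting <- .as_setting(setting)
  if (setting$half_field == 0) return(0)
  abs(solve_x_p(setting, material, geom, p = 0.2) -
        solve_x_p(setting, material, geom, p = 0.8)) * 10
}

#' Solve the full leaf-end edge problem
#'
#' Aggregates the projection geometry and the 50%-ray solve for one
#' (leaf setting, material) pair: divergence angles, the 50%-ray angle
#' `alpha`, the three axis positions (light edge, 50% dose, planning
#' position), the planning offset, the light-radiation agreement and
#' the model penumbra.
#'
#' @inheritParams x_mlc
#' @return object of class `"edge_solution"`; a list with fields
#'   `half_field`, `direction_sign`, `material`, `theta`, `theta_prime`,
#'   `theta_dprime`, `alpha` (radians), `x_tang`, `x50`, `x_mlc` (cm),
#'   `offset_mm`, `light_rad_mm`, `model_penumbra_mm`.
#' @export
#' @examples
#' w <- mlc_materials()$W100
#' solve_edge(leaf_setting(6), w)
solve_edge <- function(setting, material, geom = beamline_geometry()) {
  setting <- .as_setting(setting)
  ang <- divergence_angles(setting, material, geom)
  x50 <- solve_x_p(setting, material, geom, p = 0.5)
  xm <- x_mlc(setting, material, geom)
  xt <- x_tang(setting, geom)
  structure(
    list(half_field = setting$half_field,
         direction_sign = setting$direction_sign,
         material = material$name,
         theta = unname(ang["theta"]),
         theta_prime = unname(ang["theta_prime"]),
         theta_dprime = unname(ang["theta_dprime"]),
         alpha = atan2(x50, geom$sad),
         x_tang = xt, x50 = x50, x_mlc = xm,
         offset_mm = (x50 - xm) * 10,
         light_rad_mm = (xt - x50) * 10,
         model_penumbra_mm = model_penumbra(setting, material, geom)),
    class = "edge_solution")
}

#' @export
print.edge_solution <- function(x, ...) {
  cat(sprintf("Leaf-end edge solution: %s, half-field %.4g cm (direction %+d)\n",
              x$material, x$half_field, x$direction_sign))
  cat(sprintf("  angles [rad]: theta %.6f  theta' %.6f  theta'' %.6f  alpha %.6f\n",
              x$theta, x$theta_prime, x$theta_dprime, x$alpha))
  cat(sprintf("  axis [cm]:    X_tang %.4f  X50 %.4f  X_mlc %.4f\n",
              x$x_tang, x$x50, x$x_mlc))
  cat(sprintf("  offset %.4f mm   light-radiation agreement %.4f mm   model penumbra %.4f mm\n",
              x$offset_mm, x$light_rad_mm, x$model_penumbra_mm))
  invisible(x)
}
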