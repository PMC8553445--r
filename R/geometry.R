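#' Beamline projection geometry
#'
#' The projection geometry of a diverging beam collimated by an MLC:
#' an effective point source on the axis, the distance from that source
#' to the bottom plane of the leaves, and the source-to-axis distance
#' (SAD) at which all edge positions are reported. Defaults describe a
#' carbon-ion beamline with SAD 263.3 cm whose virtual source sits
#' 257.8 cm from the isocenter with 191.3 cm to the leaf bottom; folding
#' the virtual-source shift into the nominal SAD gives the effective
#' source-to-leaf-bottom distance 263.3 - (257.8 - 191.3) = 196.8 cm
#' (see [derive_projection_geometry()]).
#'
#' @param sad source-to-isocenter distance used for projections, cm.
#' @param source_to_leaf_bottom distance from the effective source to the
#'   bottom plane of the MLC leaves, cm; must be positive and < `sad`.
#' @param max_half_field largest nominal half-field the machine is rated
#'   for, cm. Settings beyond it warn; settings beyond twice it error.
#' @return object of class `"beamline_geometry"`.
#' @export
beamline_geometry <- function(sad = 263.3, source_to_leaf_bottom = 196.8,
                              max_half_field = 6) {
  stopifnot(is.numeric(sad), length(sad) == 1L, is.finite(sad),
            is.numeric(source_to_leaf_bottom), length(source_to_leaf_bottom) == 1L,
            is.finite(source_to_leaf_bottom),
            is.numeric(max_half_field), length(max_half_field) == 1L,
            max_half_field > 0)
  if (source_to_leaf_bottom <= 0 || source_to_leaf_bottom >= sad) {
    stop("need 0 < source_to_leaf_bottom < sad", call. = FALSE)
  }
  structure(list(sad = sad, source_to_leaf_bottom = source_to_leaf_bottom,
                 max_half_field = max_half_field),
            class = "beamline_geometry")
}

#' @export
print.beamline_geometry <- function(x, ...) {
  cat(sprintf("Beamline geometry: SAD %.4g cm, source-to-leaf-bottom %.4g cm, max half-field %.4g cm\n",
              x$sad, x$source_to_leaf_bottom, x$max_half_field))
  invisible(x)
}

#' Nominal leaf setting
#'
#' A single leaf position, expressed as the nominal light-field
#' half-width at the isocenter plane. `direction_sign = +1` means the
#' leaf travels away from the central axis (field opens);
#' `direction_sign = -1` mirrors the whole solution across the axis
#' (leaf toward or over the axis). All projections and angles are odd in
#' `direction_sign`.
#'
#' @param half_field nominal light-field half-width at isocenter, cm;
#'   non-negative (use `direction_sign` for the mirrored case).
#' @param direction_sign `+1` or `-1`.
#' @return object of class `"leaf_setting"`.
#' @export
leaf_setting <- function(half_field, direction_sign = 1) {
  stopifnot(is.numeric(half_field), length(half_field) == 1L,
            is.finite(half_field))
  if (half_field < 0) {
    stop("half_field must be >= 0; use direction_sign = -1 for the mirrored leaf",
         call. = FALSE)
  }
  if (!direction_sign %in% c(-1, 1)) {
    stop("direction_sign must be +1 or -1", call. = FALSE)
  }
  structure(list(half_field = half_field, direction_sign = direction_sign),
            class = "leaf_setting")
}

.as_setting <- function(setting) {
  if (inherits(setting, "leaf_setting")) setting else leaf_setting(setting)
}

# Rated-field check: warn beyond the rated half-field, hard error beyond 2x.
.check_setting <- function(setting, geom) {
  stopifnot(inherits(geom, "beamline_geometry"))
  h <- setting$half_field
  if (h > 2 * geom$max_half_field) {
    stop(sprintf("half_field %.4g cm exceeds twice the rated maximum (%.4g cm)",
                 h, geom$max_half_field), call. = FALSE)
  }
  if (h > geom$max_half_field) {
    warning(warningCondition(
      sprintf("half_field %.4g cm is beyond the rated maximum %.4g cm",
              h, geom$max_half_field),
      class = "mlcoffset_beyond_max_field"))
  }
  invisible(setting)
}

.check_material_geom <- function(material, geom) {
  if (geom$source_to_leaf_bottom - material$thickness <= 0) {
    stop(sprintf("material '%s' (thickness %.4g cm) places the leaf top at or behind the source",
                 material$name, material$thickness), call. = FALSE)
  }
  invisible(material)
}

#' Lateral position of the leaf-end face
#'
#' The inner face of the leaf sits where a ray from the source through
#' the leaf-bottom inner corner projects exactly to the nominal
#' half-field on the isocenter axis:
#' `half_field * source_to_leaf_bottom / sad`, signed by the travel
#' direction.
#'
#' @param setting a [leaf_setting()] (a bare non-negative number is
#'   promoted with `direction_sign = +1`).
#' @param geom a [beamline_geometry()].
#' @return lateral leaf-face position at the leaf-bottom plane, cm.
#' @export
leaf_lateral_position <- function(setting, geom = beamline_geometry()) {
  setting <- .as_setting(setting)
  .check_setting(setting, geom)
  setting$direction_sign * setting$half_field *
    geom$source_to_leaf_bottom / geom$sad
}

#' Light-field edge projection on the axis
#'
#' The visible light-field edge (projection of the leaf-bottom inner
#' corner) equals the nominal half-field by construction.
#'
#' @inheritParams leaf_lateral_position
#' @return signed position on the isocenter axis, cm.
#' @export
x_tang <- function(setting, geom = beamline_geometry()) {
  setting <- .as_setting(setting)
  .check_setting(setting, geom)
  setting$direction_sign * setting$half_field
}

#' Planning-system leaf position (leaf-end midpoint projection)
#'
#' Projects the leaf-end midpoint -- the point halfway up the vertical
#' end face -- through the source onto the isocenter axis. Monitor-unit
#' calculations in the planning system reference this point.
#'
#' @inheritParams leaf_lateral_position
#' @param material an [mlc_material()]; only the thickness enters.
#' @return signed position on the isocenter axis, cm.
#' @export
x_mlc <- function(setting, material, geom = beamline_geometry()) {
  setting <- .as_setting(setting)
  .check_setting(setting, geom)
  .check_material_geom(material, geom)
  z_mid <- geom$source_to_leaf_bottom - material$thickness / 2
  if (z_mid <= 0) {
    stop(sprintf("leaf-end midpoint of '%s' lies at or behind the source",
                 material$name), call. = FALSE)
  }
  leaf_lateral_position(setting, geom) * geom$sad / z_mid
}

#' Divergence angles of the leaf-end corners and midpoint
#'
#' Angles (radians, signed) of the rays from the source through the
#' leaf-bottom inner corner (`theta`, also the light-field edge ray),
#' the leaf-end midpoint (`theta_prime`) and the leaf-top inner corner
#' (`theta_dprime`). `theta == atan(half_field / sad)` by construction.
#'
#' @inheritParams x_mlc
#' @return named numeric vector `c(theta, theta_prime, theta_dprime)`.
#' @export
divergence_angles <- function(setting, material, geom = beamline_geometry()) {
  setting <- .as_setting(setting)
  .check_setting(setting, geom)
  .check_material_geom(material, geom)
  x_leaf <- leaf_lateral_position(setting, geom)
  z_b <- geom$source_to_leaf_bottom
  t_half <- material$thickness / 2
  c(theta = atan2(x_leaf, z_b),
    theta_prime = atan2(x_leaf, z_b - t_half),
    theta_dprime = atan2(x_leaf, z_b - material$thickness))
}
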