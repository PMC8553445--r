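#' Field-size magnification measurement for virtual-source estimation
#'
#' One measurement pair: the field size at the isocenter plane and at a
#' plane displaced by `gap` along the beam axis (positive downstream,
#' away from the source; negative upstream). A scattered beam appears
#' to diverge from a virtual point source; the ratio of the two field
#' sizes locates it.
#'
#' @param fs_at_iso field size at the isocenter plane, cm.
#' @param fs_at_gap field size at the displaced plane, cm.
#' @param gap signed plane displacement, cm; non-zero.
#' @param nominal_sad nominal machine SAD, cm (bookkeeping only).
#' @return object of class `"virtual_source_measurement"`.
#' @export
virtual_source_measurement <- function(fs_at_iso, fs_at_gap, gap,
                                       nominal_sad = 263.3) {
  stopifnot(is.numeric(fs_at_iso), fs_at_iso > 0,
            is.numeric(fs_at_gap), fs_at_gap > 0,
            is.numeric(gap), is.finite(gap))
  if (gap == 0) stop("gap must be non-zero", call. = FALSE)
  if (gap > 0 && fs_at_gap <= fs_at_iso) {
    warning("downstream gap should magnify the field for a diverging beam")
  }
  structure(list(fs_at_iso = fs_at_iso, fs_at_gap = fs_at_gap, gap = gap,
                 nominal_sad = nominal_sad),
            class = "virtual_source_measurement")
}

#' Estimate the virtual-source distance from field-size magnification
#'
#' For a point source at distance `f` from the isocenter, similar
#' triangles give `FS_gap / FS_iso = (f + g) / f`, hence
#' `f = g / (FS_gap / FS_iso - 1)`. Exact for any gap sign when the
#' divergence really is a point source.
#'
#' @param m a [virtual_source_measurement()].
#' @return virtual source-to-isocenter distance `f`, cm.
#' @export
#' @examples
#' m <- virtual_source_measurement(8, 16, gap = 10)
#' estimate_virtual_source(m)  # doubling at one extra f: f == gap
estimate_virtual_source <- function(m) {
  stopifnot(inherits(m, "virtual_source_measurement"))
  ratio <- m$fs_at_gap / m$fs_at_iso
  if (ratio == 1) {
    stop("no divergence detected: field sizes at the two planes are equal",
         call. = FALSE)
  }
  m$gap / (ratio - 1)
}

#' Combine virtual-source estimates from several gaps
#'
#' Upstream and downstream gaps each yield an estimate of `f`; they are
#' combined by the unweighted arithmetic mean, with the spread (max -
#' min) reported alongside.
#'
#' @param estimates numeric vector of `f` estimates, cm; non-empty.
#' @return list with `f` (mean, cm), `spread` (cm) and `n`.
#' @export
combine_gap_estimates <- function(estimates) {
  if (!is.numeric(estimates) || length(estimates) == 0L ||
      any(!is.finite(estimates))) {
    stop("need at least one finite estimate", call. = FALSE)
  }
  list(f = mean(estimates),
       spread = max(estimates) - min(estimates),
       n = length(estimates))
}

#' Derive the effective projection geometry from a virtual source
#'
#' The planning system projects from the nominal SAD, so a virtual
#' source measured at `f` with `f_to_leaf_bottom` to the MLC bottom is
#' folded into an effective source-to-leaf-bottom distance that
#' preserves the physical leaf-bottom-to-isocenter gap:
#' `source_to_leaf_bottom = nominal_sad - (f - f_to_leaf_bottom)`.
#' With the measured 257.8 / 191.3 cm pair and nominal SAD 263.3 cm
#' this yields the 196.8 cm constant used throughout the package.
#'
#' @param f virtual source-to-isocenter distance, cm.
#' @param f_to_leaf_bottom virtual source-to-leaf-bottom distance, cm.
#' @param nominal_sad nominal machine SAD, cm.
#' @param max_half_field passed through to [beamline_geometry()].
#' @return a [beamline_geometry()].
#' @export
derive_projection_geometry <- function(f, f_to_leaf_bottom,
                                       nominal_sad = 263.3,
                                       max_half_field = 6) {
  stopifnot(is.numeric(f), is.numeric(f_to_leaf_bottom),
            is.numeric(nominal_sad))
  if (!(f_to_leaf_bottom > 0 && f_to_leaf_bottom < f && f <= nominal_sad)) {
    stop("need 0 < f_to_leaf_bottom < f <= nominal_sad", call. = FALSE)
  }
  beamline_geometry(sad = nominal_sad,
                    source_to_leaf_bottom = nominal_sad - (f - f_to_leaf_bottom),
                    max_half_field = max_half_field)
}
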