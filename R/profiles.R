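#' One-dimensional dose profile across a leaf edge
#'
#' Sampled relative-dose profile on the isocenter axis. Doses are
#' relative to the central-axis (open-field) dose, which edge metrics
#' reference; fixtures normalize the open field to 1.
#'
#' @param positions strictly increasing axis positions, cm.
#' @param doses relative doses, same length, non-negative.
#' @param central_axis_dose reference dose for the 20/50/80% levels.
#' @return object of class `"dose_profile"`.
#' @export
dose_profile <- function(positions, doses, central_axis_dose = 1) {
  stopifnot(is.numeric(positions), is.numeric(doses),
            length(positions) == length(doses))
  if (length(positions) < 8L) {
    stop("a dose profile needs at least 8 samples", call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(doses < 0) || any(!is.finite(doses))) {
    stop("doses must be finite and non-negative", call. = FALSE)
  }
  stopifnot(is.numeric(central_axis_dose), central_axis_dose > 0)
  structure(list(positions = positions, doses = doses,
                 central_axis_dose = central_axis_dose),
            class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("Dose profile: %d samples on [%.4g, %.4g] cm, central-axis dose %.4g\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$central_axis_dose))
  invisible(x)
}

#' @export
plot.dose_profile <- function(x, ...) {
  plot(x$positions, x$doses / x$central_axis_dose, type = "l",
       xlab = "axis position [cm]", ylab = "relative dose", ...)
  abline(h = c(0.2, 0.5, 0.8), lty = 3, col = "grey50")
  invisible(x)
}

#' Ray-trace a transmission profile across the leaf edge
#'
#' Brute-force numeric counterpart of the analytic edge solve: for each
#' axis position the ray from the effective source is classified as
#' missing the leaf (relative dose 1), clipping the vertical end face
#' (chord from the entry depth to the leaf bottom, measured along the
#' ray), or passing above the leaf-top corner (full slant thickness).
#' The dose is the exponential survival of that chord. Serves as the
#' independent oracle for [solve_x_p()] and as the fixture generator's
#' engine.
#'
#' @inheritParams x_mlc
#' @param positions axis positions to sample, cm, strictly increasing.
#' @return a [dose_profile()] with open field normalized to 1.
#' @export
trace_profile <- function(setting, material, geom = beamline_geometry(),
                          positions) {
  setting <- .as_setting(setting)
  .check_setting(setting, geom)
  .check_material_geom(material, geom)
  s <- setting$direction_sign
  z_b <- geom$source_to_leaf_bottom
  z_t <- z_b - material$thickness
  x_leaf <- abs(leaf_lateral_position(setting, geom))

  # work on the mirrored (positive) side, then flip
  xs <- s * positions
  tan_t <- xs / geom$sad
  chord <- numeric(length(xs))
  hit <- xs > 0 & tan_t > 0
  z_cross <- rep(Inf, length(xs))
  z_cross[hit] <- x_leaf / tan_t[hit]          # depth where ray meets the face plane
  if (x_leaf == 0) z_cross[hit] <- 0           # face on the axis: any diverging ray enters at the top
  cos_t <- cos(atan(tan_t))
  full <- hit & z_cross <= z_t                 # enters through the leaf top
  face <- hit & z_cross > z_t & z_cross < z_b  # enters through the end face
  chord[full] <- material$thickness / cos_t[full]
  chord[face] <- (z_b - z_cross[face]) / cos_t[face]
  doses <- exp(-chord / material$lambda)
  dose_profile(positions, doses, central_axis_dose = 1)
}

.find_crossing <- function(positions, doses, level) {
  d <- doses - level
  idx <- which(d[-length(d)] * d[-1] <= 0 & (d[-length(d)] != 0 | d[-1] != 0))
  if (length(idx) == 0L) {
    if (any(d == 0)) return(list(x = positions[which(d == 0)[1L]], n = 1L))
    return(list(x = NA_real_, n = 0L))
  }
  i <- idx[length(idx)]  # outermost edge
  x0 <- positions[i]; x1 <- positions[i + 1L]
  y0 <- d[i]; y1 <- d[i + 1L]
  x <- if (y1 == y0) (x0 + x1) / 2 else x0 - y0 * (x1 - x0) / (y1 - y0)
  list(x = x, n = length(idx))
}

#' Extract edge metrics from a dose profile
#'
#' Locates the 50%, 20% and 80% crossings of the central-axis dose by
#' linear interpolation between bracketing samples and reports the
#' 20--80% penumbra. With multiple crossings of a level the outermost
#' one is used, with a warning.
#'
#' @param profile a [dose_profile()].
#' @return list with `x50`, `x20`, `x80` (cm) and `penumbra_mm`.
#' @export
extract_edge_metrics <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  levels <- c(x50 = 0.5, x20 = 0.2, x80 = 0.8) * profile$central_axis_dose
  res <- lapply(levels, function(L)
    .find_crossing(profile$positions, profile$doses, L))
  missing <- names(res)[vapply(res, function(r) r$n == 0L, logical(1))]
  if (length(missing)) {
    stop("edge not found: profile does not cross the ",
         paste(sub("^x", "", missing), collapse = "/"),
         "% dose level", call. = FALSE)
  }
  if (any(vapply(res, `[[`, 0L, "n") > 1L)) {
    warning("multiple level crossings; using the outermost edge")
  }
  list(x50 = res$x50$x, x20 = res$x20$x, x80 = res$x80$x,
       penumbra_mm = abs(res$x20$x - res$x80$x) * 10)
}

#' Generate seeded leaf-edge profile fixtures
#'
#' Writes `n_cases` ray-traced edge profiles as two-column CSV files
#' (`position_cm,dose_rel`) plus a JSON manifest holding each case's
#' parameters and the analytic generator truth (X50/X20/X80, model
#' penumbra). Cases sample the shipped materials and half-fields
#' uniformly in [1, 6] cm; optional additive Gaussian noise on relative
#' dose. Deterministic and byte-reproducible for a given seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer RNG seed.
#' @param n_cases number of fixture cases.
#' @param noise_sd additive Gaussian noise sigma on relative dose
#'   (0 = noiseless).
#' @param materials named list of [mlc_material()]s to sample from.
#' @param geom a [beamline_geometry()].
#' @param grid sampling step near the edge, cm.
#' @return invisibly, the manifest as a list.
#' @export
generate_fixture_profiles <- function(dir, seed, n_cases = 5, noise_sd = 0,
                                      materials = mlc_materials(),
                                      geom = beamline_geometry(),
                                      grid = 0.001) {
  stopifnot(length(seed) == 1L, is.finite(seed), n_cases >= 1L, noise_sd >= 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  cases <- vector("list", n_cases)
  for (k in seq_len(n_cases)) {
    mat <- materials[[sample(length(materials), 1L)]]
    h <- round(stats::runif(1, 1, 6), 3)
    setting <- leaf_setting(h)
    xt <- x_tang(setting, geom)
    x_max <- geom$sad * abs(leaf_lateral_position(setting, geom)) /
      (geom$source_to_leaf_bottom - mat$thickness)
    positions <- seq(xt - 0.05, x_max - 1e-9, by = grid)
    prof <- trace_profile(setting, mat, geom, positions)
    doses <- prof$doses
    if (noise_sd > 0) doses <- pmax(0, doses + stats::rnorm(length(doses), 0, noise_sd))
    file <- file.path(dir, sprintf("case_%03d.csv", k))
    lines <- c("position_cm,dose_rel",
               sprintf("%.6f,%.8f", positions, doses))
    writeLines(lines, file)
    cases[[k]] <- list(
      file = basename(file), material = mat$name, half_field = h,
      noise_sd = noise_sd,
      truth = list(x50 = solve_x_p(setting, mat, geom, 0.5),
                   x20 = solve_x_p(setting, mat, geom, 0.2),
                   x80 = solve_x_p(setting, mat, geom, 0.8),
                   model_penumbra_mm = model_penumbra(setting, mat, geom)))
  }
  manifest <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                   grid_cm = grid, noise_sd = noise_sd, cases = cases)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dose-profile CSV
#'
#' Two columns, header `position_cm,dose_rel`.
#'
#' @param path CSV file.
#' @param central_axis_dose reference dose.
#' @return a [dose_profile()].
#' @export
read_dose_profile <- function(path, central_axis_dose = 1) {
  df <- utils::read.csv(path)
  if (!all(c("position_cm", "dose_rel") %in% names(df))) {
    stop("profile CSV must have columns position_cm,dose_rel", call. = FALSE)
  }
  dose_profile(df$position_cm, df$dose_rel, central_axis_dose)
}
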