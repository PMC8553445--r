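#' Construct an MLC leaf material
#'
#' A material is the combination of a leaf alloy (composition, density),
#' the physical leaf thickness along the beam axis, and the attenuation
#' length \eqn{\lambda} (interaction mean free path, often called the
#' straggling range in this context) that governs exponential survival of
#' carbon-ion nuclei traversing the leaf.
#'
#' @param name short identifier, e.g. `"W100"` or `"W90Cu10"`.
#' @param composition named numeric vector of element weight percents,
#'   e.g. `c(W = 90, Cu = 10)`. Must sum to 100 within 0.5.
#' @param density bulk density in g/cm^3.
#' @param thickness leaf thickness along the beam, cm.
#' @param lambda attenuation length \eqn{\lambda}, cm.
#' @param straggling_range tabulated straggling range, cm. Defaults to
#'   `lambda`; kept as a separate field because the tungsten convention
#'   assigns \eqn{\lambda} = 2.7 cm while its tabulated straggling range
#'   is 2.62 cm.
#'
#' @return an object of class `"mlc_material"`.
#' @seealso [mlc_materials()] for the shipped nine-material database.
#' @export
#' @examples
#' w <- mlc_material("W100", c(W = 100), density = 19.3,
#'                   thickness = 6.24, lambda = 2.7,
#'                   straggling_range = 2.62)
#' survival_fraction(w$lambda * log(2), w)  # 0.5 by construction
mlc_material <- function(name, composition, density, thickness, lambda,
                         straggling_range = lambda) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (field in c("density", "thickness", "lambda", "straggling_range")) {
    v <- get(field)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("material '%s': field '%s' must be a positive number",
                   name, field), call. = FALSE)
    }
  }
  if (!is.numeric(composition) || is.null(names(composition)) ||
      any(!nzchar(names(composition))) || any(composition <= 0)) {
    stop(sprintf("material '%s': field 'composition' must be a named vector of positive weight percents",
                 name), call. = FALSE)
  }
  if (abs(sum(composition) - 100) > 0.5) {
    stop(sprintf("material '%s': field 'composition' sums to %.3f, expected 100 +/- 0.5",
                 name, sum(composition)), call. = FALSE)
  }
  structure(
    list(name = name, composition = composition, density = density,
         thickness = thickness, lambda = lambda,
         straggling_range = straggling_range),
    class = "mlc_material")
}

#' @export
print.mlc_material <- function(x, ...) {
  comp <- paste(sprintf("%s %.4g%%", names(x$composition), x$composition),
                collapse = ", ")
  cat(sprintf("MLC material %s (%s)\n", x$name, comp))
  cat(sprintf("  density %.4g g/cm^3, thickness %.4g cm, lambda %.4g cm, straggling range %.4g cm\n",
              x$density, x$thickness, x$lambda, x$straggling_range))
  invisible(x)
}

#' Fraction of beam nuclei surviving a material path
#'
#' Single-exponential survival \eqn{N/N_B = e^{-x/\lambda}} of incident
#' nuclei after traversing `path_length` of leaf material. This is the
#' whole attenuation model: no energy-loss or scatter physics.
#'
#' @param path_length material path, cm; non-negative.
#' @param material an [mlc_material()].
#' @return surviving fraction in (0, 1].
#' @export
survival_fraction <- function(path_length, material) {
  stopifnot(inherits(material, "mlc_material"))
  if (any(!is.finite(path_length)) || any(path_length < 0)) {
    stop("path_length must be finite and >= 0", call. = FALSE)
  }
  exp(-path_length / material$lambda)
}

#' Material path length attaining a given survival fraction
#'
#' Inverse of [survival_fraction()]: \eqn{-\lambda \ln p}. With
#' `p = 0.5` this is the half-value path \eqn{d_{50} = \lambda \ln 2},
#' e.g. 1.8715 cm for tungsten with \eqn{\lambda} = 2.7 cm.
#'
#' @param p target survival fraction, strictly between 0 and 1.
#' @inheritParams survival_fraction
#' @return path length in cm.
#' @export
path_for_survival <- function(p, material) {
  stopifnot(inherits(material, "mlc_material"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("survival fraction p must lie strictly inside (0, 1)", call. = FALSE)
  }
  -material$lambda * log(p)
}

.parse_composition <- function(s, name) {
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, function(x) length(x) != 2L, logical(1))
  if (length(kv) == 0L || any(bad)) {
    stop(sprintf("material '%s': field 'composition' is malformed ('%s'); expected 'El:pct;El:pct'",
                 name, s), call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 2L)))
  names(v) <- trimws(vapply(kv, `[[`, "", 1L))
  if (any(is.na(v))) {
    stop(sprintf("material '%s': non-numeric weight percent in composition '%s'",
                 name, s), call. = FALSE)
  }
  v
}

#' Load a material table from CSV
#'
#' Reads a material database with columns `name, composition,
#' density_g_cm3, thickness_cm, straggling_range_cm, lambda_cm`. The
#' `lambda_cm` column may be empty; a missing attenuation length falls
#' back to the straggling range, which is the convention for every
#' shipped material except tungsten (whose \eqn{\lambda} is 2.7 cm and is
#' stated explicitly in the file).
#'
#' @param path CSV file path. Defaults to the shipped nine-material table.
#' @return named list of [mlc_material()] objects, in file order.
#' @export
load_material_table <- function(path = system.file("extdata", "mlc_materials.csv",
                                                   package = "mlcoffset")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("material table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("material table is empty: ", path, call. = FALSE)
  required <- c("name", "composition", "density_g_cm3", "thickness_cm",
                "straggling_range_cm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("material table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mats <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    lam <- if ("lambda_cm" %in% names(df) && !is.na(row$lambda_cm) &&
               nzchar(trimws(as.character(row$lambda_cm)))) {
      as.numeric(row$lambda_cm)
    } else {
      row$straggling_range_cm
    }
    mlc_material(name = as.character(row$name),
                 composition = .parse_composition(row$composition, row$name),
                 density = row$density_g_cm3,
                 thickness = row$thickness_cm,
                 lambda = lam,
                 straggling_range = row$straggling_range_cm)
  })
  names(mats) <- vapply(mats, `[[`, "", "name")
  mats
}

#' Shipped nine-material MLC database
#'
#' Convenience accessor for the package's candidate leaf materials
#' (pure tungsten, tungsten-copper alloys, iron, nickel, copper, brass,
#' stainless steel and aluminium), with their densities, leaf
#' thicknesses and attenuation lengths for a 400 MeV/n carbon-ion beam.
#'
#' @return named list of [mlc_material()] objects.
#' @export
#' @examples
#' names(mlc_materials())
mlc_materials <- function() {
  load_material_table()
}
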