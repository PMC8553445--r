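# Published reference values for the tungsten per-field table and the
# nine-material offset matrix, used by the regeneration tests. The
# source pipeline carried radians quantized to 4 decimals, so its
# dose-point columns scatter by up to ~0.033 mm around the smooth model;
# regeneration is checked inside a 0.04 mm envelope at half-fields
# >= 2 cm, where the relative effect of that jitter is bounded.

ref_half_fields <- seq(0.5, 9, by = 0.5)

ref_t2_offset_mm <- c(-0.0301, -0.0510, -0.0763, -0.1248, -0.1729, -0.1979,
                      -0.2421, -0.2767, -0.3112, -0.3458, -0.3606, -0.3689,
                      -0.4288, -0.4379, -0.4724, -0.5068, -0.5413, -0.5757)

ref_t2_light_rad_mm <- c(-0.0504, -0.11004, -0.16515, -0.19739, -0.22978,
                         -0.28534, -0.32171, -0.36769, -0.41367, -0.45967,
                         -0.52544, -0.59767, -0.61831, -0.68975, -0.73581,
                         -0.78189, -0.82798, -0.87409)

# rows in shipped material order, columns half-fields 1..9 cm
ref_t3_offset_mm <- rbind(
  W100     = c(-0.05101, -0.12479, -0.19793, -0.27667, -0.34578, -0.36887, -0.43788, -0.50684, -0.57572),
  W90Cu10  = c(-0.07208, -0.14874, -0.22080, -0.30202, -0.36022, -0.44136, -0.49946, -0.58049, -0.64328),
  W50Cu50  = c(-0.08587, -0.17915, -0.25441, -0.33522, -0.41607, -0.51409, -0.61493, -0.68951, -0.76274),
  Fe100    = c(-0.10829, -0.21594, -0.32435, -0.43254, -0.54067, -0.65289, -0.74210, -0.86690, -0.97680),
  Ni100    = c(-0.09836, -0.19210, -0.29042, -0.38640, -0.48112, -0.57674, -0.67966, -0.76811, -0.86531),
  Cu100    = c(-0.10312, -0.19007, -0.29900, -0.39392, -0.50628, -0.61128, -0.71152, -0.79512, -0.89624),
  Cu59Zn41 = c(-0.10505, -0.21154, -0.31712, -0.41582, -0.51550, -0.63130, -0.72990, -0.84279, -0.94332),
  SS304    = c(-0.10681, -0.21337, -0.32270, -0.42765, -0.53213, -0.62525, -0.73477, -0.84632, -0.95621),
  Al100    = c(-0.25469, -0.51498, -0.77095, -1.02784, -1.28281, -1.54666, -1.79796, -2.06729, -2.31803))

test_geom <- function() beamline_geometry()

test_materials <- function() mlc_materials()

# leaf setting beyond the rated half-field without the rating warning
quiet_setting <- function(h) {
  withCallingHandlers(leaf_setting(h), mlcoffset_beyond_max_field = function(w)
    invokeRestart("muffleWarning"))
}

# evaluate an expression with the rated-field warning muffled
quiet_field <- function(expr) {
  withCallingHandlers(expr, mlcoffset_beyond_max_field = function(w)
    invokeRestart("muffleWarning"))
}
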