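#' Amino-acid property scales
#'
#' Tabulated per-residue scales used throughout the package: the
#' Kyte-Doolittle hydropathy scale, the Rose mean-fractional-area-loss
#' (buriedness) scale, and a configurable integer charge scheme.
#'
#' The charge scheme assigns +1 to arginine and lysine and -1 to aspartate
#' and glutamate; histidine and the chain termini are neutral by default,
#' which is the convention at physiological pH for the charge census of
#' low-charge storage proteins. Histidine can be switched to +1 with
#' `his_positive = TRUE`.
#'
#' @param name One of `"kyte_doolittle"`, `"rose"`, `"charge_scheme"`.
#' @param his_positive For `"charge_scheme"` only: count histidine as +1.
#' @return An object of class `residue_scale`: a named list with `name`
#'   (scale identifier) and `values` (named numeric vector over the 20
#'   standard one-letter codes).
#' @examples
#' kd <- residue_scale("kyte_doolittle")
#' scale_lookup(kd, "I")   # 4.5, most hydrophobic
#' scale_lookup(residue_scale("charge_scheme"), "K")  # +1
#' @export
residue_scale <- function(name = c("kyte_doolittle", "rose", "charge_scheme"),
                          his_positive = FALSE) {
  name <- match.arg(name)
  values <- switch(name,
    kyte_doolittle = c(
      A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
      L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2),
    rose = c(
      A = 0.74, R = 0.64, N = 0.63, D = 0.62, C = 0.91,
      Q = 0.62, E = 0.62, G = 0.72, H = 0.78, I = 0.88,
      L = 0.85, K = 0.52, M = 0.85, F = 0.88, P = 0.64,
      S = 0.66, T = 0.70, W = 0.85, Y = 0.76, V = 0.86),
    charge_scheme = {
      v <- stats::setNames(rep(0, 20), AA_CODES)
      v[c("R", "K")] <- 1
      v[c("D", "E")] <- -1
      if (his_positive) v["H"] <- 1
      v
    })
  structure(list(name = name, values = values[AA_CODES]),
            class = "residue_scale")
}

# the 20 standard one-letter amino-acid codes, fixed order
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Look up a residue's scale value
#'
#' @param table A `residue_scale` object.
#' @param residue A one-letter amino-acid code (vectorised).
#' @return Numeric scale value(s).
#' @export
scale_lookup <- function(table, residue) {
  stopifnot(inherits(table, "residue_scale"))
  bad <- !(residue %in% AA_CODES)
  if (any(bad)) {
    stop("unknown residue code(s): ", paste(unique(residue[bad]), collapse = ", "))
  }
  unname(table$values[residue])
}

#' @export
print.residue_scale <- function(x, ...) {
  cat("Residue scale:", x$name, "\n")
  print(round(x$values, 3))
  invisible(x)
}
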