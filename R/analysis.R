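#' Radius of gyration
#'
#' Root-mean-square distance of beads from their centroid (unit masses).
#' For an ensemble, recomputed from the saved coordinates frame by frame.
#'
#' @param x An n x 3 coordinate matrix, a `chain_conformation`, a list of
#'   coordinate matrices, or a `cg_ensemble`.
#' @return Rg in Angstrom (scalar, or vector with one value per frame).
#' @export
radius_of_gyration <- function(x) {
  frames <- as_frames(x)
  vapply(frames, function(fr) {
    if (nrow(fr) == 0L) stop("empty configuration")
    ctr <- colMeans(fr)
    sqrt(mean(rowSums(sweep(fr, 2, ctr)^2)))
  }, numeric(1))
}

#' End-to-end distance (first to last chain bead)
#'
#' @inheritParams radius_of_gyration
#' @return Ree in Angstrom per frame.
#' @export
end_to_end <- function(x) {
  frames <- as_frames(x)
  vapply(frames, function(fr) {
    if (nrow(fr) < 2L) stop("end-to-end distance needs at least 2 beads")
    sqrt(sum((fr[nrow(fr), ] - fr[1, ])^2))
  }, numeric(1))
}

# normalise the accepted inputs into a list of coordinate matrices
as_frames <- function(x) {
  if (inherits(x, "cg_ensemble")) {
    if (length(x$frames) == 0L) stop("ensemble holds no saved frames")
    return(x$frames)
  }
  if (inherits(x, "chain_conformation")) return(list(x$coords))
  if (is.matrix(x)) return(list(x))
  if (is.list(x) && length(x) > 0L) return(lapply(x, as.matrix))
  stop("cannot interpret input as configuration frame(s)")
}

#' Ensemble shape statistics
#'
#' The shape factor `R_shape = <Ree^2> / <Rg^2>` distinguishes globules
#' (about 1), self-avoiding random walks (about 6), and extended rods
#' (about 12). Also reports Rg moments and the single-point Flory exponent
#' derived from the mean Rg via `Rg = R0 N^nu`.
#'
#' @inheritParams radius_of_gyration
#' @param R0 Flory prefactor in Angstrom (default 2, the experimental
#'   value for proteins).
#' @return An object of class `shape_stats`: `mean_Rg`, `var_Rg`,
#'   `mean_sq_Rg`, `mean_sq_Ree`, `R_shape`, `nu`, `R0`, `N`, `n_frames`.
#' @examples
#' shape_factor(generate_rod(1000, 4.1))$R_shape  # close to 12
#' @export
shape_factor <- function(x, R0 = 2) {
  frames <- as_frames(x)
  if (nrow(frames[[1]]) < 2L) {
    stop("shape factor is undefined for single-bead chains")
  }
  rg <- radius_of_gyration(frames)
  ree <- end_to_end(frames)
  mean_sq_rg <- mean(rg^2)
  mean_sq_ree <- mean(ree^2)
  N <- nrow(frames[[1]])
  structure(list(
    mean_Rg = mean(rg),
    var_Rg = if (length(rg) > 1L) stats::var(rg) else 0,
    mean_sq_Rg = mean_sq_rg,
    mean_sq_Ree = mean_sq_ree,
    R_shape = mean_sq_ree / mean_sq_rg,
    nu = unname(coef(flory_fit(mean(rg), N = N, R0 = R0))["nu"]),
    R0 = R0, N = N, n_frames = length(frames)
  ), class = "shape_stats")
}

#' @export
print.shape_stats <- function(x, ...) {
  cat(sprintf(
    "Shape statistics (%d frames, N = %d):\n  mean Rg %.3f A (var %.3f)\n",
    x$n_frames, x$N, x$mean_Rg, x$var_Rg))
  cat(sprintf("  <Ree^2>/<Rg^2> = %.3f;  Flory nu (R0 = %g A) = %.3f\n",
              x$R_shape, x$R0, x$nu))
  invisible(x)
}

#' Fit the Flory scaling law
#'
#' `Rg = R0 * N^nu`. In single-point mode (one Rg, one N) the exponent is
#' `nu = log(Rg / R0) / log(N)`. In regression mode (a data frame with
#' columns `N` and `rg`, at least 3 distinct N) the slope of
#' `log Rg ~ log N` is fit by least squares, with the intercept fixed at
#' `log R0` when `R0` is supplied or free when `R0 = NULL` (the free fit
#' also estimates the prefactor).
#'
#' @param data Either a single mean Rg (with `N` given), or a data frame /
#'   list with components `N` and `rg`.
#' @param N Residue count (single-point mode).
#' @param R0 Prefactor in Angstrom; `NULL` for a free intercept
#'   (regression mode only).
#' @return An object of class `flory_fit` with `nu`, `R0`, `mode`, and the
#'   input data; methods: `print`, `coef`, `predict`.
#' @examples
#' coef(flory_fit(47.9, N = 265))["nu"]  # about 0.57
#' @export
flory_fit <- function(data, N = NULL, R0 = 2) {
  if (is.numeric(data) && length(data) == 1L && !is.null(N)) {
    if (data <= 0) stop("Rg must be positive")
    if (N < 2) stop("N must be >= 2")
    if (is.null(R0)) stop("single-point mode needs a fixed R0")
    nu <- log(data / R0) / log(N)
    if (nu <= 0) {
      warning("Rg <= R0 gives a non-positive Flory exponent (collapsed ",
              "beyond the scaling regime)")
    }
    out <- list(nu = nu, R0 = R0, mode = "single_point",
                data = data.frame(N = N, rg = data))
  } else {
    df <- as.data.frame(data)
    if (!all(c("N", "rg") %in% names(df))) {
      stop("regression mode expects columns 'N' and 'rg'")
    }
    if (any(df$rg <= 0) || any(df$N < 2)) stop("need rg > 0 and N >= 2")
    if (length(unique(df$N)) < 3L) {
      stop("regression mode needs at least 3 distinct chain lengths")
    }
    if (is.null(R0)) {
      fit <- stats::lm(log(rg) ~ log(N), data = df)
      nu <- unname(stats::coef(fit)[2])
      R0 <- unname(exp(stats::coef(fit)[1]))
    } else {
      x <- log(df$N)
      y <- log(df$rg) - log(R0)
      nu <- sum(x * y) / sum(x * x)
    }
    out <- list(nu = nu, R0 = R0, mode = "regression", data = df)
  }
  class(out) <- "flory_fit"
  out
}

#' @export
print.flory_fit <- function(x, ...) {
  cat(sprintf("Flory fit (%s): nu = %.4f, R0 = %.4g A  [Rg = R0 * N^nu]\n",
              x$mode, x$nu, x$R0))
  cat("  nu ~ 1/3 collapsed, 1/2 theta solvent, 3/5 good solvent\n")
  invisible(x)
}

#' @export
coef.flory_fit <- function(object, ...) {
  c(nu = object$nu, R0 = object$R0)
}

#' @export
predict.flory_fit <- function(object, N = object$data$N, ...) {
  object$R0 * N^object$nu
}

#' Radius-of-gyration distribution
#'
#' Normalised probability density of per-frame Rg with sample mean and
#' variance.
#'
#' @param x A `cg_ensemble`, frames, or a numeric vector of Rg values.
#' @param n_bins Number of histogram bins.
#' @return An object of class `rg_distribution`: `breaks`, `density`,
#'   `mids`, `mean`, `variance`, `rg` (the per-frame values).
#' @export
rg_distribution <- function(x, n_bins = 30L) {
  rg <- if (is.numeric(x)) x else radius_of_gyration(x)
  if (length(rg) == 0L) stop("no configurations")
  rng <- range(rg)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # degenerate: identical frames
  h <- graphics::hist(rg, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  structure(list(
    breaks = h$breaks, density = h$density, mids = h$mids,
    mean = mean(rg), variance = if (length(rg) > 1L) stats::var(rg) else 0,
    rg = rg
  ), class = "rg_distribution")
}

#' @export
print.rg_distribution <- function(x, ...) {
  cat(sprintf("Rg distribution: %d frames, mean %.2f A, variance %.2f A^2\n",
              length(x$rg), x$mean, x$variance))
  invisible(x)
}

#' @export
plot.rg_distribution <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "h", lwd = 3,
                 xlab = "Rg (A)", ylab = "probability density", ...)
  graphics::abline(v = x$mean, lty = 2)
  invisible(x)
}

#' Debye scattering curve and Kratky transform
#'
#' Orientation-averaged scattering intensity from coordinates,
#' `I(q) = sum_ij f_i f_j sin(q r_ij) / (q r_ij)` (the `q -> 0` limit gives
#' the forward intensity `I0 = (sum f)^2`), ensemble-averaged over frames.
#' The dimensionless Kratky transform `(q Rg)^2 I / I0` against `q Rg` uses
#' the ensemble-mean Rg; it plateaus near 2 for ideal chains and rises for
#' extended shapes.
#'
#' @inheritParams radius_of_gyration
#' @param q Scattering-vector grid in inverse Angstrom; defaults to a grid
#'   covering `q Rg` up to about 15.
#' @param f Per-bead form factor (scalar or vector, default identical 1).
#' @return An object of class `scattering_curve`: `q`, `I`, `I0`,
#'   `kratky_x`, `kratky_y`, `Rg`.
#' @export
debye_scattering <- function(x, q = NULL, f = 1) {
  frames <- as_frames(x)
  n <- nrow(frames[[1]])
  f <- rep_len(f, n)
  rg_mean <- mean(radius_of_gyration(frames))
  if (is.null(q)) {
    q <- seq(0.005, 15 / max(rg_mean, 1e-6), length.out = 80)
  }
  if (any(q < 0)) stop("q values must be non-negative")
  I <- rowMeans(vapply(frames, function(fr) cpp_debye_intensity(fr, q, f),
                       numeric(length(q))))
  I0 <- sum(f)^2
  structure(list(
    q = q, I = I, I0 = I0,
    kratky_x = q * rg_mean,
    kratky_y = (q * rg_mean)^2 * I / I0,
    Rg = rg_mean, n_frames = length(frames)
  ), class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf(
    "Debye scattering curve: %d q-points, %d frame(s), I0 = %g, Rg = %.2f A\n",
    length(x$q), x$n_frames, x$I0, x$Rg))
  invisible(x)
}

#' @export
plot.scattering_curve <- function(x, kratky = TRUE, ...) {
  if (kratky) {
    graphics::plot(x$kratky_x, x$kratky_y, type = "l", xlab = "q Rg",
                   ylab = "(q Rg)^2 I/I0", main = "Kratky plot", ...)
  } else {
    graphics::plot(x$q, x$I / x$I0, type = "l", log = "y",
                   xlab = "q (1/A)", ylab = "I/I0", ...)
  }
  invisible(x)
}

#' Guinier estimate of Rg from a scattering curve
#'
#' Fits `log I = log I0 - (q Rg)^2 / 3` on the low-q region `q Rg < qmax`.
#'
#' @param curve A [debye_scattering()] result.
#' @param qmax Upper limit of `q * Rg` for the fit window (default 1).
#' @return Estimated Rg in Angstrom.
#' @export
guinier_rg <- function(curve, qmax = 1) {
  stopifnot(inherits(curve, "scattering_curve"))
  sel <- curve$kratky_x < qmax & curve$q > 0
  if (sum(sel) < 3L) stop("too few points in the Guinier window")
  fit <- stats::lm(log(I) ~ I(q^2),
                   data = data.frame(q = curve$q[sel], I = curve$I[sel]))
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("non-negative Guinier slope; curve is not decaying")
  sqrt(-3 * slope)
}

#' Ensemble contact map
#'
#' Frequency, over frames, that two bead centres lie within `cutoff`,
#' excluding near-diagonal pairs with `|i - j| <= exclusion`. The bead
#' default cutoff is 8 Angstrom (side-chain reach plus contact for one-bead
#' residues; the atomistic convention of 5 Angstrom between side-chain
#' atoms has no direct bead analogue).
#'
#' @inheritParams radius_of_gyration
#' @param cutoff Contact distance in Angstrom.
#' @param exclusion Adjacency exclusion width (default 1: bonded
#'   neighbours never count).
#' @return An object of class `contact_map`: symmetric n x n `frequency`
#'   matrix of values between 0 and 1, plus `cutoff`, `exclusion`,
#'   `n_frames`.
#' @export
contact_map <- function(x, cutoff = 8, exclusion = 1L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  frames <- as_frames(x)
  n <- nrow(frames[[1]])
  acc <- matrix(0, n, n)
  for (fr in frames) {
    acc <- acc + cpp_contact_indicator(fr, cutoff, as.integer(exclusion))
  }
  structure(list(
    frequency = acc / length(frames),
    cutoff = cutoff, exclusion = as.integer(exclusion),
    n_frames = length(frames)
  ), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  n <- nrow(x$frequency)
  cat(sprintf(
    "Contact map: %d x %d, cutoff %.1f A, exclusion %d, %d frame(s); %d pair(s) with freq > 0.5\n",
    n, n, x$cutoff, x$exclusion, x$n_frames,
    sum(x$frequency[upper.tri(x$frequency)] > 0.5)))
  invisible(x)
}

#' @export
plot.contact_map <- function(x, ...) {
  n <- nrow(x$frequency)
  graphics::image(1:n, 1:n, x$frequency, xlab = "residue", ylab = "residue",
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  main = "contact frequency", ...)
  invisible(x)
}

#' Cysteine contact network
#'
#' Restriction of the ensemble contact frequencies to cysteine pairs, with
#' the adjacency rule applied, so vicinal cysteines (|i - j| <= exclusion)
#' carry no data.
#'
#' @inheritParams contact_map
#' @param cys_positions 1-based cysteine positions; defaults to the
#'   ensemble's own annotation.
#' @return An object of class `cys_network`: data frame with columns `i`,
#'   `j`, `frequency` (one row per non-vicinal cysteine pair) and the node
#'   list as attribute `nodes`.
#' @export
cys_contact_network <- function(x, cys_positions = NULL, cutoff = 8,
                                exclusion = 1L) {
  if (is.null(cys_positions) && inherits(x, "cg_ensemble")) {
    cys_positions <- x$cys_positions
  }
  cys_positions <- sort(unique(as.integer(cys_positions)))
  empty <- data.frame(i = integer(), j = integer(), frequency = numeric())
  if (length(cys_positions) < 2L) {
    return(structure(empty, nodes = cys_positions, class = c("cys_network", "data.frame")))
  }
  cm <- contact_map(x, cutoff = cutoff, exclusion = exclusion)
  n <- nrow(cm$frequency)
  if (any(cys_positions < 1L | cys_positions > n)) {
    stop("cysteine positions out of chain bounds (1..", n, ")")
  }
  pairs <- utils::combn(cys_positions, 2)
  keep <- (pairs[2, ] - pairs[1, ]) > exclusion
  df <- data.frame(
    i = pairs[1, keep], j = pairs[2, keep],
    frequency = cm$frequency[cbind(pairs[1, keep], pairs[2, keep])])
  structure(df, nodes = cys_positions, class = c("cys_network", "data.frame"))
}

#' @export
print.cys_network <- function(x, ...) {
  cat("Cysteine contact network:", length(attr(x, "nodes")), "cysteine(s),",
      nrow(x), "scored pair(s)\n")
  if (nrow(x) > 0) print.data.frame(x[order(-x$frequency), ], row.names = FALSE)
  invisible(x)
}

#' Write a scattering curve or contact map as CSV
#'
#' Curves are written as columns `q, I, I0, kratky_x, kratky_y`; maps as
#' tidy triplets `i, j, frequency` (upper triangle, excluded pairs
#' omitted).
#'
#' @param x A `scattering_curve` or `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  if (inherits(x, "scattering_curve")) {
    utils::write.csv(data.frame(q = x$q, I = x$I, I0 = x$I0,
                                kratky_x = x$kratky_x, kratky_y = x$kratky_y),
                     path, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "contact_map")) {
    n <- nrow(x$frequency)
    idx <- which(upper.tri(x$frequency), arr.ind = TRUE)
    keep <- (idx[, 2] - idx[, 1]) > x$exclusion
    utils::write.csv(data.frame(i = idx[keep, 1], j = idx[keep, 2],
                                frequency = x$frequency[idx[keep, , drop = FALSE]]),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    stop("x must be a scattering_curve or contact_map")
  }
  invisible(path)
}
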