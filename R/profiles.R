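#' Windowed hydropathy profile
#'
#' Slides an odd-width window along the sequence and assigns the unweighted
#' mean of the scale values to the centre residue. Only full windows are
#' scored (no edge padding), matching the ProtScale convention, so the
#' profile has `length(seq) - window + 1` positions. The profile `mean` is
#' the accumulated hydropathy index of the chain; `variation` is reported as
#' the population variance of the windowed values (sample variance and
#' standard deviation are also attached).
#'
#' @param seq A [protein_sequence()].
#' @param table A [residue_scale()] (typically Kyte-Doolittle or Rose).
#' @param window Odd window width in residues (default 15).
#' @return An object of class `hydropathy_profile` with fields `scale_name`,
#'   `window`, `positions` (1-based centre indices), `residues` (centre
#'   residues), `values`, `mean`, `variation`, `var_sample`, `sd`.
#' @examples
#' s <- protein_sequence(strrep("A", 30))
#' p <- hydropathy_profile(s, residue_scale("kyte_doolittle"), 15)
#' all(p$values == 1.8)
#' @export
hydropathy_profile <- function(seq, table = residue_scale("kyte_doolittle"),
                               window = 15L) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(table, "residue_scale"))
  window <- as.integer(window)
  n <- length(seq$residues)
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  if (window < 1L || window > n) {
    stop("window must be in [1, sequence length = ", n, "], got ", window)
  }
  raw <- scale_lookup(table, seq$residues)
  # running mean over full windows via cumulative sums
  cs <- c(0, cumsum(raw))
  values <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  half <- (window - 1L) %/% 2L
  positions <- (half + 1L):(n - half)
  m <- mean(values)
  structure(list(
    scale_name = table$name,
    window = window,
    positions = positions,
    residues = seq$residues[positions],
    values = values,
    mean = m,
    variation = mean((values - m)^2),
    var_sample = stats::var(values),
    sd = stats::sd(values)
  ), class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat("Hydropathy profile (", x$scale_name, ", window ", x$window, "): ",
      length(x$values), " positions\n", sep = "")
  cat(sprintf("  accumulated index (mean) %.3f, variance %.3f (sd %.3f)\n",
              x$mean, x$variation, x$sd))
  invisible(x)
}

#' @describeIn hydropathy_profile Write a profile as CSV
#'   (columns position, residue, value).
#' @param x A `hydropathy_profile`.
#' @param path Output CSV path.
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(inherits(x, "hydropathy_profile"))
  utils::write.csv(
    data.frame(position = x$positions, residue = x$residues, value = x$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Charge census of a sequence
#'
#' Counts positive and negative residues under a charge scheme and derives
#' the standard disorder-phase-diagram quantities: fractions of positive and
#' negative residues, fraction of charged residues FCR = f+ + f-, net charge
#' per residue NCPR = f+ - f-, plus the diagram-of-states region label (see
#' [das_pappu_classify()]).
#'
#' @param seq A [protein_sequence()].
#' @param scheme A `charge_scheme` [residue_scale()].
#' @return An object of class `charge_census` with fields `n_pos`, `n_neg`,
#'   `net`, `f_pos`, `f_neg`, `FCR`, `NCPR`, `das_pappu_region`, `length`.
#' @examples
#' charge_census(protein_sequence("KKDD"))$FCR  # 1
#' @export
charge_census <- function(seq, scheme = residue_scale("charge_scheme")) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (scheme$name != "charge_scheme") {
    stop("scheme must be a charge_scheme residue_scale, got '",
         scheme$name, "'")
  }
  q <- scale_lookup(scheme, seq$residues)
  n <- length(q)
  n_pos <- sum(q > 0)
  n_neg <- sum(q < 0)
  out <- structure(list(
    n_pos = n_pos, n_neg = n_neg, net = n_pos - n_neg,
    f_pos = n_pos / n, f_neg = n_neg / n,
    FCR = (n_pos + n_neg) / n, NCPR = (n_pos - n_neg) / n,
    das_pappu_region = NA_character_, length = n
  ), class = "charge_census")
  out$das_pappu_region <- das_pappu_classify(out)
  out
}

#' @export
print.charge_census <- function(x, ...) {
  cat(sprintf(
    "Charge census (%d residues): %d+/%d- (net %+d), f+ %.3f, f- %.3f, FCR %.3f, NCPR %+.3f -> %s\n",
    x$length, x$n_pos, x$n_neg, x$net, x$f_pos, x$f_neg, x$FCR, x$NCPR,
    x$das_pappu_region))
  invisible(x)
}

#' @describeIn charge_census Write a census as JSON.
#' @param x A `charge_census`.
#' @param path Output JSON path.
#' @export
write_census_json <- function(x, path) {
  stopifnot(inherits(x, "charge_census"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Diagram-of-states classification of disordered proteins
#'
#' Assigns the conformational class region of the charge phase diagram for
#' intrinsically disordered proteins from the fractions of positive and
#' negative residues: R1 weak polyampholytes/polyelectrolytes (globules and
#' tadpoles, FCR < 0.25), R2 boundary region (0.25 <= FCR <= 0.35), R3
#' strong polyampholytes (both fractions > 0.35: coils, hairpins, chimeras),
#' R4/R5 strong positive/negative polyelectrolytes (semi-flexible coils).
#' Ties on boundaries resolve to the lower-numbered region.
#'
#' @param census A [charge_census()] (or any list with `f_pos`, `f_neg`).
#' @return Region label, one of `"R1"` ... `"R5"`.
#' @export
das_pappu_classify <- function(census) {
  fp <- census$f_pos
  fn <- census$f_neg
  fcr <- fp + fn
  if (fcr < 0.25) return("R1")
  if (fcr <= 0.35) return("R2")
  if (fp > 0.35 && fn > 0.35) return("R3")
  if (fp > 0.35) return("R4")
  if (fn > 0.35) return("R5")
  # FCR > 0.35 with neither fraction dominant: strong polyampholyte mix
  "R3"
}

#' Hydropathy context of cysteines
#'
#' For each cysteine, reports the windowed hydropathy value at its position
#' (or the nearest scored position when the cysteine lies in the
#' window-truncated terminal region, flagged in `edge`). Residues with
#' context above `threshold` are classified hydrophobic; this is the
#' sequence feature that distinguishes intramolecular disulfide-forming
#' cysteines (hydrophobic neighbourhoods) from the intermolecular,
#' cytosol-exposed ones in LMW glutenin subunits.
#'
#' @param seq A [protein_sequence()].
#' @param profile A [hydropathy_profile()] computed on the same sequence.
#' @param threshold Classification threshold (default 0).
#' @return A data frame with columns `cys` (1-based position), `context`
#'   (profile value), `class` (`"hydrophobic"`/`"hydrophilic"`), `edge`
#'   (TRUE if the nearest scored position was used).
#' @export
cys_context <- function(seq, profile = hydropathy_profile(seq),
                        threshold = 0) {
  stopifnot(inherits(seq, "protein_sequence"),
            inherits(profile, "hydropathy_profile"))
  if (length(profile$positions) + profile$window - 1L != length(seq$residues)) {
    stop("profile was not computed on this sequence (length mismatch)")
  }
  cys <- seq$cys_positions
  if (length(cys) == 0L) {
    return(data.frame(cys = integer(), context = numeric(),
                      class = character(), edge = logical()))
  }
  lo <- min(profile$positions)
  hi <- max(profile$positions)
  nearest <- pmin(pmax(cys, lo), hi)
  context <- profile$values[match(nearest, profile$positions)]
  data.frame(
    cys = cys,
    context = context,
    class = ifelse(context > threshold, "hydrophobic", "hydrophilic"),
    edge = nearest != cys)
}
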