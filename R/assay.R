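# average (not monoisotopic) residue masses in daltons; a peptide bond
# has already condensed out one water per residue
AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Fit an ammonia standard curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept` for a Nessler-type colorimetric standard series (ammonium
#' chloride standards, absorbance read at 420 nm).
#'
#' @param concentrations_mM Standard concentrations in mM (at least 3,
#'   not all equal).
#' @param absorbances Matching absorbance readings.
#' @return An object of class `standard_curve`: `slope` (absorbance per
#'   mM), `intercept`, `r_squared`, `range` (min/max concentration) and a
#'   `degenerate` flag (`TRUE` with `r_squared = 0` when the absorbances
#'   have zero variance).
#' @examples
#' fit_standard_curve(c(0.1, 0.2, 0.3), c(0.2, 0.4, 0.6))
#' @export
fit_standard_curve <- function(concentrations_mM, absorbances) {
  stopifnot(is.numeric(concentrations_mM), is.numeric(absorbances),
            length(concentrations_mM) == length(absorbances))
  if (length(concentrations_mM) < 3L)
    stop("insufficient data: need at least 3 standard points")
  if (length(unique(concentrations_mM)) < 2L)
    stop("degenerate design: all concentrations are equal")
  fit <- stats::lm(absorbances ~ concentrations_mM)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  ss_res <- sum(fit$residuals^2)
  degenerate <- ss_tot == 0
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (degenerate) 0 else 1 - ss_res / ss_tot,
                 range = range(concentrations_mM),
                 degenerate = degenerate),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: A = %.4f * [mM] + %.4f (r2 = %.4f, range %.3g-%.3g mM)\n",
              x$slope, x$intercept, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Convert an absorbance reading to ammonia amount
#'
#' Inverts the standard curve: `conc = (A420 - intercept) / slope`, then
#' `umol = conc * volume_mL` (mM times mL gives micromoles).  Negative
#' concentrations are clamped to zero and concentrations outside the
#' curve's calibrated range are flagged as extrapolated.
#'
#' @param curve A [fit_standard_curve()] result with non-zero slope.
#' @param a420 Absorbance reading(s) at 420 nm.
#' @param volume_mL Reaction volume in mL.
#' @return A data frame with columns `conc_mM`, `umol`, `extrapolated`,
#'   `clamped`, one row per reading.
#' @export
ammonia_from_absorbance <- function(curve, a420, volume_mL) {
  stopifnot(inherits(curve, "standard_curve"), is.numeric(a420),
            is.numeric(volume_mL), volume_mL > 0)
  if (curve$slope == 0) stop("unusable curve: zero slope")
  conc <- (a420 - curve$intercept) / curve$slope
  clamped <- conc < 0
  conc[clamped] <- 0
  data.frame(conc_mM = conc, umol = conc * volume_mL,
             extrapolated = conc < curve$range[1] | conc > curve$range[2],
             clamped = clamped)
}

#' Enzyme units and specific activity
#'
#' One unit (U) is the amount of enzyme converting one micromole of
#' L-methionine to ammonia per minute; specific activity is U per mg
#' protein.  When several replicate ammonia measurements are supplied the
#' result reports their mean with a standard deviation.
#'
#' @param ammonia_umol Micromoles of ammonia produced (scalar or
#'   replicate vector).
#' @param minutes Reaction time in minutes (> 0).
#' @param protein_mg Protein amount in mg (> 0).
#' @return An object of class `activity_result`: `ammonia_umol` (mean),
#'   `minutes`, `units` (U), `protein_mg`, `specific_activity` (U/mg) and
#'   `specific_activity_sd` (`NA` for a single measurement).
#' @examples
#' specific_activity(0.9, minutes = 30, protein_mg = 0.0025)
#' @export
specific_activity <- function(ammonia_umol, minutes, protein_mg) {
  stopifnot(is.numeric(ammonia_umol), length(ammonia_umol) >= 1L,
            all(ammonia_umol >= 0))
  if (!is.numeric(minutes) || minutes <= 0)
    stop("argument error: minutes must be positive")
  if (!is.numeric(protein_mg) || protein_mg <= 0)
    stop("argument error: protein_mg must be positive")
  per_rep <- ammonia_umol / minutes / protein_mg
  units <- mean(ammonia_umol) / minutes
  structure(list(ammonia_umol = mean(ammonia_umol), minutes = minutes,
                 units = units, protein_mg = protein_mg,
                 specific_activity = units / protein_mg,
                 specific_activity_sd = if (length(ammonia_umol) > 1L)
                   stats::sd(per_rep) else NA_real_),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("activity: %.4g U; specific activity %.4g U/mg", x$units,
              x$specific_activity))
  if (!is.na(x$specific_activity_sd))
    cat(sprintf(" (sd %.3g)", x$specific_activity_sd))
  cat("\n")
  invisible(x)
}

#' Sequence-predicted molecular mass of a protein
#'
#' Sum of average residue masses plus one water, in daltons.  Undefined
#' for sequences containing `X` or other nonstandard residues.
#'
#' @param sequence Protein sequence string over the 20 standard residues.
#' @return Mass in daltons.
#' @examples
#' protein_mass("G")   # 75.07 Da
#' @export
protein_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty input: sequence has no residues")
  x <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(x), names(AA_MASS))
  if (length(bad))
    stop("ambiguity error: mass undefined for residue(s) ",
         paste(sQuote(bad), collapse = ", "))
  sum(AA_MASS[x]) + WATER_MASS
}
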