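checkVariant <- function(variant) {
  match.arg(variant, c("mean", "min", "max"))
}

# Evaluate one log10-log10 regression under a coefficient variant.
# "min"/"max" take the pointwise lower/upper envelope of the prediction over
# the +/-1 SE coefficient box: intercept shifted by -/+SE and the slope term
# by -/+ slope_se * |log10(L)|. This keeps min <= mean <= max for every
# length, including lengths below 1 mm where log10(L) changes sign.
evalRegression <- function(length_mm, intercept, intercept_se, slope,
                           slope_se, variant) {
  lg <- log10(length_mm)
  shift <- switch(variant, mean = 0, max = 1, min = -1)
  log10m <- intercept + shift * intercept_se + slope * lg +
    shift * slope_se * abs(lg)
  10^log10m
}

#' Convert body length to dry mass
#'
#' Evaluates every length-mass regression registered for the morphogroup on
#' the log10-log10 scale, back-transforms, and averages the predictions
#' arithmetically. The \code{variant} argument propagates coefficient
#' uncertainty: \code{"max"}/\code{"min"} evaluate the upper/lower envelope
#' of each regression over its +/-1 standard-error coefficient box.
#'
#' @param length_mm body length in mm (> 0); vectorized.
#' @param morphogroup morphogroup name(s), recycled against
#'   \code{length_mm}.
#' @param allometry an [AllometrySet-class].
#' @param variant one of \code{"mean"} (default), \code{"min"}, \code{"max"}.
#' @return dry mass in micrograms.
#' @examples
#' lengthToDryMass(1.2, "entomobryomorpha", defaultAllometry())
#' @export
lengthToDryMass <- function(length_mm, morphogroup,
                            allometry = defaultAllometry(),
                            variant = "mean") {
  variant <- checkVariant(variant)
  stopIfNot(all(length_mm > 0), "length_mm must be > 0")
  tb <- allometryTable(allometry)
  unknown <- setdiff(unique(morphogroup), tb$group)
  if (length(unknown))
    stop("morphogroup(s) not in allometry set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- max(length(length_mm), length(morphogroup))
  length_mm <- rep_len(length_mm, n)
  morphogroup <- rep_len(morphogroup, n)
  vapply(seq_len(n), function(i) {
    rows <- tb[tb$group == morphogroup[i], , drop = FALSE]
    mean(evalRegression(length_mm[i], rows$intercept, rows$intercept_se,
                        rows$slope, rows$slope_se, variant))
  }, numeric(1))
}

#' Convert dry to fresh mass
#'
#' Multiplies dry mass by the morphogroup's dry-to-fresh factor (averaged
#' over the group's regression rows). The factor exceeds 1 by construction
#' (fresh mass includes body water). \code{variant} shifts the factor by
#' +/- its standard error.
#'
#' @param dry_mass_ug dry mass in micrograms (>= 0); vectorized.
#' @inheritParams lengthToDryMass
#' @return fresh mass in micrograms.
#' @export
dryToFreshMass <- function(dry_mass_ug, morphogroup,
                           allometry = defaultAllometry(),
                           variant = "mean") {
  variant <- checkVariant(variant)
  stopIfNot(all(dry_mass_ug >= 0), "dry_mass_ug must be >= 0")
  tb <- allometryTable(allometry)
  unknown <- setdiff(unique(morphogroup), tb$group)
  if (length(unknown))
    stop("morphogroup(s) not in allometry set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  shift <- switch(variant, mean = 0, max = 1, min = -1)
  agg <- stats::aggregate(cbind(dry_fresh_factor, dry_fresh_se) ~ group,
                          data = tb, FUN = mean)
  f <- agg$dry_fresh_factor + shift * agg$dry_fresh_se
  dry_mass_ug * f[match(morphogroup, agg$group)]
}

#' Individual metabolic rate (Boltzmann-Arrhenius)
#'
#' Metabolic-theory rate for an individual of fresh mass \eqn{M} (mg) at
#' absolute temperature \eqn{T} (K):
#' \deqn{I = \exp(\ln i_0 + a \ln M - E/(kT)) \quad [J\,h^{-1}]}
#' The rate is strictly increasing in both mass and temperature and scales
#' as \eqn{M^a}: doubling the mass multiplies the rate by \eqn{2^a}.
#'
#' @param fresh_mass_mg fresh body mass in mg (> 0); vectorized.
#' @param temperature_K absolute temperature in K (> 0); vectorized.
#' @param constants a [metabolicConstants()] list.
#' @return metabolic rate in J per hour.
#' @examples
#' individualMetabolicRate(0.01, 283.15) # ~2.1e-4 J/h
#' @export
individualMetabolicRate <- function(fresh_mass_mg, temperature_K,
                                    constants = metabolicConstants()) {
  stopIfNot(all(fresh_mass_mg > 0), "fresh_mass_mg must be > 0")
  stopIfNot(all(temperature_K > 0), "temperature_K must be > 0")
  exp(constants$ln_i0 + constants$a * log(fresh_mass_mg) -
        constants$E / (constants$k * temperature_K))
}

#' Celsius to Kelvin
#' @param celsius temperature in degrees C.
#' @return temperature in K.
#' @export
celsiusToKelvin <- function(celsius) celsius + 273.15

#' Symmetrically trimmed mean
#'
#' Drops \code{floor(n * trim)} smallest and the same number of largest
#' values (stable sort, so tied values are kept or dropped by input order),
#' then averages the rest. With fewer than \code{1/trim} values nothing is
#' dropped. Used to damp outlier influence when averaging community-weighted
#' means across samples.
#'
#' @param values numeric vector, non-empty; NAs removed first.
#' @param trim fraction trimmed from each tail, in [0, 0.5).
#' @return scalar mean of the retained values.
#' @examples
#' trimmedMean(1:10, 0.10) # mean of 2..9 = 5.5
#' @export
trimmedMean <- function(values, trim = 0.10) {
  values <- values[!is.na(values)]
  stopIfNot(length(values) > 0, "trimmedMean: no data (empty input is not zero)")
  stopIfNot(trim >= 0 && trim < 0.5, "trim must be in [0, 0.5)")
  k <- floor(length(values) * trim)
  if (k > 0) {
    s <- sort(values, method = "radix")  # stable
    values <- s[(k + 1):(length(s) - k)]
  }
  mean(values)
}

#' Convert an energy flux to carbon mass flux
#'
#' Energy is first expressed as fresh-mass equivalents via the tissue energy
#' density, then reduced to dry mass via the water fraction, then to carbon
#' via the carbon fraction of dry mass:
#' \deqn{C = E / e \times (1 - w) \times c}
#' The chain is linear in the input.
#'
#' @param energy_J energy (or energy flux) in J (>= 0); vectorized.
#' @param constants a [carbonConstants()] list.
#' @return carbon mass in kg (per the same time unit as the input).
#' @examples
#' energyToCarbon(7e6) # 1 kg fresh-mass equivalent -> 0.135 kg C
#' @export
energyToCarbon <- function(energy_J, constants = carbonConstants()) {
  stopIfNot(all(energy_J >= 0), "energy_J must be >= 0")
  energy_J / constants$energy_density *
    (1 - constants$water_fraction) * constants$carbon_fraction_of_dry
}
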