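#' Latitudinal belt averages
#'
#' Slices the latitudinal gradient into fixed-width bins (default 5 degrees,
#' edges at multiples of the width, half-open \code{[lo, hi)}) and computes a
#' symmetric trimmed mean of the metric per belt, giving every belt equal
#' statistical weight regardless of how many sites fall in it. Skewed
#' metrics should be averaged on the log10 scale (\code{log_scale = TRUE}
#' trims and averages \code{log10(x)} and back-transforms).
#'
#' @param metrics data.frame with \code{latitude} and the metric column.
#' @param metric name of the metric column.
#' @param width belt width in degrees (default 5).
#' @param trim trim fraction per tail within a belt (default 0.10).
#' @param log_scale average on the log10 scale (default TRUE).
#' @return data.frame with \code{belt_lo}, \code{belt_hi}, \code{belt_mid},
#'   \code{n}, \code{mean} (back-transformed when \code{log_scale}).
#'   Empty belts are omitted.
#' @examples
#' m <- data.frame(latitude = c(2, 3, 52, 53), density = c(10, 20, 100, 200))
#' beltAverages(m, "density")
#' @export
beltAverages <- function(metrics, metric, width = 5, trim = 0.10,
                         log_scale = TRUE) {
  stopIfNot(metric %in% names(metrics), paste("no column", metric))
  ok <- is.finite(metrics$latitude) & is.finite(metrics[[metric]])
  lat <- metrics$latitude[ok]
  val <- metrics[[metric]][ok]
  if (log_scale) {
    stopIfNot(all(val > 0),
              "log-scale belt averages need strictly positive values")
  }
  lo <- floor(lat / width) * width
  belts <- split(seq_along(lat), lo)
  out <- lapply(names(belts), function(b) {
    idx <- belts[[b]]
    v <- val[idx]
    m <- if (log_scale) 10^trimmedMean(log10(v), trim) else trimmedMean(v, trim)
    data.frame(belt_lo = as.numeric(b), belt_hi = as.numeric(b) + width,
               belt_mid = as.numeric(b) + width / 2, n = length(idx),
               mean = m)
  })
  res <- do.call(rbind, out)
  res[order(res$belt_lo), , drop = FALSE]
}

#' Log10 transformation with domain check
#'
#' Skewed community metrics (density, biomass, metabolism) are log10
#' transformed before modelling; zeros or negatives are a data error, not a
#' value to coerce.
#'
#' @param values numeric vector, strictly positive.
#' @return log10 of the values.
#' @examples
#' log10Metric(1000)
#' @export
log10Metric <- function(values) {
  stopIfNot(all(is.finite(values)), "values must be finite")
  if (any(values <= 0))
    stop("log10Metric: ", sum(values <= 0),
         " value(s) <= 0; filter or offset zero densities before transforming",
         call. = FALSE)
  log10(values)
}

#' Ecosystem-type summaries
#'
#' Median, quartiles and site count of a metric per retained ecosystem type
#' (the nine well-represented band x habitat combinations).
#'
#' @param metrics data.frame with \code{ecosystem_type} and the metric
#'   column (e.g. from [computeSiteMetrics()]).
#' @param metric name of the metric column.
#' @param retained_only restrict to the nine retained types (default TRUE).
#' @return data.frame with \code{ecosystem_type}, \code{n}, \code{median},
#'   \code{q25}, \code{q75}.
#' @export
ecosystemSummary <- function(metrics, metric = "density",
                             retained_only = TRUE) {
  stopIfNot(metric %in% names(metrics), paste("no column", metric))
  g <- metrics[is.finite(metrics[[metric]]), , drop = FALSE]
  if (retained_only)
    g <- g[g$ecosystem_type %in% RETAINED_ECOSYSTEM_TYPES, , drop = FALSE]
  out <- lapply(split(g, g$ecosystem_type), function(d) {
    q <- stats::quantile(d[[metric]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(ecosystem_type = d$ecosystem_type[1], n = nrow(d),
               median = q[2], q25 = q[1], q75 = q[3])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
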