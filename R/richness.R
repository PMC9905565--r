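#' Build a sample x taxon incidence matrix for one site
#'
#' @param cd a [CommunityData-class].
#' @param site_id site to extract.
#' @return binary matrix, rows = samples, columns = taxa with at least one
#'   occurrence at the site.
#' @export
incidenceMatrix <- function(cd, site_id) {
  s <- communitySamples(cd)
  s <- s[s$site_id == site_id & s$abundance > 0, , drop = FALSE]
  stopIfNot(nrow(s) > 0, paste("no occurrences for site", site_id))
  tab <- table(s$sample_id, s$taxon) > 0
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  mat[, colSums(mat) > 0, drop = FALSE]
}

checkIncidence <- function(inc) {
  stopIfNot(is.matrix(inc) && nrow(inc) >= 1 && ncol(inc) >= 0,
            "incidence matrix must have >= 1 sample row")
  stopIfNot(all(inc %in% c(0, 1)), "incidence matrix must be binary")
  invisible(inc)
}

#' Analytic sample-based rarefaction
#'
#' Expected species richness in a random subset of t of the m sampling units,
#' for t = 1..m, from the hypergeometric expectation
#' \deqn{E[S(t)] = \sum_j \left(1 - \binom{m - m_j}{t} / \binom{m}{t}\right)}
#' where \eqn{m_j} is the number of samples in which species j occurs. The
#' curve is non-decreasing and reaches the observed richness at t = m.
#'
#' @param inc binary incidence matrix (samples x species).
#' @return data.frame with columns \code{t} and \code{richness}.
#' @examples
#' inc <- rbind(c(1, 0), c(0, 1))
#' rarefactionCurve(inc) # E[S(1)] = 1, S(2) = 2
#' @export
rarefactionCurve <- function(inc) {
  checkIncidence(inc)
  m <- nrow(inc)
  mj <- colSums(inc)
  mj <- mj[mj > 0]
  richness <- vapply(seq_len(m), function(t) {
    # lchoose handles m - mj < t (choose = 0) via -Inf -> exp 0
    sum(1 - exp(lchoose(m - mj, t) - lchoose(m, t)))
  }, numeric(1))
  data.frame(t = seq_len(m), richness = richness)
}

#' Incidence-based Chao richness extrapolation
#'
#' Chao estimator on incidence frequencies with the small-sample correction:
#' \deqn{\hat S = S_{obs} + \frac{m - 1}{m}\,\frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}}
#' where \eqn{Q_1} and \eqn{Q_2} are the numbers of species found in exactly
#' one and exactly two samples. The +1 in the denominator makes the
#' estimator defined when no doubletons exist; the estimate never falls
#' below the observed richness. The classic (uncorrected) form
#' \eqn{S_{obs} + \frac{m-1}{m} Q_1^2 / (2 Q_2)} is available via
#' \code{bias_corrected = FALSE}; an abundance-based Chao1 via
#' [chao1Abundance()].
#'
#' @param inc binary incidence matrix (samples x species).
#' @param bias_corrected use the \eqn{Q_1(Q_1-1)/(2(Q_2+1))} form (default).
#' @return list with \code{estimate}, \code{S_obs}, \code{Q1}, \code{Q2},
#'   \code{m}, and \code{degenerate} (TRUE when m < 2, in which case the
#'   estimate is \code{S_obs}).
#' @examples
#' # m = 4, S_obs = 10, Q1 = 4, Q2 = 2 -> 11.5
#' @export
chaoRichness <- function(inc, bias_corrected = TRUE) {
  checkIncidence(inc)
  m <- nrow(inc)
  mj <- colSums(inc)
  S_obs <- sum(mj > 0)
  Q1 <- sum(mj == 1)
  Q2 <- sum(mj == 2)
  if (m < 2) {
    return(list(estimate = S_obs, S_obs = S_obs, Q1 = Q1, Q2 = Q2, m = m,
                degenerate = TRUE))
  }
  extra <- if (bias_corrected) {
    (m - 1) / m * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
  } else if (Q2 > 0) {
    (m - 1) / m * Q1^2 / (2 * Q2)
  } else {
    (m - 1) / m * Q1 * (Q1 - 1) / 2
  }
  list(estimate = S_obs + extra, S_obs = S_obs, Q1 = Q1, Q2 = Q2, m = m,
       degenerate = FALSE)
}

#' Abundance-based Chao1 estimator
#'
#' Bias-corrected Chao1 from singleton and doubleton abundances, pooled over
#' a site's samples. Provided as an alternative to the default sample-based
#' estimator.
#'
#' @param abundance named or unnamed vector of pooled per-species abundances.
#' @return list with \code{estimate}, \code{S_obs}, \code{F1}, \code{F2}.
#' @export
chao1Abundance <- function(abundance) {
  abundance <- abundance[abundance > 0]
  S_obs <- length(abundance)
  F1 <- sum(abundance == 1)
  F2 <- sum(abundance == 2)
  list(estimate = S_obs + F1 * (F1 - 1) / (2 * (F2 + 1)),
       S_obs = S_obs, F1 = F1, F2 = F2)
}

#' Sampling completeness of a site
#'
#' Ratio of observed to Chao-extrapolated richness, in (0, 1].
#'
#' @param inc binary incidence matrix (samples x species).
#' @return scalar completeness.
#' @export
sampleCompleteness <- function(inc) {
  ch <- chaoRichness(inc)
  stopIfNot(ch$estimate > 0, "Chao estimate must be positive")
  ch$S_obs / ch$estimate
}

#' Fit the completeness model
#'
#' Binomial GLM (logit link) of per-site sampling completeness on the number
#' of samples, latitude, and their interaction:
#' \code{Completeness ~ N_samples * Latitude}. Completeness values are
#' continuous proportions, so the model is fitted by quasi-binomial
#' likelihood with unit weights; per-term chi-square statistics come from
#' sequential (Type I) likelihood-ratio tests as in
#' \code{anova(fit, test = "Chisq")}. Only sites with at least
#' \code{min_samples} samples enter the fit.
#'
#' @param records data.frame with columns \code{completeness} (in (0, 1]),
#'   \code{n_samples}, \code{latitude}.
#' @param min_samples minimum samples per site for eligibility (default 5).
#' @return list with \code{fit} (the glm object), \code{anova} (sequential
#'   LR table), \code{n} (sites used), \code{converged}.
#' @export
fitCompletenessModel <- function(records, min_samples = 5) {
  need <- c("completeness", "n_samples", "latitude")
  stopIfNot(all(need %in% names(records)),
            "records needs completeness, n_samples, latitude")
  rec <- records[records$n_samples >= min_samples &
                   is.finite(records$completeness), , drop = FALSE]
  stopIfNot(nrow(rec) >= 10, "too few eligible sites to fit completeness model")
  stopIfNot(all(rec$completeness > 0 & rec$completeness <= 1),
            "completeness must be in (0, 1]")
  fit <- stats::glm(completeness ~ n_samples * latitude,
                    family = stats::quasibinomial(link = "logit"),
                    data = rec)
  if (!fit$converged)
    warning("completeness model did not converge", call. = FALSE)
  an <- stats::anova(fit, test = "Chisq")
  list(fit = fit, anova = an, n = nrow(rec), converged = fit$converged)
}

#' Predict extrapolated richness for pooled sites
#'
#' For sites where only pooled (site-level) species lists exist, divides the
#' pooled observed richness by the completeness predicted from
#' [fitCompletenessModel()]. The logit link keeps predicted completeness in
#' (0, 1), so the result is always at least the observed richness. Predicted
#' completeness below \code{flag_below} (default 0.1, i.e. more than
#' 10-fold extrapolation) is flagged.
#'
#' @param S_obs_pooled observed pooled richness (vectorized).
#' @param n_samples number of samples at the site.
#' @param latitude site latitude, degrees.
#' @param model result of [fitCompletenessModel()].
#' @param flag_below completeness threshold for the extrapolation flag.
#' @return data.frame with \code{richness}, \code{completeness},
#'   \code{flagged}.
#' @export
predictPooledRichness <- function(S_obs_pooled, n_samples, latitude, model,
                                  flag_below = 0.1) {
  p <- stats::predict(model$fit,
                      newdata = data.frame(n_samples = n_samples,
                                           latitude = latitude),
                      type = "response")
  data.frame(richness = S_obs_pooled / p, completeness = as.numeric(p),
             flagged = p < flag_below)
}

#' Site-level richness metrics
#'
#' Observed and Chao-extrapolated richness with completeness for every site
#' with per-sample data. Extrapolations for sites with fewer than
#' \code{min_samples} samples are suppressed (reported as \code{NA}), as
#' such estimates are unreliable.
#'
#' @param cd a [CommunityData-class].
#' @param min_samples minimum samples for an extrapolated estimate
#'   (default 3).
#' @return data.frame with \code{site_id}, \code{n_samples}, \code{S_obs},
#'   \code{S_chao}, \code{completeness}.
#' @export
siteRichness <- function(cd, min_samples = 3) {
  sites <- siteTable(cd)
  out <- lapply(sites$site_id, function(id) {
    inc <- tryCatch(incidenceMatrix(cd, id), error = function(e) NULL)
    if (is.null(inc))
      return(data.frame(site_id = id, n_samples = 0L, S_obs = 0L,
                        S_chao = NA_real_, completeness = NA_real_))
    ch <- chaoRichness(inc)
    ok <- nrow(inc) >= min_samples
    data.frame(site_id = id, n_samples = nrow(inc), S_obs = ch$S_obs,
               S_chao = if (ok) ch$estimate else NA_real_,
               completeness = if (ok) ch$S_obs / ch$estimate else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
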