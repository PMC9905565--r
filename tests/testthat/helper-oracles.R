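# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# Exhaustive sample-based rarefaction: mean richness over all C(m, t) subsets.
bruteRarefaction <- function(inc) {
  m <- nrow(inc)
  vapply(seq_len(m), function(t) {
    subsets <- utils::combn(m, t)
    mean(apply(subsets, 2, function(rows) {
      sum(colSums(inc[rows, , drop = FALSE]) > 0)
    }))
  }, numeric(1))
}

# Trimmed mean by explicit rank enumeration.
bruteTrimmedMean <- function(x, trim) {
  k <- floor(length(x) * trim)
  r <- rank(x, ties.method = "first")
  mean(x[r > k & r <= length(x) - k])
}

# Per-specimen expansion oracle for site biomass/metabolism (individuals
# enumerated one by one).
bruteSiteSums <- function(samples, massCol) {
  bySample <- split(samples, samples$sample_id)
  vals <- vapply(bySample, function(g) {
    tot <- 0
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(g$abundance[i])) tot <- tot + g[[massCol]][i]
    }
    tot / g$sampling_area[1]
  }, numeric(1))
  mean(vals)
}

# Classic dynamic-programming Levenshtein distance.
bruteLevenshtein <- function(a, b) {
  a <- strsplit(tolower(a), "")[[1]]
  b <- strsplit(tolower(b), "")[[1]]
  d <- matrix(0, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a)
  d[1, ] <- 0:length(b)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[length(a) + 1, length(b) + 1]
}

# Random binary incidence matrix with at least one occurrence.
randomIncidence <- function(m, S, p = 0.4) {
  repeat {
    inc <- matrix(rbinom(m * S, 1, p), nrow = m)
    if (any(colSums(inc) > 0)) return(inc)
  }
}

# Incidence matrix with prescribed m, Q1, Q2 and additional common species.
incidenceWithQ <- function(m, S_obs, Q1, Q2) {
  stopifnot(Q1 + Q2 <= S_obs, m >= 3)
  cols <- list()
  for (i in seq_len(Q1)) {v <- rep(0, m); v[1 + (i %% m)] <- 1; cols[[length(cols) + 1]] <- v}
  for (i in seq_len(Q2)) {v <- rep(0, m); v[c(1, 2)] <- 1; cols[[length(cols) + 1]] <- v}
  for (i in seq_len(S_obs - Q1 - Q2)) cols[[length(cols) + 1]] <- rep(1, m)
  do.call(cbind, cols)
}

# Tiny trait-attached community for metric tests.
toyCommunity <- function() {
  samples <- data.frame(
    site_id = "a", sample_id = rep(c("a1", "a2"), c(2, 1)),
    taxon = c("Folsomia", "Tomocerus", "Folsomia"),
    abundance = c(10, 2, 6), sampling_area = 0.01,
    sampling_depth = 5, layers = "litter+soil", method = "tullgren")
  sites <- data.frame(site_id = "a", latitude = 50, longitude = 8,
                      habitat = "woodland", soil_temperature = 10)
  attachTraits(communityData(samples, sites))
}

toyAllometry <- function() {
  allometrySet(data.frame(
    group = "g", intercept = 0, intercept_se = 0.1, slope = 2,
    slope_se = 0.1, dry_fresh_factor = 10 / 3, dry_fresh_se = 0.2))
}
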