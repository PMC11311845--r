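# Independent oracles and small fixture builders used across the suite.

# Closed-form ordinary least squares via the normal equations.
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Exhaustive minimum-cost frame-pair linking. Objective identical to the
# package's LAP formulation: sum of squared link displacements plus
# b = maxLinkDist^2 for every unlinked spot in either frame; links longer
# than maxLinkDist are forbidden. Enumerates all injective partial
# matchings (feasible for <= 6 spots per frame).
bruteForceLinkCost <- function(xy1, xy2, maxLinkDist) {
  n1 <- nrow(xy1); n2 <- nrow(xy2)
  b <- maxLinkDist^2
  d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
  best <- Inf
  recurse <- function(i, used2, cost) {
    if (cost >= best) return()
    if (i > n1) {
      total <- cost + b * sum(!used2)
      if (total < best) best <<- total
      return()
    }
    recurse(i + 1L, used2, cost + b)  # spot i unlinked
    for (j in which(!used2)) {
      if (d2[i, j] <= b) {
        used2[j] <- TRUE
        recurse(i + 1L, used2, cost + d2[i, j])
        used2[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(n2), 0)
  best
}

# Total objective cost of the package's frame-pair linking.
packageLinkCost <- function(xy1, xy2, maxLinkDist) {
  link <- flowPhantom:::.linkFramePair(xy1, xy2, maxLinkDist)
  b <- maxLinkDist^2
  cost <- b * sum(is.na(link)) + b * (nrow(xy2) - sum(!is.na(link)))
  for (i in seq_along(link)) {
    if (!is.na(link[i]))
      cost <- cost + sum((xy1[i, ] - xy2[link[i], ])^2)
  }
  cost
}

# A bead field holding explicitly placed beads (bypasses the Poisson draw).
manualBeadField <- function(x, y, radiusUm = 5, fluorescent = TRUE) {
  new("BeadField",
      beads = data.frame(x_mm = x, y_mm = y,
                         radius_um = rep_len(radiusUm, length(x)),
                         is_fluorescent = rep_len(fluorescent, length(x))),
      area = c(xmin = min(x) - 1, xmax = max(x) + 1,
               ymin = min(y) - 1, ymax = max(y) + 1),
      totalDensity = 1, fluorescentDensity = 1, seed = 0L)
}

# Noise-free line-scan configuration for geometry tests.
cleanLineScanConfig <- function(...) {
  lineScanConfig(shotNoise = FALSE, readNoiseSd = 0, ...)
}
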