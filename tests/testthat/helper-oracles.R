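# Independent oracles used across the suite. Each deliberately re-derives
# the expected result through a different code path than the package.

# Brute-force phenotype rule evaluator: literal transcription of the five
# rule-sets as hard-coded boolean logic (vs the package's table-driven
# classifier).
oracle_classify <- function(raw_net, raw_axial, raw_major, raw_rough,
                            z_net, z_axial, z_major) {
  if (z_net < -4) return("small")
  if (raw_net < 8000 && raw_axial < 1.7 && z_net < -1 && z_axial < -3) {
    return("small_round")
  }
  if (raw_net > 8000 && raw_axial < 1.7 && z_net > 1 && z_axial < -4) {
    return("big_round")
  }
  if (raw_axial > 2.4 && raw_major > 200 && raw_rough > 5 &&
      z_axial > 1 && z_major > 1) {
    return("long_rough")
  }
  if (raw_axial > 2.1 && raw_major > 180 && raw_rough < 5) {
    return("long_smooth")
  }
  "unclassified"
}

# All matching classes (not just the first), same literal logic.
oracle_classify_all <- function(raw_net, raw_axial, raw_major, raw_rough,
                                z_net, z_axial, z_major) {
  out <- character(0)
  if (z_net < -4) out <- c(out, "small")
  if (raw_net < 8000 && raw_axial < 1.7 && z_net < -1 && z_axial < -3) {
    out <- c(out, "small_round")
  }
  if (raw_net > 8000 && raw_axial < 1.7 && z_net > 1 && z_axial < -4) {
    out <- c(out, "big_round")
  }
  if (raw_axial > 2.4 && raw_major > 200 && raw_rough > 5 &&
      z_axial > 1 && z_major > 1) {
    out <- c(out, "long_rough")
  }
  if (raw_axial > 2.1 && raw_major > 180 && raw_rough < 5) {
    out <- c(out, "long_smooth")
  }
  out
}

# Factorial grid spanning every printed threshold +/- eps plus interior
# points; > 10^4 combinations.
threshold_grid <- function(eps = 1e-3) {
  expand.grid(
    raw_net = c(5000, 8000 - eps, 8000 + eps),
    raw_axial = c(1.7 - eps, 1.7 + eps, 2.1 - eps, 2.1 + eps,
                  2.4 - eps, 2.4 + eps),
    raw_major = c(180 - eps, 180 + eps, 200 - eps, 200 + eps),
    raw_rough = c(5 - eps, 5 + eps),
    z_net = c(-4 - eps, -4 + eps, -1 - eps, -1 + eps, 1 - eps, 1 + eps),
    z_axial = c(-4 - eps, -4 + eps, -3 - eps, -3 + eps, 1 - eps, 1 + eps),
    z_major = c(1 - eps, 1 + eps)
  )
}

# Deconvolution validity by direct transcription of the rule: pool
# significant on >= 1 tested parameter, and >= 2 singles each significant
# with a sign concordant with the pool on some tested parameter.
oracle_deconvolution <- function(pool, singles, z_cut = 2) {
  pool_sig <- any(abs(pool) >= z_cut)
  n_conc <- 0
  for (s in singles) {
    if (is.null(s)) next
    ok <- FALSE
    for (p in seq_along(pool)) {
      if (abs(s[p]) >= z_cut && pool[p] != 0 &&
          ((s[p] > 0) == (pool[p] > 0))) ok <- TRUE
    }
    if (ok) n_conc <- n_conc + 1
  }
  pool_sig && n_conc >= 2
}

# Comparison-counting mid-ranks (independent of base rank()).
oracle_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
  }, numeric(1))
}

# Dunn z for one pair by direct arithmetic on comparison-counted ranks.
oracle_dunn_z <- function(values, groups, a, b) {
  r <- oracle_midranks(values)
  n <- length(values)
  tie <- table(values)
  tie_term <- sum(tie^3 - tie) / (12 * (n - 1))
  ra <- mean(r[groups == a]); rb <- mean(r[groups == b])
  na <- sum(groups == a); nb <- sum(groups == b)
  (ra - rb) / sqrt((n * (n + 1) / 12 - tie_term) * (1 / na + 1 / nb))
}

# Adjusted Rand index from the contingency table.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Naive O(n^3) complete-linkage agglomeration: returns merge heights and
# the partition at each k, for cross-checking hclust-based clustering.
oracle_complete_linkage <- function(x) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  labels <- seq_len(n)
  partitions[[n]] <- labels
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    heights <- c(heights, best[1])
    labels <- integer(nrow(x))
    for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
    partitions[[length(clusters)]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

# Straight rasterized ellipse mask (optionally rotated), for geometry tests.
raster_ellipse <- function(a, b, theta = 0, pad = 10) {
  r <- ceiling(max(a, b)) + pad
  n <- 2 * r + 1
  cy <- cx <- r + 1
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  u <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  v <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
  matrix((u / a)^2 + (v / b)^2 <= 1, n, n)
}
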