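# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and, where the package delegates to a stats routine, the
# closed-form textbook computation is written out instead).

# Two-sided Fisher exact p by full hypergeometric enumeration over the
# support, summing probabilities <= observed (with the conventional
# relative tolerance on "<=").
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # positives
  n1 <- a + c         # group-1 cells
  N <- a + b + c + d
  ks <- max(0, n1 - (N - m)):min(m, n1)
  logp <- lchoose(m, ks) + lchoose(N - m, n1 - ks) - lchoose(N, n1)
  p_obs <- logp[ks == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# BH step-up by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Simple linear regression via the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(slope = slope, intercept = intercept,
       r = sxy / sqrt(sxx * ss_tot), adj_r2 = adj_r2)
}

# One-way ANOVA F from the textbook sum-of-squares decomposition.
oracle_anova_F <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Kruskal-Wallis H with the ties correction.
oracle_kw_H <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Ripley K by explicit double loop over ordered pairs (strict d < t).
oracle_ripley_K <- function(points, area, t_grid) {
  n <- nrow(points)
  vapply(t_grid, function(t) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) {
          d <- sqrt(sum((points[i, ] - points[j, ])^2))
          if (d < t) acc <- acc + 1
        }
      }
    }
    (area / n) * acc / n
  }, numeric(1))
}

# Point-in-polygon by ray casting (horizontal ray to +Inf).
oracle_point_in_polygon <- function(x, y, vertices) {
  n <- nrow(vertices)
  vapply(seq_along(x), function(k) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- vertices[i, 1]; yi <- vertices[i, 2]
      xj <- vertices[j, 1]; yj <- vertices[j, 2]
      if ((yi > y[k]) != (yj > y[k]) &&
          x[k] < (xj - xi) * (y[k] - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# Independent re-statement of the divisive marker-rule cascade, written
# per cell against the rule lists, for truth-table comparison.
oracle_classify_one <- function(counts, in_sgl, rules) {
  pos <- function(g) any(counts[intersect(g, names(counts))] >= 1)
  if (pos(rules$neuron_exclusion)) {
    if (pos(rules$astro_positive) && !pos(rules$astro_negative)) return("astrocyte")
    if (pos(rules$micro_positive) && !pos(rules$micro_negative)) return("microglia")
    if (pos(rules$oligo_positive) && !pos(rules$oligo_negative)) return("oligodendrocyte")
    return("other")
  }
  immature <- (in_sgl && pos(rules$immature_positive)) ||
    (pos(rules$immature_alt_positive) && !pos(rules$immature_alt_negative))
  if (immature) return("immature")
  if (pos(rules$pan_neuronal) && pos(rules$inhibitory_markers)) return("inhibitory")
  "excitatory"
}
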