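# Independent oracles used across the suite. Each one recomputes a quantity
# by brute force or numerical integration, never through the package's own
# code path.

# Equal-tailed Beta quantile by trapezoid integration of the density.
oracle_beta_quantile <- function(p, a, b, n_grid = 200001) {
  grid <- seq(0, 1, length.out = n_grid)
  dens <- stats::dbeta(grid, a, b)
  dens[!is.finite(dens)] <- 0  # endpoint singularities for a<1 or b<1
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2) * (grid[2] - grid[1]))
  cdf <- cdf / cdf[n_grid]
  stats::approx(cdf, grid, xout = p, ties = "ordered")$y
}

# Posterior tail probability by adaptive quadrature.
oracle_beta_tail <- function(threshold, a, b) {
  stats::integrate(function(x) stats::dbeta(x, a, b), 0, threshold,
                   rel.tol = 1e-10)$value
}

# Predictive probability of final success by exhaustive enumeration of all
# 2^m future response sequences; each sequence with k responders has
# marginal probability B(a+k, b+m-k)/B(a, b) under the beta-binomial.
oracle_predictive_success <- function(design, n, r) {
  a <- design$prior_alpha + r
  b <- design$prior_beta + n - r
  m <- design$n_max - n
  if (m == 0) {
    return(as.numeric(
      1 - stats::pbeta(design$p_efficacy, a, b) >= design$threshold_efficacy))
  }
  total <- 0
  for (s in 0:(2^m - 1)) {
    k <- sum(as.integer(intToBits(s))[seq_len(m)])
    p_seq <- exp(lbeta(a + k, b + m - k) - lbeta(a, b))
    final_tail <- 1 - stats::pbeta(design$p_efficacy, a + k, b + (m - k))
    if (final_tail >= design$threshold_efficacy) total <- total + p_seq
  }
  total
}

# All-pairs colocalization scan, written independently of the package's
# brute/grid implementations.
oracle_coloc <- function(map, source = "CD20", targets = c("CD4", "CD8"),
                         radius = 10) {
  cells <- map$cells
  src <- which(cells[[source]] == 1)
  tgt <- which(Reduce(`|`, lapply(targets, function(t) cells[[t]] == 1)))
  sapply(src, function(i) {
    hit <- FALSE
    for (j in tgt) {
      if (j == i) next
      if (sqrt((cells$x_um[j] - cells$x_um[i])^2 +
               (cells$y_um[j] - cells$y_um[i])^2) <= radius) {
        hit <- TRUE
        break
      }
    }
    hit
  })
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign vectors.
oracle_wilcoxon_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  ranks <- rank(abs(d))
  v_obs <- sum(ranks[d > 0])
  v_all <- numeric(2^n)
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(n)]
    v_all[s + 1] <- sum(ranks[bits == 1])
  }
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# A small deterministic random cell map for spatial tests.
random_cell_map <- function(n_cells, seed, side = 200, area_mm2 = 0.04,
                            p_flags = c(CD20 = 0.3, CD4 = 0.25, CD8 = 0.2,
                                        CD163 = 0.2, PD1 = 0.3)) {
  set.seed(seed)
  cells <- data.frame(x_um = runif(n_cells, 0, side),
                      y_um = runif(n_cells, 0, side))
  for (ph in names(p_flags)) {
    cells[[ph]] <- rbinom(n_cells, 1, p_flags[[ph]])
  }
  cell_map(cells, area_mm2 = area_mm2, sample_id = paste0("s", seed))
}
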