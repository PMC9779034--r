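# Independent reference implementations and fixture builders used as
# oracles. These are deliberately written from the textbook formulas,
# not by calling the package's own code paths.

# GeoJSON unit square feature
square_feature <- function(id, x, y, size = 1) {
  s <- size
  list(type = "Feature", properties = list(id = id),
       geometry = list(type = "Polygon", coordinates = list(list(
         list(x, y), list(x + s, y), list(x + s, y + s),
         list(x, y + s), list(x, y)))))
}

grid_geojson <- function(rows, cols, gap = 0) {
  feats <- list()
  k <- 0
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      k <- k + 1
      feats[[k]] <- square_feature(paste0("g", k),
                                   (c - 1) * (1 + gap), (r - 1) * (1 + gap))
    }
  }
  list(type = "FeatureCollection", features = feats)
}

# Covariance of the per-component-centered ICAR distribution: pseudo
# inverse of tau * Q0 via eigendecomposition.
icar_covariance <- function(Q, tau) {
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / (tau * eg$values[pos]), sum(pos)) %*%
    t(eg$vectors[, pos, drop = FALSE])
}

# Split-chain potential scale reduction, written directly from the
# between/within variance formula. chains: iterations x chains matrix.
ref_rhat <- function(chains) {
  n2 <- floor(nrow(chains) / 2)
  halves <- list()
  for (c in seq_len(ncol(chains))) {
    halves[[length(halves) + 1]] <- chains[1:n2, c]
    halves[[length(halves) + 1]] <- chains[(nrow(chains) - n2 + 1):nrow(chains), c]
  }
  n <- n2
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size from the variogram estimator with paired
# truncation, written independently of the package implementation.
ref_ess <- function(chains) {
  C <- ncol(chains); n <- nrow(chains)
  W <- mean(apply(chains, 2, var))
  mu <- colMeans(chains)
  B <- if (C > 1) n * var(mu) else W
  vp <- (n - 1) / n * W + B / n
  vg <- function(t) {
    tot <- 0
    for (c in seq_len(C)) {
      d <- chains[(t + 1):n, c] - chains[1:(n - t), c]
      tot <- tot + sum(d^2)
    }
    tot / (C * (n - t))
  }
  tau <- 1
  t <- 1
  repeat {
    if (t + 1 > n - 1) break
    r1 <- 1 - vg(t) / (2 * vp)
    r2 <- 1 - vg(t + 1) / (2 * vp)
    if (r1 + r2 <= 0) break
    tau <- tau + 2 * (r1 + r2)
    t <- t + 2
  }
  min(C * n, C * n / tau)
}

# Type-7 quantile by explicit sort-and-interpolate.
quantile_type7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Small standardized factor-structure fixture shared by BEFA tests.
befa_recovery_fixture <- function(m = 200, seed = 42) {
  alloc <- c(1L, 1L, 1L, 2L, 2L, 2L)
  loads <- c(0.9, -0.9, 0.9, 0.9, 0.9, -0.9)
  sim <- simulate_covariates(m, alloc, loads, rep(sqrt(1 - 0.81), 6),
                             seed = seed)
  list(X = standardize_columns(sim$X), scores = sim$scores,
       allocation = alloc, loadings = loads)
}

# Same-partition comparison that ignores factor relabeling.
same_partition <- function(z1, z2) {
  ok <- TRUE
  for (a in unique(z1)) {
    grp <- which(z1 == a)
    if (a == 0) {
      ok <- ok && all(z2[grp] == 0)
    } else {
      ok <- ok && length(unique(z2[grp])) == 1 && all(z2[grp] > 0)
    }
  }
  for (b in unique(z2[z2 > 0])) {
    grp <- which(z2 == b)
    ok <- ok && length(unique(z1[grp])) == 1
  }
  ok
}
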