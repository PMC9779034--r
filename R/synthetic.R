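#' Draw from the intrinsic CAR distribution on a graph
#'
#' Samples the spatially structured effect `u` from the intrinsic CAR
#' (ICAR) distribution restricted to the subspace orthogonal to its null
#' space, i.e. with a sum-to-zero constraint inside every connected
#' component. The draw is built spectrally: eigenvectors of the structure
#' matrix `Q0` with eigenvalue `lambda_k > 0` receive independent normal
#' coordinates with variance `sigma_u^2 / lambda_k`; null directions
#' (component indicators) get zero mass, so isolated areas are exactly 0.
#'
#' @param graph an [area_graph()].
#' @param sigma_u positive marginal scale (the ICAR precision is
#'   `1/sigma_u^2 * Q0`).
#' @param seed integer seed; the same seed and graph give a bit-identical
#'   draw.
#' @return numeric vector of length `n_areas(graph)` with per-component
#'   mean zero.
#' @export
sample_icar <- function(graph, sigma_u, seed) {
  stopifnot(inherits(graph, "area_graph"))
  if (graph$m == 0) stop("graph has no areas")
  if (sigma_u <= 0) stop("sigma_u must be positive")
  Q <- icar_structure(graph)
  eg <- eigen(Q, symmetric = TRUE)
  tol <- max(eg$values) * 1e-9 + 1e-12
  pos <- eg$values > tol
  u <- numeric(graph$m)
  if (any(pos)) {
    set.seed(as.integer(seed))
    z <- stats::rnorm(sum(pos), sd = sigma_u / sqrt(eg$values[pos]))
    u <- as.vector(eg$vectors[, pos, drop = FALSE] %*% z)
  }
  # remove numerical residue so per-component means are exactly zero
  for (g in unique(graph$component_labels)) {
    idx <- which(graph$component_labels == g)
    u[idx] <- u[idx] - mean(u[idx])
  }
  u
}

#' Simulate covariates with a dedicated factor structure
#'
#' Generates an area-by-covariate matrix from the dedicated-loading factor
#' model the exploratory factor analysis assumes: each covariate loads on
#' at most one latent factor, `X[, j] = mean_j + loading_j * f[, k_j] +
#' noise`, with standard-normal independent factor scores. Allocation 0
#' means pure noise (no factor).
#'
#' @param m number of areas.
#' @param allocation integer vector (length `M`) of factor indices in
#'   `0..K`; every factor that appears must have at least two dedicated
#'   covariates, otherwise its loading is unidentifiable.
#' @param loadings numeric vector (length `M`) of loadings, in the units
#'   of the covariates.
#' @param noise_sd positive idiosyncratic noise SDs (length `M`).
#' @param seed integer seed (factor scores and noise use separate derived
#'   streams, so adding covariates never perturbs the scores).
#' @param col_means optional covariate means (default 0), letting the
#'   generator produce proportion-scale columns.
#' @return list with elements `X` (`m x M`, unstandardized) and `scores`
#'   (`m x K`).
#' @export
simulate_covariates <- function(m, allocation, loadings, noise_sd, seed,
                                col_means = 0) {
  M <- length(allocation)
  stopifnot(length(loadings) == M, length(noise_sd) == M)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  allocation <- as.integer(allocation)
  if (any(allocation < 0)) stop("allocation entries must be in 0..K")
  K <- max(allocation, 0L)
  counts <- tabulate(allocation[allocation > 0], nbins = K)
  if (any(counts == 1)) {
    stop("factor ", which(counts == 1)[1],
         " has exactly one dedicated covariate (unidentifiable)")
  }
  col_means <- rep_len(col_means, M)
  set.seed(stream_seed(seed, "scores"))
  scores <- matrix(stats::rnorm(m * K), m, K)
  set.seed(stream_seed(seed, "noise"))
  noise <- matrix(stats::rnorm(m * M), m, M) * rep(noise_sd, each = m)
  X <- matrix(rep(col_means, each = m), m, M) + noise
  for (j in seq_len(M)) {
    if (allocation[j] > 0) {
      X[, j] <- X[, j] + loadings[j] * scores[, allocation[j]]
    }
  }
  list(X = X, scores = scores)
}

#' Forward-simulate an areal count study
#'
#' Generates observed counts from the convolution model the inference
#' stage assumes: expected counts `e_i = population_i * base_rate`, a
#' spatially structured effect `u` from the ICAR distribution, independent
#' heterogeneity `v_i ~ N(0, sigma_v^2)`, log relative risk
#' `log(theta_i) = alpha0 + X_i beta + u_i + v_i`, and counts
#' `y_i ~ Poisson(e_i * theta_i)`. The generating parameters are stored so
#' recovery can be checked against the truth.
#'
#' @param graph an [area_graph()].
#' @param populations positive population at risk per area.
#' @param alpha0 common log relative risk.
#' @param beta covariate effects (may be `NULL` with `Xcov = NULL`).
#' @param Xcov area-by-covariate matrix entering the linear predictor.
#' @param sigma_u ICAR scale (0 switches the spatial effect off).
#' @param sigma_v heterogeneity SD (0 switches it off).
#' @param base_rate overall event rate per unit population, in (0, 1).
#' @param seed integer seed; separate derived streams drive `u`, `v` and
#'   `y`.
#' @return an object of class `synthetic_study`: a list with `data` (an
#'   [area_data()] including `expected`), `graph` and `truth` (alpha0,
#'   beta, u, v, sigma_u, sigma_v, eta, theta).
#' @export
simulate_study <- function(graph, populations, alpha0 = 0, beta = NULL,
                           Xcov = NULL, sigma_u = 0.3, sigma_v = 0.1,
                           base_rate = 0.01, seed = 1) {
  stopifnot(inherits(graph, "area_graph"))
  m <- graph$m
  populations <- as.numeric(populations)
  if (length(populations) != m || any(populations <= 0)) {
    stop("populations must be positive, one per area")
  }
  if (base_rate <= 0 || base_rate >= 1) stop("base_rate must be in (0, 1)")
  if (is.null(Xcov)) {
    Xb <- numeric(m)
    beta <- numeric(0)
  } else {
    Xcov <- as.matrix(Xcov)
    stopifnot(nrow(Xcov) == m, length(beta) == ncol(Xcov))
    Xb <- as.vector(Xcov %*% beta)
  }
  e <- populations * base_rate
  u <- if (sigma_u > 0) {
    sample_icar(graph, sigma_u, stream_seed(seed, "u"))
  } else numeric(m)
  v <- if (sigma_v > 0) {
    set.seed(stream_seed(seed, "v"))
    stats::rnorm(m, sd = sigma_v)
  } else numeric(m)
  eta <- alpha0 + Xb + u + v
  theta <- exp(eta)
  mu <- e * theta
  if (any(mu > 1e9)) {
    stop("expected Poisson mean exceeds 1e9; use a smaller base_rate")
  }
  set.seed(stream_seed(seed, "y"))
  y <- stats::rpois(m, mu)
  data <- area_data(graph$area_ids, y, populations, expected = e, X = Xcov)
  structure(list(data = data, graph = graph,
                 truth = list(alpha0 = alpha0, beta = beta, u = u, v = v,
                              sigma_u = sigma_u, sigma_v = sigma_v,
                              eta = eta, theta = theta,
                              base_rate = base_rate, seed = seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study: ", x$graph$m, " areas, total observed ",
      sum(x$data$observed), "\n", sep = "")
  cat("  truth: alpha0 = ", x$truth$alpha0, ", sigma_u = ", x$truth$sigma_u,
      ", sigma_v = ", x$truth$sigma_v, "\n", sep = "")
  invisible(x)
}

#' Default study-region polygons
#'
#' The package's standing 33-area fixture: a 5-row by 6-column block of
#' unit squares, two extra squares attached east of the block, and one
#' offset square with no neighbour at all, exercising the island code
#' path (a real study region can contain an archipelago with no land
#' border). Returned as a GeoJSON FeatureCollection list with an `id`
#' property per feature.
#'
#' @return a list representing a GeoJSON FeatureCollection of 33 polygons.
#' @export
default_study_polygons <- function() {
  square <- function(id, x, y) {
    list(type = "Feature", properties = list(id = id),
         geometry = list(type = "Polygon", coordinates = list(list(
           list(x, y), list(x + 1, y), list(x + 1, y + 1),
           list(x, y + 1), list(x, y)))))
  }
  feats <- list()
  k <- 0L
  for (r in seq_len(5)) {
    for (c in seq_len(6)) {
      k <- k + 1L
      feats[[k]] <- square(sprintf("A%02d", k), c - 1, 5 - r)
    }
  }
  feats[[31]] <- square("A31", 6, 4)   # east of the block, touching it
  feats[[32]] <- square("A32", 7, 4)   # touching A31 only
  feats[[33]] <- square("A33", 10, 10) # island: no neighbour
  list(type = "FeatureCollection", features = feats)
}

#' Default 33-area contiguity graph
#'
#' Queen-contiguity graph of [default_study_polygons()]: a connected
#' 32-area mainland plus one island, mirroring a national study with 33
#' administrative areas one of which has no land neighbour.
#'
#' @return an [area_graph()] with 33 areas and 2 components.
#' @export
default_study_graph <- function() {
  build_adjacency_from_geojson(default_study_polygons(), rule = "queen")
}

#' Default covariate specification for the synthetic study
#'
#' Ten area-level proportions organised in three dedicated factors
#' plus an unallocated noise column, chosen to resemble national
#' survey aggregates: household decision-making indicators (factor 1),
#' education/purchase autonomy (factor 2, with "no education" loading
#' negatively), and reproductive-health knowledge (factor 3). Means sit
#' in the 58-98% range with SDs of roughly 3-10 percentage points.
#'
#' @return a list with `names`, `means`, `allocation`, `loadings` and
#'   `noise_sd`.
#' @export
default_covariate_spec <- function() {
  list(
    names = c("decides_own_health", "visits_family_friends", "no_decisions",
              "decides_big_purchases", "decides_daily_purchases",
              "no_education", "modern_contraception", "knows_free_methods",
              "not_using_contraception", "sales_services_work"),
    means = c(78.2, 73.1, 25.0, 58.6, 61.2, 8.0, 72.9, 58.3, 27.1, 60.3),
    allocation = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 0L),
    loadings = c(4.5, 4.8, -5.5, 4.7, 3.9, -3.5, 7.5, 8.0, -6.0, 0),
    noise_sd = c(2.8, 2.5, 3.0, 2.2, 1.9, 1.6, 3.5, 4.0, 3.3, 9.5))
}

#' Generate the default synthetic study
#'
#' One call producing the whole study-shaped dataset: the 33-area graph
#' (mainland + island), heterogeneous populations at risk (log-normal,
#' median 200,000), proportion-scale covariates with the dedicated factor
#' structure of [default_covariate_spec()], and counts from the
#' convolution model with effects on the standardized true factor scores.
#' Default effect sizes (`alpha0 = -0.2`, `beta = c(0.3, -0.2, 0.1)`,
#' `sigma_u = 0.3`, `sigma_v = 0.1`, `base_rate = 0.017` events per woman
#' over the pooled study window) are in the range typical of small-area
#' violence-risk analyses.
#'
#' @param seed integer master seed.
#' @param alpha0,beta,sigma_u,sigma_v,base_rate generating parameters.
#' @return a `synthetic_study` whose `truth` also records the covariate
#'   `allocation`, `loadings` and latent `scores`.
#' @export
default_study <- function(seed = 1, alpha0 = -0.2, beta = c(0.3, -0.2, 0.1),
                          sigma_u = 0.3, sigma_v = 0.1, base_rate = 0.017) {
  graph <- default_study_graph()
  m <- graph$m
  set.seed(stream_seed(seed, "populations"))
  populations <- exp(stats::rnorm(m, mean = log(2e5), sd = 0.6))
  spec <- default_covariate_spec()
  cov <- simulate_covariates(m, spec$allocation, spec$loadings, spec$noise_sd,
                             seed = seed, col_means = spec$means)
  colnames(cov$X) <- spec$names
  scores_std <- scale(cov$scores)
  study <- simulate_study(graph, populations, alpha0 = alpha0, beta = beta,
                          Xcov = scores_std, sigma_u = sigma_u,
                          sigma_v = sigma_v, base_rate = base_rate,
                          seed = seed)
  # expose the proportion-scale covariates as the study's X; keep the
  # latent structure in truth
  study$data <- area_data(graph$area_ids, study$data$observed, populations,
                          expected = study$data$expected, X = cov$X,
                          covariate_names = spec$names)
  study$truth$allocation <- spec$allocation
  study$truth$loadings <- spec$loadings
  study$truth$scores <- cov$scores
  study
}
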