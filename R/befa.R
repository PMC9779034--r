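#' Configuration for the Bayesian exploratory factor analysis
#'
#' The factor model is `x_j = lambda_j * f_{z_j} + eps_j` with dedicated
#' allocations `z_j` in `0..K_max` (0 = no factor), standard-normal
#' orthogonal factors, normal loading prior and inverse-gamma
#' idiosyncratic variances. The number of active factors is not fixed in
#' advance: allocations (and hence the model dimension) are sampled
#' jointly with the loadings.
#'
#' @param K_max maximum number of factors entertained.
#' @param n_iter,n_warmup total sweeps and warm-up sweeps discarded before
#'   summarization (defaults 10000 / 4000).
#' @param loading_prior_sd prior SD of each loading. The default `NULL`
#'   resolves to `sqrt(m)` at fit time (a unit-information prior): the
#'   loading prior is what sets the Occam penalty of the integrated
#'   likelihood that decides allocations, and unit-information scaling
#'   makes that penalty grow like BIC, so spurious factors fitted to
#'   sampling noise are rejected consistently as the number of areas
#'   grows. Any fixed positive value can be supplied instead.
#' @param idio_shape,idio_rate inverse-gamma prior on idiosyncratic
#'   variances.
#' @param null_weight prior weight of the null allocation relative to each
#'   active factor. The default `NULL` resolves to `K_max`, i.e. half the
#'   per-covariate prior mass on "no factor" and half split over the
#'   factors; this corrects the combinatorial multiplicity of allocated
#'   configurations, without which pure-noise data would be assigned
#'   spurious factors simply because there are many ways to form one.
#'   `1` gives a uniform prior over `0..K_max`.
#' @param min_dedicated smallest number of covariates an active factor may
#'   have (2 by default; a single-variable factor is unidentifiable).
#' @param retention_threshold a covariate is reported as retained when its
#'   posterior probability of the null allocation falls below this value.
#' @param seed integer seed.
#' @return a list of class `befa_config`.
#' @export
befa_config <- function(K_max = 3, n_iter = 10000, n_warmup = 4000,
                        loading_prior_sd = NULL, idio_shape = 2, idio_rate = 1,
                        null_weight = NULL, min_dedicated = 2,
                        retention_threshold = 0.5, seed = 1) {
  if (K_max < 1) stop("K_max must be at least 1")
  if (n_warmup >= n_iter) stop_validation("n_warmup must be smaller than n_iter")
  if (retention_threshold <= 0 || retention_threshold >= 1) {
    stop("retention_threshold must be in (0, 1)")
  }
  if (min_dedicated < 2) stop("min_dedicated must be at least 2")
  if (is.null(null_weight)) null_weight <- K_max
  if (!is.null(loading_prior_sd) && loading_prior_sd <= 0) {
    stop("loading_prior_sd must be positive")
  }
  if (idio_shape <= 0 || idio_rate <= 0 || null_weight <= 0) {
    stop("prior parameters must be positive")
  }
  structure(list(K_max = as.integer(K_max), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup),
                 loading_prior_sd = loading_prior_sd,
                 idio_shape = idio_shape, idio_rate = idio_rate,
                 null_weight = null_weight,
                 min_dedicated = as.integer(min_dedicated),
                 retention_threshold = retention_threshold,
                 seed = as.integer(seed)),
            class = "befa_config")
}

#' Standardize covariate columns
#'
#' Centers every column to mean 0 and scales to sample SD 1, the
#' pre-conditioning the factor model expects.
#'
#' @param X numeric matrix.
#' @return matrix of the same shape; dimnames preserved.
#' @export
standardize_columns <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X) %||% paste0("cov_", seq_len(ncol(X)))
    stop("constant column: ", nm[which(sds == 0)[1]])
  }
  out <- scale(X)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# Log marginal likelihood of one covariate column under allocation k,
# with the loading integrated out analytically under its N(0, s0^2)
# prior: x ~ N(0, sig2 I + s0^2 f f').  active = FALSE gives the null
# allocation x ~ N(0, sig2 I).
befa_marg_core <- function(Sxx, Sff, Sfx, m, sig2, s02, active) {
  base <- -m / 2 * log(2 * pi * sig2)
  if (!active) {
    return(base - Sxx / (2 * sig2))
  }
  base - 0.5 * log1p(s02 * Sff / sig2) -
    (Sxx - s02 * Sfx^2 / (sig2 + s02 * Sff)) / (2 * sig2)
}

# Vector interface used by tests (quadrature oracle) and documentation;
# f = NULL means the null allocation.
befa_log_marginal <- function(x, f = NULL, sigma2 = 1, s0 = 1) {
  m <- length(x)
  if (is.null(f)) {
    return(befa_marg_core(sum(x^2), 0, 0, m, sigma2, s0^2, FALSE))
  }
  befa_marg_core(sum(x^2), sum(f^2), sum(f * x), m, sigma2, s0^2, TRUE)
}

#' Fit the dedicated-allocation Bayesian exploratory factor analysis
#'
#' Metropolis-within-Gibbs sampler. Each sweep (1) updates every
#' allocation `z_j` by Metropolis-Hastings with the loading integrated
#' out analytically under its conjugate normal prior, vetoing moves that
#' would leave a factor with fewer dedicated covariates than
#' `min_dedicated`; (2) proposes one paired birth/death move (two null
#' covariates jointly founding an empty factor, or a minimal two-member
#' factor dissolving) so the model dimension can change even though
#' single-covariate moves cannot create a factor; (3) Gibbs-updates
#' loadings, factor scores and idiosyncratic variances from their
#' conjugate conditionals; and (4) enforces the sign convention that the
#' lowest-index covariate of each active factor loads positively, by
#' flipping the (loading, score) pair.
#'
#' @param X standardized numeric matrix (areas in rows, covariates in
#'   columns); see [standardize_columns()].
#' @param config a [befa_config()].
#' @return an object of class `befa_posterior` with post-warmup draws:
#'   `allocation_draws` (S x M), `loading_draws`, `idio_var_draws`,
#'   `score_draws` (S x m x K_max), per-covariate MH `acceptance_rate`,
#'   the `config` and the covariate names.
#' @export
befa_fit <- function(X, config = befa_config()) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values")
  m <- nrow(X)
  M <- ncol(X)
  K <- config$K_max
  if (K * config$min_dedicated > M) {
    stop("K_max * min_dedicated exceeds the number of covariates: ",
         "no feasible fully active allocation")
  }
  cn <- colnames(X) %||% paste0("cov_", seq_len(M))
  s0 <- config$loading_prior_sd %||% sqrt(m)
  config$loading_prior_sd <- s0
  s02 <- s0^2
  a0 <- config$idio_shape
  b0 <- config$idio_rate
  mind <- config$min_dedicated
  lw <- c(log(config$null_weight), rep(0, K)) # log prior weight by z + 1

  set.seed(config$seed)
  z <- integer(M)
  lambda <- stats::rnorm(M, 0, s0)
  sig2 <- rep(1, M)
  F <- matrix(stats::rnorm(m * K), m, K)
  Sxx <- colSums(X^2)

  S <- config$n_iter - config$n_warmup
  alloc_draws <- matrix(0L, S, M, dimnames = list(NULL, cn))
  load_draws <- matrix(0, S, M, dimnames = list(NULL, cn))
  idio_draws <- matrix(0, S, M, dimnames = list(NULL, cn))
  score_draws <- array(0, c(S, m, K))
  acc <- numeric(M)
  prop_n <- numeric(M)

  counts <- tabulate(z[z > 0], nbins = K)

  lm_jk <- function(j, k, Sff, SfX) {
    if (k == 0L) {
      befa_marg_core(Sxx[j], 0, 0, m, sig2[j], s02, FALSE)
    } else {
      befa_marg_core(Sxx[j], Sff[k], SfX[k, j], m, sig2[j], s02, TRUE)
    }
  }

  for (t in seq_len(config$n_iter)) {
    Sff <- colSums(F^2)
    SfX <- crossprod(F, X)

    ## (1) per-covariate allocation MH, loading integrated out
    for (j in seq_len(M)) {
      cur <- z[j]
      cand <- setdiff(0:K, cur)
      prop <- cand[sample.int(length(cand), 1)]
      prop_n[j] <- prop_n[j] + 1
      # veto moves that strand a factor below min_dedicated
      ok <- TRUE
      if (cur > 0L && (counts[cur] - 1L) %in% seq_len(mind - 1L)) ok <- FALSE
      if (prop > 0L && (counts[prop] + 1L) %in% seq_len(mind - 1L)) ok <- FALSE
      if (!ok) next
      la <- lm_jk(j, prop, Sff, SfX) - lm_jk(j, cur, Sff, SfX) +
        lw[prop + 1L] - lw[cur + 1L]
      if (log(stats::runif(1)) < la) {
        if (cur > 0L) counts[cur] <- counts[cur] - 1L
        if (prop > 0L) counts[prop] <- counts[prop] + 1L
        z[j] <- prop
        acc[j] <- acc[j] + 1
      }
    }

    ## (2) grouped birth/death dimension moves: `mind` null covariates
    ## jointly found an empty factor, or a minimal factor dissolves.
    ## Reversible-jump with a data-informed score proposal: the newborn
    ## factor's scores are drawn from their Gibbs conditional given the
    ## group (with loadings pinned at moment estimates), and the
    ## Hastings ratio carries the proposal-vs-prior density correction.
    ## Proposing scores from the prior instead would almost never be
    ## accepted under the unit-information loading prior.
    moment_loadings <- function(jj) {
      lam <- numeric(length(jj))
      s1j <- vapply(jj, function(j) sum(X[, jj[1]] * X[, j]), numeric(1))
      lam[1] <- sqrt(abs(s1j[2]) / m)
      if (lam[1] == 0) lam[1] <- 0.1
      for (l in seq_along(jj)[-1]) {
        lam[l] <- sign(s1j[l]) * sqrt(abs(s1j[l]) / m)
        if (lam[l] == 0) lam[l] <- 0.1
      }
      lam
    }
    birth_proposal <- function(jj) {
      lam <- moment_loadings(jj)
      d <- 1 + sum(lam^2 / sig2[jj])
      mu <- as.vector(X[, jj, drop = FALSE] %*% (lam / sig2[jj])) / d
      list(mu = mu, sd = sqrt(1 / d))
    }
    lm_f <- function(j, f, Sff_f) {
      befa_marg_core(Sxx[j], Sff_f, sum(f * X[, j]), m, sig2[j], s02, TRUE)
    }
    for (att in seq_len(M)) {
      n0 <- which(z == 0L)
      minimal <- which(counts == mind)
      empty <- which(counts == 0L)
      if (stats::runif(1) < 0.5) {
        if (length(n0) >= mind && length(empty) >= 1) {
          jj <- n0[sample.int(length(n0), mind)]
          k <- empty[sample.int(length(empty), 1)]
          qp <- birth_proposal(jj)
          fstar <- stats::rnorm(m, qp$mu, qp$sd)
          Sff_star <- sum(fstar^2)
          delta <- sum(vapply(jj, function(j) {
            lm_f(j, fstar, Sff_star) - lm_jk(j, 0L, Sff, SfX)
          }, numeric(1))) + mind * (lw[k + 1L] - lw[1L])
          q_fwd <- -log(choose(length(n0), mind) * length(empty))
          q_rev <- -log(length(minimal) + 1)
          dens_corr <- sum(stats::dnorm(fstar, log = TRUE)) -
            sum(stats::dnorm(fstar, qp$mu, qp$sd, log = TRUE))
          if (log(stats::runif(1)) < delta + q_rev - q_fwd + dens_corr) {
            z[jj] <- k
            counts[k] <- mind
            F[, k] <- fstar
            Sff[k] <- Sff_star
            SfX[k, ] <- as.vector(crossprod(fstar, X))
          }
        }
      } else {
        if (length(minimal) >= 1) {
          k <- minimal[sample.int(length(minimal), 1)]
          jj <- which(z == k)
          fcur <- F[, k]
          qp <- birth_proposal(jj)
          delta <- sum(vapply(jj, function(j) {
            lm_jk(j, 0L, Sff, SfX) - lm_jk(j, k, Sff, SfX)
          }, numeric(1))) + mind * (lw[1L] - lw[k + 1L])
          q_fwd <- -log(length(minimal))
          q_rev <- -log(choose(length(n0) + mind, mind) * (length(empty) + 1))
          dens_corr <- sum(stats::dnorm(fcur, qp$mu, qp$sd, log = TRUE)) -
            sum(stats::dnorm(fcur, log = TRUE))
          if (log(stats::runif(1)) < delta + q_rev - q_fwd + dens_corr) {
            z[jj] <- 0L
            counts[k] <- 0L
            F[, k] <- stats::rnorm(m)
            Sff[k] <- sum(F[, k]^2)
            SfX[k, ] <- as.vector(crossprod(F[, k], X))
          }
        }
      }
    }

    ## (3) conjugate Gibbs updates
    Sff <- colSums(F^2)
    SfX <- crossprod(F, X)
    for (j in seq_len(M)) {
      if (z[j] > 0L) {
        k <- z[j]
        prec <- Sff[k] / sig2[j] + 1 / s02
        mu <- SfX[k, j] / sig2[j] / prec
        lambda[j] <- stats::rnorm(1, mu, sqrt(1 / prec))
      } else {
        lambda[j] <- stats::rnorm(1, 0, s0)
      }
    }
    for (k in seq_len(K)) {
      mem <- which(z == k)
      if (length(mem) == 0) {
        F[, k] <- stats::rnorm(m)
      } else {
        d <- 1 + sum(lambda[mem]^2 / sig2[mem])
        mu <- as.vector(X[, mem, drop = FALSE] %*% (lambda[mem] / sig2[mem])) / d
        F[, k] <- stats::rnorm(m, mu, sqrt(1 / d))
      }
    }
    for (j in seq_len(M)) {
      r <- if (z[j] > 0L) X[, j] - lambda[j] * F[, z[j]] else X[, j]
      sig2[j] <- 1 / stats::rgamma(1, a0 + m / 2, rate = b0 + sum(r^2) / 2)
    }

    ## (4) sign convention: lowest-index member of each factor loads > 0
    for (k in seq_len(K)) {
      mem <- which(z == k)
      if (length(mem) && lambda[mem[1]] < 0) {
        lambda[mem] <- -lambda[mem]
        F[, k] <- -F[, k]
      }
    }

    if (t > config$n_warmup) {
      s <- t - config$n_warmup
      alloc_draws[s, ] <- z
      load_draws[s, ] <- lambda
      idio_draws[s, ] <- sig2
      score_draws[s, , ] <- F
    }
  }

  structure(list(allocation_draws = alloc_draws, loading_draws = load_draws,
                 idio_var_draws = idio_draws, score_draws = score_draws,
                 acceptance_rate = stats::setNames(acc / prop_n, cn),
                 covariate_names = cn, X = X, config = config),
            class = "befa_posterior")
}

#' @export
print.befa_posterior <- function(x, ...) {
  cat("befa_posterior: ", nrow(x$allocation_draws), " draws, ",
      length(x$covariate_names), " covariates, K_max = ",
      x$config$K_max, "\n", sep = "")
  print(allocation_summary(x))
  invisible(x)
}

#' Summarize the posterior allocation of covariates to factors
#'
#' One row per covariate: the modal factor (0 = none), its posterior
#' probability, the sign of the posterior-mean loading under the modal
#' allocation (+1 / -1), the raw Metropolis-Hastings acceptance rate of
#' the allocation proposals, and whether the covariate is retained, i.e.
#' its posterior probability of carrying no factor falls below the
#' configured retention threshold.
#'
#' @param post a [befa_fit()] result.
#' @param covariate_names optional replacement labels.
#' @return a data.frame with columns `covariate`, `factor`, `probability`,
#'   `sign`, `acceptance_rate`, `retained`.
#' @export
allocation_summary <- function(post, covariate_names = NULL) {
  stopifnot(inherits(post, "befa_posterior"))
  cn <- covariate_names %||% post$covariate_names
  M <- ncol(post$allocation_draws)
  S <- nrow(post$allocation_draws)
  if (S == 0) stop("empty posterior")
  out <- data.frame(covariate = cn, factor = integer(M),
                    probability = numeric(M), sign = integer(M),
                    acceptance_rate = as.numeric(post$acceptance_rate),
                    retained = logical(M), stringsAsFactors = FALSE)
  thr <- post$config$retention_threshold
  for (j in seq_len(M)) {
    zj <- post$allocation_draws[, j]
    tab <- table(zj)
    modal <- as.integer(names(tab)[which.max(tab)])
    out$factor[j] <- modal
    out$probability[j] <- max(tab) / S
    p0 <- mean(zj == 0L)
    out$retained[j] <- p0 < thr
    if (modal > 0) {
      lam <- post$loading_draws[zj == modal, j]
      out$sign[j] <- if (mean(lam) >= 0) 1L else -1L
    } else {
      out$sign[j] <- NA_integer_
    }
  }
  out
}

#' Posterior-mean factor scores per area
#'
#' Averages the sampled factor scores of every retained factor over the
#' posterior draws, aligning labels draw by draw (a draw's factor is
#' matched to a modal factor by the overlap of their dedicated covariate
#' sets, and its sign aligned so the score correlates positively with the
#' factor's lowest-index covariate). Columns are re-standardized to mean
#' 0, SD 1.
#'
#' @param post a [befa_fit()] result.
#' @return an `m x K_active` matrix, columns named `factor_<k>` by modal
#'   factor index.
#' @export
factor_scores <- function(post) {
  stopifnot(inherits(post, "befa_posterior"))
  summ <- allocation_summary(post)
  active <- sort(unique(summ$factor[summ$factor > 0 & summ$retained]))
  if (length(active) == 0) stop("no active factor in the posterior")
  S <- nrow(post$allocation_draws)
  m <- dim(post$score_draws)[2]
  out <- matrix(0, m, length(active),
                dimnames = list(NULL, paste0("factor_", active)))
  for (a in seq_along(active)) {
    k <- active[a]
    members <- which(summ$factor == k & summ$retained)
    j0 <- members[1]
    x0 <- post$X[, j0]
    acc <- numeric(m)
    n_used <- 0L
    for (s in seq_len(S)) {
      zs <- post$allocation_draws[s, members]
      zs <- zs[zs > 0]
      if (length(zs) == 0) next
      kk <- as.integer(names(which.max(table(zs))))
      f <- post$score_draws[s, , kk]
      sgn <- sign(sum(f * x0))
      if (sgn == 0) sgn <- 1
      acc <- acc + sgn * f
      n_used <- n_used + 1L
    }
    if (n_used == 0L) stop("factor ", k, " never active in stored draws")
    sc <- acc / n_used
    sc <- (sc - mean(sc)) / stats::sd(sc)
    if (stats::cor(sc, x0) < 0) sc <- -sc
    out[, a] <- sc
  }
  out
}

#' Classify areas by the quadrant of two factor scores
#'
#' Biplot-style typology: each area is labelled by the signs of its
#' scores on two chosen factors, `"++"`, `"+-"`, `"-+"` or `"--"` (first
#' symbol = x factor). Exact zeros land on the positive side.
#'
#' @param scores matrix of per-area factor scores (see [factor_scores()]).
#' @param factor_x,factor_y column indices of the two factors.
#' @return character vector of quadrant labels, one per area.
#' @export
classify_areas <- function(scores, factor_x = 1, factor_y = 2) {
  scores <- as.matrix(scores)
  if (factor_x > ncol(scores) || factor_y > ncol(scores)) {
    stop("requested factor column does not exist")
  }
  sx <- ifelse(scores[, factor_x] >= 0, "+", "-")
  sy <- ifelse(scores[, factor_y] >= 0, "+", "-")
  paste0(sx, sy)
}
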