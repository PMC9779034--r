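#' Priors for the convolution model
#'
#' Regression terms get an improper flat prior by default (or a normal
#' prior with common SD); the two precision hyperparameters get Gamma
#' priors, defaulting to `Gamma(0.5, 0.0005)`, the long-standing
#' disease-mapping convention for ICAR and exchangeable precision terms.
#'
#' @param beta_prior `"flat"` or `"normal"`.
#' @param beta_sd prior SD when `beta_prior = "normal"`.
#' @param tau_u_shape,tau_u_rate Gamma prior on the ICAR precision.
#' @param tau_v_shape,tau_v_rate Gamma prior on the heterogeneity
#'   precision.
#' @return a list of class `bym_priors`.
#' @export
bym_priors <- function(beta_prior = c("flat", "normal"), beta_sd = 10,
                       tau_u_shape = 0.5, tau_u_rate = 0.0005,
                       tau_v_shape = 0.5, tau_v_rate = 0.0005) {
  beta_prior <- match.arg(beta_prior)
  if (any(c(tau_u_shape, tau_u_rate, tau_v_shape, tau_v_rate) <= 0)) {
    stop("Gamma prior parameters must be positive")
  }
  structure(list(beta_prior = beta_prior, beta_sd = beta_sd,
                 tau_u_shape = tau_u_shape, tau_u_rate = tau_u_rate,
                 tau_v_shape = tau_v_shape, tau_v_rate = tau_v_rate),
            class = "bym_priors")
}

#' Unnormalized log posterior of the convolution model
#'
#' Poisson log likelihood (constants in `y!` dropped) plus the intrinsic
#' CAR term `(rank(Q0)/2) log(tau_u) - (tau_u/2) u' Q0 u`, the
#' exchangeable normal term for `v`, Gamma log priors for the precisions
#' and, if configured, a normal log prior for the regression terms.
#' States whose relative risks overflow return `-Inf` rather than error.
#'
#' @param state list with elements `alpha0`, `beta`, `u`, `v`, `tau_u`,
#'   `tau_v`.
#' @param data an [area_data()] with expected counts.
#' @param graph an [area_graph()].
#' @param priors a [bym_priors()].
#' @param Xcov covariate matrix of the linear predictor (defaults to
#'   `data$X`; `NULL` for an intercept-only model).
#' @return a single finite number, or `-Inf` for invalid states.
#' @export
log_posterior_bym <- function(state, data, graph, priors = bym_priors(),
                              Xcov = data$X) {
  m <- graph$m
  y <- data$observed
  e <- data$expected
  if (is.null(e)) stop("expected counts not computed")
  Xb <- if (is.null(Xcov)) 0 else as.vector(as.matrix(Xcov) %*% state$beta)
  eta <- state$alpha0 + Xb + state$u + state$v
  mu <- e * exp(eta)
  if (any(!is.finite(mu)) || state$tau_u <= 0 || state$tau_v <= 0) {
    return(-Inf)
  }
  ll <- sum(y * log(mu) - mu)
  edges <- graph$edges
  uQu <- if (nrow(edges)) {
    sum((state$u[edges[, 1]] - state$u[edges[, 2]])^2)
  } else 0
  rank_q <- m - max(graph$component_labels)
  lp <- ll +
    rank_q / 2 * log(state$tau_u) - state$tau_u / 2 * uQu +
    m / 2 * log(state$tau_v) - state$tau_v / 2 * sum(state$v^2) +
    stats::dgamma(state$tau_u, priors$tau_u_shape, priors$tau_u_rate,
                  log = TRUE) +
    stats::dgamma(state$tau_v, priors$tau_v_shape, priors$tau_v_rate,
                  log = TRUE)
  if (priors$beta_prior == "normal") {
    lp <- lp + sum(stats::dnorm(c(state$alpha0, state$beta), 0,
                                priors$beta_sd, log = TRUE))
  }
  if (!is.finite(lp)) return(-Inf)
  lp
}

# Univariate slice sampler (stepping out + shrinkage) for a log-concave
# log density; w is an initial bracket width of the order of the
# conditional SD.
slice_sample1 <- function(x0, logf, w, max_step = 50L) {
  y <- logf(x0) - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  k <- max_step
  while (k > 0L && logf(L) > y) { L <- L - w; k <- k - 1L }
  k <- max_step
  while (k > 0L && logf(R) > y) { R <- R + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Full conditional of one ICAR effect
#'
#' Under the intrinsic CAR prior, the conditional distribution of an
#' area's spatial effect given its neighbours is normal with mean the
#' neighbour average and variance `1 / (tau_u * degree)`.
#'
#' @param i area index.
#' @param u current vector of spatial effects.
#' @param tau_u positive ICAR precision.
#' @param graph an [area_graph()].
#' @return list with elements `mean` and `variance`.
#' @export
car_full_conditional <- function(i, u, tau_u, graph) {
  d <- graph$degrees[i]
  if (d == 0) {
    stop("area ", graph$area_ids[i],
         " has no neighbour; its ICAR conditional is undefined")
  }
  e <- graph$edges
  nb <- c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])
  list(mean = mean(u[nb]), variance = 1 / (tau_u * d))
}

#' Fit the Besag-York-Mollie convolution model by MCMC
#'
#' Metropolis-within-Gibbs sampler for Poisson counts with offset:
#' `y_i ~ Poisson(e_i * theta_i)`,
#' `log(theta_i) = alpha0 + X_i beta + u_i + v_i`, `u` intrinsic CAR,
#' `v_i ~ N(0, 1/tau_v)`. Each sweep jointly updates `(alpha0, beta)` by
#' an adaptive random-walk proposal (adaptation runs during warm-up only
#' and the kernel is frozen afterwards), updates every `u_i` from its
#' full conditional (Poisson likelihood times the CAR conditional) by
#' univariate slice sampling, followed by per-component recentering (the
#' mean removed from the largest component is folded into the
#' intercept), updates every `v_i` the same way against
#' Poisson x N(0, 1/tau_v), and draws both precisions from their
#' conjugate Gamma conditionals. The log-concave site conditionals make
#' slice sampling exact and tuning-free, which keeps the chains mixing
#' within the default 10,000-sweep protocol. Areas with no neighbour
#' keep `u_i = 0` and are informed by covariates and `v_i` alone.
#'
#' @param data an [area_data()] with expected counts.
#' @param Xcov covariate matrix of the linear predictor (`NULL` for
#'   intercept-only; columns should be centered/standardized for an
#'   interpretable intercept).
#' @param graph an [area_graph()] over the same areas.
#' @param priors a [bym_priors()].
#' @param n_iter,n_warmup sweeps per chain and warm-up sweeps discarded
#'   (defaults 10000 / 4000).
#' @param n_chains number of independent chains (default 3), each with
#'   its own derived seed and jittered start.
#' @param seed integer master seed; the same seed gives bit-identical
#'   draws.
#' @param thin keep every `thin`-th post-warmup sweep.
#' @return an object of class `bym_posterior`: per-chain draws of
#'   `alpha0`, `beta`, `u`, `v`, `tau_u`, `tau_v` and `theta`, acceptance
#'   rates, and the inputs needed to recompute `theta` from any stored
#'   draw.
#' @export
bym_fit <- function(data, Xcov = data$X, graph, priors = bym_priors(),
                    n_iter = 10000, n_warmup = 4000, n_chains = 3,
                    seed = 1, thin = 1) {
  stopifnot(inherits(data, "area_data"), inherits(graph, "area_graph"))
  if (is.null(data$expected)) stop("expected counts not computed")
  if (sum(data$observed) == 0) stop("no observed cases: nothing to fit")
  if (n_warmup >= n_iter) stop_validation("n_warmup must be smaller than n_iter")
  m <- graph$m
  if (length(data$observed) != m) stop("data and graph disagree on m")
  y <- data$observed
  e <- data$expected
  if (!is.null(Xcov)) {
    Xcov <- as.matrix(Xcov)
    if (any(!is.finite(Xcov))) stop("Xcov contains non-finite values")
    if (any(apply(Xcov, 2, stats::sd) == 0)) {
      stop("constant covariate column; the intercept is separate")
    }
  }
  p <- if (is.null(Xcov)) 0L else ncol(Xcov)

  nbs <- neighbour_list(m, graph$edges)
  deg <- graph$degrees
  comp <- graph$component_labels
  ei <- graph$edges[, 1]
  ej <- graph$edges[, 2]
  rank_q <- m - max(comp)
  # non-trivial components, largest first; islands keep u = 0
  comp_sizes <- table(comp)
  nontriv <- as.integer(names(comp_sizes)[comp_sizes > 1])
  nontriv <- nontriv[order(-comp_sizes[as.character(nontriv)])]
  comp_idx <- lapply(nontriv, function(g) which(comp == g))
  scan_order <- which(deg > 0)

  normal_beta <- priors$beta_prior == "normal"
  S_keep <- floor((n_iter - n_warmup) / thin)
  chains <- vector("list", n_chains)

  for (ch in seq_len(n_chains)) {
    set.seed(stream_seed(seed, "chain") + 131L * ch)
    alpha0 <- log(sum(y) / sum(e)) + stats::rnorm(1, 0, 0.1)
    beta <- stats::rnorm(p, 0, 0.1)
    u <- numeric(m)
    v <- numeric(m)
    tau_u <- 10
    tau_v <- 10
    Xb <- if (p) as.vector(Xcov %*% beta) else numeric(m)

    ls_ab <- log(0.1)

    a_draw <- numeric(S_keep)
    b_draw <- matrix(0, S_keep, p)
    u_draw <- matrix(0, S_keep, m)
    v_draw <- matrix(0, S_keep, m)
    tu_draw <- numeric(S_keep)
    tv_draw <- numeric(S_keep)
    th_draw <- matrix(0, S_keep, m)
    acc_ab <- 0
    n_ab <- 0
    kept <- 0L

    for (t in seq_len(n_iter)) {
      adapting <- t <= n_warmup

      ## (1) joint random-walk update of (alpha0, beta)
      prop <- c(alpha0, beta) + stats::rnorm(p + 1L) * exp(ls_ab)
      eta_old <- alpha0 + Xb + u + v
      Xb_new <- if (p) as.vector(Xcov %*% prop[-1]) else numeric(m)
      eta_new <- prop[1] + Xb_new + u + v
      la <- sum(y * eta_new - e * exp(eta_new)) -
        sum(y * eta_old - e * exp(eta_old))
      if (normal_beta) {
        la <- la + sum(stats::dnorm(prop, 0, priors$beta_sd, log = TRUE)) -
          sum(stats::dnorm(c(alpha0, beta), 0, priors$beta_sd, log = TRUE))
      }
      a_ind <- is.finite(la) && log(stats::runif(1)) < la
      if (a_ind) {
        alpha0 <- prop[1]
        if (p) beta <- prop[-1]
        Xb <- Xb_new
      }
      n_ab <- n_ab + 1
      acc_ab <- acc_ab + a_ind
      if (adapting) ls_ab <- ls_ab + (a_ind - 0.3) / t^0.6

      # univariate slice refreshes of the fixed effects (their
      # conditionals are log-concave); these decorrelate the block far
      # faster than the random walk alone
      offset_a <- Xb + u + v
      logf_a <- function(a) {
        la <- sum(y) * a - sum(e * exp(a + offset_a))
        if (normal_beta) la <- la + stats::dnorm(a, 0, priors$beta_sd, TRUE)
        la
      }
      alpha0 <- slice_sample1(alpha0, logf_a, 1 / sqrt(sum(e)))
      if (p) {
        for (jb in seq_len(p)) {
          xj <- Xcov[, jb]
          off_j <- alpha0 + Xb - beta[jb] * xj + u + v
          yx <- sum(y * xj)
          logf_b <- function(b) {
            la <- yx * b - sum(e * exp(off_j + b * xj))
            if (normal_beta) la <- la + stats::dnorm(b, 0, priors$beta_sd, TRUE)
            la
          }
          w_b <- 1 / sqrt(sum(e * xj^2) + 1e-12)
          beta[jb] <- slice_sample1(beta[jb], logf_b, w_b)
        }
        Xb <- as.vector(Xcov %*% beta)
      }

      ## (2) slice-sample each u_i from Poisson x CAR conditional
      for (i in scan_order) {
        mnb <- mean(u[nbs[[i]]])
        base_i <- alpha0 + Xb[i] + v[i]
        yi <- y[i]; eei <- e[i]; td <- tau_u * deg[i]
        logf <- function(ui) {
          yi * ui - eei * exp(base_i + ui) - 0.5 * td * (ui - mnb)^2
        }
        w <- 1 / sqrt(td + eei * exp(base_i + u[i]))
        u[i] <- slice_sample1(u[i], logf, w)
      }
      ## (2b) exchange scan along the likelihood-null direction: only
      ## u_i + v_i enters the linear predictor, so the split between the
      ## spatial and unstructured effect is resampled exactly from its
      ## Gaussian conditional with eta held fixed.  Without this the
      ## u/v (and hence tau_u/tau_v) decomposition mixes only by
      ## diffusion.
      for (i in scan_order) {
        mnb <- mean(u[nbs[[i]]])
        P <- tau_u * deg[i] + tau_v
        mu_a <- (tau_u * deg[i] * mnb + tau_v * (u[i] + v[i])) / P
        a <- stats::rnorm(1, mu_a, 1 / sqrt(P))
        v[i] <- v[i] + u[i] - a
        u[i] <- a
      }
      # per-component recentering; largest component's mean folds into
      # the intercept so the linear predictor there is unchanged
      for (gi in seq_along(comp_idx)) {
        idx <- comp_idx[[gi]]
        cg <- mean(u[idx])
        u[idx] <- u[idx] - cg
        if (gi == 1L) alpha0 <- alpha0 + cg
      }

      # interim conjugate precision draw between the two effect scans
      uQu <- if (length(ei)) sum((u[ei] - u[ej])^2) else 0
      tau_u <- stats::rgamma(1, priors$tau_u_shape + rank_q / 2,
                             rate = priors$tau_u_rate + uQu / 2)

      ## (3) slice-sample each v_i from Poisson x N(0, 1/tau_v)
      base_v <- alpha0 + Xb + u
      for (i in seq_len(m)) {
        yi <- y[i]; eei <- e[i]; bi <- base_v[i]
        logf <- function(vi) {
          yi * vi - eei * exp(bi + vi) - 0.5 * tau_v * vi^2
        }
        w <- 1 / sqrt(tau_v + eei * exp(bi + v[i]))
        v[i] <- slice_sample1(v[i], logf, w)
      }

      ## (4) conjugate Gamma draws for the precisions
      uQu <- if (length(ei)) sum((u[ei] - u[ej])^2) else 0
      tau_u <- stats::rgamma(1, priors$tau_u_shape + rank_q / 2,
                             rate = priors$tau_u_rate + uQu / 2)
      tau_v <- stats::rgamma(1, priors$tau_v_shape + m / 2,
                             rate = priors$tau_v_rate + sum(v^2) / 2)

      ## (5) interweaving: re-express each effect in non-centered form
      ## (u_tilde = sqrt(tau_u) u ~ ICAR(1), v_tilde = sqrt(tau_v) v ~
      ## N(0, I)) and slice-sample log tau there.  In that
      ## parameterization a precision move rescales the whole effect
      ## vector, traversing the funnel ridge that the centered conjugate
      ## draw explores only by diffusion.
      base_u <- alpha0 + Xb + v
      if (length(scan_order)) {
        ut <- sqrt(tau_u) * u
        logf_tu <- function(lt) {
          ui <- ut * exp(-lt / 2)
          sum(y * ui - e * exp(base_u + ui)) +
            stats::dgamma(exp(lt), priors$tau_u_shape, priors$tau_u_rate,
                          log = TRUE) + lt
        }
        lt <- slice_sample1(log(tau_u), logf_tu, 1)
        tau_u <- exp(lt)
        u <- ut * exp(-lt / 2)
      }
      base_v <- alpha0 + Xb + u
      vt <- sqrt(tau_v) * v
      logf_tv <- function(lt) {
        vi <- vt * exp(-lt / 2)
        sum(y * vi - e * exp(base_v + vi)) +
          stats::dgamma(exp(lt), priors$tau_v_shape, priors$tau_v_rate,
                        log = TRUE) + lt
      }
      lt <- slice_sample1(log(tau_v), logf_tv, 1)
      tau_v <- exp(lt)
      v <- vt * exp(-lt / 2)

      if (t > n_warmup && (t - n_warmup) %% thin == 0L) {
        kept <- kept + 1L
        a_draw[kept] <- alpha0
        if (p) b_draw[kept, ] <- beta
        u_draw[kept, ] <- u
        v_draw[kept, ] <- v
        tu_draw[kept] <- tau_u
        tv_draw[kept] <- tau_v
        th_draw[kept, ] <- exp(alpha0 + Xb + u + v)
      }
    }

    chains[[ch]] <- list(alpha0 = a_draw, beta = b_draw, u = u_draw,
                         v = v_draw, tau_u = tu_draw, tau_v = tv_draw,
                         theta = th_draw,
                         acceptance = c(fixed = acc_ab / n_ab))
  }

  structure(list(chains = chains, n_chains = n_chains, n_iter = n_iter,
                 n_warmup = n_warmup, thin = thin, seed = seed,
                 area_ids = data$area_ids, Xcov = Xcov,
                 covariate_names = if (p) colnames(Xcov) %||%
                   paste0("X", seq_len(p)) else character(0),
                 component_labels = comp, priors = priors),
            class = "bym_posterior")
}

#' @export
print.bym_posterior <- function(x, ...) {
  cat("bym_posterior: ", x$n_chains, " chains, ",
      length(x$chains[[1]]$alpha0), " stored draws each (",
      x$n_iter, " sweeps, ", x$n_warmup, " warm-up)\n", sep = "")
  print(summarize_coefficients(x))
  invisible(x)
}

# Pool a named component of all chains into one matrix/vector.
pool_chains <- function(post, what) {
  parts <- lapply(post$chains, `[[`, what)
  if (is.matrix(parts[[1]])) do.call(rbind, parts) else do.call(c, parts)
}

#' Posterior summary of the regression coefficients
#'
#' Pooled over chains: posterior mean, SD and equal-tailed 95% credibility
#' interval (empirical 2.5% / 97.5% quantiles) for the intercept and each
#' covariate effect.
#'
#' @param post a [bym_fit()] result.
#' @param names optional covariate labels.
#' @return data.frame with columns `name`, `mean`, `sd`, `q2.5`, `q97.5`.
#' @export
summarize_coefficients <- function(post, names = NULL) {
  stopifnot(inherits(post, "bym_posterior"))
  draws <- cbind(Intercept = pool_chains(post, "alpha0"))
  b <- pool_chains(post, "beta")
  if (!is.null(b) && ncol(b) > 0) draws <- cbind(draws, b)
  labels <- c("Intercept", names %||% post$covariate_names)
  colnames(draws) <- labels
  data.frame(name = labels,
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             q2.5 = apply(draws, 2, stats::quantile, probs = 0.025),
             q97.5 = apply(draws, 2, stats::quantile, probs = 0.975),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior summary of area relative risks
#'
#' Per-area posterior mean and 95% credibility interval of the relative
#' risk, plus the exceedance probability `P(theta_i > 1)` (the fraction of
#' draws strictly above 1).
#'
#' @param post a [bym_fit()] result.
#' @param area_ids optional replacement labels.
#' @return data.frame with columns `area`, `mean`, `q2.5`, `q97.5`,
#'   `prob_exceed`.
#' @export
relative_risk_summary <- function(post, area_ids = NULL) {
  stopifnot(inherits(post, "bym_posterior"))
  th <- pool_chains(post, "theta")
  data.frame(area = area_ids %||% post$area_ids,
             mean = colMeans(th),
             q2.5 = apply(th, 2, stats::quantile, probs = 0.025),
             q97.5 = apply(th, 2, stats::quantile, probs = 0.975),
             prob_exceed = colMeans(th > 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
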