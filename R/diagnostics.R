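#' Bundle MCMC draws from several chains
#'
#' @param draws either a 3-d array `[chain, iteration, parameter]` or a
#'   list of per-chain matrices (iterations in rows, parameters in
#'   columns) of equal dimensions.
#' @param param_names optional parameter labels.
#' @return an object of class `chain_set`.
#' @export
chain_set <- function(draws, param_names = NULL) {
  if (is.list(draws)) {
    mats <- lapply(draws, function(d) {
      d <- as.matrix(d)
      d
    })
    dims <- vapply(mats, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("all chains must have equal dimensions")
    }
    arr <- array(0, c(length(mats), dims[1, 1], dims[2, 1]))
    for (c in seq_along(mats)) arr[c, , ] <- mats[[c]]
    if (is.null(param_names)) param_names <- colnames(mats[[1]])
    draws <- arr
  }
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[2] < 2) stop("chains must have at least 2 iterations")
  if (is.null(param_names)) {
    param_names <- paste0("param_", seq_len(dim(draws)[3]))
  }
  structure(list(draws = draws, param_names = param_names),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  d <- dim(x$draws)
  cat("chain_set: ", d[1], " chains x ", d[2], " iterations x ", d[3],
      " parameters\n", sep = "")
  invisible(x)
}

#' Split every chain of a chain set in half
#'
#' Doubling the chain count lets the potential scale reduction factor be
#' computed from a single chain (first half vs second half).
#'
#' @param cs a [chain_set()].
#' @return a [chain_set()] with `2 * n_chains` chains of half length.
#' @export
split_chains <- function(cs) {
  stopifnot(inherits(cs, "chain_set"))
  d <- dim(cs$draws)
  n <- d[2] %/% 2
  out <- array(0, c(2 * d[1], n, d[3]))
  for (c in seq_len(d[1])) {
    out[2 * c - 1, , ] <- cs$draws[c, seq_len(n), , drop = FALSE]
    out[2 * c, , ] <- cs$draws[c, seq(d[2] - n + 1, d[2]), , drop = FALSE]
  }
  chain_set(out, cs$param_names)
}

#' Potential scale reduction factor (split-chain R-hat)
#'
#' Gelman-Rubin convergence statistic: each chain is split in half and
#' the square root of the ratio of the pooled variance estimate
#' `(n-1)/n W + B/n` to the within-chain variance `W` is reported per
#' parameter. Values near 1 indicate the chains agree; a common gate is
#' R-hat < 1.05.
#'
#' @param cs a [chain_set()] with at least 2 chains (split a single chain
#'   first with [split_chains()]).
#' @return named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(cs) {
  stopifnot(inherits(cs, "chain_set"))
  if (dim(cs$draws)[1] < 2) {
    stop("need at least 2 chains; use split_chains() for split-chain mode")
  }
  halved <- split_chains(cs)
  arr <- halved$draws
  C <- dim(arr)[1]; n <- dim(arr)[2]; P <- dim(arr)[3]
  out <- numeric(P)
  for (p in seq_len(P)) {
    x <- arr[, , p, drop = FALSE]
    dim(x) <- c(C, n)
    mu <- rowMeans(x)
    W <- mean(apply(x, 1, stats::var))
    B <- n * stats::var(mu)
    if (W == 0) {
      out[p] <- NA_real_
      next
    }
    out[p] <- sqrt(((n - 1) / n * W + B / n) / W)
  }
  stats::setNames(out, cs$param_names)
}

#' Effective sample size
#'
#' Autocorrelation-sum estimator: lagged correlations are estimated from
#' the variogram pooled over chains and summed in consecutive pairs,
#' truncating at the first pair with a non-positive sum (initial positive
#' sequence). The ESS is the total number of draws divided by
#' `1 + 2 * sum(rho)`, capped at the total number of draws. Chains with
#' zero variance report the total draw count and carry a
#' `zero_variance` attribute.
#'
#' @param cs a [chain_set()] (one chain of length >= 10 suffices).
#' @return named numeric vector of ESS values, with a logical attribute
#'   `zero_variance` marking degenerate parameters.
#' @export
effective_sample_size <- function(cs) {
  stopifnot(inherits(cs, "chain_set"))
  arr <- cs$draws
  C <- dim(arr)[1]; n <- dim(arr)[2]; P <- dim(arr)[3]
  if (n < 10) stop("chains must have at least 10 iterations")
  out <- numeric(P)
  zv <- logical(P)
  for (p in seq_len(P)) {
    x <- arr[, , p, drop = FALSE]
    dim(x) <- c(C, n)
    W <- mean(apply(x, 1, stats::var))
    if (W == 0) {
      out[p] <- C * n
      zv[p] <- TRUE
      next
    }
    mu <- rowMeans(x)
    B <- if (C > 1) n * stats::var(mu) else W
    var_plus <- (n - 1) / n * W + B / n
    # variogram-based lag correlations, paired truncation
    tau <- 1
    t <- 1L
    repeat {
      if (t + 1L > n - 1L) break
      rho1 <- 1 - variogram_at(x, t) / (2 * var_plus)
      rho2 <- 1 - variogram_at(x, t + 1L) / (2 * var_plus)
      if (rho1 + rho2 <= 0) break
      tau <- tau + 2 * (rho1 + rho2)
      t <- t + 2L
    }
    out[p] <- min(C * n, C * n / tau)
  }
  if (any(zv)) warning("zero-variance chain(s): ESS reported as total draws")
  structure(stats::setNames(out, cs$param_names), zero_variance = zv)
}

variogram_at <- function(x, t) {
  C <- nrow(x); n <- ncol(x)
  s <- 0
  for (c in seq_len(C)) {
    d <- x[c, seq(t + 1, n)] - x[c, seq_len(n - t)]
    s <- s + sum(d^2)
  }
  s / (C * (n - t))
}

#' Chain set of the headline convolution-model parameters
#'
#' Extracts intercept, covariate effects and log precisions from a fitted
#' model for convergence checking.
#'
#' @param post a [bym_fit()] result.
#' @return a [chain_set()].
#' @export
bym_chain_set <- function(post) {
  stopifnot(inherits(post, "bym_posterior"))
  mats <- lapply(post$chains, function(ch) {
    cbind(ch$alpha0, ch$beta, log(ch$tau_u), log(ch$tau_v))
  })
  chain_set(mats, c("alpha0", post$covariate_names, "log_tau_u", "log_tau_v"))
}
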