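# Internal helpers shared across modules.

# Derive a deterministic substream seed from a master seed and a named
# stream, so that adding a new source of randomness to a generator never
# perturbs the draws of an existing one.  Kept below 2^31 - 1.
stream_seed <- function(seed, stream) {
  streams <- c(populations = 1L, scores = 2L, noise = 3L, u = 4L, v = 5L,
               y = 6L, chain = 7L, init = 8L, covariates = 9L, befa = 10L)
  if (!stream %in% names(streams)) {
    stop("unknown random stream: ", stream)
  }
  base <- as.integer(abs(as.numeric(seed)) %% 2000003)
  base * 1009L + streams[[stream]] * 7919L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("arealrisk_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
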