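# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit FNV-1a hash of an R object (used for run manifests).
object_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(raw)) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(low8, b)
    # 32-bit modular multiply in two 16-bit halves (doubles lose
    # precision above 2^53)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  # h is a double (possibly above integer range): format in 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Low-pass cutoff actually applied for a given sampling rate: the nominal
# 5 Hz movement cutoff, capped below Nyquist for low-rate recordings.
effective_lowpass <- function(cutoff, sampling_rate)
  min(cutoff, 0.45 * sampling_rate)

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
}
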