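# Internal helpers: seed substreams and scoped RNG state.

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed; each component
#' (environment tables, community draws, grids, CV fold shuffles, permutation
#' blocks) draws from its own named substream so that adding one component
#' never perturbs another's stream.
#'
#' @param seed master seed (integer-like).
#' @param stream substream identifier: an integer or a character label.
#' @return An integer seed in \code{[0, 2^31)}.
#' @keywords internal
substream <- function(seed, stream) {
  if (is.character(stream)) {
    v <- utf8ToInt(stream)
    stream <- sum(v * seq_along(v)) %% 1e6
  }
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(stream) * 7919 + 12345) %%
               2147483629)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  if (!is.null(seed)) set.seed(seed)
  force(code)
}

# Small stable text hash (FNV-1a over UTF-8 bytes), for run-record config hashes.
text_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
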