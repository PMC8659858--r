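# internal helpers

# evaluate code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8-hex-digit string;
# used to checksum the serialized truth block in dataset manifests
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256), keeping h exact in doubles
    h <- (h - h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619, split to stay exact
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  # h is a double holding a 32-bit value; format halves as hex
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# derive a bounded child seed from a base seed and a stream index
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7907 * as.numeric(k)) %% 2147483629
}
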