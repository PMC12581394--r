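# run code under a temporary RNG seed, restoring the caller's RNG state;
# seed = NULL leaves the global stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# FNV-1a hash of a character scalar, reported as 8 hex digits; used to stamp
# outputs with a fingerprint of their configuration
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  # 32-bit xor in doubles (bitwXor is limited to signed 32-bit integers)
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
  }
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    # 32-bit modular multiply by the FNV prime 16777619 (= 2^24 + 403),
    # kept inside double precision: h * 2^24 mod 2^32 == (h mod 2^8) * 2^24
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"))
}
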