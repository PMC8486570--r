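# shared internal helpers

# soft-thresholding operator
soft_threshold <- function(z, g) {
  sign(z) * pmax(abs(z) - g, 0)
}

# row-wise softmax with max subtraction (overflow-safe)
row_softmax <- function(scores) {
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

softmax_vec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# polynomial rolling hash of a string, 8 hex digits (run-log config fingerprint)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
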