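# Internal helpers shared across modules.

# Deterministic 31-bit seed derived from a master seed and string keys.
# Polynomial rolling hash (djb2-style) over the UTF-8 code points of the
# key, folded with the master seed modulo a prime below 2^31. Stable across
# platforms because it only uses exact double-precision integer arithmetic
# (all intermediates stay far below 2^53).
mix_seed <- function(master, ...) {
  key <- paste(..., sep = "", collapse = "")
  M <- 2147483629 # largest prime < 2^31
  h <- 5381
  for (cp in utf8ToInt(key)) h <- (h * 33 + cp) %% M
  h <- (h * 31 + (as.numeric(master) %% M)) %% M
  as.integer(h + 1)
}

# Full-precision numeric formatting used by every artifact writer so that
# read(write(x)) round-trips exactly and repeated runs are byte-identical.
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 2x2 symmetric positive-definite checks/ops used by the samplers.
det2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]

is_spd2 <- function(m) {
  is.matrix(m) && all(dim(m) == 2) && isTRUE(all.equal(m[1, 2], m[2, 1])) &&
    m[1, 1] > 0 && det2(m) > 0
}
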