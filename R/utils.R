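# internal numerical helpers: unitary FFTs, shifts, seeded RNG, hashing

# swap halves so that DC (index 1 of fft output) moves to N/2 + 1
fftshift1 <- function(x) {
  n <- length(x)
  c(x[(floor(n / 2) + 1):n], x[1:floor(n / 2)])
}

ifftshift1 <- function(x) {
  n <- length(x)
  c(x[(ceiling(n / 2) + 1):n], x[1:ceiling(n / 2)])
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((ceiling(n1 / 2) + 1):n1, 1:ceiling(n1 / 2)),
    c((ceiling(n2 / 2) + 1):n2, 1:ceiling(n2 / 2))]
}

# unitary 2-D FFT (forward: sign -1; inverse: sign +1)
fft2u <- function(m, inverse = FALSE) {
  out <- stats::mvfft(t(stats::mvfft(m, inverse = inverse)),
                      inverse = inverse)
  t(out) / sqrt(length(m))
}

# run expr with a local RNG state so callers' streams are untouched
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# 32-bit FNV-1a over a character string; used for provenance hashes and
# stable per-animal seed derivation. Arithmetic on doubles stays < 2^53
# so it is exact; the xor with an 8-bit value only touches the low byte.
fnv32d <- function(s) {
  b <- utf8ToInt(enc2utf8(paste(s, collapse = "|")))
  h <- 2166136261
  for (x in b) {
    # xor of h (32-bit) with x (8-bit): only low byte affected
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(x))
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# derive a deterministic 31-bit seed from a master seed and string tags
deriveSeed <- function(master, ...) {
  tag <- paste(c(as.character(master), vapply(list(...), as.character,
                                              character(1))),
               collapse = "||")
  as.integer(fnv32d(tag) %% 2147483647)
}

# short hex hash of an R object via its deparsed/JSON form
objectHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- fnv32d(as.character(s))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# cumulative trapezoid integral on a uniform or non-uniform grid
cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}
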