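# Internal numeric helpers shared across modules.

# clamp values into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Euclidean distance between (x1,y1) and (x2,y2), vectorised
euclid <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

# Centred rolling sums over a window of `w` frames, treating NA as absent.
# Returns list(sum, sumsq, n) where n counts non-NA values in each window.
# For frame i the window is i - h1 .. i + h2 with h1 = floor((w-1)/2).
roll_stats <- function(x, w) {
  stopifnot(w >= 1)
  n <- length(x)
  ok <- !is.na(x)
  v <- ifelse(ok, x, 0)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  cn <- cumsum(as.numeric(ok))
  h1 <- floor((w - 1) / 2)
  h2 <- w - 1 - h1
  i <- seq_len(n)
  hi <- pmin(i + h2, n)
  lo <- pmax(i - h1, 1)
  at <- function(c, idx) ifelse(idx >= 1, c[pmax(idx, 1)], 0)
  list(
    sum   = cs[hi] - at(cs, lo - 1),
    sumsq = cs2[hi] - at(cs2, lo - 1),
    n     = cn[hi] - at(cn, lo - 1)
  )
}

# Centred rolling mean with minimum support; NA where support < min_n.
roll_mean <- function(x, w, min_n = 1) {
  st <- roll_stats(x, w)
  out <- st$sum / st$n
  out[st$n < min_n] <- NA_real_
  out
}

# Centred rolling sample variance (n-1 denominator); NA where support < min_n.
roll_var <- function(x, w, min_n = 2) {
  st <- roll_stats(x, w)
  out <- (st$sumsq - st$sum^2 / st$n) / (st$n - 1)
  out[st$n < max(min_n, 2)] <- NA_real_
  pmax(out, 0) # guard tiny negative round-off
}

# last-observation-carried-forward, then backfill leading NAs
locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cumsum(ok)
  filled <- c(x[ok][1], x[ok])[idx + 1]
  filled
}

# run-length segments of a logical vector: data.frame(start, end) of TRUE runs
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

# 32-bit FNV-1a hash of a deparsed R object, as 8 hex digits; stamps output
# files with a config fingerprint.
config_hash <- function(obj) {
  s <- paste(deparse(obj, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor the byte into the low 8 bits (b < 256 after UTF-8 encoding of ints
    # may exceed 255 for multibyte chars; fold it first)
    b <- b %% 256
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    # h * 16777619 mod 2^32 in exact double arithmetic
    h <- ((lo * 16777619) %% 4294967296 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_st <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
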