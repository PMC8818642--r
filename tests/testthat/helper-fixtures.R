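# Shared fixture builders (all generated in code; no stored data).

# minimal localization table with explicit values
tiny_table <- function() {
  loc_table(frame = c(3L, 1L, 2L),
            x_nm = c(100.5, 250.25, 400),
            y_nm = c(50, 75.5, 90),
            precision_nm = c(12, 18, 25))
}

# straight horizontal bundle with optional noise, precision zero
straight_bundle_table <- function(n = 1000, sigma = 0, length_nm = 2000,
                                  precision = 0, seed = 1) {
  set.seed(seed)
  x <- runif(n, 0, length_nm)
  y <- rnorm(n, 0, sigma)
  if (precision > 0) {
    x <- x + rnorm(n, 0, precision)
    y <- y + rnorm(n, 0, precision)
  }
  loc_table(frame = sample.int(1000, n, TRUE), x_nm = x, y_nm = y,
            precision_nm = rep(max(precision, 1e-9), n))
}

# brute-force Otsu oracle: exhaustive threshold search maximizing
# between-class variance (smallest threshold on ties)
otsu_oracle <- function(v, candidates = 0:255) {
  best_t <- NA
  best_b <- -Inf
  for (t in candidates) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    b <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (b > best_b + 1e-12) {
      best_b <- b
      best_t <- t
    }
  }
  best_t
}

# "+" cross skeleton fixture: two 1-px lines crossing at the center,
# arm length `arm` pixels, on a (2*arm+1+2*pad)^2 canvas
cross_mask <- function(arm = 20, pad = 3) {
  n <- 2 * arm + 1 + 2 * pad
  ctr <- pad + arm + 1
  m <- matrix(FALSE, n, n)
  m[ctr, (ctr - arm):(ctr + arm)] <- TRUE
  m[(ctr - arm):(ctr + arm), ctr] <- TRUE
  m
}
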