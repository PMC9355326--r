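# Shared small fixtures, built once per test run.

small_cfg <- function(n = 3L) {
  shade_config(n_per_level = n)
}

# A 12-scene dataset at reduced resolution, shared across test files.
small_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- synth_dataset(small_cfg(), seed = 101L, width = 64L, height = 64L)
    }
    ds
  }
})

# Independent brute-force Kapur oracle: bins and scans every cut explicitly.
kapur_oracle <- function(values, n_bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  p <- counts / sum(counts)
  best_h <- -Inf
  best_t <- NA_integer_
  for (t in 1:(n_bins - 1L)) {
    p0 <- p[1:t]; p1 <- p[(t + 1L):n_bins]
    P0 <- sum(p0); P1 <- sum(p1)
    if (P0 <= 0 || P1 <= 0) next
    h0 <- 0
    for (q in p0) if (q > 0) h0 <- h0 - (q / P0) * log(q / P0)
    h1 <- 0
    for (q in p1) if (q > 0) h1 <- h1 - (q / P1) * log(q / P1)
    if (h0 + h1 > best_h) { best_h <- h0 + h1; best_t <- t }
  }
  edges[best_t + 1L]
}

as_gray <- function(m) {
  structure(list(gray = m, valid = matrix(TRUE, nrow(m), ncol(m))),
            class = "gray_image")
}
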