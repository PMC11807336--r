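# shared fixtures for the suite

# the worked toy example: k = 6, m = 3, lexicographic minimizer order
toy_params <- function(f = 1) {
  sketch_params(k = 6L, m = 3L, f = f, order = "lex")
}
TOY_SEQ <- "CTGAAATGCACATTT"

default_params <- function(f = 1, seed = 42L, ...) {
  sketch_params(k = 31L, m = 15L, f = f, seed = seed, ...)
}

# standard error of the mean of an autocorrelated 0/1 series, from disjoint
# block means (overlapping k-mers share m-mers, so plain binomial SEs
# understate the fluctuation by ~sqrt(w))
blocked_se <- function(x, block = 1000L) {
  nb <- length(x) %/% block
  bm <- colMeans(matrix(x[seq_len(nb * block)], nrow = block))
  stats::sd(bm) / sqrt(nb)
}

# per-k-mer minimizer oracle: hash every m-mer of the k-mer independently
# and take the leftmost argmin (no sliding-window machinery)
oracle_minimizer <- function(kmer, params) {
  m <- params$m
  starts <- seq_len(nchar(kmer) - m + 1L)
  hv <- hash_mmer(substring(kmer, starts, starts + m - 1L), params)
  pos <- which.min(hv)  # which.min takes the first minimum: leftmost
  list(position = pos - 1L, hash = hv[pos],
       sequence = substring(kmer, pos, pos + m - 1L))
}

# GC count of every k-mer of a sequence, via cumulative sums
kmer_gc <- function(seq, k) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]] %in% c("G", "C")
  cs <- cumsum(b)
  n <- length(b) - k + 1L
  cs[k:(n + k - 1L)] - c(0, cs)[1:n]
}
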