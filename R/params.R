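# Sketching parameters and the fraction <-> threshold calibration.

# Size of the integer hash space. Hash-order minimizers use 53-bit hashes so
# values stay exact in an R double; lexicographic order uses the 2-bit packed
# value on [0, 4^m).
hash_space_size <- function(order, m) {
  if (order == "lex") 4^m else 2^53
}

#' Sketching parameters
#'
#' Bundles every knob that governs sketch construction: the k-mer length `k`,
#' the minimizer length `m` (so each k-mer holds `w = k - m + 1` m-mers), the
#' target sampled fraction `f` of the k-mer space (equivalently the
#' subsampling rate `s = 1/f`), the hash seed, strand handling and the
#' minimizer order. The integer hash threshold `t` is derived from `f` via
#' [threshold_from_fraction()] so that a k-mer is covered (contains a small
#' m-mer) with probability `f`.
#'
#' @param k k-mer length in bases (`k >= 2`).
#' @param m minimizer length in bases (`m < k`, `m <= 26`).
#' @param s subsampling rate, `s = 1/f`. Mutually exclusive with `f`;
#'   defaults to 1000 when neither is given.
#' @param f target sampled fraction in (0, 1].
#' @param seed integer seed of the m-mer hash function.
#' @param canonical if `TRUE`, m-mer hashes are strand-canonical
#'   (`hash(x) == hash(revcomp(x))`, implemented as the min of the two strand
#'   hashes). Default `FALSE`: sequences are processed as given.
#' @param order minimizer order: `"hash"` (seeded random order, the default)
#'   or `"lex"` (lexicographic, useful for worked examples).
#' @param uhs_mode `"none"` or `"decycling"`: restrict candidate minimizers
#'   to members of a decycling set of the order-`m` de Bruijn graph.
#' @return An object of class `sketch_params` with fields `k`, `m`, `w`, `f`,
#'   `s`, `p` (probability an m-mer is small), `t` (integer hash threshold),
#'   `space` (hash space size), `sigma`, `seed`, `canonical`, `order`,
#'   `uhs_mode`.
#' @examples
#' sketch_params(k = 31, m = 15, s = 1000)
#' @export
sketch_params <- function(k = 31L, m = 15L, s = NULL, f = NULL, seed = 42L,
                          canonical = FALSE, order = c("hash", "lex"),
                          uhs_mode = c("none", "decycling")) {
  order <- match.arg(order)
  uhs_mode <- match.arg(uhs_mode)
  k <- as.integer(k); m <- as.integer(m)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (is.na(m) || m < 1L || m >= k) stop("m must satisfy 1 <= m < k")
  if (m > 26L) stop("m must be <= 26 (2-bit packed minimizer keys)")
  w <- k - m + 1L
  if (w < 2L) stop("window count w = k - m + 1 must be >= 2")
  if (!is.null(s) && !is.null(f)) stop("give either s or f, not both")
  if (is.null(f)) f <- 1 / (if (is.null(s)) 1000 else s)
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("sampled fraction f must lie in (0, 1]")
  space <- hash_space_size(order, m)
  th <- threshold_from_fraction(f, w, space = space)
  structure(
    list(k = k, m = m, w = w, f = f, s = 1 / f, p = th$p, t = th$t,
         space = space, sigma = 4L, seed = as.integer(seed),
         canonical = isTRUE(canonical), order = order, uhs_mode = uhs_mode),
    class = "sketch_params")
}

#' @export
print.sketch_params <- function(x, ...) {
  cat(sprintf("Sketch parameters: k = %d, m = %d (w = %d)\n", x$k, x$m, x$w))
  cat(sprintf("  sampled fraction f = %g (rate s = %g), p = %g, t = %.0f\n",
              x$f, x$s, x$p, x$t))
  cat(sprintf("  order = %s, canonical = %s, uhs_mode = %s, seed = %d\n",
              x$order, x$canonical, x$uhs_mode, x$seed))
  invisible(x)
}

#' Hash threshold achieving a target covered fraction
#'
#' Inverts the coverage relation `f = 1 - (1 - p)^w`: to cover a fraction `f`
#' of k-mers, a single m-mer must be small with probability
#' `p = 1 - (1 - f)^(1/w)`, and the integer threshold on the hash space is
#' `t = round(p * space)`.
#'
#' @param f target covered fraction in (0, 1].
#' @param w window count (number of m-mers per k-mer), `w >= 1`.
#' @param space hash space size (default the 53-bit hash space).
#' @return A list with components `p` (per-m-mer probability) and `t`
#'   (integer threshold).
#' @seealso [coverage_from_probability()] for the forward direction.
#' @export
threshold_from_fraction <- function(f, w, space = 2^53) {
  if (!is.numeric(f) || any(f <= 0) || any(f > 1))
    stop("f must lie in (0, 1]")
  if (!is.numeric(w) || any(w < 1)) stop("w must be >= 1")
  p <- -expm1(log1p(-f) / w)  # 1 - (1 - f)^(1/w), stable for small f
  list(p = p, t = round(p * space))
}

#' Expected covered fraction from the small-m-mer probability
#'
#' Among k-mers whose `w` m-mers are distinct, the expected fraction
#' containing at least one small m-mer is `f = 1 - (1 - p)^w`.
#'
#' @param p probability that a single m-mer is small, in \[0, 1\].
#' @param w window count, `w >= 1`.
#' @return The expected covered fraction.
#' @export
coverage_from_probability <- function(p, w) {
  if (!is.numeric(p) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  if (!is.numeric(w) || any(w < 1)) stop("w must be >= 1")
  -expm1(w * log1p(-p))  # 1 - (1 - p)^w
}

# params compatibility for sketch comparison
params_compatible <- function(a, b) {
  identical(a$k, b$k) && identical(a$m, b$m) && identical(a$t, b$t) &&
    identical(a$seed, b$seed) && identical(a$canonical, b$canonical) &&
    identical(a$order, b$order) && identical(a$uhs_mode, b$uhs_mode)
}
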