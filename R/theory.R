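# Closed-form density, coverage, maximal-proportion and encoding-cost theory
# for small-minimizer sampling on i.i.d. random sequences. All functions
# return leading terms; o(1/w) corrections are not modelled, so empirical
# checks treat these as (upper) bounds plus sampling noise.

#' Expected density bound of small minimizers
#'
#' Leading term of the density bound for the small-minimizer scheme on a
#' random sequence: `2 f / (w + 1)`. At `f = 1` this is the classical
#' `2 / (w + 1)` random-order minimizer density.
#'
#' @param f sampled fraction in (0, 1].
#' @param w window count, `w >= 2`.
#' @return The density bound (selected minimizers per m-mer position).
#' @export
density_bound <- function(f, w) {
  if (!is.numeric(f) || any(f <= 0) || any(f > 1)) stop("f must lie in (0, 1]")
  if (!is.numeric(w) || any(w < 2)) stop("w must be >= 2")
  2 * f / (w + 1)
}

#' Restricted density factor
#'
#' Dimensionless factor of the density bound restricted to the covered part
#' of the sequence (the bound times `w + 1`):
#' `2 (f + (1 - f) ln(1 - f)) / f^2`.
#' It decreases from 2 at `f = 1` (the classical random-order factor) to 1
#' as `f -> 0`, i.e. sparse sampling approaches the optimal density on what
#' it covers. The endpoint `f = 1` is the analytic continuation (the `ln`
#' term vanishes); small `f` uses a series expansion to avoid cancellation.
#'
#' @param f sampled fraction in (0, 1].
#' @return The restricted density factor, in \[1, 2\].
#' @export
restricted_density_factor <- function(f) {
  if (!is.numeric(f) || any(f <= 0) || any(f > 1)) stop("f must lie in (0, 1]")
  out <- numeric(length(f))
  one <- f == 1
  tiny <- !one & f < 1e-3
  mid <- !one & !tiny
  out[one] <- 2
  # 2 * (f + (1-f)log(1-f)) / f^2 = 1 + f/3 + f^2/6 + f^3/10 + ...
  out[tiny] <- 1 + f[tiny] / 3 + f[tiny]^2 / 6 + f[tiny]^3 / 10
  fm <- f[mid]
  out[mid] <- 2 * (fm + (1 - fm) * log1p(-fm)) / fm^2
  out
}

#' Expected proportion of maximal super-k-mers
#'
#' Closed-form expected fraction of super-k-mers that are maximal (contain
#' the full `w = k - m + 1` k-mers) among super-k-mers built from small
#' minimizers on a random sequence:
#' `((1 - 1/w) f / (1 + f))^2 + (1 - f (1 - 2/w)) / (1 + f)`.
#' At `f = 1` this equals `1/4 + 1/(2w) + 1/(4 w^2)`, approaching 1/4 for
#' large `w`; as `f -> 0` it tends to 1 (nearly all stored super-k-mers are
#' maximal under sparse sampling).
#'
#' @param f sampled fraction in \[0, 1\].
#' @param w window count, `w >= 2`.
#' @param clamp if `TRUE`, clamp the result into \[0, 1\] (the closed form
#'   can exceed 1/4-anchored values by O(1/w) terms). Default `FALSE`:
#'   return the expression as printed.
#' @return Expected maximal proportion.
#' @export
maximal_fraction <- function(f, w, clamp = FALSE) {
  if (!is.numeric(f) || any(f < 0) || any(f > 1)) stop("f must lie in [0, 1]")
  if (!is.numeric(w) || any(w < 2)) stop("w must be >= 2")
  val <- ((1 - 1 / w) * f / (1 + f))^2 + (1 - f * (1 - 2 / w)) / (1 + f)
  if (clamp) val <- pmin(pmax(val, 0), 1)
  val
}

#' Density bound under a UHS restriction
#'
#' When candidate minimizers are restricted to a universal hitting set of
#' density `d_U`, the expected density of selected small minimizers is
#' bounded by `f * d_U` (leading term). With `d_U = 2/(w+1)` and `f = 1`
#' this recovers [density_bound()].
#'
#' @param f sampled fraction in (0, 1].
#' @param d_U density of the restricting universal hitting set, `> 0`.
#' @return The density bound `f * d_U`.
#' @export
uhs_density_bound <- function(f, d_U) {
  if (!is.numeric(f) || any(f <= 0) || any(f > 1)) stop("f must lie in (0, 1]")
  if (!is.numeric(d_U) || any(d_U <= 0)) stop("d_U must be > 0")
  f * d_U
}

#' Super-k-mer encoding costs in bits per k-mer
#'
#' The four closed-form storage costs for super-k-mer encodings of sampled
#' k-mers (2 bits per base):
#' \describe{
#'   \item{plain_superkmer}{`2(3k - m - 1)/(k - m + 1)` — average-length
#'     super-k-mers, no length fields.}
#'   \item{with_length}{`2(3k - m - 1 + log2(k - m + 1))/(k - m + 1)` —
#'     adds a per-record k-mer-count field so no artefactual k-mers can be
#'     read across record boundaries (`log2` as a real number, not a
#'     ceiling).}
#'   \item{maximal}{`2(2k - m)/(k - m + 1)` — maximal super-k-mers, which
#'     need no length field.}
#'   \item{partitioned_maximal}{`4(k - m)/(k - m + 1)` — maximal
#'     super-k-mers with the minimizer omitted (stored once per
#'     partition).}
#' }
#'
#' @param k k-mer length, `k > m`.
#' @param m minimizer length.
#' @return A list of class `encoding_cost` with fields `k`, `m` and the four
#'   costs; always `partitioned_maximal < maximal < with_length`.
#' @export
encoding_costs <- function(k, m) {
  if (!is.numeric(k) || !is.numeric(m) || any(m >= k) || any(m < 1))
    stop("need 1 <= m < k")
  w <- k - m + 1
  structure(
    list(k = k, m = m,
         plain_superkmer = 2 * (3 * k - m - 1) / w,
         with_length = 2 * (3 * k - m - 1 + log2(w)) / w,
         maximal = 2 * (2 * k - m) / w,
         partitioned_maximal = 4 * (k - m) / w),
    class = "encoding_cost")
}

#' @export
print.encoding_cost <- function(x, ...) {
  cat(sprintf("Encoding costs (bits/k-mer) for k = %d, m = %d:\n",
              as.integer(x$k[1]), as.integer(x$m[1])))
  cat(sprintf("  plain super-k-mer      %.3f\n", x$plain_superkmer[1]))
  cat(sprintf("  with length field      %.3f\n", x$with_length[1]))
  cat(sprintf("  maximal                %.3f\n", x$maximal[1]))
  cat(sprintf("  partitioned maximal    %.3f\n", x$partitioned_maximal[1]))
  invisible(x)
}

#' Theory grid as a data frame
#'
#' Evaluates the closed-form quantities over a grid of `(f, k, m)`, one row
#' per combination. Used by the `theory` CLI subcommand.
#'
#' @param f sampled fractions.
#' @param k,m k-mer and minimizer lengths (recycled pairwise).
#' @return A data frame with columns `f`, `w`, `k`, `m`, `density_bound`,
#'   `restricted_density_factor`, `maximal_fraction` and the four encoding
#'   costs.
#' @export
theory_table <- function(f = 1, k = 31L, m = 15L) {
  grid <- expand.grid(f = f, k = k, m = m, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$m < grid$k, , drop = FALSE]
  w <- grid$k - grid$m + 1
  ec <- encoding_costs(grid$k, grid$m)
  data.frame(
    f = grid$f, w = w, k = grid$k, m = grid$m,
    density_bound = density_bound(grid$f, w),
    restricted_density_factor = restricted_density_factor(grid$f),
    maximal_fraction = maximal_fraction(grid$f, w),
    plain_superkmer = ec$plain_superkmer,
    with_length = ec$with_length,
    maximal = ec$maximal,
    partitioned_maximal = ec$partitioned_maximal)
}
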