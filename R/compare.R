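# Sketch comparison: partition-wise (skipping partitions present in only one
# sketch), a naive whole-sketch reference path, and the Jaccard, containment,
# cosine and angular similarity computations.

comparison_result <- function(shared, size_a, size_b, cosine = NA_real_,
                              skipped_partitions = NA_integer_) {
  un <- size_a + size_b - shared
  structure(list(
    shared = shared, size_a = size_a, size_b = size_b, union = un,
    jaccard = if (un > 0) shared / un else NA_real_,
    containment_a_in_b = if (size_a > 0) shared / size_a else NA_real_,
    containment_b_in_a = if (size_b > 0) shared / size_b else NA_real_,
    cosine = cosine,
    angular_similarity = if (is.na(cosine)) NA_real_
                         else angular_similarity(cosine),
    skipped_partitions = skipped_partitions),
    class = "fhs_comparison")
}

#' @export
print.fhs_comparison <- function(x, ...) {
  cat("Sketch comparison\n")
  cat(sprintf("  shared %d | union %d | |A| %d | |B| %d\n",
              x$shared, x$union, x$size_a, x$size_b))
  cat(sprintf("  jaccard %.6g | containment A-in-B %.6g | B-in-A %.6g\n",
              x$jaccard, x$containment_a_in_b, x$containment_b_in_a))
  if (!is.na(x$cosine))
    cat(sprintf("  cosine %.6g | angular similarity %.6g\n",
                x$cosine, x$angular_similarity))
  if (!is.na(x$skipped_partitions))
    cat(sprintf("  partitions skipped: %d\n", x$skipped_partitions))
  invisible(x)
}

# cosine between two decoded abundance maps (named vectors); absent keys
# contribute 0, so only shared keys enter the dot product
abundance_cosine <- function(ab_a, ab_b) {
  if (length(ab_a) == 0L || length(ab_b) == 0L) return(NA_real_)
  common <- intersect(names(ab_a), names(ab_b))
  dot <- if (length(common)) sum(ab_a[common] * ab_b[common]) else 0
  na <- sqrt(sum(ab_a^2)); nb <- sqrt(sum(ab_b^2))
  if (na == 0 || nb == 0)
    stop(errorCondition("undefined cosine similarity: all-zero vector",
                        class = c("fhs_undefined_similarity", "error",
                                  "condition")))
  dot / (na * nb)
}

#' Compare two sketches partition by partition
#'
#' Counts shared k-mers by visiting only the minimizer partitions present
#' in both sketches; partitions unique to one sketch are skipped (they
#' cannot hold shared k-mers and contribute only to the set sizes). Because
#' sketches store sampled k-mers exactly, the result equals a naive
#' comparison of the two sampled k-mer sets. When both sketches carry an
#' abundance block, cosine and angular similarity of the k-mer multisets
#' are computed from the decoded abundances.
#'
#' @param a,b `fhs_sketch` objects built with compatible parameters
#'   (same `k`, `m`, threshold, seed, strand handling, order).
#' @return An `fhs_comparison` with fields `shared`, `size_a`, `size_b`,
#'   `union`, `jaccard`, `containment_a_in_b`, `containment_b_in_a`,
#'   `cosine`, `angular_similarity`, `skipped_partitions`.
#' @export
compare_sketches <- function(a, b) {
  stopifnot(inherits(a, "fhs_sketch"), inherits(b, "fhs_sketch"))
  if (!params_compatible(a$params, b$params))
    stop(errorCondition(
      "incompatible sketches: parameters (k, m, t, seed, canonical, order) differ",
      class = c("fhs_incompatible_sketch", "error", "condition")))
  keys_a <- names(a$partitions)
  keys_b <- names(b$partitions)
  common <- intersect(keys_a, keys_b)
  skipped <- (length(keys_a) - length(common)) +
    (length(keys_b) - length(common))
  k <- a$params$k
  shared <- 0L
  for (key in common) {
    ka <- cpp_superkmers_to_kmers(a$partitions[[key]]$superkmers, k)
    kb <- cpp_superkmers_to_kmers(b$partitions[[key]]$superkmers, k)
    shared <- shared + sum(ka %in% kb)
  }
  cosine <- NA_real_
  if (a$abundance_mode != "none" && b$abundance_mode != "none")
    cosine <- abundance_cosine(decode_abundances(a), decode_abundances(b))
  comparison_result(shared, a$kmer_count, b$kmer_count, cosine, skipped)
}

#' Naive whole-sketch comparison
#'
#' Reference implementation that flattens both inputs into plain k-mer sets
#' and counts the intersection through a single dictionary, ignoring the
#' partition structure. Used as the oracle for [compare_sketches()].
#'
#' @param a,b `fhs_sketch` objects or character vectors of k-mers.
#' @param abund_a,abund_b optional named abundance vectors (used when `a`,
#'   `b` are plain k-mer vectors).
#' @return An `fhs_comparison` (with `skipped_partitions = NA`).
#' @export
naive_compare <- function(a, b, abund_a = NULL, abund_b = NULL) {
  flat <- function(x, ab) {
    if (inherits(x, "fhs_sketch")) {
      list(k = sketch_kmers(x),
           ab = if (x$abundance_mode != "none") decode_abundances(x) else NULL)
    } else list(k = unique(as.character(x)), ab = ab)
  }
  fa <- flat(a, abund_a)
  fb <- flat(b, abund_b)
  if (inherits(a, "fhs_sketch") && inherits(b, "fhs_sketch") &&
      !params_compatible(a$params, b$params))
    stop(errorCondition(
      "incompatible sketches: parameters (k, m, t, seed, canonical, order) differ",
      class = c("fhs_incompatible_sketch", "error", "condition")))
  shared <- sum(!is.na(match(fa$k, fb$k)))
  cosine <- if (!is.null(fa$ab) && !is.null(fb$ab))
    abundance_cosine(fa$ab, fb$ab) else NA_real_
  comparison_result(shared, length(fa$k), length(fb$k), cosine)
}

#' Cosine similarity of two abundance vectors
#'
#' `CS = (A . B) / (|A| |B|)` over the union of keys; a k-mer absent from
#' one vector contributes 0, so the value lies in \[0, 1\] for count
#' vectors.
#'
#' @param counts_a,counts_b named non-negative numeric vectors (k-mer
#'   abundances).
#' @return The cosine similarity.
#' @export
cosine_similarity <- function(counts_a, counts_b) {
  if (is.null(names(counts_a)) || is.null(names(counts_b)))
    stop("abundance vectors must be named by k-mer")
  abundance_cosine(counts_a, counts_b)
}

#' Angular similarity from a cosine similarity
#'
#' `AS = 1 - arccos(CS) / pi`, which turns the cosine into a quantity whose
#' complement (the angular distance `arccos(CS)/pi`) satisfies the triangle
#' inequality. The input is clamped to \[-1, 1\] against floating-point
#' overshoot.
#'
#' @param cs cosine similarity values.
#' @return Angular similarity in \[0, 1\].
#' @export
angular_similarity <- function(cs) {
  1 - acos(pmin(pmax(cs, -1), 1)) / pi
}

#' All-versus-all sketch comparison
#'
#' @param sketches a list of two or more compatible `fhs_sketch` objects
#'   (names become matrix dimnames).
#' @param metrics subset of `c("jaccard", "containment", "angular")`.
#' @return A named list of matrices: symmetric `jaccard` (and `angular`),
#'   and full `containment` with entry `[i, j] = C(A_i in A_j)`.
#'   Diagonals are 1; each pair is computed once.
#' @export
all_vs_all <- function(sketches,
                       metrics = c("jaccard", "containment", "angular")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  n <- length(sketches)
  if (n < 2L) stop("need at least two sketches")
  bad <- which(!vapply(sketches, function(s)
    params_compatible(sketches[[1L]]$params, s$params), logical(1)))
  if (length(bad))
    stop(errorCondition(
      sprintf("incompatible sketches at positions: %s",
              paste(bad, collapse = ", ")),
      class = c("fhs_incompatible_sketch", "error", "condition")))
  nm <- names(sketches)
  if (is.null(nm)) nm <- paste0("sketch", seq_len(n))
  mk <- function() matrix(1, n, n, dimnames = list(nm, nm))
  out <- list()
  if ("jaccard" %in% metrics) out$jaccard <- mk()
  if ("containment" %in% metrics) out$containment <- mk()
  if ("angular" %in% metrics) out$angular <- mk()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    cmp <- compare_sketches(sketches[[i]], sketches[[j]])
    if (!is.null(out$jaccard))
      out$jaccard[i, j] <- out$jaccard[j, i] <- cmp$jaccard
    if (!is.null(out$containment)) {
      out$containment[i, j] <- cmp$containment_a_in_b
      out$containment[j, i] <- cmp$containment_b_in_a
    }
    if (!is.null(out$angular))
      out$angular[i, j] <- out$angular[j, i] <- cmp$angular_similarity
  }
  if (!is.null(out$angular) &&
      any(vapply(sketches, function(s) s$abundance_mode == "none",
                 logical(1))))
    out$angular <- NULL
  out
}
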