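# Synthetic-data generation and empirical measurement: random sequences,
# genome pairs with controlled overlap, error-prone read simulation, and the
# density / coverage / maximal-proportion estimators that confront the
# closed-form theory. All generators take an explicit seed and restore the
# caller's RNG state.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Random DNA sequence
#'
#' I.i.d. uniform bases; reproducible from `seed` without disturbing the
#' caller's RNG state.
#'
#' @param length sequence length in bases.
#' @param seed integer seed (`NULL` uses and advances the current RNG).
#' @return A single DNA string.
#' @export
random_sequence <- function(length, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1")
  with_seed(seed, {
    v <- sample.int(4L, length, replace = TRUE)
    intToUtf8(c(65L, 67L, 71L, 84L)[v])
  })
}

# i.i.d. substitutions at `rate`; substituted bases are drawn uniformly from
# the three alternatives
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    ch[hit] <- vapply(ch[hit], function(b)
      alt[[b]][sample.int(3L, 1L)], character(1), USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

#' Measure minimizer density on a sequence
#'
#' Counts distinct selected (small) minimizer occurrences and derives the
#' density (occurrences per m-mer position) and density factor (density
#' times `w + 1`). The restricted variant divides by the m-mer positions
#' lying inside maximal runs of consecutive covered k-mers only — the
#' finite-sequence analog of conditioning on full coverage — and is the
#' empirical counterpart of [restricted_density_factor()].
#'
#' @param seq DNA string(s); non-ACGT characters split the sequence into
#'   independently processed fragments.
#' @param params a [sketch_params()] object.
#' @return An object of class `fhs_density` with fields `positions`,
#'   `selected`, `density`, `density_factor`, `covered_positions`,
#'   `restricted_density`, `restricted_density_factor`, `covered_kmers`,
#'   `total_kmers`, `coverage`, `maximal_count`, `superkmer_count`,
#'   `maximal_fraction`, and `warning` (non-`NULL` when the sequence is too
#'   short for stable estimates).
#' @export
measure_density <- function(seq, params) {
  fr <- dna_fragments(seq)
  st <- cpp_density_stats(fr$fragment, params$k, params$m, params$seed,
                          params$canonical, params$order == "lex",
                          params$uhs_mode == "decycling", params$t)
  wp1 <- params$w + 1
  warn <- NULL
  if (st$kmers < 1e4) {
    warn <- sprintf(
      "only %d k-mers scanned; density estimates will be noisy", st$kmers)
    warning(warn)
  }
  structure(list(
    positions = st$mmer_positions,
    selected = st$superkmers_small,
    density = st$superkmers_small / st$mmer_positions,
    density_factor = st$superkmers_small / st$mmer_positions * wp1,
    covered_positions = st$covered_mmer_positions,
    restricted_density = st$superkmers_small / st$covered_mmer_positions,
    restricted_density_factor =
      st$superkmers_small / st$covered_mmer_positions * wp1,
    covered_kmers = st$covered_kmers,
    total_kmers = st$kmers,
    coverage = st$covered_kmers / st$kmers,
    maximal_count = st$maximal_small,
    superkmer_count = st$superkmers_small,
    maximal_fraction = st$maximal_small / st$superkmers_small,
    warning = warn), class = "fhs_density")
}

#' @export
print.fhs_density <- function(x, ...) {
  cat("Density measurement\n")
  cat(sprintf("  %d selected / %.0f m-mer positions: density %.3g (factor %.4f)\n",
              x$selected, x$positions, x$density, x$density_factor))
  cat(sprintf("  restricted factor %.4f over %.0f covered positions\n",
              x$restricted_density_factor, x$covered_positions))
  cat(sprintf("  coverage %.4g (%d / %.0f k-mers); maximal %.4f (%d / %d super-k-mers)\n",
              x$coverage, x$covered_kmers, x$total_kmers,
              x$maximal_fraction, x$maximal_count, x$superkmer_count))
  invisible(x)
}

#' Measure the covered k-mer fraction
#'
#' Fraction of k-mers containing at least one small m-mer; the empirical
#' counterpart of [coverage_from_probability()] (`f = 1 - (1 - p)^w`).
#'
#' @inheritParams measure_density
#' @return The covered fraction (a scalar).
#' @export
measure_coverage <- function(seq, params) {
  fr <- dna_fragments(seq)
  st <- cpp_density_stats(fr$fragment, params$k, params$m, params$seed,
                          params$canonical, params$order == "lex",
                          params$uhs_mode == "decycling", params$t)
  st$covered_kmers / st$kmers
}

#' Measure the maximal super-k-mer proportion
#'
#' Fraction of selected (small-minimizer) super-k-mers that are maximal;
#' the empirical counterpart of [maximal_fraction()].
#'
#' @inheritParams measure_density
#' @return The measured maximal proportion (a scalar).
#' @export
measure_maximal_fraction <- function(seq, params) {
  m <- suppressWarnings(measure_density(seq, params))
  m$maximal_fraction
}

#' Synthetic sequence pair with known overlap
#'
#' Two sequences sharing a common random core: `seq_a` embeds the core
#' between private random flanks, `seq_b` embeds an independently mutated
#' copy between its own flanks. The true Jaccard, containment and angular
#' similarity are recomputed by brute-force k-mer enumeration of the two
#' sequences (never assumed from the construction).
#'
#' @param core_length shared core length in bases.
#' @param flank_length private flank length on each side of each sequence
#'   (0 for none).
#' @param mutation_rate per-base substitution rate applied to the core copy
#'   in `seq_b`.
#' @param seed integer seed.
#' @param k k-mer length used for the exact truth values.
#' @return An object of class `fhs_synthetic_pair` with fields `seq_a`,
#'   `seq_b`, `true_jaccard`, `true_containment_a_in_b`,
#'   `true_containment_b_in_a`, `true_angular`, and the construction
#'   parameters.
#' @export
synthetic_pair <- function(core_length = 20000, flank_length = 2000,
                           mutation_rate = 0.01, seed = 1L, k = 31L) {
  k <- as.integer(k)
  if (core_length < k) stop("core_length must be >= k")
  pair <- with_seed(seed, {
    core <- random_sequence(core_length)
    fl <- function() if (flank_length > 0)
      random_sequence(flank_length) else ""
    list(a = paste0(fl(), core, fl()),
         b = paste0(fl(), mutate_sequence(core, mutation_rate), fl()))
  })
  ca <- cpp_kmer_counts(pair$a, k)
  cb <- cpp_kmer_counts(pair$b, k)
  shared <- sum(ca$kmer %in% cb$kmer)
  un <- length(ca$kmer) + length(cb$kmer) - shared
  cos <- abundance_cosine(setNames(as.numeric(ca$count), ca$kmer),
                          setNames(as.numeric(cb$count), cb$kmer))
  structure(list(
    seq_a = pair$a, seq_b = pair$b,
    true_jaccard = shared / un,
    true_containment_a_in_b = shared / length(ca$kmer),
    true_containment_b_in_a = shared / length(cb$kmer),
    true_angular = angular_similarity(cos),
    core_length = core_length, flank_length = flank_length,
    mutation_rate = mutation_rate, seed = seed, k = k),
    class = "fhs_synthetic_pair")
}

#' Simulate error-prone sequencing reads
#'
#' Uniform read start positions and i.i.d. substitution errors; the mean
#' per-base depth over the genome equals `coverage` in expectation.
#'
#' @param genome a DNA string.
#' @param coverage target mean depth.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return Character vector of reads.
#' @export
simulate_reads <- function(genome, coverage = 100, read_length = 150,
                           error_rate = 0.001, seed = 1L) {
  L <- nchar(genome)
  if (read_length > L) stop("read_length exceeds genome length")
  n_reads <- round(coverage * L / read_length)
  with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    reads <- substring(genome, starts, starts + read_length - 1L)
    if (error_rate > 0) {
      joined <- mutate_sequence(paste(reads, collapse = ""), error_rate)
      reads <- substring(joined,
                         (seq_len(n_reads) - 1L) * read_length + 1L,
                         seq_len(n_reads) * read_length)
    }
    reads
  })
}

#' Measurements versus theory
#'
#' Runs the density, restricted-density, coverage and maximal-proportion
#' estimators on a random sequence and tabulates them against the
#' closed-form expectations, with standard errors computed from the run
#' itself. Used by the `simulate` CLI subcommand.
#'
#' @param length random sequence length in bases.
#' @param params a [sketch_params()] object.
#' @param seed integer seed for the sequence.
#' @return A data frame with columns `quantity`, `measured`, `theory`,
#'   `stderr`, `pass` (measured within 3 standard errors of theory, or
#'   below it for the bound rows).
#' @export
measurement_table <- function(length = 5e6, params = sketch_params(),
                              seed = 1L) {
  seq <- random_sequence(length, seed = seed)
  dm <- suppressWarnings(measure_density(seq, params))
  th_cov <- coverage_from_probability(params$p, params$w)
  se_cov <- sqrt(th_cov * (1 - th_cov) / dm$total_kmers)
  # occurrence counts treated as binomial over positions for the SE scale
  se_df <- sqrt(dm$selected) / dm$positions * (params$w + 1)
  se_rdf <- sqrt(dm$selected) / dm$covered_positions * (params$w + 1)
  th_mx <- maximal_fraction(params$f, params$w)
  se_mx <- sqrt(th_mx * (1 - th_mx) / max(dm$superkmer_count, 1))
  rows <- data.frame(
    quantity = c("density_factor_bound", "restricted_density_factor",
                 "coverage", "maximal_fraction"),
    measured = c(dm$density_factor, dm$restricted_density_factor,
                 dm$coverage, dm$maximal_fraction),
    theory = c(density_bound(params$f, params$w) * (params$w + 1),
               restricted_density_factor(params$f), th_cov, th_mx),
    stderr = c(se_df, se_rdf, se_cov, se_mx),
    stringsAsFactors = FALSE)
  rows$pass <- ifelse(
    rows$quantity == "density_factor_bound",
    rows$measured <= rows$theory + 3 * rows$stderr,
    abs(rows$measured - rows$theory) <= 3 * rows$stderr)
  rows
}
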