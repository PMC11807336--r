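# DNA alphabet handling, m-mer hashing, minimizer selection and super-k-mer
# decomposition. Sequences are uppercased and split at non-ACGT characters;
# each fragment of length >= k is processed independently.

# Split sequences at non-ACGT characters; returns the pure-ACGT fragments and
# their 0-based start offsets in the original string.
dna_fragments <- function(x, min_len = 1L) {
  x <- toupper(as.character(x))
  hits <- gregexpr("[ACGT]+", x)
  frags <- regmatches(x, hits)
  out <- list(fragment = character(0), start = integer(0), seq_index = integer(0))
  for (i in seq_along(frags)) {
    fr <- frags[[i]]
    if (length(fr) == 1L && is.na(fr[1])) next
    st <- as.integer(hits[[i]])
    keep <- nchar(fr) >= min_len & st > 0L
    if (!any(keep)) next
    out$fragment <- c(out$fragment, fr[keep])
    out$start <- c(out$start, st[keep] - 1L)
    out$seq_index <- c(out$seq_index, rep.int(i, sum(keep)))
  }
  out
}

#' Reverse complement
#'
#' @param x character vector of DNA strings (A/C/G/T, case kept upper).
#' @return The reverse complement of each string.
#' @export
revcomp <- function(x) {
  vapply(chartr("ACGTacgt", "TGCATGCA", as.character(x)), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Hash an m-mer
#'
#' Deterministic seeded hash of an m-mer, approximately uniform on the hash
#' space (`[0, 2^53)` for the random hash order, `[0, 4^m)` for the
#' lexicographic order, where the hash is the 2-bit packed value itself).
#' With `canonical` parameters the hash is strand-symmetric:
#' `hash_mmer(x) == hash_mmer(revcomp(x))`.
#'
#' @param mmer character vector of m-mers of length `params$m`.
#' @param params a [sketch_params()] object.
#' @return Numeric vector of integer-valued hashes.
#' @export
hash_mmer <- function(mmer, params) {
  mmer <- toupper(as.character(mmer))
  if (any(nchar(mmer) != params$m))
    stop(sprintf("m-mers must have length m = %d", params$m))
  cpp_hash_mmers(mmer, params$seed, params$canonical, params$order == "lex")
}

#' Hashes of every m-mer position of a sequence
#'
#' @param seq a single DNA string (ACGT only).
#' @param params a [sketch_params()] object.
#' @return Numeric vector of hashes, one per m-mer start position.
#' @export
mmer_hashes <- function(seq, params) {
  seq <- toupper(seq)
  n <- nchar(seq) - params$m + 1L
  if (n <= 0L) return(numeric(0))
  starts <- seq_len(n)
  cpp_hash_mmers(substring(seq, starts, starts + params$m - 1L),
                 params$seed, params$canonical, params$order == "lex")
}

#' Minimizer of a k-mer
#'
#' The m-mer occurrence of smallest hash within the k-mer; ties in hash
#' value are broken by the leftmost position.
#'
#' @param kmer a single k-mer of length `params$k` (ACGT only).
#' @param params a [sketch_params()] object.
#' @return A list (minimizer hit) with fields `sequence` (the m-mer),
#'   `hash`, and `position` (0-based offset within the k-mer).
#' @export
minimizer_of_kmer <- function(kmer, params) {
  kmer <- toupper(kmer)
  if (nchar(kmer) != params$k)
    stop(sprintf("k-mer must have length k = %d", params$k))
  sc <- cpp_scan_kmers(kmer, params$k, params$m, params$seed,
                       params$canonical, params$order == "lex",
                       params$uhs_mode == "decycling", params$t)
  pos <- sc$minpos[1]
  list(sequence = substr(kmer, pos + 1L, pos + params$m),
       hash = sc$minhash[1], position = pos)
}

#' Is a minimizer small?
#'
#' A minimizer is small when its hash falls below the threshold `t` derived
#' from the target fraction `f`; only k-mers with a small minimizer enter a
#' sketch.
#'
#' @param hit a minimizer hit (as returned by [minimizer_of_kmer()]) or a
#'   numeric vector of hash values.
#' @param params a [sketch_params()] object.
#' @return Logical vector.
#' @export
is_small <- function(hit, params) {
  h <- if (is.list(hit)) hit$hash else hit
  h < params$t
}

#' Decompose a sequence into super-k-mers
#'
#' A super-k-mer is a maximal run of consecutive k-mers sharing the same
#' minimizer occurrence (the same m-mer position, not merely the same m-mer
#' value). Boundaries fall exactly where the occurrence changes; a maximal
#' super-k-mer has length `2k - m` and contains `w = k - m + 1` k-mers, with
#' the minimizer as the suffix of its first k-mer and the prefix of its
#' last. The sequence is split at non-ACGT characters first; fragments
#' shorter than `k` contribute nothing.
#'
#' @param seq a single DNA string.
#' @param params a [sketch_params()] object.
#' @return A data frame with one row per super-k-mer, in sequence order:
#'   `sequence`, `start` (0-based start in `seq`), `length`, `kmer_count`,
#'   `minimizer`, `offset` (0-based minimizer offset within the
#'   super-k-mer), `hash`, `is_maximal`, `is_small`.
#' @export
split_superkmers <- function(seq, params) {
  fr <- dna_fragments(seq, min_len = params$k)
  rows <- vector("list", length(fr$fragment))
  for (i in seq_along(fr$fragment)) {
    s <- fr$fragment[i]
    sc <- cpp_scan_kmers(s, params$k, params$m, params$seed,
                         params$canonical, params$order == "lex",
                         params$uhs_mode == "decycling", params$t)
    r <- rle(sc$minpos)
    last <- cumsum(r$lengths)          # last k-mer index (1-based) per run
    first <- last - r$lengths + 1L
    kstart <- first - 1L               # 0-based k-mer start within fragment
    len <- r$lengths + params$k - 1L
    minpos <- r$values                 # 0-based m-mer position within fragment
    rows[[i]] <- data.frame(
      sequence = substring(s, kstart + 1L, kstart + len),
      start = fr$start[i] + kstart,
      length = len,
      kmer_count = r$lengths,
      minimizer = substring(s, minpos + 1L, minpos + params$m),
      offset = minpos - kstart,
      hash = sc$minhash[first],
      is_maximal = r$lengths == params$w,
      is_small = sc$small[first],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sequence = character(0), start = integer(0),
                      length = integer(0), kmer_count = integer(0),
                      minimizer = character(0), offset = integer(0),
                      hash = numeric(0), is_maximal = logical(0),
                      is_small = logical(0), stringsAsFactors = FALSE)
  out
}

#' Decycling set membership
#'
#' Membership in a decycling set of the order-`m` de Bruijn graph, via the
#' complex embedding criterion: an m-mer with digits `d_j` belongs to the
#' set when the argument of `sum_j d_j exp(2*pi*i*j/m)` falls in
#' `(0, 2*pi/m]`; one rotation of every rotation class with nonzero
#' embedding satisfies this. Classes with zero embedding (e.g. periodic
#' words such as `"AAAAA"`) fall back to keeping the word equal to its
#' lexicographically minimal rotation, so every rotation class contains at
#' least one member.
#'
#' @param mmer character vector of m-mers (ACGT only, any common length).
#' @return Logical vector of memberships.
#' @export
decycling_member <- function(mmer) {
  cpp_decycling_member(toupper(as.character(mmer)))
}

# covered flags (one per k-mer) of a single pure-ACGT fragment
kmer_covered <- function(seq, params) {
  sc <- cpp_scan_kmers(toupper(seq), params$k, params$m, params$seed,
                       params$canonical, params$order == "lex",
                       params$uhs_mode == "decycling", params$t)
  sc$small
}
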