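# alphabet handling, hashing, minimizer selection, super-k-mer decomposition

test_that("m-mer hashing is deterministic, seeded and strand-symmetric when asked", {
  p <- default_params()
  x <- "ACGTACGTACGTACG"
  expect_identical(hash_mmer(x, p), hash_mmer(x, p))
  p2 <- default_params(seed = 43L)
  expect_false(hash_mmer(x, p) == hash_mmer(x, p2))
  pc <- sketch_params(k = 31, m = 3, f = 1, canonical = TRUE)
  expect_identical(hash_mmer("ACG", pc), hash_mmer("CGT", pc))
  pn <- sketch_params(k = 31, m = 3, f = 1, canonical = FALSE)
  expect_false(hash_mmer("ACG", pn) == hash_mmer("CGT", pn))
  expect_error(hash_mmer("ACN", pn), "alphabet")
  expect_error(hash_mmer("ACGT", pn), "length")
})

test_that("hashes are uniform: chi-square on the top byte over all 8-mers", {
  p <- sketch_params(k = 31, m = 8, f = 1)
  bases <- c("A", "C", "G", "T")
  all8 <- do.call(paste0, expand.grid(rep(list(bases), 8)))
  expect_length(all8, 65536L)
  h <- hash_mmer(all8, p)
  expect_equal(anyDuplicated(h), 0L)
  top <- floor(h / 2^45)  # top byte of the 53-bit hash
  pval <- chisq.test(tabulate(top + 1, nbins = 256))$p.value
  expect_gt(pval, 0.001)
})

test_that("threshold and coverage are exact inverses with the right values", {
  # frozen from high-precision evaluation of 1 - (1-f)^(1/w)
  expect_equal(threshold_from_fraction(1e-3, 17)$p, 5.8851228997508e-05,
               tolerance = 1e-12)
  expect_equal(threshold_from_fraction(0.5, 17)$p, 0.0399533131452068,
               tolerance = 1e-12)
  expect_equal(threshold_from_fraction(1, 17)$p, 1)
  # frozen 1 - 0.9^17
  expect_equal(coverage_from_probability(0.1, 17), 0.833228183003334,
               tolerance = 1e-12)
  expect_equal(coverage_from_probability(1, 17), 1)
  for (f in c(0.001, 0.01, 0.5, 1))
    expect_equal(coverage_from_probability(
      threshold_from_fraction(f, 17)$p, 17), f, tolerance = 1e-9)
  expect_error(threshold_from_fraction(0, 17), "0, 1")
  expect_error(threshold_from_fraction(1.5, 17), "0, 1")
  expect_error(coverage_from_probability(-0.1, 17), "0, 1")
})

test_that("minimizer selection picks the smallest m-mer, leftmost on ties", {
  p <- toy_params()
  hit <- minimizer_of_kmer("CTGAAA", p)
  expect_equal(hit$sequence, "AAA")
  expect_equal(hit$position, 3L)
  hit2 <- minimizer_of_kmer("AAAAAA", p)
  expect_equal(hit2$sequence, "AAA")
  expect_equal(hit2$position, 0L)
  hit3 <- minimizer_of_kmer("TGCACA", p)
  expect_equal(hit3$sequence, "ACA")
  expect_equal(hit3$position, 3L)
  expect_error(minimizer_of_kmer("CTGAA", p), "length")
})

test_that("the toy sequence splits into the expected four super-k-mers", {
  sk <- split_superkmers(TOY_SEQ, toy_params())
  expect_equal(sk$sequence, c("CTGAAATGC", "AATGCA", "ATGCAC", "TGCACATTT"))
  expect_equal(sk$minimizer, c("AAA", "AAT", "ATG", "ACA"))
  expect_equal(sk$kmer_count, c(4L, 1L, 1L, 4L))
  expect_equal(sk$is_maximal, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(nchar(sk$sequence[sk$is_maximal]), c(9L, 9L))  # 2k - m
  # in a maximal super-k-mer the minimizer is the suffix of the first k-mer
  expect_equal(sk$offset[sk$is_maximal], c(3L, 3L))           # k - m
})

test_that("degenerate inputs: length-k sequence, short sequence, ambiguity splits", {
  p <- default_params()
  s <- random_sequence(31, seed = 5)
  sk <- split_superkmers(s, p)
  expect_equal(nrow(sk), 1L)
  expect_equal(sk$sequence, s)
  expect_equal(nrow(split_superkmers("ACGT", p)), 0L)
  # non-ACGT characters split; each fragment processed independently
  left <- random_sequence(80, seed = 6); right <- random_sequence(50, seed = 7)
  skn <- split_superkmers(paste0(left, "N", right), p)
  expect_equal(skn, rbind(split_superkmers(left, p),
                          within(split_superkmers(right, p),
                                 start <- start + 81L)),
               ignore_attr = TRUE)
})

test_that("super-k-mers conserve and partition the k-mer multiset", {
  p <- default_params()
  for (seed in 1:5) {
    s <- random_sequence(400, seed = seed)
    sk <- split_superkmers(s, p)
    got <- sort(fhsketch:::cpp_superkmers_to_kmers(sk$sequence, p$k))
    n <- nchar(s) - p$k + 1L
    want <- sort(substring(s, 1:n, 1:n + p$k - 1L))
    expect_identical(got, want)
    expect_true(all(nchar(sk$sequence) <= 2 * p$k - p$m))
    expect_identical(sk$is_maximal, nchar(sk$sequence) == 2L * p$k - p$m)
  }
})

test_that("split_superkmers agrees with an independent per-k-mer oracle", {
  p <- default_params()
  for (seed in 1:60) {
    s <- random_sequence(200, seed = 1000 + seed)
    sk <- split_superkmers(s, p)
    n <- nchar(s) - p$k + 1L
    kmers <- substring(s, 1:n, 1:n + p$k - 1L)
    om <- lapply(kmers, oracle_minimizer, params = p)
    minpos <- vapply(seq_len(n), function(i) om[[i]]$position + i - 1L,
                     integer(1))
    r <- rle(minpos)
    expect_equal(sk$kmer_count, r$lengths)
    expect_equal(sk$offset + sk$start, r$values)
    expect_equal(sk$hash,
                 vapply(om[cumsum(r$lengths) - r$lengths + 1L],
                        `[[`, numeric(1), "hash"))
  }
})

test_that("is_small hits the target probability and its boundary cases", {
  p1 <- default_params(f = 1)
  pn <- default_params()
  pn$t <- 0  # nothing small
  s <- random_sequence(1e6 + 14, seed = 9)
  h <- mmer_hashes(s, p1)
  expect_length(h, 1e6L)
  expect_true(all(is_small(h, p1)))
  expect_false(any(is_small(h, pn)))
  # fraction of ~1e6 m-mers that are small ~ p within 3 binomial SE
  pt <- sketch_params(k = 31, m = 15, f = 0.16)  # p ~ 0.0102
  frac <- mean(is_small(h, pt))
  se <- sqrt(pt$p * (1 - pt$p) / length(h))
  expect_lt(abs(frac - pt$p), 3 * se)
  # accepts a minimizer hit too
  expect_true(is_small(minimizer_of_kmer("CTGAAA", toy_params()),
                       toy_params()))
})

test_that("decycling set hits every rotation class without over-selecting", {
  bases <- c("A", "C", "G", "T")
  for (m in c(3, 5)) {
    all_m <- do.call(paste0, expand.grid(rep(list(bases), m)))
    member <- decycling_member(all_m)
    rot <- function(s) vapply(seq_len(nchar(s)), function(r)
      paste0(substring(s, r), substring(s, 1, r - 1)), character(1))
    seen <- character(0)
    n_classes <- 0L
    for (s in all_m) {
      if (s %in% seen) next
      cls <- unique(rot(s))
      seen <- c(seen, cls)
      n_classes <- n_classes + 1L
      expect_true(any(member[match(cls, all_m)]),
                  label = sprintf("rotation class of %s has a member", s))
    }
    # membership is rotation-dependent: roughly one member per class
    expect_lte(sum(member), 2L * n_classes)
  }
  expect_type(decycling_member("AAAAA"), "logical")  # no infinite loop
  expect_true(decycling_member("AAAAA"))  # minimal rotation of itself
})

test_that("covered/uncovered status is independent of k-mer GC content", {
  p <- default_params(f = 0.5)
  s <- random_sequence(5e6 + 30, seed = 21)
  covered <- fhsketch:::kmer_covered(s, p)
  gc <- kmer_gc(s, p$k)
  # sample >= 1e5 k-mers at a stride wider than 2k - m so their minimizer
  # windows are disjoint (overlapping k-mers share covered status and would
  # break the independence assumption of the chi-square test)
  idx <- seq(1L, length(covered), by = 50L)
  bin <- cut(gc[idx], breaks = c(-1, 11, 13, 15, 17, 19, 31))
  pval <- chisq.test(table(bin, covered[idx]))$p.value
  expect_gt(pval, 0.001)
})
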