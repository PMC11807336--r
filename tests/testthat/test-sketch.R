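# sketch construction, abundance handling, reassembly, serialization

test_that("a full-fraction sketch holds exactly the distinct k-mer set", {
  p <- default_params(f = 1)
  s <- random_sequence(5000, seed = 31)
  sk <- build_sketch(s, p)
  truth <- fhsketch:::cpp_kmer_counts(s, p$k)
  expect_identical(sort(sketch_kmers(sk)), truth$kmer)
  expect_equal(sk$kmer_count, length(truth$kmer))
})

test_that("the toy sketch has the four expected minimizer partitions", {
  sk <- build_sketch(TOY_SEQ, toy_params())
  expect_equal(names(sk$partitions), c("AAA", "AAT", "ACA", "ATG"))
  expect_equal(sk$kmer_count, 10L)  # 15 - 6 + 1 distinct k-mers
  expect_equal(sort(sketch_kmers(sk)),
               sort(substring(TOY_SEQ, 1:10, 6:15)))
})

test_that("sampling calibration: sampled fraction tracks f", {
  p <- sketch_params(k = 31, m = 15, f = 0.01)
  s <- random_sequence(2e6, seed = 33)
  sk <- build_sketch(s, p)
  n <- nchar(s) - p$k + 1
  se <- sqrt(p$f * (1 - p$f) / n)
  expect_lt(abs(sk$kmer_count / n - p$f), 3 * se)
  # every stored super-k-mer's minimizer is small
  for (key in names(sk$partitions))
    expect_true(all(is_small(hash_mmer(key, p), p)))
})

test_that("partitions never hold duplicate k-mers and spell no false k-mers", {
  p <- default_params(f = 1)
  # duplicated input: every k-mer seen twice across sequences
  s <- random_sequence(2000, seed = 35)
  sk <- build_sketch(c(s, s), p)
  kk <- sketch_kmers(sk)
  expect_equal(anyDuplicated(kk), 0L)
  expect_identical(sort(kk), fhsketch:::cpp_kmer_counts(s, p$k)$kmer)
})

test_that("abundance filtering keeps exactly the k-mers at or above the cutoff", {
  counts <- c(x = 1, y = 3, z = 2)
  expect_setequal(filter_by_abundance(counts, 1), c("x", "y", "z"))
  expect_setequal(filter_by_abundance(counts, 2), c("y", "z"))
  expect_error(filter_by_abundance(counts, 0), ">= 1")
})

test_that("abundance-filtered sketch of noisy reads recovers the genome", {
  p <- default_params(f = 1)
  genome <- random_sequence(8000, seed = 41)
  reads <- simulate_reads(genome, coverage = 60, read_length = 100,
                          error_rate = 0.01, seed = 42)
  sk <- build_sketch(reads, p, abundance_mode = "raw", min_abundance = 3L)
  truth <- fhsketch:::cpp_kmer_counts(genome, p$k)$kmer
  got <- sketch_kmers(sk)
  jac <- length(intersect(got, truth)) / length(union(got, truth))
  expect_gt(jac, 0.95)
})

test_that("reassembly is lossless and near-optimal on maximal super-k-mer subsets", {
  p <- sketch_params(k = 11, m = 4, f = 1, seed = 7)  # w = 8
  # find a genuinely maximal super-k-mer on a random sequence
  s <- random_sequence(4000, seed = 51)
  sk <- split_superkmers(s, p)
  mx <- sk$sequence[sk$is_maximal][1]
  expect_equal(nchar(mx), 2 * p$k - p$m)
  n <- nchar(mx) - p$k + 1L
  kmers <- substring(mx, 1:n, 1:n + p$k - 1L)
  # full set -> exactly the maximal super-k-mer back
  ra <- reassemble_superkmers(kmers, p)
  expect_equal(nrow(ra), 1L)
  expect_equal(ra$sequence, mx)
  expect_true(ra$is_maximal)
  # minus the middle k-mer -> two records covering the rest
  ra2 <- reassemble_superkmers(kmers[-5], p)
  expect_equal(nrow(ra2), 2L)
  expect_setequal(unlist(lapply(ra2$sequence, function(x) {
    nn <- nchar(x) - p$k + 1L
    substring(x, 1:nn, 1:nn + p$k - 1L)
  })), kmers[-5])
  # random subsets: total bases within k-1 of the run-optimal grouping
  set.seed(99)
  for (trial in 1:30) {
    pick <- sort(sample(n, sample(2:n, 1)))
    ras <- reassemble_superkmers(kmers[pick], p)
    spelled <- unlist(lapply(ras$sequence, function(x) {
      nn <- nchar(x) - p$k + 1L
      substring(x, 1:nn, 1:nn + p$k - 1L)
    }))
    expect_setequal(spelled, kmers[pick])
    expect_equal(anyDuplicated(spelled), 0L)
    runs <- rle(diff(pick) == 1L)
    n_runs <- sum(!runs$values) + 1L
    optimal <- length(pick) + n_runs * (p$k - 1L)  # group consecutive indices
    expect_lte(sum(nchar(ras$sequence)), optimal + p$k - 1L)
  }
})

test_that("abundance encodings follow their quantization rules", {
  # raw round trip
  counts <- setNames(c(1, 2, 7, 250, 300), paste0("k", 1:5))
  enc <- encode_abundances(counts, "raw")
  expect_identical(unname(enc), unname(counts))
  # log: count 1 -> 0; quantized decode within 5% relative
  lenc <- encode_abundances(counts, "log")
  expect_equal(unname(lenc[1]), 0)
  dec <- fhsketch:::decode_abundance_values(lenc, "log")
  expect_true(all(abs(dec - counts) / counts < 0.05))
  # super_avg: mean of (2,2,4,4) stored as 3
  cc <- setNames(c(2, 2, 4, 4), paste0("s", 1:4))
  expect_equal(unname(encode_abundances(cc, "super_avg",
                                        records = list(names(cc)))), 3)
  expect_error(encode_abundances(counts, "super_avg"), "records")
  expect_error(fhsketch:::encode_abundance_values(counts, "nope"), "unknown")
})

test_that("maximal proportion in sketches rises as f falls, near theory at f = 1", {
  s <- random_sequence(3e6, seed = 55)
  fr <- vapply(c(1, 0.1, 0.01), function(f)
    measure_maximal_fraction(s, default_params(f = f)), numeric(1))
  expect_true(all(diff(fr) > 0))
  # f = 1: the closed form carries O(1/w)-scale corrections (~2.7% at
  # w = 17), so agreement is asserted at 5% relative
  expect_lt(abs(fr[1] - maximal_fraction(1, 17)) / maximal_fraction(1, 17),
            0.05)
  expect_gt(fr[3], 0.95)
})

test_that("sketch files round-trip bit-exactly, plain and gzipped", {
  tmp <- withr::local_tempfile(fileext = ".fhsk")
  sk <- build_sketch(TOY_SEQ, toy_params())
  write_sketch(sk, tmp)
  expect_equal(read_sketch(tmp), sk)
  # larger sketch, hash order, with raw abundances
  p <- sketch_params(k = 31, m = 15, f = 0.1)
  s <- random_sequence(2e5, seed = 61)
  sk2 <- build_sketch(c(s, substr(s, 1, 5e4)), p, abundance_mode = "raw")
  write_sketch(sk2, tmp)
  expect_equal(read_sketch(tmp), sk2)
  tmpz <- withr::local_tempfile(fileext = ".fhsk.gz")
  write_sketch(sk2, tmpz, compress = TRUE)
  expect_equal(read_sketch(tmpz), sk2)
  expect_lt(file.size(tmpz), file.size(tmp))
  # all abundance modes survive the round trip
  for (mode in c("log", "super_avg", "super_log")) {
    sk3 <- build_sketch(c(s, substr(s, 1, 5e4)), p, abundance_mode = mode)
    write_sketch(sk3, tmp)
    expect_equal(read_sketch(tmp), sk3)
  }
})

test_that("corrupt sketch files raise typed format errors", {
  tmp <- withr::local_tempfile(fileext = ".fhsk")
  sk <- build_sketch(TOY_SEQ, toy_params())
  write_sketch(sk, tmp)
  bytes <- readBin(tmp, "raw", file.size(tmp))
  bad <- bytes; bad[1:4] <- charToRaw("NOPE")
  writeBin(bad, tmp)
  expect_error(read_sketch(tmp), "magic", class = "fhsk_format_error")
  bad <- bytes; bad[5] <- as.raw(99)
  writeBin(bad, tmp)
  expect_error(read_sketch(tmp), "version", class = "fhsk_version_error")
  writeBin(bytes[1:20], tmp)
  expect_error(read_sketch(tmp), "truncated", class = "fhsk_format_error")
})

test_that("filtering then reassembly never loses or duplicates a k-mer", {
  p <- default_params(f = 1)
  genome <- random_sequence(3000, seed = 71)
  reads <- simulate_reads(genome, coverage = 20, read_length = 80,
                          error_rate = 0.005, seed = 72)
  fr <- fhsketch:::dna_fragments(reads, min_len = p$k)
  part <- fhsketch:::cpp_build_partitions(
    fr$fragment, p$k, p$m, p$seed, p$canonical, FALSE, FALSE, p$t)
  counts <- setNames(part$count, part$kmer)
  surviving <- filter_by_abundance(counts, 2L)
  sk <- build_sketch(reads, p, abundance_mode = "raw", min_abundance = 2L)
  expect_setequal(sketch_kmers(sk), surviving)
  expect_equal(anyDuplicated(sketch_kmers(sk)), 0L)
})

test_that("bits per k-mer shrink with the rate and stay inside the model bracket", {
  p1 <- sketch_params(k = 31, m = 15, s = 10)
  p2 <- sketch_params(k = 31, m = 15, s = 100)
  s <- random_sequence(2e6, seed = 81)
  tmp <- withr::local_tempfile()
  bits <- vapply(list(p1, p2), function(p) {
    sk <- build_sketch(s, p)
    write_sketch(sk, tmp)
    file.size(tmp) * 8 / sk$kmer_count
  }, numeric(1))
  expect_lt(bits[2], bits[1])
  ec <- encoding_costs(31, 15)
  expect_gt(bits[2], ec$partitioned_maximal)
})
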