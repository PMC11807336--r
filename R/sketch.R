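# Sketch construction, abundance filtering/encoding and serialization.
#
# A sketch stores, for every sampled (covered) k-mer, its sequence exactly,
# grouped into super-k-mers and partitioned by minimizer. Construction always
# goes through per-partition distinct-k-mer deduplication followed by greedy
# reassembly, so the distinct-k-mer invariant holds uniformly and the same
# code path serves the post-abundance-filter "assembly" phase.

ABUNDANCE_MODES <- c("none", "raw", "log", "super_avg", "super_log")

#' Build a fractional hitting set sketch
#'
#' Scans the input sequences, keeps every super-k-mer whose minimizer is
#' small (hash below the threshold `t` of `params`), and stores the sampled
#' k-mers exactly, partitioned by minimizer. Duplicate k-mers across the
#' input collapse (set semantics); their multiplicities accumulate in the
#' abundance map when an abundance mode is active. With `f = 1` the sketch
#' holds exactly the distinct k-mer set of the input.
#'
#' @param x character vector of DNA sequences (or a `DNAStringSet`).
#'   Sequences are uppercased and split at non-ACGT characters.
#' @param params a [sketch_params()] object.
#' @param abundance_mode one of `"none"`, `"raw"`, `"log"` (quantized log2
#'   counts), `"super_avg"` (one mean count per super-k-mer record),
#'   `"super_log"` (quantized log2 of that mean).
#' @param min_abundance integer cutoff `c >= 1`; k-mers seen fewer than `c`
#'   times in the input are dropped before the sketch is assembled
#'   (`c = 1` keeps everything). Requires abundance counting, which is done
#'   automatically.
#' @return An object of class `fhs_sketch` with fields `params`,
#'   `abundance_mode`, `partitions` (named list, ascending minimizer order;
#'   each partition holds `minimizer`, `superkmers`, `offsets`, `nkmers`,
#'   `maximal`, and `abund` for the `super_*` modes), `kmer_count`, and
#'   `kmer_abund` (named encoded values for the `raw`/`log` modes).
#' @examples
#' p <- sketch_params(k = 6, m = 3, f = 1, order = "lex")
#' build_sketch("CTGAAATGCACATTT", p)
#' @export
build_sketch <- function(x, params, abundance_mode = "none",
                         min_abundance = 1L) {
  abundance_mode <- match.arg(abundance_mode, ABUNDANCE_MODES)
  min_abundance <- as.integer(min_abundance)
  if (is.na(min_abundance) || min_abundance < 1L)
    stop("min_abundance must be an integer >= 1")
  x <- as.character(x)
  if (length(x) == 0L) stop("no input sequences")
  fr <- dna_fragments(x, min_len = params$k)
  part <- if (length(fr$fragment) == 0L) {
    list(kmer = character(0), minimizer = character(0),
         offset = integer(0), count = integer(0))
  } else {
    cpp_build_partitions(fr$fragment, params$k, params$m, params$seed,
                         params$canonical, params$order == "lex",
                         params$uhs_mode == "decycling", params$t)
  }
  keep <- part$count >= min_abundance
  kmer <- part$kmer[keep]
  minim <- part$minimizer[keep]
  off <- part$offset[keep]
  cntmap <- setNames(as.numeric(part$count[keep]), kmer)

  idx <- split(seq_along(kmer), factor(minim, levels = unique(minim)))
  partitions <- lapply(names(idx), function(mm) {
    ii <- idx[[mm]]
    ra <- cpp_reassemble(kmer[ii], off[ii], params$k, params$m)
    ord <- order(!ra$maximal)  # stable: maximal records first
    list(minimizer = mm,
         superkmers = ra$superkmer[ord],
         offsets = ra$offset[ord],
         nkmers = ra$nkmers[ord],
         maximal = ra$maximal[ord],
         abund = NULL)
  })
  names(partitions) <- names(idx)

  kmer_abund <- NULL
  if (abundance_mode %in% c("raw", "log")) {
    ck <- canonical_kmer_order(partitions, params$k)
    kmer_abund <- setNames(
      encode_abundance_values(cntmap[ck], abundance_mode), ck)
  } else if (abundance_mode %in% c("super_avg", "super_log")) {
    partitions <- lapply(partitions, function(p) {
      p$abund <- vapply(p$superkmers, function(sk) {
        kk <- cpp_superkmers_to_kmers(sk, params$k)
        encode_abundance_values(mean(cntmap[kk]), abundance_mode)
      }, numeric(1), USE.NAMES = FALSE)
      p
    })
  }

  structure(list(params = params, abundance_mode = abundance_mode,
                 partitions = partitions, kmer_count = length(kmer),
                 kmer_abund = kmer_abund),
            class = "fhs_sketch")
}

# all k-mers of a sketch in canonical traversal order:
# partitions ascending, records in stored order, positions left to right
canonical_kmer_order <- function(partitions, k) {
  unlist(lapply(partitions, function(p)
    cpp_superkmers_to_kmers(p$superkmers, k)), use.names = FALSE)
}

#' All sampled k-mers of a sketch
#'
#' @param sketch an `fhs_sketch`.
#' @return Character vector of the distinct sampled k-mers, in canonical
#'   sketch order (ascending partitions, record order, left to right).
#' @export
sketch_kmers <- function(sketch) {
  stopifnot(inherits(sketch, "fhs_sketch"))
  ck <- canonical_kmer_order(sketch$partitions, sketch$params$k)
  if (is.null(ck)) character(0) else ck
}

#' @export
print.fhs_sketch <- function(x, ...) {
  cat(sprintf(
    "FHS sketch: k = %d, m = %d, s = %g (f = %g)\n",
    x$params$k, x$params$m, x$params$s, x$params$f))
  nmax <- sum(vapply(x$partitions, function(p) sum(p$maximal), numeric(1)))
  nskm <- sum(vapply(x$partitions, function(p) length(p$superkmers),
                     numeric(1)))
  cat(sprintf("  %d distinct k-mers in %d super-k-mers (%d maximal), %d partitions\n",
              x$kmer_count, nskm, nmax, length(x$partitions)))
  cat(sprintf("  abundance mode: %s\n", x$abundance_mode))
  invisible(x)
}

#' Filter k-mers by abundance
#'
#' @param counts named integer/numeric vector of per-k-mer occurrence
#'   counts.
#' @param cutoff integer cutoff `c >= 1`; exactly the k-mers with
#'   `count >= c` survive.
#' @return Character vector of surviving k-mers.
#' @export
filter_by_abundance <- function(counts, cutoff) {
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L) stop("cutoff must be an integer >= 1")
  names(counts)[counts >= cutoff]
}

#' Reassemble k-mers into super-k-mers
#'
#' Greedy "assembly" of a set of sampled k-mers into super-k-mers: chains
#' are seeded at k-mers whose minimizer is a suffix (or, failing that, at
#' k-mers with no available predecessor) and extended rightwards while the
#' next k-mer of the same minimizer occurrence is present. Every input
#' k-mer appears in exactly one output record; maximal super-k-mers are
#' preferred, then greedily longest runs (simplitig-style).
#'
#' @param kmers character vector of distinct k-mers (each of length
#'   `params$k`).
#' @param params a [sketch_params()] object.
#' @return A data frame with columns `sequence`, `minimizer`, `offset`
#'   (minimizer offset within the record), `kmer_count`, `is_maximal`.
#' @export
reassemble_superkmers <- function(kmers, params) {
  kmers <- unique(toupper(as.character(kmers)))
  if (any(nchar(kmers) != params$k))
    stop(sprintf("all k-mers must have length k = %d", params$k))
  if (length(kmers) == 0L)
    return(data.frame(sequence = character(0), minimizer = character(0),
                      offset = integer(0), kmer_count = integer(0),
                      is_maximal = logical(0), stringsAsFactors = FALSE))
  part <- cpp_build_partitions(kmers, params$k, params$m, params$seed,
                               params$canonical, params$order == "lex",
                               params$uhs_mode == "decycling", Inf)
  idx <- split(seq_along(part$kmer),
               factor(part$minimizer, levels = unique(part$minimizer)))
  rows <- lapply(names(idx), function(mm) {
    ii <- idx[[mm]]
    ra <- cpp_reassemble(part$kmer[ii], part$offset[ii], params$k, params$m)
    ord <- order(!ra$maximal)
    data.frame(sequence = ra$superkmer[ord], minimizer = mm,
               offset = ra$offset[ord], kmer_count = ra$nkmers[ord],
               is_maximal = ra$maximal[ord], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# quantized log2 with 1/16 steps in an unsigned byte, saturating at 255;
# relative decode error < 5% over ~5 orders of magnitude
encode_abundance_values <- function(counts, mode) {
  switch(mode,
    raw = ,
    super_avg = round(counts),
    log = ,
    super_log = pmin(round(16 * log2(pmax(counts, 1))), 255),
    stop(sprintf("unknown abundance mode '%s'", mode)))
}

decode_abundance_values <- function(values, mode) {
  switch(mode,
    raw = ,
    super_avg = values,
    log = ,
    super_log = 2^(values / 16),
    stop(sprintf("unknown abundance mode '%s'", mode)))
}

#' Encode an abundance block
#'
#' Applies one of the abundance-encoding heuristics to raw per-k-mer counts:
#' `raw` stores counts as-is, `log` stores `round(16 * log2(count))`
#' saturating at 255 (decoded as `2^(v/16)`, i.e. < 5% relative error),
#' and the `super_*` modes store a single value per super-k-mer record —
#' the arithmetic mean of its constituent k-mer counts, rounded
#' half-to-even (`super_avg`) or log-quantized (`super_log`).
#'
#' @param counts named numeric vector of per-k-mer counts.
#' @param mode one of `"raw"`, `"log"`, `"super_avg"`, `"super_log"`.
#' @param records for the `super_*` modes, a list of character vectors
#'   giving the constituent k-mers of each super-k-mer record.
#' @return For `raw`/`log`: encoded values named by k-mer. For `super_*`:
#'   one encoded value per record.
#' @export
encode_abundances <- function(counts, mode, records = NULL) {
  mode <- match.arg(mode, ABUNDANCE_MODES[-1])
  if (mode %in% c("raw", "log"))
    return(setNames(encode_abundance_values(as.numeric(counts), mode),
                    names(counts)))
  if (is.null(records))
    stop("super_* modes need `records`, the per-record k-mer lists")
  vapply(records, function(kk)
    encode_abundance_values(mean(counts[kk]), mode), numeric(1))
}

#' Decoded per-k-mer abundances of a sketch
#'
#' Inverts the active abundance encoding into one abundance estimate per
#' sampled k-mer. In the `super_*` modes every constituent k-mer inherits
#' its record's single stored value.
#'
#' @param sketch an `fhs_sketch` built with an abundance mode.
#' @return Named numeric vector, one value per sampled k-mer.
#' @export
decode_abundances <- function(sketch) {
  stopifnot(inherits(sketch, "fhs_sketch"))
  mode <- sketch$abundance_mode
  if (mode == "none") stop("sketch has no abundance block")
  if (mode %in% c("raw", "log"))
    return(setNames(decode_abundance_values(unname(sketch$kmer_abund), mode),
                    names(sketch$kmer_abund)))
  k <- sketch$params$k
  vals <- lapply(sketch$partitions, function(p) {
    unlist(lapply(seq_along(p$superkmers), function(i) {
      kk <- cpp_superkmers_to_kmers(p$superkmers[i], k)
      setNames(rep(decode_abundance_values(p$abund[i], mode), length(kk)), kk)
    }))
  })
  out <- unlist(unname(vals))
  if (is.null(out)) out <- setNames(numeric(0), character(0))
  out
}

# ---- serialization ----------------------------------------------------------
# Little-endian binary layout ("FHSK"):
#   magic "FHSK" | version u8 | k u8 | m u8 | order u8 | canonical u8 |
#   uhs u8 | abundance u8 | f f64 | t f64 | seed i32 | kmer_count f64 |
#   n_partitions i32
# then per partition (ascending packed-minimizer order):
#   minimizer 2-bit packed, ceil(m/4) bytes | n_maximal i32 | n_other i32 |
#   maximal records: prefix+suffix packed, ceil(2(k-m)/4) bytes each |
#   other records: nkmers u16 | offset u16 | packed bases ceil(len/4) |
#   abundance block (mode-dependent: u32 per k-mer for raw, u8 per k-mer for
#   log, u32/u8 per record for super_avg/super_log)

fhsk_error <- function(msg, class = "fhsk_format_error") {
  stop(errorCondition(msg, class = c(class, "fhsk_format_error", "error",
                                     "condition")))
}

#' Write a sketch to disk
#'
#' Serializes a sketch in the binary `FHSK` format: a parameter header
#' followed by per-partition blocks in ascending minimizer order. Maximal
#' super-k-mers are stored minimizer-omitted (2-bit packed prefix+suffix,
#' `2(k-m)` bases each); non-maximal records carry an explicit k-mer-count
#' field so no artefactual k-mers can be read across record boundaries.
#' [read_sketch()] reproduces the sketch bit-exactly.
#'
#' @param sketch an `fhs_sketch`.
#' @param path output file path.
#' @param compress gzip the file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_sketch <- function(sketch, path, compress = FALSE) {
  stopifnot(inherits(sketch, "fhs_sketch"))
  p <- sketch$params
  if (p$k > 255L) stop("serialization supports k <= 255")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  amode <- match(sketch$abundance_mode, ABUNDANCE_MODES) - 1L
  writeBin(charToRaw("FHSK"), con)
  writeBin(as.raw(c(1L, p$k, p$m, as.integer(p$order == "lex"),
                    as.integer(p$canonical),
                    as.integer(p$uhs_mode == "decycling"), amode)), con)
  writeBin(as.numeric(p$f), con, size = 8, endian = "little")
  writeBin(as.numeric(p$t), con, size = 8, endian = "little")
  writeBin(as.integer(p$seed), con, size = 4, endian = "little")
  writeBin(as.numeric(sketch$kmer_count), con, size = 8, endian = "little")
  writeBin(as.integer(length(sketch$partitions)), con, size = 4,
           endian = "little")
  for (part in sketch$partitions) {
    writeBin(cpp_pack_dna(part$minimizer)[[1]], con)
    is_max <- part$maximal
    writeBin(as.integer(c(sum(is_max), sum(!is_max))), con, size = 4,
             endian = "little")
    for (i in which(is_max)) {
      sk <- part$superkmers[i]
      core <- paste0(substr(sk, 1L, p$k - p$m),
                     substr(sk, p$k + 1L, 2L * p$k - p$m))
      writeBin(cpp_pack_dna(core)[[1]], con)
    }
    for (i in which(!is_max)) {
      writeBin(as.integer(c(part$nkmers[i], part$offsets[i])), con,
               size = 2, endian = "little")
      writeBin(cpp_pack_dna(part$superkmers[i])[[1]], con)
    }
    ord <- c(which(is_max), which(!is_max))
    if (sketch$abundance_mode %in% c("raw", "log")) {
      kk <- cpp_superkmers_to_kmers(part$superkmers[ord], p$k)
      v <- unname(sketch$kmer_abund[kk])
      if (sketch$abundance_mode == "raw")
        writeBin(as.integer(v), con, size = 4, endian = "little")
      else writeBin(as.raw(v), con)
    } else if (sketch$abundance_mode == "super_avg") {
      writeBin(as.integer(part$abund[ord]), con, size = 4, endian = "little")
    } else if (sketch$abundance_mode == "super_log") {
      writeBin(as.raw(part$abund[ord]), con)
    }
  }
  bytes <- rawConnectionValue(con)
  out <- if (compress) gzfile(path, "wb") else file(path, "wb")
  writeBin(bytes, out)
  close(out)
  invisible(path)
}

read_all_bytes <- function(path) {
  con <- gzfile(path, "rb")  # reads plain files transparently too
  on.exit(close(con), add = TRUE)
  chunks <- list()
  repeat {
    b <- readBin(con, "raw", n = 1048576L)
    if (length(b) == 0L) break
    chunks[[length(chunks) + 1L]] <- b
  }
  do.call(c, chunks)
}

#' Read a sketch from disk
#'
#' @param path a file produced by [write_sketch()] (plain or gzipped).
#' @return The reconstructed `fhs_sketch`.
#' @export
read_sketch <- function(path) {
  if (!file.exists(path)) stop(sprintf("sketch file not found: %s", path))
  bytes <- read_all_bytes(path)
  con <- rawConnection(bytes, "rb")
  on.exit(close(con), add = TRUE)
  need <- function(what, n, size = 1, ...) {
    v <- readBin(con, what, n = n, size = size, endian = "little", ...)
    if (length(v) < n)
      fhsk_error(sprintf("truncated sketch file: %s", path))
    v
  }
  magic <- need("raw", 4L)
  if (!identical(rawToChar(magic), "FHSK"))
    fhsk_error(sprintf("not an FHSK sketch (bad magic): %s", path))
  hdr <- as.integer(need("raw", 7L))
  if (hdr[1] != 1L)
    fhsk_error(sprintf("unsupported FHSK version %d in %s", hdr[1], path),
               class = "fhsk_version_error")
  k <- hdr[2]; m <- hdr[3]
  ord <- if (hdr[4] == 1L) "lex" else "hash"
  canonical <- hdr[5] == 1L
  uhs <- if (hdr[6] == 1L) "decycling" else "none"
  amode <- ABUNDANCE_MODES[hdr[7] + 1L]
  if (is.na(amode)) fhsk_error("corrupt abundance mode byte")
  f <- need("numeric", 1L, size = 8)
  t <- need("numeric", 1L, size = 8)
  seed <- need("integer", 1L, size = 4)
  params <- tryCatch(
    sketch_params(k = k, m = m, f = f, seed = seed, canonical = canonical,
                  order = ord, uhs_mode = uhs),
    error = function(e) fhsk_error(
      sprintf("corrupt parameter header (%s): %s", conditionMessage(e), path)))
  if (!isTRUE(all.equal(params$t, t)))
    fhsk_error(sprintf("parameter header corruption: stored threshold %.0f != derived %.0f",
                       t, params$t))
  kmer_count <- need("numeric", 1L, size = 8)
  n_part <- need("integer", 1L, size = 4)
  mbytes <- (m + 3L) %/% 4L
  partitions <- vector("list", n_part)
  keys <- character(n_part)
  abund_vals <- vector("list", n_part)  # per-kmer values for raw/log
  for (pi in seq_len(n_part)) {
    minim <- cpp_unpack_dna(list(need("raw", mbytes)), m)
    nmax <- need("integer", 1L, size = 4)
    noth <- need("integer", 1L, size = 4)
    sks <- character(nmax + noth)
    offs <- integer(nmax + noth)
    nks <- integer(nmax + noth)
    if (nmax > 0L) {
      cbytes <- (2L * (k - m) + 3L) %/% 4L
      for (i in seq_len(nmax)) {
        core <- cpp_unpack_dna(list(need("raw", cbytes)), 2L * (k - m))
        sks[i] <- paste0(substr(core, 1L, k - m), minim,
                         substr(core, k - m + 1L, 2L * (k - m)))
        offs[i] <- k - m
        nks[i] <- k - m + 1L
      }
    }
    if (noth > 0L) {
      for (i in seq_len(noth)) {
        hd <- need("integer", 2L, size = 2, signed = FALSE)
        len <- k + hd[1] - 1L
        sks[nmax + i] <- cpp_unpack_dna(list(need("raw", (len + 3L) %/% 4L)),
                                        len)
        offs[nmax + i] <- hd[2]
        nks[nmax + i] <- hd[1]
      }
    }
    part <- list(minimizer = minim, superkmers = sks, offsets = offs,
                 nkmers = nks, maximal = nks == (k - m + 1L), abund = NULL)
    if (amode %in% c("raw", "log")) {
      nk_total <- sum(nks)
      abund_vals[[pi]] <- if (amode == "raw")
        as.numeric(need("integer", nk_total, size = 4))
      else as.numeric(as.integer(need("raw", nk_total)))
    } else if (amode == "super_avg") {
      part$abund <- as.numeric(need("integer", nmax + noth, size = 4))
    } else if (amode == "super_log") {
      part$abund <- as.numeric(as.integer(need("raw", nmax + noth)))
    }
    partitions[[pi]] <- part
    keys[pi] <- minim
  }
  names(partitions) <- keys
  kmer_abund <- NULL
  if (amode %in% c("raw", "log")) {
    ck <- canonical_kmer_order(partitions, k)
    kmer_abund <- setNames(unlist(abund_vals, use.names = FALSE), ck)
    if (is.null(kmer_abund)) kmer_abund <- setNames(numeric(0), character(0))
  }
  structure(list(params = params, abundance_mode = amode,
                 partitions = partitions, kmer_count = as.integer(kmer_count),
                 kmer_abund = kmer_abund),
            class = "fhs_sketch")
}
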