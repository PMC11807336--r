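# FASTA/FASTQ input. Format is auto-detected from the first record character
# ('>' FASTA, '@' FASTQ) after transparent gzip decompression; parsing itself
# is delegated to Biostrings.

#' Read sequences from FASTA or FASTQ
#'
#' @param path path to a FASTA or FASTQ file, plain or gzip-compressed.
#'   Format is auto-detected; FASTQ qualities are ignored.
#' @return Named character vector of uppercased sequences (names are the
#'   record ids).
#' @export
read_fasta_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  con <- gzfile(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0L || !nzchar(first[1]))
    stop(sprintf("empty input file: %s", path))
  fmt <- if (startsWith(first[1], ">")) "fasta"
         else if (startsWith(first[1], "@")) "fastq"
         else stop(sprintf(
           "cannot detect format of %s: first character '%s' is neither '>' nor '@'",
           path, substr(first[1], 1, 1)))
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop(sprintf(
      "malformed %s record in %s: %s", toupper(fmt), path,
      conditionMessage(e))))
  if (length(ss) == 0L)
    stop(sprintf("malformed input: no records in %s", path))
  if (any(Biostrings::width(ss) == 0L))
    stop(sprintf("malformed %s record (empty sequence) in %s: record %d",
                 toupper(fmt), path, which(Biostrings::width(ss) == 0L)[1]))
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

# minimal FASTA writer for simulate fixtures
write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)), path)
  invisible(path)
}
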