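# Readers and writers for the plain-text formats the toolkit exchanges.

#' Read / write FASTA
#'
#' Sequences are uppercased on read; ids are the full header lines. Writing
#' wraps at 80 columns. Gzipped paths are handled transparently. Duplicate
#' ids and empty sequences are rejected with the offending record named.
#'
#' @param path FASTA file path.
#' @param x Named character vector of sequences.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  if (any(Biostrings::width(ss) == 0))
    stop("empty sequence for record: ", ids[Biostrings::width(ss) == 0][1])
  setNames(toupper(as.character(ss)), ids)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA id: ", names(x)[duplicated(names(x))][1])
  if (any(!nzchar(x)))
    stop("empty sequence for record: ", names(x)[!nzchar(x)][1])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 80,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

strip_mate_suffix <- function(ids) sub("[/ ].*$", "", sub("/[12]$", "", ids))

#' Read synchronized paired FASTQ files
#'
#' Files must be synchronized by record order; mate ids are checked for the
#' `/1` `/2` or identical-id conventions, and quality strings must match
#' sequence lengths.
#'
#' @param r1,r2 FASTQ paths (gz-capable).
#' @return Read-pair data frame (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @export
read_fastq_paired <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(s1) != length(s2))
    stop(sprintf("paired files out of sync: %d vs %d records (first orphan at record %d)",
                 length(s1), length(s2), min(length(s1), length(s2)) + 1L))
  q1 <- as.character(S4Vectors::mcols(s1)$qualities)
  q2 <- as.character(S4Vectors::mcols(s2)$qualities)
  id1 <- strip_mate_suffix(names(s1)); id2 <- strip_mate_suffix(names(s2))
  bad <- which(id1 != id2)
  if (length(bad))
    stop("mate id mismatch at record ", bad[1], ": ", id1[bad[1]], " vs ",
         id2[bad[1]])
  seq1 <- toupper(as.character(s1)); seq2 <- toupper(as.character(s2))
  if (any(nchar(q1) != nchar(seq1)) || any(nchar(q2) != nchar(seq2)))
    stop("quality string length mismatch at record ",
         which(nchar(q1) != nchar(seq1) | nchar(q2) != nchar(seq2))[1])
  data.frame(id = id1, seq1 = unname(seq1), qual1 = unname(q1),
             seq2 = unname(seq2), qual2 = unname(q2))
}

#' Write paired reads as two FASTQ files
#'
#' @param pairs Read-pair data frame.
#' @param r1,r2 Output FASTQ paths (`.gz` supported).
#' @return Invisibly, `c(r1, r2)`.
#' @export
write_fastq_paired <- function(pairs, r1, r2) {
  check_pairs(pairs)
  w <- function(seqs, quals, ids, path, mate) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- paste0(ids, "/", mate)
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = grepl("\\.gz$", path))
  }
  w(pairs$seq1, pairs$qual1, pairs$id, r1, 1)
  w(pairs$seq2, pairs$qual2, pairs$id, r2, 2)
  invisible(c(r1, r2))
}

#' Read / write abundance tables as TSV
#'
#' Samples are rows (first column `sample`), species are columns; the header
#' row is mandatory, negative values are rejected, and numeric formatting
#' preserves full precision so tables round-trip.
#'
#' @param path TSV path.
#' @param table An `abundance_table` or matrix.
#' @return `read_abundance_table` returns an `abundance_table`;
#'   `write_abundance_table` returns `path` invisibly.
#' @export
read_abundance_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "sample\t"))
    stop("missing header row (expected first column 'sample')")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  if (any(m < 0)) stop("negative abundance value in ", path)
  abundance_table(m, "raw")
}

#' @rdname read_abundance_table
#' @export
write_abundance_table <- function(table, path) {
  m <- as.matrix(table)
  df <- data.frame(sample = rownames(m) %||% paste0("sample", seq_len(nrow(m))),
                   m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer sheet (TSV: name, sequence, role)
#'
#' @param path TSV path with columns `name`, `sequence`, `role`.
#' @return Named list of [primer] objects.
#' @export
read_primer_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "sequence", "role") %in% names(df)))
    stop("primer sheet needs columns name, sequence, role")
  setNames(lapply(seq_len(nrow(df)), function(i)
    primer(df$name[i], df$sequence[i], df$role[i])), df$name)
}

#' Read a barcode sheet (TSV: sample, barcode)
#'
#' @param path TSV path with columns `sample`, `barcode`.
#' @return Data frame `sample`, `barcode`.
#' @export
read_barcode_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "barcode") %in% names(df)))
    stop("barcode sheet needs columns sample, barcode")
  df
}
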