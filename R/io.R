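## FASTA / FASTQ / TSV interfaces.  All readers are gzip-transparent
## (Biostrings handles .gz paths natively).

#' Read a monomer catalog from FASTA
#'
#' Headers are monomer names following the `<Sp>Sat<NN>-<RUL>` convention,
#' optionally followed by a `species=` tag (ignored for parsing; the name
#' prefix is authoritative).
#'
#' @param path FASTA file (plain or gzip).
#' @return A [catalog()].
#' @export
read_catalog_fasta <- function(path) {
  x <- readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  members <- lapply(seq_along(x), function(i) {
    monomer_record(nm[i], as.character(x[[i]]))
  })
  catalog(members)
}

#' Write a monomer catalog to FASTA
#'
#' @param cat A [catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(cat, path) {
  seqs <- DNAStringSet(catalog_sequences(cat))
  names(seqs) <- paste0(names(cat$members), " species=", cat$species)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a paired-end library from two FASTQ files
#'
#' Mate order is preserved; the two files must have equal record counts.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2 (plain or gzip).
#' @param source_label Provenance label stored on the result.
#' @return A [paired_reads()] object.
#' @export
read_paired_fastq <- function(path1, path2, source_label = basename(path1)) {
  r1 <- readDNAStringSet(path1, format = "fastq")
  r2 <- readDNAStringSet(path2, format = "fastq")
  paired_reads(r1, r2, source_label = source_label)
}

#' Write a paired-end library to two FASTQ files
#'
#' Constant Phred-40 qualities are emitted (the package models substitution
#' errors directly, not quality strings).
#'
#' @param reads A [paired_reads()] object.
#' @param path1,path2 Output FASTQ paths.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_paired_fastq <- function(reads, path1, path2) {
  wr <- function(x, mate, path) {
    if (is.null(names(x)) || !length(x)) {
      names(x) <- paste0("pair", seq_along(x), "/", mate)
    }
    q <- PhredQuality(vapply(width(x), function(w)
      paste(rep("I", w), collapse = ""), character(1)))
    writeQualityScaledXStringSet(QualityScaledDNAStringSet(x, q), path)
  }
  wr(reads$read1, 1, path1)
  wr(reads$read2, 2, path2)
  invisible(c(path1, path2))
}

#' Write a data frame as TSV
#'
#' Plain-text tab-separated output used for all report tables.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE)
}
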