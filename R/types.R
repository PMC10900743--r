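#' Satellite DNA monomer record
#'
#' One consensus monomer of a satDNA family, named by the field convention
#' `<SpeciesCode>Sat<NN>-<RUL>` (e.g. `"ClaSat01-41"`): a 3-letter species
#' code, the family rank `NN` in decreasing genomic abundance, and the
#' repeat unit length (RUL) in nucleotides.
#'
#' @param name Monomer name following the convention above.
#' @param sequence DNA string over `{A,C,G,T,N}`; its length must equal the
#'   RUL encoded in the name, and be at least 10 nt.
#' @param species Optional 3-letter species code; derived from `name` when
#'   omitted, validated against it otherwise.
#' @return An object of class `monomer_record`: a list with fields `name`,
#'   `species`, `sequence`, `rul` and `at_fraction` (A+T fraction of the
#'   non-N bases).
#' @examples
#' m <- monomer_record("XxxSat01-40", random_dna(40))
#' m$rul
#' @export
monomer_record <- function(name, sequence, species = NULL) {
  check_dna(sequence, "sequence")
  if (!grepl("^[A-Z][a-z]{2}Sat[0-9]+-[0-9]+$", name)) {
    stop("name '", name, "' does not follow the <Sp>Sat<NN>-<RUL> convention",
         call. = FALSE)
  }
  rul <- nchar(sequence)
  if (rul < 10) stop("monomer '", name, "' is shorter than 10 nt", call. = FALSE)
  suffix <- as.integer(sub(".*-", "", name))
  if (suffix != rul) {
    stop("name '", name, "' declares RUL ", suffix,
         " but the sequence has ", rul, " nt", call. = FALSE)
  }
  code <- substr(name, 1, 3)
  if (!is.null(species) && !identical(species, code)) {
    stop("species '", species, "' does not match name prefix '", code, "'",
         call. = FALSE)
  }
  structure(list(
    name = name,
    species = code,
    sequence = sequence,
    rul = rul,
    at_fraction = at_fraction_of(sequence)
  ), class = "monomer_record")
}

#' @export
print.monomer_record <- function(x, ...) {
  cat(sprintf("%s  [%s]  %d nt, A+T %.1f%%\n", x$name, x$species, x$rul,
              100 * x$at_fraction))
  invisible(x)
}

#' Satellite DNA catalog of one species
#'
#' An ordered set of [monomer_record()]s for one species, ordered by
#' decreasing genomic abundance (the `NN` name ranks).  Member indices must
#' run 1..n with no gaps and all members must share the species code.
#'
#' @param members List of [monomer_record()] objects.
#' @param species Optional species code; derived from the members when
#'   omitted.
#' @return An object of class `sat_catalog` with fields `species` and
#'   `members` (named list, catalog order).
#' @export
catalog <- function(members, species = NULL) {
  stopifnot(length(members) >= 1)
  members <- lapply(members, function(m) {
    if (!inherits(m, "monomer_record")) stop("members must be monomer_record objects")
    m
  })
  codes <- vapply(members, `[[`, character(1), "species")
  species <- species %||% codes[1]
  if (!all(codes == species)) {
    stop("all members must share the species code '", species, "'", call. = FALSE)
  }
  nn <- as.integer(sub("^[A-Za-z]{3}Sat([0-9]+)-.*$", "\\1",
                       vapply(members, `[[`, character(1), "name")))
  ord <- order(nn)
  members <- members[ord]
  nn <- nn[ord]
  if (!identical(nn, seq_along(nn))) {
    stop("member indices must run 1..n with no gaps; got ",
         paste(nn, collapse = ","), call. = FALSE)
  }
  names(members) <- vapply(members, `[[`, character(1), "name")
  structure(list(species = species, members = members), class = "sat_catalog")
}

#' @export
print.sat_catalog <- function(x, ...) {
  cat(sprintf("sat_catalog of %s: %d families\n", x$species, length(x$members)))
  for (m in x$members) print(m)
  invisible(x)
}

#' @export
length.sat_catalog <- function(x) length(x$members)

catalog_sequences <- function(cat) {
  vapply(cat$members, `[[`, character(1), "sequence")
}

#' Paired-end read set
#'
#' Container for an Illumina-style paired-end library: two mate vectors in
#' matching order.  Fragment (insert) sizes of such libraries are typically
#' around 300-400 nt.
#'
#' @param read1,read2 Character vectors (or `DNAStringSet`s) of equal
#'   length; mate order is preserved.
#' @param insert_mean,insert_sd Nominal fragment-length distribution, kept
#'   as metadata.
#' @param source_label Free-text provenance label.
#' @return An object of class `paired_reads` with fields `read1`, `read2`
#'   (`DNAStringSet`), `read_length`, `insert_mean`, `insert_sd`,
#'   `source_label`.
#' @export
paired_reads <- function(read1, read2, insert_mean = NA_real_,
                         insert_sd = NA_real_, source_label = "") {
  r1 <- if (is(read1, "DNAStringSet")) read1 else DNAStringSet(read1)
  r2 <- if (is(read2, "DNAStringSet")) read2 else DNAStringSet(read2)
  if (length(r1) != length(r2)) {
    stop("both mates must be present for every pair", call. = FALSE)
  }
  rl <- if (length(r1)) as.integer(max(c(width(r1), width(r2)))) else NA_integer_
  if (length(r1) && min(c(width(r1), width(r2))) < 30) {
    stop("read length must be at least 30 nt", call. = FALSE)
  }
  structure(list(read1 = r1, read2 = r2, read_length = rl,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 source_label = source_label),
            class = "paired_reads")
}

#' @export
print.paired_reads <- function(x, ...) {
  cat(sprintf("paired_reads: %d pairs, read length %s, insert %s +/- %s  %s\n",
              length(x$read1), x$read_length, x$insert_mean, x$insert_sd,
              x$source_label))
  invisible(x)
}

#' @export
length.paired_reads <- function(x) length(x$read1)

## all mates as one DNAStringSet; mates of pair i sit at 2i-1 and 2i
all_mates <- function(reads) {
  n <- length(reads$read1)
  if (n == 0) return(DNAStringSet())
  out <- DNAStringSet(rep("", 2 * n))
  idx1 <- seq(1, 2 * n, by = 2)
  out[idx1] <- reads$read1
  out[idx1 + 1] <- reads$read2
  names(out) <- paste0("pair", rep(seq_len(n), each = 2), "/", c(1, 2))
  out
}
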