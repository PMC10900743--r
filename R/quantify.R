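## Read-masking abundance, Tandem Structure Index, single-copy-gene
## normalization and the clustered abundance matrix.
##
## Masking emulates a cross_match-style RepeatMasker run at desk scale:
## every read is locally aligned against each family consensus (tandem-
## extended so a full read can align across the array junction, both
## strands), the best-scoring family wins the read exclusively (ties go to
## the more abundant-ranked family), and a hit counts only if it spans at
## least half the read and lies within the Kimura divergence cutoff
## (default 20%).  An exact 11-mer prefilter skips the vast majority of
## non-repetitive reads before any alignment is attempted; a read inside
## the divergence cutoff has a vanishing probability of sharing no 11-mer
## with its family, so the prefilter does not change results.

PREFILTER_K <- 11L

## subject used for masking: monomer repeated so that a full read plus one
## unit fits (>= 2 copies; the circularity device generalized to short RULs)
masking_subject <- function(monomer, read_len) {
  rul <- nchar(monomer)
  reps <- max(2L, ceiling((read_len + rul) / rul))
  strrep(monomer, reps)
}

## unique k-mers of a subject, both strands, N-free
subject_kmers <- function(subj, k = PREFILTER_K) {
  if (nchar(subj) < k) return(character())
  both <- c(subj, revcomp(subj))
  kmers <- unique(unlist(lapply(both, function(s)
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))))
  kmers[!grepl("N", kmers, fixed = TRUE)]
}

## indices of reads sharing at least one exact k-mer with subj (either
## strand)
prefilter_candidates <- function(mates, subj, k = PREFILTER_K) {
  kmers <- subject_kmers(subj, k)
  if (!length(kmers)) return(seq_along(mates))
  pd <- PDict(DNAStringSet(kmers))
  which(vcountPDict(pd, mates, collapse = 2) > 0)
}

## per-family candidate read sets from one shared k-mer dictionary: one
## PDict over the union of all families' words, one scan of the mates,
## and an inversion of the hits -- building a dictionary per family is
## far more expensive than the scan itself
candidates_by_family <- function(mates, subjects, k = PREFILTER_K) {
  kmer_list <- lapply(subjects, subject_kmers, k = k)
  all_kmers <- unique(unlist(kmer_list, use.names = FALSE))
  if (!length(all_kmers)) {
    return(lapply(seq_along(subjects), function(i) seq_along(mates)))
  }
  pd <- PDict(DNAStringSet(all_kmers))
  hits <- Biostrings::vwhichPDict(pd, mates)
  ## kmer index -> families carrying it
  k2f <- split(rep(seq_along(kmer_list), lengths(kmer_list)),
               match(unlist(kmer_list, use.names = FALSE), all_kmers))
  k2f_full <- vector("list", length(all_kmers))
  k2f_full[as.integer(names(k2f))] <- k2f
  cand_reads <- which(lengths(hits) > 0)
  fams <- lapply(cand_reads, function(r)
    unique(unlist(k2f_full[hits[[r]]], use.names = FALSE)))
  by_fam <- split(rep(cand_reads, lengths(fams)),
                  unlist(fams, use.names = FALSE))
  out <- vector("list", length(subjects))
  out[as.integer(names(by_fam))] <- by_fam
  out
}

## best local alignment of each candidate mate against subj (one strand);
## returns aln_column_stats rows
align_candidates <- function(mates, subj) {
  aln <- pairwiseAlignment(mates, DNAString(subj), type = "local",
                           substitutionMatrix = sat_submat(),
                           gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
  has_n <- any(grepl("N", as.character(mates), fixed = TRUE)) ||
    grepl("N", subj, fixed = TRUE)
  aln_column_stats(aln, has_n = has_n)
}

## Exclusive assignment of mates to families.
## Returns a data.frame with one row per mate: family (integer index or
## NA), span, P, Q, k2p, accepted.
map_mates <- function(mates, cat, max_divergence = 20,
                      min_span_fraction = 0.5, circular = TRUE) {
  n <- length(mates)
  widths <- width(mates)
  best <- data.frame(family = rep(NA_integer_, n), score = -Inf,
                     span = 0L, P = 0, Q = 0)
  seqs <- catalog_sequences(cat)
  read_len <- if (n) max(widths) else 0L
  subjects <- vapply(seqs, function(s)
    if (circular) masking_subject(s, read_len) else s, character(1))
  ## one k-mer dictionary over every family: reads sharing no word with a
  ## family are never aligned against it
  cand_by_fam <- candidates_by_family(mates, subjects)
  for (fi in seq_along(seqs)) {
    subj <- subjects[[fi]]
    cand <- cand_by_fam[[fi]]
    if (is.null(cand) || !length(cand)) next
    sub_mates <- mates[cand]
    for (strand in c("+", "-")) {
      st <- align_candidates(sub_mates,
                             if (strand == "+") subj else revcomp(subj))
      better <- st$score > best$score[cand] + 1e-9
      idx <- cand[better]
      if (!length(idx)) next
      best$family[idx] <- fi
      best$score[idx] <- st$score[better]
      best$span[idx] <- st$pattern_end[better] - st$pattern_start[better] + 1L
      nong <- st$nongap_columns[better]
      best$P[idx] <- ifelse(nong > 0, st$transitions[better] / nong, 0)
      best$Q[idx] <- ifelse(nong > 0, st$transversions[better] / nong, 0)
    }
  }
  best$k2p <- ifelse(is.na(best$family), NA_real_, kimura2p(best$P, best$Q))
  best$accepted <- !is.na(best$family) &
    best$span >= min_span_fraction * widths &
    !is.na(best$k2p) & 100 * best$k2p <= max_divergence
  best
}

#' Mask reads against a satellite catalog and estimate abundances
#'
#' Emulates RepeatMasker/cross_match masking at desk scale: each mate is
#' assigned to at most one family (best local-alignment score; ties go to
#' the more abundant-ranked family) and a hit is accepted when it spans at
#' least `min_span_fraction` of the read and its Kimura 2-parameter
#' divergence is at most `max_divergence` percent.  Genomic abundance is
#' reported as masked nucleotides over analyzed nucleotides; the literal
#' masked-reads-per-analyzed-nucleotide quotient is also emitted for
#' traceability.
#'
#' @param reads A [paired_reads()] object or a `DNAStringSet` of mates.
#' @param cat A [catalog()].
#' @param max_divergence Kimura divergence cutoff in percent (default 20).
#' @param min_span_fraction Minimum fraction of the read the hit must span
#'   (default 0.5).
#' @return An object of class `abundance_table`: a data frame with one row
#'   per family -- `family`, `masked_reads`, `masked_nt`, `analyzed_nt`,
#'   `abundance_fraction` (`masked_nt / analyzed_nt`),
#'   `reads_per_nt` (`masked_reads / analyzed_nt`) -- with attributes
#'   `profiles` (per-family [divergence_profile()]s) and `assignment` (the
#'   per-mate table).
#' @export
mask_reads <- function(reads, cat, max_divergence = 20,
                       min_span_fraction = 0.5) {
  stopifnot(inherits(cat, "sat_catalog"))
  if (length(cat) == 0) stop("empty catalog", call. = FALSE)
  mates <- if (inherits(reads, "paired_reads")) all_mates(reads) else reads
  if (length(mates) == 0) stop("no reads supplied", call. = FALSE)
  asg <- map_mates(mates, cat, max_divergence = max_divergence,
                   min_span_fraction = min_span_fraction)
  analyzed_nt <- sum(width(mates))
  fam_names <- names(cat$members)
  rows <- lapply(seq_along(fam_names), function(fi) {
    hit <- asg$accepted & asg$family == fi & !is.na(asg$family)
    data.frame(family = fam_names[fi],
               masked_reads = sum(hit),
               masked_nt = sum(asg$span[hit]),
               analyzed_nt = analyzed_nt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$abundance_fraction <- out$masked_nt / out$analyzed_nt
  out$reads_per_nt <- out$masked_reads / out$analyzed_nt
  profiles <- lapply(seq_along(fam_names), function(fi) {
    hit <- asg$accepted & asg$family == fi & !is.na(asg$family)
    divergence_profile(data.frame(P = asg$P[hit], Q = asg$Q[hit],
                                  span = asg$span[hit]),
                       family_name = fam_names[fi])
  })
  names(profiles) <- fam_names
  structure(out, class = c("abundance_table", "data.frame"),
            profiles = profiles, assignment = asg)
}

#' Tandem Structure Index
#'
#' The TSI of a family is the fraction of its mapped mates whose partner
#' maps to the same family.  Reads inside long tandem arrays almost always
#' have their mate in the same array, so TSI near 1 indicates long arrays;
#' scattered short arrays leave the partner in unique sequence and drive
#' TSI toward 0.  Mapping uses the same acceptance rule as [mask_reads()].
#'
#' @param reads A [paired_reads()] object (mate pairing intact).
#' @param cat A [catalog()]; the TSI is computed for every family.
#' @inheritParams mask_reads
#' @return An object of class `tsi_table`: a data frame with columns
#'   `family`, `mapped_mates`, `concordant_mates`, `tsi` (`NA` when no
#'   mate maps -- undefined, not 0).
#' @export
compute_tsi <- function(reads, cat, max_divergence = 20,
                        min_span_fraction = 0.5) {
  stopifnot(inherits(reads, "paired_reads"), inherits(cat, "sat_catalog"))
  mates <- all_mates(reads)
  if (length(mates) == 0) stop("no reads supplied", call. = FALSE)
  asg <- map_mates(mates, cat, max_divergence = max_divergence,
                   min_span_fraction = min_span_fraction)
  fam <- ifelse(asg$accepted, asg$family, NA_integer_)
  n <- length(fam)
  ## partner index: mate 2i-1 <-> 2i
  idx <- seq_len(n)
  partner_idx <- ifelse(idx %% 2 == 1, idx + 1, idx - 1)
  partner <- fam[partner_idx]
  rows <- lapply(seq_along(cat$members), function(fi) {
    mapped <- sum(fam == fi, na.rm = TRUE)
    conc <- sum(fam == fi & partner == fi, na.rm = TRUE)
    data.frame(family = names(cat$members)[fi],
               mapped_mates = mapped, concordant_mates = conc,
               tsi = if (mapped > 0) conc / mapped else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("tsi_table", "data.frame"))
}

#' Count reads mapping to single-copy genes
#'
#' Maps mates against a set of single-copy gene sequences with the same
#' acceptance rule as [mask_reads()] (genes are linear: no tandem
#' extension) and returns per-gene mapped-read counts.
#'
#' @param reads A [paired_reads()] object or `DNAStringSet` of mates.
#' @param genes Named character vector (or `DNAStringSet`) of gene
#'   sequences.
#' @inheritParams mask_reads
#' @return Named integer vector of mapped reads per gene.
#' @export
count_gene_hits <- function(reads, genes, max_divergence = 20,
                            min_span_fraction = 0.5) {
  mates <- if (inherits(reads, "paired_reads")) all_mates(reads) else reads
  if (is(genes, "DNAStringSet")) genes <- setNames(as.character(genes), names(genes))
  if (is.null(names(genes))) names(genes) <- paste0("gene", seq_along(genes))
  members <- lapply(seq_along(genes), function(i)
    monomer_record(sprintf("GnxSat%02d-%d", i, nchar(genes[[i]])), genes[[i]]))
  gcat <- catalog(members, "Gnx")
  asg <- map_mates(mates, gcat, max_divergence = max_divergence,
                   min_span_fraction = min_span_fraction, circular = FALSE)
  counts <- vapply(seq_along(genes), function(fi)
    sum(asg$accepted & asg$family == fi, na.rm = TRUE), integer(1))
  setNames(counts, names(genes))
}

#' Normalize per-species abundances by single-copy gene coverage
#'
#' Species sequenced at different depths are made comparable by dividing
#' per-read masked counts by a per-species normalization factor, the mean
#' per-read single-copy depth over the reference genes:
#' `factor = mean_g( mapped_reads_g * read_length / (gene_length_g *
#' analyzed_reads) )`.  The matrix entry for species `s` and family `f` is
#' `log10( (masked_reads[s,f] / analyzed_reads[s]) / factor[s] +
#' pseudo_count )`, so a family absent from a species is exactly 0 and
#' doubling the sequencing depth of a species leaves its row unchanged up
#' to sampling error.
#'
#' @param masked_counts Species x family matrix of masked read counts
#'   (dimnames required; families = union of all catalogs).
#' @param gene_hits Species x gene matrix of reads mapped to each
#'   single-copy gene.
#' @param read_length Read length in nt (scalar or per-species vector).
#' @param gene_lengths Named vector of gene lengths (nt).
#' @param analyzed_reads Named per-species count of analyzed reads.
#' @param pseudo_count Added inside the log10 (default 1).
#' @return An object of class `normalized_matrix`: the log10 matrix with
#'   attribute `normalization_factor` (per species).
#' @export
normalize_by_single_copy <- function(masked_counts, gene_hits, read_length,
                                     gene_lengths, analyzed_reads,
                                     pseudo_count = 1) {
  stopifnot(is.matrix(masked_counts), is.matrix(gene_hits))
  sp <- rownames(masked_counts)
  stopifnot(!is.null(sp), all(sp %in% rownames(gene_hits)))
  gene_hits <- gene_hits[sp, , drop = FALSE]
  gl <- gene_lengths[colnames(gene_hits)]
  if (any(is.na(gl))) stop("gene_lengths must name every gene column", call. = FALSE)
  ar <- analyzed_reads[sp]
  if (any(is.na(ar))) stop("analyzed_reads must name every species", call. = FALSE)
  rl <- rep_len(read_length, length(sp))
  zero <- which(gene_hits == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    stop("no reads mapped to single-copy gene '",
         colnames(gene_hits)[zero[1, 2]], "' in species '",
         sp[zero[1, 1]], "'", call. = FALSE)
  }
  factor_s <- vapply(seq_along(sp), function(i) {
    mean(gene_hits[i, ] * rl[i] / (gl * ar[i]))
  }, numeric(1))
  if (any(factor_s <= 0)) stop("normalization factor must be positive", call. = FALSE)
  rate <- sweep(masked_counts, 1, ar, "/")
  vals <- log10(sweep(rate, 1, factor_s, "/") + pseudo_count)
  structure(vals, class = c("normalized_matrix", "matrix"),
            normalization_factor = setNames(factor_s, sp))
}

#' Hierarchically cluster a normalized abundance matrix
#'
#' UPGMA (average linkage) on Euclidean distances, rows and columns
#' independently, with rows pre-sorted by label so that degenerate
#' (identical-row) inputs order stably by species code.  A single-column
#' matrix orders rows by decreasing value instead of clustering.
#'
#' @param m A `normalized_matrix` (or plain numeric matrix, >= 2 rows).
#' @return An object of class `clustermap`: a list with `matrix` (values
#'   reordered), `row_order`, `col_order` (labels), `row_dendrogram` and
#'   `col_dendrogram` (Newick strings, `NULL` when not clustered).
#' @export
clustermap_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2)
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  row_nwk <- col_nwk <- NULL
  if (ncol(m) == 1) {
    row_ord <- order(-m[, 1])
  } else {
    hc <- hclust(dist(unclass(m)), method = "average")
    row_ord <- hc$order
    row_nwk <- ape::write.tree(ape::as.phylo(hc))
  }
  if (ncol(m) >= 2) {
    hcc <- hclust(dist(t(unclass(m))), method = "average")
    col_ord <- hcc$order
    col_nwk <- ape::write.tree(ape::as.phylo(hcc))
  } else {
    col_ord <- 1L
  }
  structure(list(matrix = unclass(m)[row_ord, col_ord, drop = FALSE],
                 row_order = rownames(m)[row_ord],
                 col_order = colnames(m)[col_ord],
                 row_dendrogram = row_nwk,
                 col_dendrogram = col_nwk),
            class = "clustermap")
}

#' @export
print.clustermap <- function(x, ...) {
  cat("clustermap:", nrow(x$matrix), "species x", ncol(x$matrix), "families\n")
  if (!is.null(x$row_dendrogram)) cat("rows:", x$row_dendrogram, "\n")
  invisible(x)
}
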