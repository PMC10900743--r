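## Kimura 2-parameter divergence and divergence-binned landscapes.
##
## Convention throughout (matching the RepeatMasker calcDivergenceFromAlign
## usage): P and Q are transition/transversion proportions over the
## *ungapped* aligned columns, and saturated distances are reported as NA,
## counted, and excluded from means -- never coerced to a large number.

#' Kimura 2-parameter distance
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P` and `Q` are the
#' observed transition and transversion proportions per site.  Vectorized.
#'
#' @param P Transition proportion(s), `>= 0`.
#' @param Q Transversion proportion(s), `>= 0`; `P + Q <= 1`.
#' @return Distance(s) in substitutions/site.  Saturated inputs (where
#'   `1 - 2P - Q <= 0` or `1 - 2Q <= 0`) yield `NA` (undefined), not an
#'   arbitrary large value.
#' @examples
#' kimura2p(0.1, 0.05)   # ~0.1702
#' kimura2p(0.5, 0)      # NA: saturation boundary
#' @export
kimura2p <- function(P, Q) {
  if (length(P) != length(Q)) {
    n <- max(length(P), length(Q))
    P <- rep_len(P, n)
    Q <- rep_len(Q, n)
  }
  if (any(is.na(P) | is.na(Q))) stop("P and Q must be non-missing", call. = FALSE)
  if (any(P < 0 | Q < 0)) stop("P and Q must be non-negative", call. = FALSE)
  if (any(P + Q > 1 + 1e-12)) stop("P + Q must not exceed 1", call. = FALSE)
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  out <- rep(NA_real_, length(P))
  ok <- a > 0 & b > 0
  out[ok] <- -0.5 * log(a[ok] * sqrt(b[ok]))
  out
}

## P and Q of one global alignment between two sequences (no rotation)
pq_of_pair <- function(a, b) {
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "global",
                           substitutionMatrix = sat_submat(),
                           gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
  has_n <- grepl("N", a, fixed = TRUE) || grepl("N", b, fixed = TRUE)
  st <- aln_column_stats(aln, has_n = has_n)
  if (st$nongap_columns == 0) return(c(P = 0, Q = 0))
  c(P = st$transitions / st$nongap_columns,
    Q = st$transversions / st$nongap_columns)
}

#' Pairwise Kimura 2-parameter divergence matrix
#'
#' Globally aligns every pair (after circular rotation/strand registration
#' when `rotate = TRUE`, appropriate for full monomers) and converts the
#' transition/transversion proportions of the ungapped columns into K2P
#' distances.  Saturated pairs are `NA` and excluded from the mean, with
#' their count carried along.
#'
#' @param seqs Named character vector of DNA strings, a list of
#'   [monomer_record()]s, or a [catalog()] (>= 2 sequences).
#' @param rotate Register rotations/strand before aligning (default FALSE;
#'   use TRUE for circular monomers).
#' @return An object of class `divergence_matrix`: the symmetric numeric
#'   matrix with `labels` as dimnames, and attributes `n_saturated` (count
#'   of undefined pairs) and `mean` (mean of the defined off-diagonal
#'   entries).
#' @export
pairwise_divergence <- function(seqs, rotate = FALSE) {
  if (inherits(seqs, "sat_catalog")) seqs <- catalog_sequences(seqs)
  if (is.list(seqs)) {
    nm <- vapply(seqs, function(x)
      if (inherits(x, "monomer_record")) x$name else NA_character_, character(1))
    seqs <- vapply(seqs, as_sequence, character(1))
    if (all(!is.na(nm))) names(seqs) <- nm
  }
  stopifnot(length(seqs) >= 2)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  n_sat <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      b <- seqs[[j]]
      if (rotate) b <- register_to(b, seqs[[i]])
      pq <- pq_of_pair(seqs[[i]], b)
      k <- kimura2p(pq["P"], pq["Q"])
      if (is.na(k)) n_sat <- n_sat + 1L
      m[i, j] <- m[j, i] <- unname(k)
    }
  }
  if (n_sat > 0) {
    warning(n_sat, " saturated pair(s) recorded as undefined", call. = FALSE)
  }
  off <- m[upper.tri(m)]
  structure(m, class = c("divergence_matrix", "matrix"),
            n_saturated = n_sat,
            mean = mean(off, na.rm = TRUE))
}

#' Mean of the defined off-diagonal entries of a divergence matrix
#'
#' @param dm A `divergence_matrix` (or plain symmetric matrix).
#' @return Mean K2P distance, `NA`s excluded.
#' @export
mean_divergence <- function(dm) {
  mean(dm[upper.tri(dm)], na.rm = TRUE)
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("divergence_matrix: %d sequences, mean K2P %.4f, %d saturated pair(s)\n",
              nrow(x), attr(x, "mean"), attr(x, "n_saturated")))
  print(unclass(x))
  invisible(x)
}

#' Divergence-binned abundance landscape of one family
#'
#' Bins per-read hits by Kimura divergence in 1% bins over 0-20% (21 bins,
#' floor binning); hits beyond 20% or with undefined (saturated) K2P are
#' dropped.  Masked nucleotides are conserved across binning for the
#' retained hits.
#'
#' @param hits Data frame with columns `P`, `Q` (per-hit proportions) and
#'   `span` (masked nucleotides of the hit), as produced by [mask_reads()].
#' @param family_name Label stored on the profile.
#' @return An object of class `divergence_profile`: a data frame with
#'   columns `bin_percent` (0..20) and `masked_nt`, plus attributes
#'   `family_name` and `n_dropped`.
#' @export
divergence_profile <- function(hits, family_name = "") {
  bins <- 0:20
  out <- data.frame(bin_percent = bins, masked_nt = 0)
  dropped <- 0L
  if (!is.null(hits) && nrow(hits) > 0) {
    k <- 100 * kimura2p(hits$P, hits$Q)
    keep <- !is.na(k) & k <= 20
    dropped <- sum(!keep)
    if (any(keep)) {
      b <- pmin(floor(k[keep]), 20)
      agg <- tapply(hits$span[keep], factor(b, levels = bins), sum)
      out$masked_nt <- ifelse(is.na(agg), 0, agg)
    }
  }
  structure(out, class = c("divergence_profile", "data.frame"),
            family_name = family_name, n_dropped = dropped)
}

#' Write a divergence matrix as TSV
#'
#' @param dm A `divergence_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_divergence_matrix <- function(dm, path) {
  df <- data.frame(name = rownames(dm), as.data.frame(unclass(dm)),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Write per-family divergence landscapes as a long TSV
#'
#' Columns: `family`, `bin_percent`, `masked_nt`.
#'
#' @param profiles List of `divergence_profile` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_divergence_landscape <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(family = attr(p, "family_name"),
               bin_percent = p$bin_percent, masked_nt = p$masked_nt)
  })
  write_tsv(do.call(rbind, rows), path)
}
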