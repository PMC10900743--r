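## Core domain types and alignment primitives.
##
## Scoring follows the permissive cross_match-like scheme used for diverged
## tandem repeats: match +1, mismatch -1, gap open -2, gap extend -1.  N is
## neutral (scores 0 against everything, never counted as match, mismatch or
## a transition/transversion event).  Coordinates are 0-based half-open in
## all returned tables.

## mismatch carries a +0.001 epsilon so that among equal-score optimal
## alignments the match-maximal one wins (local alignment otherwise trims
## terminal (mismatch, match) pairs arbitrarily); score differences of one
## full unit are unaffected.
sat_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      bases <- c("A", "C", "G", "T", "N")
      x <- matrix(-0.999, 5, 5, dimnames = list(bases, bases))
      diag(x) <- 1
      x["N", ] <- 0
      x[, "N"] <- 0
      m <<- x
    }
    m
  }
})

GAP_OPEN <- 2
GAP_EXT <- 1

## transitions are A<->G and C<->T
TRANSITION_PAIRS <- c("AG", "GA", "CT", "TC")

## Column-wise statistics for a vector of alignments (one subject).
## Fast path uses nmatch/nmismatch/mismatchTable; sequences containing N are
## routed through a per-column path.  Returns a data.frame with one row per
## pattern.
aln_column_stats <- function(aln, has_n = FALSE) {
  n <- length(aln)
  ni <- Biostrings::nindel(aln)
  cols <- nmatch(aln) + nmismatch(aln) +
    Biostrings::insertion(ni)[, "WidthSum"] + Biostrings::deletion(ni)[, "WidthSum"]
  nm <- nmatch(aln)
  nmm <- nmismatch(aln)
  ti <- integer(n)
  tv <- integer(n)
  n_excl <- integer(n)  # N-involving non-gap columns, excluded everywhere
  if (any(nmm > 0)) {
    mt <- mismatchTable(aln)
    ps <- as.character(mt$PatternSubstring)
    ss <- as.character(mt$SubjectSubstring)
    isN <- ps == "N" | ss == "N"
    key <- paste0(ps, ss)
    id <- mt$PatternId
    ti <- tabulate(id[!isN & key %in% TRANSITION_PAIRS], nbins = n)
    tv <- tabulate(id[!isN & !(key %in% TRANSITION_PAIRS)], nbins = n)
    n_excl <- tabulate(id[isN], nbins = n)
  }
  if (has_n) {
    ## N==N pairs are counted as matches by nmatch(); remove them
    pa <- as.character(alignedPattern(aln))
    sa <- as.character(alignedSubject(aln))
    nn <- mapply(function(p, s) {
      pc <- seq_chars(p); sc <- seq_chars(s)
      sum(pc == "N" & sc == "N")
    }, pa, sa, USE.NAMES = FALSE)
    nm <- nm - nn
    n_excl <- n_excl + nn
  }
  nongap <- nm + (nmm - n_excl)  # N columns removed from the denominator
  data.frame(
    score = score(aln),
    columns = cols,
    matches = nm,
    mismatches = nmm - n_excl,
    gap_columns = cols - nm - nmm,
    nongap_columns = nongap,
    transitions = ti,
    transversions = tv,
    pattern_start = start(pattern(aln)),
    pattern_end = end(pattern(aln)),
    subject_start = start(subject(aln)),
    subject_end = end(subject(aln))
  )
}

#' Align two DNA sequences
#'
#' Optimal pairwise alignment under the package's repeat-permissive scoring
#' (match +1, mismatch -1, gap open -2, gap extend -1), with transition and
#' transversion proportions computed over non-gap aligned columns.  `N`
#' aligns as neutral: it is never a match, a mismatch, nor a P/Q event, and
#' N-involving columns are excluded from the P/Q denominator.
#'
#' @param a,b Non-empty DNA strings over `{A,C,G,T,N}`.
#' @param mode `"global"` (Needleman-Wunsch) or `"local"` (Smith-Waterman).
#' @return An object of class `pairwise_alignment`: a list with fields
#'   `matches`, `mismatches`, `transitions_P`, `transversions_Q`
#'   (proportions of non-gap columns), `gap_columns`, `aligned_length`
#'   (alignment columns, gaps included), `identity`
#'   (`matches / aligned_length`), `score`, `strand` (always `"+"`; strand
#'   search lives in [monomer_similarity()]), and `rotation_offset` (0).
#' @examples
#' align_pair("ACGT", "ACGA")$transversions_Q  # T->A is a transversion
#' @export
align_pair <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  check_dna(a, "a")
  check_dna(b, "b")
  type <- if (mode == "global") "global" else "local"
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = type,
                           substitutionMatrix = sat_submat(),
                           gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
  has_n <- grepl("N", a, fixed = TRUE) || grepl("N", b, fixed = TRUE)
  st <- aln_column_stats(aln, has_n = has_n)
  structure(list(
    matches = st$matches,
    mismatches = st$mismatches,
    transitions_P = if (st$nongap_columns > 0) st$transitions / st$nongap_columns else 0,
    transversions_Q = if (st$nongap_columns > 0) st$transversions / st$nongap_columns else 0,
    gap_columns = st$gap_columns,
    aligned_length = st$columns,
    identity = if (st$columns > 0) st$matches / st$columns else NA_real_,
    score = st$score,
    strand = "+",
    rotation_offset = 0L
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "pairwise_alignment: %d columns, identity %.3f, P=%.4f Q=%.4f, %d gap columns\n",
    x$aligned_length, x$identity, x$transitions_P, x$transversions_Q,
    x$gap_columns))
  invisible(x)
}

#' Rotation- and strand-aware similarity between two monomers
#'
#' Satellite monomers are circular and deposited with arbitrary phase and
#' strand, so similarity is the best local-alignment identity over both
#' strands and all circular rotations.  Rotations are captured in one linear
#' alignment by doubling the shorter monomer; the best local alignment must
#' span at least `min_span` of the shorter monomer, otherwise similarity is
#' 0 (tiny seed matches must not link unrelated long monomers).  Identity is
#' matched bases over the alignment columns, with the denominator floored at
#' the shorter monomer's length, so similarity reads as "fraction of the
#' shorter monomer matched" and local end-trimming cannot inflate it.
#'
#' @param a,b Monomer sequences: DNA strings or [monomer_record()] objects.
#' @param min_span Minimum fraction of the shorter monomer the alignment
#'   must cover (default 0.5).
#' @return A list with `similarity` (percent identity of the best qualifying
#'   alignment, 0-100), `strand` (`"+"` or `"-"`), `rotation_offset`
#'   (left rotation of the first/shorter monomer that registers it with the
#'   other, in `[0, shorter length)`), and the bookkeeping fields
#'   `matches`, `shorter_length`, `longer_length` used by the
#'   classification significance gate.  Symmetric in its arguments.
#' @examples
#' s <- random_dna(40)
#' monomer_similarity(s, rotate_seq(s, 13))$similarity  # 100
#' @export
monomer_similarity <- function(a, b, min_span = 0.5) {
  a <- as_sequence(a)
  b <- as_sequence(b)
  check_dna(a, "a")
  check_dna(b, "b")
  ## shorter monomer is doubled and used as the subject; ties keep `a`
  if (nchar(b) < nchar(a)) {
    res <- monomer_similarity(b, a, min_span = min_span)
    return(res)
  }
  s <- a
  l <- b
  L <- nchar(s)
  doubled <- paste0(s, s)
  best <- list(similarity = 0, strand = "+", rotation_offset = 0L,
               matches = 0L, shorter_length = L, longer_length = nchar(l),
               score = 0, gap_fraction = 0, aligned_columns = 0L)
  has_n <- grepl("N", s, fixed = TRUE) || grepl("N", l, fixed = TRUE)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") l else revcomp(l)
    aln <- pairwiseAlignment(DNAString(pat), DNAString(doubled),
                             type = "local",
                             substitutionMatrix = sat_submat(),
                             gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
    if (has_n) {
      st <- aln_column_stats(aln, has_n = TRUE)
      matches <- st$matches
      mismatches <- st$mismatches
      columns <- st$columns
      s_start <- st$subject_start
      s_end <- st$subject_end
    } else {
      matches <- nmatch(aln)
      mismatches <- nmismatch(aln)
      ni <- Biostrings::nindel(aln)
      columns <- matches + mismatches +
        Biostrings::insertion(ni)[, "WidthSum"] +
        Biostrings::deletion(ni)[, "WidthSum"]
      s_start <- start(subject(aln))
      s_end <- end(subject(aln))
    }
    span <- min(s_end - s_start + 1L, L)
    if (span < min_span * L) next
    sim <- 100 * matches / max(columns, L)
    if (sim > best$similarity) {
      best <- list(similarity = sim, strand = strand,
                   rotation_offset = as.integer((s_start - 1L) %% L),
                   matches = matches, shorter_length = L,
                   longer_length = nchar(l), score = score(aln),
                   gap_fraction = if (columns > 0)
                     (columns - matches - mismatches) / columns else 0,
                   aligned_columns = as.integer(columns))
    }
  }
  best
}

## Homology gates for classification edges.  Chance local alignments of
## unrelated monomers have scores in the logarithmic (Gumbel) regime --
## empirically <= ~10-12 under this scoring regardless of monomer lengths
## -- while genuine homology scores grow linearly with the shorter
## monomer.  Gap "weaving" can inflate the *match count* of a chance
## alignment far beyond the binomial level without raising its score, so
## the match-count test (similarity_evalue) is only trusted for
## essentially ungapped alignments, where the binomial null is exact.
## A hit is credible if its score clears the chance regime outright, or
## if it is colinear and its match count is unachievable by chance.
similarity_is_credible <- function(sim, min_score = 15,
                                   max_evalue = 5e-4,
                                   max_gap_fraction = 0.02) {
  if (sim$score >= min_score) return(TRUE)
  (sim$gap_fraction %||% 0) <= max_gap_fraction &&
    similarity_evalue(sim) <= max_evalue
}

## Chance expectation of a similarity hit: the number of equally good or
## better match counts expected from aligning the shorter monomer at every
## placement (both strands, all rotations) against random sequence.  Short
## monomers reach 50-65% "similarity" against unrelated sequence purely by
## best-window selection; classification edges are therefore gated on this
## statistic, mirroring the score thresholds alignment-based maskers apply.
similarity_evalue <- function(sim) {
  ## the null draws as many Bernoulli(0.25) trials as the alignment has
  ## columns (the doubled subject lets windows exceed the monomer length),
  ## floored at the full monomer so window trimming cannot help
  n <- max(sim$aligned_columns %||% 0, sim$shorter_length)
  p <- stats::pbinom(sim$matches - 1, n, 0.25, lower.tail = FALSE)
  4 * sim$longer_length * p
}

#' Consensus of a set of monomer copies
#'
#' Builds the column-wise majority consensus of a star alignment: every
#' member is (optionally) rotated and strand-oriented onto a reference
#' member, globally aligned to it, and votes per reference column.  Ties are
#' broken by the fixed base order A < C < G < T; columns where gaps hold a
#' strict majority are dropped.
#'
#' @param members Character vector of DNA strings (>= 1), all within 20%
#'   length of the median member.
#' @param circular Register rotations/strand before aligning (default TRUE;
#'   set FALSE for linear subrepeats).
#' @return A DNA string; its length lies within the member length range.
#' @export
build_consensus <- function(members, circular = TRUE) {
  members <- vapply(members, as_sequence, character(1), USE.NAMES = FALSE)
  stopifnot(length(members) >= 1)
  for (m in members) check_dna(m, "member")
  lens <- nchar(members)
  med <- stats::median(lens)
  if (any(abs(lens - med) > 0.2 * med)) {
    stop("heterogeneous member lengths: spread exceeds 20% of the median",
         call. = FALSE)
  }
  if (length(members) == 1) return(members)
  ref_i <- which.min(abs(lens - med))
  ref <- members[ref_i]
  reflen <- nchar(ref)
  ## one vote matrix over reference columns; row per member; members are
  ## aligned to the reference in a single vectorized call
  votes <- matrix("-", nrow = length(members), ncol = reflen)
  votes[ref_i, ] <- seq_chars(ref)
  others <- setdiff(seq_along(members), ref_i)
  oriented <- vapply(others, function(i) {
    if (circular) register_to(members[i], ref) else members[i]
  }, character(1))
  aln <- pairwiseAlignment(DNAStringSet(oriented), DNAString(ref),
                           type = "global",
                           substitutionMatrix = sat_submat(),
                           gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
  pas <- as.character(alignedPattern(aln))
  sas <- as.character(alignedSubject(aln))
  for (k in seq_along(others)) {
    pa <- seq_chars(pas[k])
    sa <- seq_chars(sas[k])
    refpos <- cumsum(sa != "-")
    keep <- sa != "-"
    votes[others[k], refpos[keep]] <- pa[keep]
  }
  cons <- apply(votes, 2, function(col) {
    gaps <- sum(col == "-")
    if (gaps > length(col) / 2) return("-")
    col <- col[col %in% BASES]
    if (length(col) == 0) return("-")
    tab <- table(factor(col, levels = BASES))
    BASES[which.max(tab)]  # which.max takes the first max: A < C < G < T
  })
  paste(cons[cons != "-"], collapse = "")
}

## Accept either a plain string or a monomer_record
as_sequence <- function(x) {
  if (inherits(x, "monomer_record")) x$sequence else x
}

## Orient (strand) and rotate `m` so that its phase matches `ref`.
## The candidate rotation comes from the phase of the best local alignment
## of `ref` against the doubled candidate; both strands are tried.
register_to <- function(m, ref) {
  best <- m
  best_score <- -Inf
  Lm <- nchar(m)
  for (mm in c(m, revcomp(m))) {
    aln <- pairwiseAlignment(DNAString(ref), DNAString(paste0(mm, mm)),
                             type = "local",
                             substitutionMatrix = sat_submat(),
                             gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
    if (score(aln) > best_score) {
      best_score <- score(aln)
      best <- rotate_seq(mm, (start(subject(aln)) - 1L) %% Lm)
    }
  }
  best
}
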