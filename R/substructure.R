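## Monomer internal structure: self-dotplots, periodicity, subrepeat
## decomposition and higher-order-repeat (HOR) annotation.
##
## Long satellite monomers typically arise from successive cycles of
## duplication and divergence of shorter units; the decomposition
## quantifies this by comparing the divergence between subunits within one
## repeat (intra-repeat: fixed at the original duplication) against the
## divergence between like subunits of different repeats (inter-repeat:
## accumulated since array amplification, and kept low by concerted
## evolution).  Coordinates in all returned tables are 0-based half-open.

#' Self-dotplot diagonal summary
#'
#' Slides the monomer against itself and reports every off-main diagonal
#' (offset) supported by at least `min_support` k-words matching with at
#' most `max_mismatch` mismatches.  The dotplot is symmetric about the main
#' diagonal, so only positive offsets are listed.
#'
#' @param monomer DNA string (or [monomer_record()]), length >= `2k`.
#' @param k Word size (>= 4).
#' @param max_mismatch Mismatches tolerated within a k-word (default 0).
#' @param min_support Minimum number of supporting k-words (default 3).
#' @return A data frame with columns `offset`, `support` (matching
#'   k-words), `match_fraction` (position-wise identity along the
#'   diagonal) and `overlap` (diagonal length), one row per supported
#'   diagonal.
#' @export
self_dotplot <- function(monomer, k = 8, max_mismatch = 0, min_support = 3) {
  s <- as_sequence(monomer)
  check_dna(s, "monomer")
  if (k < 4) stop("word size k must be at least 4", call. = FALSE)
  L <- nchar(s)
  if (L < 2 * k) stop("monomer shorter than 2k", call. = FALSE)
  ch <- seq_chars(s)
  rows <- vector("list", L - k)
  for (d in seq_len(L - k)) {
    ov <- L - d
    eq <- ch[seq_len(ov)] == ch[(d + 1):L]
    nwin <- ov - k + 1
    if (nwin >= 1) {
      cs <- cumsum(c(0, as.integer(eq)))
      win_matches <- cs[(k + 1):(ov + 1)] - cs[seq_len(nwin)]
      support <- sum(k - win_matches <= max_mismatch)
    } else {
      support <- 0L
    }
    if (support >= min_support) {
      rows[[d]] <- data.frame(offset = d, support = support,
                              match_fraction = mean(eq), overlap = ov)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(offset = integer(), support = integer(),
                      match_fraction = numeric(), overlap = integer()))
  }
  do.call(rbind, rows)
}

#' Detect internal periodicity of a monomer
#'
#' Combines self-dotplot diagonal support with substring autocorrelation
#' (position-wise identity per offset): offsets where at least
#' `min_support` fuzzy k-words match and the diagonal identity reaches
#' `min_fraction` are candidate periods, ranked by identity (ties:
#' smaller period first, so the fundamental period outranks its
#' harmonics).  An empty vector means no internal repetition is
#' detectable.
#'
#' @param monomer DNA string or [monomer_record()], length >= 20.
#' @param k,max_mismatch Fuzzy word parameters (defaults 8 and 2: a
#'   k-word still matches at ~25% divergence, where exact words vanish).
#' @param min_fraction Minimum diagonal identity (default 0.55; random
#'   sequence sits near 0.25).
#' @param min_overlap Minimum diagonal length considered (default 10).
#' @return Integer vector of candidate periods, best first (possibly
#'   empty).
#' @export
detect_period <- function(monomer, k = 8, max_mismatch = 2,
                          min_fraction = 0.55, min_overlap = 10) {
  s <- as_sequence(monomer)
  check_dna(s, "monomer")
  if (nchar(s) < 20) stop("monomer shorter than 20 nt", call. = FALSE)
  dp <- self_dotplot(s, k = k, max_mismatch = max_mismatch, min_support = 3)
  dp <- dp[dp$match_fraction >= min_fraction & dp$overlap >= min_overlap, ,
           drop = FALSE]
  if (!nrow(dp)) return(integer())
  dp <- dp[order(-dp$match_fraction, dp$offset), , drop = FALSE]
  as.integer(dp$offset)
}

## subunit boundaries implied by lag q within a repeat of length `period`:
## uniform tiling when q nearly divides the period, else two unequal
## subunits (q, period - q)
split_for_lag <- function(q, period) {
  m <- round(period / q)
  if (m >= 2 && abs(period - m * q) <= 3) {
    sa <- q * seq_len(m - 1)
    sa[sa < period - 3]
  } else if (period - q >= 10 && q >= 10) {
    q
  } else {
    integer()
  }
}

## Duplication-homology score of a candidate split at a given rotation of
## the repeat consensus: mean positional identity between each consecutive
## pair of subunit pieces (over their shared prefix).  The best rotation
## registers the repeat frame so that subunit boundaries coincide with the
## old duplication junctions.
split_phase_score <- function(rep_cons, split_at) {
  plen <- nchar(rep_cons)
  bounds <- c(0L, split_at, plen)
  best <- c(phase = 0, score = -1)
  for (r in 0:(plen - 1)) {
    cr <- seq_chars(rotate_seq(rep_cons, r))
    sc <- vapply(seq_len(length(bounds) - 2), function(i) {
      a0 <- bounds[i]; a1 <- bounds[i + 1]; b1 <- bounds[i + 2]
      w <- min(a1 - a0, b1 - a1)
      if (w < 4) return(NA_real_)
      mean(cr[(a0 + 1):(a0 + w)] == cr[(a1 + 1):(a1 + w)])
    }, numeric(1))
    sc <- mean(sc, na.rm = TRUE)
    if (!is.nan(sc) && sc > best["score"]) best <- c(phase = r, score = sc)
  }
  best
}

## all-pairs mean K2P between two sets of (possibly unequal-length)
## sequences aligned globally; batched one-subject-many-patterns, NA-safe
k2p_batch <- function(patterns, subject) {
  aln <- pairwiseAlignment(DNAStringSet(patterns), DNAString(subject),
                           type = "global",
                           substitutionMatrix = sat_submat(),
                           gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
  has_n <- any(grepl("N", patterns, fixed = TRUE)) ||
    grepl("N", subject, fixed = TRUE)
  st <- aln_column_stats(aln, has_n = has_n)
  P <- ifelse(st$nongap_columns > 0, st$transitions / st$nongap_columns, 0)
  Q <- ifelse(st$nongap_columns > 0, st$transversions / st$nongap_columns, 0)
  kimura2p(P, Q)
}

mean_k2p_between <- function(xs, ys = NULL) {
  xs <- unlist(xs, use.names = FALSE)
  vals <- numeric()
  if (is.null(ys)) {
    n <- length(xs)
    if (n < 2) return(NA_real_)
    for (j in 2:n) {
      vals <- c(vals, k2p_batch(xs[seq_len(j - 1)], xs[j]))
    }
  } else {
    ys <- unlist(ys, use.names = FALSE)
    for (y in ys) vals <- c(vals, k2p_batch(xs, y))
  }
  if (!length(vals) || all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Decompose an array-like monomer into repeats and subrepeats
#'
#' Treats the monomer as circular (analysis starts from its canonical --
#' lexicographically minimal -- rotation, so any rotation of the input
#' yields identical results), tiles it into repeat units of approximately
#' `period` nt (boundaries refined by up to 3 nt against the first
#' repeat), and infers the subunit structure within the repeat unit from
#' the self-dotplot lags of the whole array: a lag `q < period` with
#' strong fuzzy-word support splits the repeat into subunits of ~`q` nt
#' (uniformly when `q` nearly divides the period, e.g. 60 = 3 x 20;
#' otherwise into two unequal subunits `q` and `period - q`, e.g.
#' 40 = 29 + 11).  Subunits are labeled `alpha`, `beta`, ... cyclically
#' across repeats.
#'
#' Two divergence summaries are computed from global alignments (gap
#' columns excluded, all-pairs means): `intra_repeat_divergence_mean`
#' between differently-labeled subunits of the same repeat, and
#' `inter_repeat_divergence_mean` between like-labeled subunits of
#' different repeats.  When no subunit structure is detectable each repeat
#' is its own subunit and the two means coincide (all-pairs repeat
#' divergence).
#'
#' @param monomer DNA string or [monomer_record()].
#' @param period Repeat unit length in nt (`period <= length / 2`, i.e.
#'   at least two repeats).
#' @param n_labels Optional: force this many subunits per repeat instead
#'   of inferring from the dotplot.
#' @return An object of class `subunit_decomposition`: a list with fields
#'   `monomer_name`, `period_estimate`, `subunits` (data frame: `start`,
#'   `end` 0-based half-open on the canonical rotation, `label`,
#'   `repeat_index`), `intra_repeat_divergence_mean`,
#'   `inter_repeat_divergence_mean`, `pairing` (`"all-pairs"`), and
#'   `canonical_offset` (rotation applied to the input).
#' @export
decompose_subunits <- function(monomer, period, n_labels = NULL) {
  nm <- if (inherits(monomer, "monomer_record")) monomer$name else ""
  s <- as_sequence(monomer)
  check_dna(s, "monomer")
  L <- nchar(s)
  period <- as.integer(period)
  if (period < 4 || period > L / 2) {
    stop("period must give at least two repeat units", call. = FALSE)
  }
  canon <- canonical_rotation(s)
  s <- canon$seq
  rotation_applied <- canon$offset
  ## tile `x` into repeats of ~period nt, each boundary refined by up to
  ## +/-3 nt against the first repeat
  tile_repeats <- function(x) {
    first <- substr(x, 1, period)
    starts <- 0L
    pos <- period
    while (L - pos >= period / 2) {
      lo <- max(starts[length(starts)] + 4L, pos - 3L)
      hi <- min(L - 1L, pos + 3L)
      cand <- lo:hi
      ident <- vapply(cand, function(b) {
        w <- min(period, L - b)
        mean(seq_chars(substr(x, b + 1, b + w)) ==
               seq_chars(substr(first, 1, w)))
      }, numeric(1))
      b <- cand[which.max(ident)]
      starts <- c(starts, b)
      pos <- b + period
    }
    ends <- c(starts[-1], L)
    ## drop a trailing fragment shorter than half a period (intervening)
    keep <- (ends - starts) >= period / 2
    data.frame(start = starts[keep], end = ends[keep])
  }
  reps <- tile_repeats(s)
  if (nrow(reps) < 2) stop("period yields fewer than two repeats", call. = FALSE)
  rep_seqs <- substring(s, reps$start + 1, reps$end)
  ## --- subunit split from array-level dotplot lags (lags do not depend
  ## on the rotation phase; the phase is registered afterwards)
  split_at <- integer()
  phase <- 0L
  if (!is.null(n_labels)) {
    m <- as.integer(n_labels)
    if (m > 1) {
      split_at <- round(seq_len(m - 1) * period / m)
      ph <- split_phase_score(build_consensus(rep_seqs, circular = FALSE),
                              split_at)
      phase <- as.integer(ph["phase"])
    }
  } else {
    k_word <- 8L
    mm_max <- 2L
    dp <- self_dotplot(s, k = k_word, max_mismatch = mm_max, min_support = 0)
    ## subunit lags lie well inside the repeat unit
    dp <- dp[dp$offset >= 8 & dp$offset <= period - 8, , drop = FALSE]
    if (nrow(dp)) {
      ## keep lags whose support clearly exceeds the chance level for
      ## fuzzy k-words on random sequence; a true subunit lag also recurs
      ## in every repeat unit, so support scales with the repeat count.
      ## The word criterion is blind to duplications whose fixed mismatch
      ## pattern happens to lack any dense window, so a strongly elevated
      ## diagonal identity over a long overlap (0.40 vs the 0.25 random
      ## baseline) also qualifies.
      p_rand <- sum(choose(k_word, 0:mm_max) * 3^(0:mm_max)) / 4^k_word
      expected <- (dp$overlap - k_word + 1) * p_rand
      by_words <- dp$support >= pmax(ceiling(3 * expected),
                                     ceiling(1.5 * nrow(reps)), 4)
      by_fraction <- dp$match_fraction >= 0.40 & dp$overlap >= 100
      dp <- dp[by_words | by_fraction, , drop = FALSE]
    }
    if (nrow(dp)) {
      ## evaluate every gated lag and keep the split whose phase-
      ## registered duplication homology is strongest
      rep_cons <- build_consensus(rep_seqs, circular = FALSE)
      best_adj <- -Inf
      for (q in unique(dp$offset)) {
        sa <- split_for_lag(q, period)
        if (!length(sa)) next
        ph <- split_phase_score(rep_cons, sa)
        ## random sequence sits near 0.25 identity; 0.45 keeps genuine
        ## duplications detectable up to ~45-50% realized subunit
        ## divergence (the gated lag has already established periodicity;
        ## the phase score mainly registers the frame)
        if (ph["score"] < 0.45) next
        ## penalize narrow homology windows: a short chance window must
        ## not outscore a long genuine duplication
        w <- min(diff(c(0L, sa, period)))
        adj <- ph["score"] - 0.5 / w
        if (adj > best_adj + 1e-9) {
          best_adj <- adj
          split_at <- sa
          phase <- as.integer(ph["phase"])
        }
      }
    }
  }
  if (length(split_at) && phase > 0) {
    ## re-register the repeat frame so that subunit boundaries coincide
    ## with the duplication junctions
    s <- rotate_seq(s, phase)
    rotation_applied <- (rotation_applied + phase) %% L
    reps <- tile_repeats(s)
    rep_seqs <- substring(s, reps$start + 1, reps$end)
  }
  ## --- build subunit table
  labels <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
              "theta")
  sub_rows <- list()
  for (r in seq_len(nrow(reps))) {
    plen <- reps$end[r] - reps$start[r]
    bounds <- unique(pmin(c(0L, split_at, plen), plen))
    bounds <- sort(bounds[bounds <= plen])
    if (bounds[length(bounds)] != plen) bounds <- c(bounds, plen)
    ## merge a terminal sliver (< 4 nt) into the previous subunit
    if (length(bounds) > 2 && diff(utils::tail(bounds, 2)) < 4) {
      bounds <- bounds[-(length(bounds) - 1)]
    }
    nb <- length(bounds) - 1
    sub_rows[[r]] <- data.frame(
      start = reps$start[r] + bounds[-length(bounds)],
      end = reps$start[r] + bounds[-1],
      label = labels[((seq_len(nb) - 1) %% length(labels)) + 1],
      repeat_index = r - 1L)
  }
  subunits <- do.call(rbind, sub_rows)
  sub_seq <- substring(s, subunits$start + 1, subunits$end)
  ## --- divergence means
  if (length(split_at) == 0) {
    ## degenerate: each repeat is its own subunit; both means are the
    ## all-pairs repeat divergence
    intra <- inter <- mean_k2p_between(rep_seqs)
  } else {
    intra_vals <- c()
    for (r in unique(subunits$repeat_index)) {
      ss <- sub_seq[subunits$repeat_index == r]
      if (length(ss) >= 2) {
        intra_vals <- c(intra_vals, mean_k2p_between(ss))
      }
    }
    intra <- if (length(intra_vals)) mean(intra_vals, na.rm = TRUE) else NA_real_
    inter_vals <- c()
    for (lab in unique(subunits$label)) {
      ss <- sub_seq[subunits$label == lab]
      if (length(ss) >= 2) {
        inter_vals <- c(inter_vals, mean_k2p_between(ss))
      }
    }
    inter <- if (length(inter_vals)) mean(inter_vals, na.rm = TRUE) else NA_real_
  }
  structure(list(monomer_name = nm,
                 period_estimate = period,
                 subunits = subunits,
                 intra_repeat_divergence_mean = intra,
                 inter_repeat_divergence_mean = inter,
                 pairing = "all-pairs",
                 canonical_offset = rotation_applied),
            class = "subunit_decomposition")
}

#' @export
print.subunit_decomposition <- function(x, ...) {
  cat(sprintf(
    "subunit_decomposition%s: period %d, %d subunits (%s), intra %.4f / inter %.4f\n",
    if (nzchar(x$monomer_name)) paste0(" of ", x$monomer_name) else "",
    x$period_estimate, nrow(x$subunits),
    paste(unique(x$subunits$label), collapse = ","),
    x$intra_repeat_divergence_mean, x$inter_repeat_divergence_mean))
  invisible(x)
}

## raw (Hamming) divergence between equal-length strings
raw_div <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  mean(ca != cb)
}

#' Annotate higher-order-repeat structure of a long monomer
#'
#' Greedy left-to-right segmentation into maximal tandem runs: at each
#' position the smallest unit length whose next copy stays within
#' `max_divergence` starts a run, the run extends while consecutive units
#' remain within the cutoff, and unassigned stretches are emitted as
#' unlabeled "intervening" segments.  Length bookkeeping is exact:
#' segment plus intervening lengths sum to the monomer length.
#'
#' @param monomer DNA string or [monomer_record()], length >= 200.
#' @param min_unit,max_unit Unit length search range in nt (defaults 15
#'   and 300).
#' @param max_divergence Maximum raw divergence between consecutive units
#'   (default 0.45).
#' @return An object of class `hor_annotation`: a data frame with columns
#'   `start`, `end` (0-based half-open), `type` (`"tandem"` or
#'   `"intervening"`), `repeat_count`, `unit_length`, `unit_consensus`,
#'   `divergence_within` (mean all-pairs K2P between units; 0-row counts
#'   for intervening segments are NA).
#' @export
annotate_hor <- function(monomer, min_unit = 15, max_unit = 300,
                         max_divergence = 0.45) {
  nm <- if (inherits(monomer, "monomer_record")) monomer$name else ""
  s <- as_sequence(monomer)
  check_dna(s, "monomer")
  L <- nchar(s)
  if (L < 200) stop("monomer shorter than 200 nt", call. = FALSE)
  ch <- seq_chars(s)
  ## best (identity, unit length) of a candidate run start; memoized
  best_cache <- new.env(parent = emptyenv())
  best_at <- function(pos) {
    key <- as.character(pos)
    hit <- best_cache[[key]]
    if (!is.null(hit)) return(hit)
    umax <- min(max_unit, (L - pos) %/% 2)
    res <- c(id = -1, u = 0)
    if (umax >= min_unit) {
      us <- min_unit:umax
      ids <- vapply(us, function(u)
        mean(ch[(pos + 1):(pos + u)] == ch[(pos + u + 1):(pos + 2 * u)]),
        numeric(1))
      ok <- ids >= 1 - max_divergence
      if (any(ok)) {
        ## prefer the shortest unit close to the best identity, so a 2x
        ## or 3x multiple of the true unit never wins on noise alone
        top <- max(ids[ok])
        pick <- which(ok & ids >= top - 0.08)[1]
        res <- c(id = ids[pick], u = us[pick])
      }
    }
    best_cache[[key]] <- res
    res
  }
  runs <- data.frame(start = integer(), end = integer(),
                     unit_length = integer())
  pos <- 0L
  while (pos < L) {
    cand <- best_at(pos)
    accept <- FALSE
    if (cand["u"] > 0) {
      ## start refinement: a run may only start where no position within
      ## the next unit offers a strictly better first comparison
      ## (otherwise a misphased start would swallow intervening sequence)
      lookahead <- pos + seq_len(cand["u"] - 1)
      lookahead <- lookahead[lookahead < L]
      better <- FALSE
      for (p2 in lookahead) {
        if (best_at(p2)["id"] > cand["id"] + 1e-9) { better <- TRUE; break }
      }
      if (!better) {
        u <- as.integer(cand["u"])
        count <- 2L
        while (pos + (count + 1) * u <= L) {
          id <- mean(ch[(pos + (count - 1) * u + 1):(pos + count * u)] ==
                       ch[(pos + count * u + 1):(pos + (count + 1) * u)])
          if (id < 1 - max_divergence) break
          count <- count + 1L
        }
        ## guard against chance 2-unit runs in unstructured sequence
        accept <- count >= 3L || cand["id"] >= 0.75
      }
    }
    if (accept) {
      runs <- rbind(runs, data.frame(start = pos, end = pos + count * u,
                                     unit_length = u))
      pos <- pos + count * u
    } else {
      pos <- pos + 1L
    }
  }
  ## refinement: extend runs unit-by-unit against the run consensus.  A
  ## consensus comparison tolerates twice the divergence a consecutive-
  ## unit comparison does, recovering units the greedy seeding eroded.
  if (nrow(runs)) {
    for (ri in seq_len(nrow(runs))) {
      u <- runs$unit_length[ri]
      units <- lapply(seq_len((runs$end[ri] - runs$start[ri]) %/% u) - 1L,
                      function(i) ch[(runs$start[ri] + i * u + 1):
                                       (runs$start[ri] + (i + 1) * u)])
      cons <- apply(do.call(rbind, units), 2, function(col) {
        tab <- table(factor(col, levels = BASES))
        BASES[which.max(tab)]
      })
      lo <- if (ri > 1) runs$end[ri - 1] else 0L
      hi <- if (ri < nrow(runs)) runs$start[ri + 1] else L
      while (runs$start[ri] - u >= lo &&
             mean(ch[(runs$start[ri] - u + 1):runs$start[ri]] == cons) >=
               1 - max_divergence) {
        runs$start[ri] <- runs$start[ri] - u
      }
      while (runs$end[ri] + u <= hi &&
             mean(ch[(runs$end[ri] + 1):(runs$end[ri] + u)] == cons) >=
               1 - max_divergence) {
        runs$end[ri] <- runs$end[ri] + u
      }
    }
  }
  ## assemble the segment table with exact length bookkeeping
  segs <- list()
  cursor <- 0L
  emit_intervening <- function(from, to) {
    if (to > from) {
      segs[[length(segs) + 1]] <<- data.frame(
        start = from, end = to, type = "intervening",
        repeat_count = NA_integer_, unit_length = NA_integer_,
        unit_consensus = NA_character_, divergence_within = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(runs)) {
    for (ri in seq_len(nrow(runs))) {
      emit_intervening(cursor, runs$start[ri])
      u <- runs$unit_length[ri]
      count <- (runs$end[ri] - runs$start[ri]) %/% u
      units <- vapply(seq_len(count) - 1L, function(i)
        substr(s, runs$start[ri] + i * u + 1, runs$start[ri] + (i + 1) * u),
        character(1))
      segs[[length(segs) + 1]] <- data.frame(
        start = runs$start[ri], end = runs$end[ri], type = "tandem",
        repeat_count = count, unit_length = u,
        unit_consensus = build_consensus(units, circular = FALSE),
        divergence_within = mean_k2p_between(as.list(units)),
        stringsAsFactors = FALSE)
      cursor <- runs$end[ri]
    }
  }
  emit_intervening(cursor, L)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  structure(out, class = c("hor_annotation", "data.frame"), monomer_name = nm)
}

#' Write a subunit decomposition (and optional HOR table) as TSV
#'
#' @param x A `subunit_decomposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(x, path) {
  df <- x$subunits
  df$monomer <- x$monomer_name
  df$intra_repeat_divergence_mean <- x$intra_repeat_divergence_mean
  df$inter_repeat_divergence_mean <- x$inter_repeat_divergence_mean
  df$pairing <- x$pairing
  write_tsv(df, path)
}
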