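## Shared fixture builders.  Everything is generated in code under fixed
## seeds; no stored data.

## substitute exactly round(d * nchar(s)) positions (uniform target base)
mutate_exact <- function(s, d) {
  ch <- strsplit(s, "")[[1]]
  n <- round(d * length(ch))
  if (n > 0) {
    pos <- sample(length(ch), n)
    for (i in pos) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
  }
  paste(ch, collapse = "")
}

## a random unit with no internal self-similarity, by fuzzy words or by
## diagonal identity (the premise of the perfect-tandem examples: a unit
## with an accidental 40%-identity self-shift is weakly structured, and a
## tandem array of it legitimately decomposes)
random_unstructured_unit <- function(n) {
  repeat {
    u <- random_dna(n)
    dp <- self_dotplot(strrep(u, 4), k = 8, max_mismatch = 2,
                       min_support = 0)
    dp <- dp[dp$offset >= 8 & dp$offset <= n - 8, , drop = FALSE]
    if (nrow(dp) == 0 ||
        all(dp$support < 2 & dp$match_fraction < 0.35)) return(u)
  }
}

## brute-force similarity oracle: position-wise identity over all
## rotations and both strands (equal-length sequences)
similarity_oracle <- function(a, b) {
  L <- nchar(a)
  best <- 0
  for (bb in c(b, revcomp(b))) {
    for (k in 0:(L - 1)) {
      rb <- rotate_seq(bb, k)
      best <- max(best, mean(strsplit(a, "")[[1]] == strsplit(rb, "")[[1]]))
    }
  }
  100 * best
}

## plain Rand index between two partitions
rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  s / choose(n, 2)
}

## tiny catalog of k monomers derived from one ancestor at divergence d
make_family_catalog <- function(k, ancestor, d, species = "Xxx") {
  seqs <- vapply(seq_len(k), function(i) mutate_exact(ancestor, d),
                 character(1))
  name_families(data.frame(sequence = seqs,
                           abundance = rev(seq_len(k)) / 100),
                species)
}
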