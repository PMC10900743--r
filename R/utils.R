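BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' Draws an i.i.d. uniform DNA string.  All randomness in the package flows
#' through R's RNG; callers that need reproducibility should use
#' [with_seed()] or set the seed themselves.
#'
#' @param n Sequence length in nucleotides.
#' @param gc GC content in `[0, 1]` (default 0.5).
#' @return A character scalar over `{A,C,G,T}`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Rotate a circular sequence
#'
#' Left-rotates `s` by `k` positions: `rotate_seq("ABCDE", 2) == "CDEAB"`.
#' Satellite monomers are circular units of a tandem array, so any rotation
#' names the same repeat.
#'
#' @param s DNA string.
#' @param k Rotation offset (any integer; reduced modulo `nchar(s)`).
#' @return The rotated string.
#' @export
rotate_seq <- function(s, k) {
  n <- nchar(s)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

#' Reverse complement
#'
#' @param s DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## lexicographically minimal rotation; canonical phase for circular monomers
canonical_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1) return(list(seq = s, offset = 0L))
  rots <- vapply(0:(n - 1), function(k) rotate_seq(s, k), character(1))
  k <- which(rots == min(rots))[1] - 1L
  list(seq = rots[k + 1L], offset = k)
}

is_dna_string <- function(s) {
  is.character(s) && length(s) == 1L && !is.na(s) && nzchar(s) &&
    !grepl("[^ACGTN]", s)
}

check_dna <- function(s, what = "sequence") {
  if (!is_dna_string(s)) {
    stop(what, " must be a non-empty DNA string over {A,C,G,T,N}",
         call. = FALSE)
  }
  invisible(s)
}

## split a DNA string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

at_fraction_of <- function(s) {
  ch <- seq_chars(s)
  ch <- ch[ch != "N"]
  if (length(ch) == 0) return(NA_real_)
  mean(ch %in% c("A", "T"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## uniform integer draw on [lo, hi]; safe when lo == hi (base sample()
## would treat a scalar as 1:n)
sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}
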