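test_that("self_dotplot finds exact duplications and stays quiet on noise", {
  set.seed(51)
  A <- random_dna(20)
  dp <- self_dotplot(paste0(A, A), k = 8)
  expect_true(20 %in% dp$offset)
  expect_equal(dp$match_fraction[dp$offset == 20], 1)
  ## expected exact k-word collisions in a random 200-mer are << 3
  dp2 <- self_dotplot(random_dna(200), k = 8)
  expect_equal(nrow(dp2), 0)
  expect_error(self_dotplot(random_dna(100), k = 3), "at least 4")
  expect_error(self_dotplot(random_dna(10), k = 8), "2k")
})

test_that("self_dotplot resolves a diverged 21+20 duplication", {
  set.seed(52)
  alpha <- random_dna(21)
  beta <- mutate_exact(substr(alpha, 1, 20), 0.15)  # 3 substitutions
  dp <- self_dotplot(paste0(alpha, beta), k = 8, max_mismatch = 2,
                     min_support = 3)
  expect_true(any(abs(dp$offset - 21) <= 1))
})

test_that("detect_period ranks the fundamental period first", {
  p <- detect_period(strrep("ACGTT", 8))
  expect_equal(p[1], 5)
  set.seed(53)
  ## 41-mer built from a 21/20 duplication at 15% subunit divergence
  hits <- 0
  for (i in 1:5) {
    alpha <- random_dna(21)
    mono <- paste0(alpha, mutate_exact(substr(alpha, 1, 20), 0.15))
    cand <- detect_period(mono)
    if (length(cand) && any(head(cand, 3) %in% 19:22)) hits <- hits + 1
  }
  expect_gte(hits, 4)
  ## verified-structureless monomers yield nothing; plain random draws
  ## carry chance fuzzy self-similarity only rarely
  for (i in 1:3) {
    expect_length(detect_period(random_unstructured_unit(60)), 0)
  }
  empty <- sum(vapply(1:10, function(i)
    length(detect_period(random_dna(60))) == 0, logical(1)))
  expect_gte(empty, 8)
})

test_that("a perfect tandem decomposes with zero intra and inter divergence", {
  set.seed(54)
  U <- random_unstructured_unit(30)
  d <- decompose_subunits(strrep(U, 4), 30)
  expect_equal(d$intra_repeat_divergence_mean, 0)
  expect_equal(d$inter_repeat_divergence_mean, 0)
  expect_equal(nrow(d$subunits), 4)
  expect_error(decompose_subunits(strrep(U, 4), 70), "two repeat")
})

test_that("duplication-then-amplification leaves inter < intra divergence", {
  ## d1 = 0.30 at the duplication, d2 = 0.05 during amplification
  set.seed(55)
  ok <- 0
  for (i in 1:5) {
    alpha <- random_dna(21)
    beta <- mutate_exact(substr(alpha, 1, 20), 0.30)
    rep41 <- paste0(alpha, beta)
    arr <- paste(vapply(1:8, function(j) mutate_exact(rep41, 0.05),
                        character(1)), collapse = "")
    d <- decompose_subunits(arr, 41)
    lens <- with(d$subunits[d$subunits$repeat_index == 0, ], end - start)
    if (isTRUE(d$inter_repeat_divergence_mean <
                 d$intra_repeat_divergence_mean) &&
        length(lens) == 2 && all(abs(sort(lens) - c(20, 21)) <= 3)) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 4)
})

test_that("unequal 29+11 subrepeats are recovered within 3 nt", {
  set.seed(56)
  ok <- 0
  for (i in 1:5) {
    a29 <- random_dna(29)
    b11 <- mutate_exact(substr(a29, 1, 11), 0.22)
    arr <- paste(vapply(1:8, function(j) mutate_exact(paste0(a29, b11), 0.03),
                        character(1)), collapse = "")
    d <- decompose_subunits(arr, 40)
    lens <- with(d$subunits[d$subunits$repeat_index == 0, ], end - start)
    if (length(lens) == 2 && all(abs(sort(lens) - c(11, 29)) <= 3)) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 4)
})

test_that("decompose_subunits is rotation invariant", {
  set.seed(57)
  a29 <- random_dna(29)
  b11 <- mutate_exact(substr(a29, 1, 11), 0.22)
  arr <- paste(vapply(1:8, function(j) mutate_exact(paste0(a29, b11), 0.03),
                      character(1)), collapse = "")
  d0 <- decompose_subunits(arr, 40)
  for (k in c(7, 77, 201)) {
    dk <- decompose_subunits(rotate_seq(arr, k), 40)
    expect_equal(dk$intra_repeat_divergence_mean,
                 d0$intra_repeat_divergence_mean, tolerance = 1e-9)
    expect_equal(dk$inter_repeat_divergence_mean,
                 d0$inter_repeat_divergence_mean, tolerance = 1e-9)
  }
})

test_that("annotate_hor segments an exact HOR construction", {
  set.seed(58)
  U41 <- random_dna(41)
  V81 <- random_dna(81)
  spacer <- random_dna(23)
  mono <- paste0(strrep(U41, 12), spacer, strrep(V81, 6))
  h <- annotate_hor(mono)
  tand <- h[h$type == "tandem", ]
  expect_equal(nrow(tand), 2)
  expect_equal(tand$repeat_count, c(12, 6))
  expect_equal(tand$unit_length, c(41, 81))
  expect_equal(tand$divergence_within, c(0, 0))
  ## exact length bookkeeping: segments + intervening tile the monomer
  expect_equal(sum(h$end - h$start), nchar(mono))
  expect_equal(sum(h$end[h$type == "intervening"] -
                     h$start[h$type == "intervening"]), 23)
})

test_that("annotate_hor tolerates 20% unit divergence within one unit count", {
  set.seed(59)
  U41 <- random_dna(41)
  V81 <- random_dna(81)
  spacer <- random_dna(23)
  mono <- paste0(
    paste(vapply(1:12, function(i) mutate_exact(U41, 0.2), character(1)),
          collapse = ""),
    spacer,
    paste(vapply(1:6, function(i) mutate_exact(V81, 0.2), character(1)),
          collapse = ""))
  h <- annotate_hor(mono)
  tand <- h[h$type == "tandem", ]
  expect_equal(nrow(tand), 2)
  expect_lte(abs(tand$repeat_count[1] - 12), 1)
  expect_lte(abs(tand$repeat_count[2] - 6), 1)
  expect_equal(sum(h$end - h$start), nchar(mono))
})

test_that("annotate_hor reports unstructured input as one intervening segment", {
  set.seed(60)
  for (i in 1:3) {
    h <- annotate_hor(random_dna(300))
    expect_equal(nrow(h), 1)
    expect_equal(h$type, "intervening")
    expect_equal(h$end - h$start, 300)
  }
})
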