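test_that("monomer records validate the naming convention", {
  set.seed(1)
  s <- random_dna(40)
  m <- monomer_record("XxxSat01-40", s)
  expect_equal(m$rul, 40)
  expect_equal(m$species, "Xxx")
  expect_equal(m$at_fraction,
               mean(strsplit(s, "")[[1]] %in% c("A", "T")))
  expect_error(monomer_record("XxxSat01-41", s), "RUL")
  expect_error(monomer_record("bad-name", s), "convention")
  expect_error(monomer_record("XxxSat01-5", random_dna(5)), "10 nt")
})

test_that("catalogs enforce gap-free 1..n member indices and one species", {
  set.seed(2)
  mk <- function(nm, n = 40) monomer_record(nm, random_dna(n))
  expect_silent(catalog(list(mk("XxxSat01-40"), mk("XxxSat02-40"))))
  expect_error(catalog(list(mk("XxxSat01-40"), mk("XxxSat03-40"))), "gaps")
  expect_error(catalog(list(mk("XxxSat01-40"), mk("YyySat02-40"))),
               "species")
})

test_that("align_pair classifies substitutions and scores identity", {
  p <- align_pair("ACGT", "ACGT")
  expect_equal(p$identity, 1)
  expect_equal(p$transitions_P, 0)
  expect_equal(p$transversions_Q, 0)
  expect_equal(p$gap_columns, 0)

  ## T->A is a transversion
  p <- align_pair("ACGT", "ACGA")
  expect_equal(p$aligned_length, 4)
  expect_equal(p$matches, 3)
  expect_equal(p$transversions_Q, 0.25)
  expect_equal(p$transitions_P, 0)
  expect_equal(p$identity, 0.75)

  ## 60-mer with 6 substitutions: position-wise comparison is the oracle
  set.seed(11)
  a <- random_dna(60)
  b <- mutate_exact(a, 0.1)
  expect_equal(sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), 6)
  p <- align_pair(a, b)
  expect_equal(p$identity, 0.9)
  expect_error(align_pair("", "ACGT"), "non-empty")
})

test_that("align_pair treats N as neutral", {
  p <- align_pair("ACNT", "ACGT")
  expect_equal(p$matches, 3)
  expect_equal(p$mismatches, 0)
  expect_equal(p$transitions_P + p$transversions_Q, 0)
})

test_that("monomer_similarity is rotation- and strand-invariant", {
  set.seed(3)
  s <- random_dna(40)
  expect_equal(monomer_similarity(s, s)$similarity, 100)
  r <- monomer_similarity(s, rotate_seq(s, 13))
  expect_equal(r$similarity, 100)
  expect_equal(r$rotation_offset, 13)
  expect_equal(monomer_similarity(s, revcomp(s))$similarity, 100)
  for (i in 1:8) {
    s <- random_dna(sample(25:90, 1))
    k <- sample(0:(nchar(s) - 1), 1)
    expect_equal(monomer_similarity(s, rotate_seq(revcomp(s), k))$similarity,
                 100)
  }
})

test_that("monomer_similarity matches the brute-force rotation oracle", {
  set.seed(4)
  for (i in 1:6) {
    a <- random_dna(40)
    b <- mutate_exact(a, 0.2)  # exactly 8 substitutions
    got <- monomer_similarity(a, b)$similarity
    expect_equal(got, similarity_oracle(a, b))
    expect_equal(got, 80)
    ## symmetry
    expect_equal(monomer_similarity(b, a)$similarity, got)
  }
})

test_that("unrelated long monomers fall below the 50% tier", {
  set.seed(5)
  sims <- replicate(10,
    monomer_similarity(random_dna(100), random_dna(200))$similarity)
  expect_true(all(sims < 50))
})

test_that("build_consensus recovers the majority base per column", {
  set.seed(6)
  anc <- random_dna(41)
  expect_equal(build_consensus(anc), anc)
  ## one substitution in one of three copies is outvoted
  ch <- strsplit(anc, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  expect_equal(build_consensus(c(anc, anc, paste(ch, collapse = ""))), anc)
  ## 20 variants at 5% divergence: consensus within 2% of the ancestor
  members <- vapply(1:20, function(i) mutate_exact(anc, 0.05), character(1))
  cons <- build_consensus(members)
  expect_gte(align_pair(cons, anc)$identity, 0.98)
  ## rotated/reverse-complemented members still vote coherently
  members_rot <- vapply(members, function(m)
    rotate_seq(m, sample(40, 1)), character(1))
  cons2 <- build_consensus(members_rot)
  expect_gte(monomer_similarity(cons2, anc)$similarity, 98)
  expect_error(build_consensus(c(random_dna(40), random_dna(80))),
               "heterogeneous")
})

test_that("catalog FASTA and paired FASTQ round-trip", {
  set.seed(7)
  cat1 <- make_family_catalog(3, random_dna(50), 0.05)
  fa <- tempfile(fileext = ".fa")
  write_catalog_fasta(cat1, fa)
  cat2 <- read_catalog_fasta(fa)
  expect_equal(names(cat2$members), names(cat1$members))
  expect_equal(vapply(cat2$members, `[[`, character(1), "sequence"),
               vapply(cat1$members, `[[`, character(1), "sequence"))

  reads <- paired_reads(replicate(5, random_dna(50)),
                        replicate(5, random_dna(50)),
                        insert_mean = 200, insert_sd = 10)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_paired_fastq(reads, f1, f2)
  back <- read_paired_fastq(f1, f2)
  expect_equal(as.character(back$read1), as.character(reads$read1),
               ignore_attr = TRUE)
  expect_equal(as.character(back$read2), as.character(reads$read2),
               ignore_attr = TRUE)
})

test_that("paired_reads rejects unpaired mates and short reads", {
  expect_error(paired_reads(c("ACGTACGTACGTACGTACGTACGTACGTACGT"),
                            character(0)), "both mates")
  expect_error(paired_reads("ACGT", "ACGT"), "at least 30")
})
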