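## Small end-to-end masking fixtures: genomes assembled by hand so the
## satellite content is known exactly.

make_genome_reads <- function(genome, n_pairs, read_len = 100,
                              insert = 250, insert_sd = 15) {
  G <- nchar(genome)
  frag <- pmax(read_len, round(rnorm(n_pairs, insert, insert_sd)))
  frag <- pmin(frag, G)
  starts <- floor(runif(n_pairs, 0, G - frag + 1))
  r1 <- substring(genome, starts + 1, starts + read_len)
  r2 <- vapply(substring(genome, starts + frag - read_len + 1,
                         starts + frag), revcomp, character(1),
               USE.NAMES = FALSE)
  paired_reads(r1, r2, insert_mean = insert, insert_sd = insert_sd)
}

test_that("mask_reads recovers a planted abundance and rejects noise", {
  set.seed(41)
  mon <- random_dna(50)
  cat1 <- name_families(data.frame(sequence = mon, abundance = 0.1), "Xxx")

  ## reads with no similarity to the family mask nothing
  noise <- paired_reads(replicate(40, random_dna(100)),
                        replicate(40, random_dna(100)))
  ab <- mask_reads(noise, cat1)
  expect_equal(ab$masked_reads, 0)
  expect_equal(ab$abundance_fraction, 0)
  expect_equal(ab$analyzed_nt, 8000)

  ## a genome that is 10% one perfect satellite array
  array_nt <- 2000
  genome <- paste0(random_dna(9000), strrep(mon, array_nt / 50),
                   random_dna(9000))
  reads <- make_genome_reads(genome, 1000)
  ab <- mask_reads(reads, cat1)
  expect_lt(abs(ab$abundance_fraction - 0.10), 0.02)
  ## masked nucleotides never exceed analyzed nucleotides
  expect_lte(ab$masked_nt, ab$analyzed_nt)
  ## the landscape concentrates at 0% divergence for a perfect array
  prof <- attr(ab, "profiles")[[1]]
  expect_equal(sum(prof$masked_nt), ab$masked_nt)
  expect_gt(prof$masked_nt[prof$bin_percent == 0] / sum(prof$masked_nt),
            0.95)
  expect_error(mask_reads(noise, cat1[0]), "catalog")
})

test_that("the divergence cutoff removes arrays past 20%", {
  set.seed(42)
  mon <- random_dna(60)
  cat1 <- name_families(data.frame(sequence = mon, abundance = 0.1), "Xxx")
  far <- paste(vapply(1:40, function(i) mutate_exact(mon, 0.3),
                      character(1)), collapse = "")
  genome <- paste0(random_dna(5000), far, random_dna(5000))
  reads <- make_genome_reads(genome, 600)
  ab <- mask_reads(reads, cat1)
  expect_lt(ab$abundance_fraction, 0.02)

  ## the same geometry within the cutoff is recovered
  near <- paste(vapply(1:40, function(i) mutate_exact(mon, 0.08),
                       character(1)), collapse = "")
  genome2 <- paste0(random_dna(5000), near, random_dna(5000))
  reads2 <- make_genome_reads(genome2, 600)
  ab2 <- mask_reads(reads2, cat1)
  expect_gt(ab2$abundance_fraction, 0.1)
  ## modal divergence bin sits near the simulated 8%
  prof <- attr(ab2, "profiles")[[1]]
  expect_true(prof$bin_percent[which.max(prof$masked_nt)] %in% 6:10)
})

test_that("reads are masked exclusively, favoring the abundance rank on ties", {
  set.seed(43)
  mon <- random_dna(80)
  cat2 <- name_families(data.frame(sequence = c(mon, random_dna(80)),
                                   abundance = c(0.02, 0.01)), "Xxx")
  genome <- paste0(random_dna(3000), strrep(mon, 30), random_dna(3000))
  reads <- make_genome_reads(genome, 500)
  ab <- mask_reads(reads, cat2)
  expect_gt(ab$masked_reads[1], 0)
  expect_equal(ab$masked_reads[2], 0)
  asg <- attr(ab, "assignment")
  expect_lte(sum(ab$masked_nt), ab$analyzed_nt[1])
})

test_that("compute_tsi separates long arrays from scattered copies", {
  set.seed(44)
  mon <- random_dna(150)
  cat1 <- name_families(data.frame(sequence = mon, abundance = 0.1), "Xxx")

  ## one long pure array (>> insert size)
  genome <- paste0(random_dna(4000), strrep(mon, 40), random_dna(4000))
  reads <- make_genome_reads(genome, 800)
  tsi <- compute_tsi(reads, cat1)
  expect_gte(tsi$tsi, 0.95)

  ## isolated single monomers separated by >> insert size
  genome2 <- paste(c(vapply(1:12, function(i)
    paste0(random_dna(1200), mon), character(1)), random_dna(1200)),
    collapse = "")
  reads2 <- make_genome_reads(genome2, 800)
  tsi2 <- compute_tsi(reads2, cat1)
  expect_gt(tsi2$mapped_mates, 0)
  expect_lte(tsi2$tsi, 0.1)

  ## no mapped mates: undefined, not zero
  noise <- paired_reads(replicate(30, random_dna(100)),
                        replicate(30, random_dna(100)))
  tsi3 <- compute_tsi(noise, cat1)
  expect_true(is.na(tsi3$tsi))
  expect_equal(tsi3$mapped_mates, 0)
})

test_that("single-copy normalization is symmetric and depth-invariant", {
  set.seed(45)
  counts <- matrix(c(100, 100, 40, 40), nrow = 2, byrow = FALSE,
                   dimnames = list(c("Aaa", "Bbb"), c("fam1", "fam2")))
  gene_hits <- matrix(c(50, 50, 60, 60, 55, 55), nrow = 2,
                      dimnames = list(c("Aaa", "Bbb"), paste0("g", 1:3)))
  gl <- setNames(c(1000, 1200, 1100), paste0("g", 1:3))
  ar <- c(Aaa = 10000, Bbb = 10000)
  nm <- normalize_by_single_copy(counts, gene_hits, 150, gl, ar)
  f <- attr(nm, "normalization_factor")
  expect_equal(unname(f["Aaa"]), unname(f["Bbb"]))
  expect_equal(nm["Aaa", ], nm["Bbb", ])

  ## doubling depth doubles counts and analyzed reads: values unchanged
  nm2 <- normalize_by_single_copy(counts * 2, gene_hits * 2, 150, gl,
                                  ar * 2)
  expect_equal(unclass(nm2), unclass(nm))

  ## an absent family is exactly log10(0 + 1) = 0
  counts0 <- counts
  counts0["Aaa", "fam2"] <- 0
  nm3 <- normalize_by_single_copy(counts0, gene_hits, 150, gl, ar)
  expect_equal(nm3["Aaa", "fam2"], 0)

  ## zero gene coverage names the gene
  gh0 <- gene_hits
  gh0["Bbb", "g2"] <- 0
  expect_error(normalize_by_single_copy(counts, gh0, 150, gl, ar), "g2")
})

test_that("clustermap clusters deterministically with stable degenerate order", {
  m <- rbind(Aaa = c(1, 2, 3, 0), Bbb = c(1, 2, 3, 0), Ccc = c(9, 0, 1, 4))
  colnames(m) <- paste0("f", 1:4)
  cm <- clustermap_matrix(m)
  ## the identical pair joins first: adjacent in the row order
  pos <- match(c("Aaa", "Bbb"), cm$row_order)
  expect_equal(abs(diff(pos)), 1)
  expect_equal(cm$matrix, m[cm$row_order, cm$col_order], ignore_attr = TRUE)
  cm2 <- clustermap_matrix(m)
  expect_identical(cm$row_dendrogram, cm2$row_dendrogram)

  ## single column: rows ordered by decreasing value
  m1 <- matrix(c(0.1, 2, 1), ncol = 1,
               dimnames = list(c("Aaa", "Bbb", "Ccc"), "f1"))
  cm1 <- clustermap_matrix(m1)
  expect_equal(cm1$row_order, c("Bbb", "Ccc", "Aaa"))
  expect_error(clustermap_matrix(m1[1, , drop = FALSE]), "2")
})

test_that("doubling reads shrinks the abundance standard error", {
  set.seed(46)
  mon <- random_dna(60)
  cat1 <- name_families(data.frame(sequence = mon, abundance = 0.1), "Xxx")
  genome <- paste0(random_dna(4500), strrep(mon, 20), random_dna(4500))
  est <- function(n_pairs) {
    reads <- make_genome_reads(genome, n_pairs)
    mask_reads(reads, cat1)$abundance_fraction
  }
  e1 <- replicate(8, est(150))
  e2 <- replicate(8, est(600))
  ## quadrupling reads should roughly halve the spread
  expect_lt(sd(e2), sd(e1))
})
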