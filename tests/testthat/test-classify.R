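test_that("intraspecific tiers separate variants and superfamilies", {
  set.seed(31)
  anc <- random_dna(41)
  twin <- anc                                  # same sequence variant
  variant <- mutate_exact(anc, 0.10)           # ~90%: variant tier
  ## 25 of 41 positions preserved (~61%): superfamily tier; substitutions
  ## spread evenly so the homology is colinear over the whole monomer
  cousin <- local({
    ch <- strsplit(anc, "")[[1]]
    for (i in round(seq(3, 39, length.out = 16))) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    paste(ch, collapse = "")
  })
  stranger <- random_dna(120)
  cat1 <- name_families(data.frame(
    sequence = c(anc, twin, variant, cousin, stranger),
    abundance = c(5, 4, 3, 2, 1) / 100), "Xxx")
  tiers <- classify_intraspecific(cat1)
  id_of <- function(col, nm) tiers[[col]][match(nm, tiers$name)]
  nm <- names(cat1$members)  # abundance order: anc, twin, variant, cousin, stranger
  expect_equal(id_of("same_variant_id", nm[1]), id_of("same_variant_id", nm[2]))
  expect_equal(id_of("variant_id", nm[1]), id_of("variant_id", nm[3]))
  expect_false(id_of("same_variant_id", nm[1]) ==
                 id_of("same_variant_id", nm[3]))
  expect_equal(id_of("superfamily", nm[1]), id_of("superfamily", nm[4]))
  expect_false(id_of("variant_id", nm[1]) == id_of("variant_id", nm[4]))
  ## singleton superfamilies stay blank, like the field convention
  expect_true(is.na(id_of("superfamily", nm[5])))
})

test_that("a six-member 50-80% similarity cluster forms one superfamily", {
  ## premise: six monomers pairwise >= 50% and < 80% similar; drawn until
  ## the premise holds (deterministic under the seed)
  set.seed(32)
  repeat {
    anc <- random_dna(41)
    seqs <- vapply(1:6, function(i) mutate_exact(anc, 0.20), character(1))
    sims <- combn(6, 2, function(ij)
      monomer_similarity(seqs[ij[1]], seqs[ij[2]])$similarity)
    if (all(sims >= 50 & sims < 80)) break
  }
  cat1 <- name_families(data.frame(sequence = seqs,
                                   abundance = 6:1 / 100), "Cla")
  tiers <- classify_intraspecific(cat1)
  expect_equal(unique(tiers$superfamily), 1L)
  expect_equal(length(unique(tiers$variant_id)), 6)
})

test_that("tier nesting holds on random catalogs", {
  set.seed(33)
  for (rep in 1:3) {
    anc1 <- random_dna(60)
    anc2 <- random_dna(45)
    seqs <- c(vapply(1:3, function(i) mutate_exact(anc1, runif(1, 0, 0.3)),
                     character(1)),
              vapply(1:3, function(i) mutate_exact(anc2, runif(1, 0, 0.3)),
                     character(1)))
    cat1 <- name_families(data.frame(sequence = seqs,
                                     abundance = 6:1 / 100), "Xxx")
    tiers <- classify_intraspecific(cat1)
    ## every 95% component lies inside one 80% component inside one 50%
    ## component
    expect_true(all(tapply(tiers$variant_id, tiers$same_variant_id,
                           function(v) length(unique(v))) == 1))
    sf <- ifelse(is.na(tiers$superfamily), -seq_len(nrow(tiers)),
                 tiers$superfamily)
    expect_true(all(tapply(sf, tiers$variant_id,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("assign_groups links descendants across species and flags main groups", {
  set.seed(34)
  anc <- random_dna(50)
  species <- c("Aaa", "Bbb", "Ccc", "Ddd", "Eee")
  catalogs <- lapply(species, function(sp)
    name_families(data.frame(sequence = mutate_exact(anc, 0.12),
                             abundance = 0.01), sp))
  grp <- assign_groups(catalogs)
  expect_equal(sum(!is.na(grp$group)), 5)
  expect_equal(unique(grp$group[!is.na(grp$group)]), 1L)
  g <- attr(grp, "groups")
  expect_equal(g$species_span, 5L)
  expect_true(g$is_main)
})

test_that("mutually unrelated monomers stay ungrouped", {
  set.seed(35)
  catalogs <- lapply(c("Aaa", "Bbb", "Ccc"), function(sp)
    name_families(data.frame(sequence = random_dna(120),
                             abundance = 0.01), sp))
  grp <- assign_groups(catalogs)
  expect_true(all(is.na(grp$group)))
  expect_equal(nrow(attr(grp, "groups")), 0)
})

test_that("assign_groups is invariant to catalog order and monomer rotation/strand", {
  set.seed(36)
  anc1 <- random_dna(60)
  anc2 <- random_dna(80)
  mk <- function(sp, rot = 0, rc = FALSE) {
    s1 <- rotate_seq(mutate_exact(anc1, 0.08), rot)
    s2 <- mutate_exact(anc2, 0.08)
    if (rc) s2 <- revcomp(s2)
    name_families(data.frame(sequence = c(s1, s2),
                             abundance = c(0.02, 0.01)), sp)
  }
  cats <- list(mk("Aaa"), mk("Bbb", rot = 11), mk("Ccc", rot = 25, rc = TRUE))
  g1 <- assign_groups(cats)
  g2 <- assign_groups(rev(cats))
  expect_equal(as.data.frame(g1), as.data.frame(g2))
  expect_equal(sort(unique(g1$group)), c(1L, 2L))
})

test_that("name_families ranks by abundance with deterministic tie-breaks", {
  set.seed(37)
  s1 <- random_dna(41)
  cat1 <- name_families(data.frame(sequence = s1, abundance = 0.005), "Xxx")
  expect_equal(names(cat1$members), "XxxSat01-41")

  ## higher abundance wins rank 1 regardless of input order
  s2 <- random_dna(60)
  cat2 <- name_families(data.frame(sequence = c(s1, s2),
                                   abundance = c(0.005, 0.022)), "Xxx")
  expect_equal(names(cat2$members), c("XxxSat01-60", "XxxSat02-41"))
  expect_equal(cat2$members[[1]]$sequence, s2)

  ## abundance ties broken by lower divergence, then sequence
  s3 <- random_dna(41)
  cat3 <- name_families(data.frame(sequence = c(s1, s3),
                                   abundance = c(0.01, 0.01),
                                   divergence = c(0.2, 0.1)), "Xxx")
  expect_equal(cat3$members[[1]]$sequence, s3)

  ## simulated multi-family catalog reproduces the true abundance order
  seqs <- vapply(1:6, function(i) random_dna(sample(40:80, 1)), character(1))
  ab <- runif(6, 0.0002, 0.022)
  cat4 <- name_families(data.frame(sequence = seqs, abundance = ab), "Yyy")
  expect_equal(vapply(cat4$members, `[[`, character(1), "sequence"),
               seqs[order(-ab)], ignore_attr = TRUE)
})
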