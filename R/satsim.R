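## Synthetic satellitome generator.
##
## Implements the library hypothesis at desk scale: a set of ancestral
## satDNA families (each built by duplication-divergence cycles from a
## short unit) evolves along a species tree; branches accumulate
## substitutions (plus rare indels) and resample per-family amplification
## multipliers, occasionally silencing a family to scattered-only remnants.
## Leaves receive abundance-ranked catalogs; genomes are random background
## with clustered tandem arrays and scattered short arrays, plus planted
## single-copy genes; paired-end reads are sampled uniformly with
## substitution errors.  Everything is driven by one integer seed and is
## byte-reproducible.

#' Simulation configuration
#'
#' Assembles and validates the dial set of the synthetic satellitome
#' generator.  Defaults emulate a five-species crocodylian-like design: an
#' ultrametric tree with one long outgroup branch, 6 ancestral families of
#' 20-60 nt units expanded by 0-2 duplication cycles, genomic abundances
#' in the 0.02-2.2% range, Illumina-like 150 nt paired-end reads with
#' ~350 nt fragments.
#'
#' @param tree Newick string (branch lengths in arbitrary Myr-like units).
#' @param n_ancestral_families Families in the root library.
#' @param ancestral_unit_length_range Unit length range (nt) before
#'   duplication cycles.
#' @param duplication_cycles_range Duplication-divergence cycles per
#'   family (each cycle roughly doubles the unit).
#' @param cycle_divergence Subunit divergence applied at each duplication
#'   cycle.
#' @param subst_rate Substitutions/site per branch-length unit.
#' @param indel_ratio Indels per substitution (default 0.1; substitutions
#'   dominate so orthologs keep their unit length).
#' @param amplification_sdlog Log-sd of the per-branch log-normal
#'   amplification multiplier (scaled by the square root of relative
#'   branch length).
#' @param silencing_prob Per-branch probability that a family collapses to
#'   scattered-only remnants.
#' @param abundance_range Root genomic abundance fractions (log-uniform
#'   draw).
#' @param clustered_fraction Fraction of a family's copies in clustered
#'   arrays: `NULL` draws one value per family and species uniformly on
#'   (0.5, 1); a scalar fixes it for every family.
#' @param array_copy_range Copies per clustered array.
#' @param scattered_copy_range Copies per scattered short array.
#' @param array_divergence_range Per-copy divergence from the family
#'   consensus inside arrays (uniform draw per family).
#' @param genome_length Genome length per species (nt).
#' @param n_genes,gene_length Planted single-copy genes.
#' @param read_length,insert_mean,insert_sd,error_rate,n_pairs Read
#'   simulation dials.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree = "((((Cya:11,Cla:11):14,Mni:25):40,Ptr:65):25,Asi:90);",
                       n_ancestral_families = 6,
                       ancestral_unit_length_range = c(20, 60),
                       duplication_cycles_range = c(0, 2),
                       cycle_divergence = 0.25,
                       subst_rate = 0.0012,
                       indel_ratio = 0.1,
                       amplification_sdlog = 1,
                       silencing_prob = 0.05,
                       abundance_range = c(0.0002, 0.022),
                       clustered_fraction = NULL,
                       array_copy_range = c(20, 100),
                       scattered_copy_range = c(1, 3),
                       array_divergence_range = c(0.02, 0.10),
                       genome_length = 2e6,
                       n_genes = 3,
                       gene_length = 1000,
                       read_length = 150,
                       insert_mean = 350,
                       insert_sd = 30,
                       error_rate = 0.001,
                       n_pairs = 50000,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(tree = tree, n_ancestral_families = n_ancestral_families,
              ancestral_unit_length_range = ancestral_unit_length_range,
              duplication_cycles_range = duplication_cycles_range,
              cycle_divergence = cycle_divergence,
              subst_rate = subst_rate, indel_ratio = indel_ratio,
              amplification_sdlog = amplification_sdlog,
              silencing_prob = silencing_prob,
              abundance_range = abundance_range,
              clustered_fraction = clustered_fraction,
              array_copy_range = array_copy_range,
              scattered_copy_range = scattered_copy_range,
              array_divergence_range = array_divergence_range,
              genome_length = genome_length, n_genes = n_genes,
              gene_length = gene_length, read_length = read_length,
              insert_mean = insert_mean, insert_sd = insert_sd,
              error_rate = error_rate, n_pairs = n_pairs,
              seed = as.integer(seed))
  stopifnot(cfg$subst_rate >= 0, cfg$indel_ratio >= 0,
            cfg$silencing_prob >= 0, cfg$silencing_prob <= 1,
            is.null(cfg$clustered_fraction) ||
              (cfg$clustered_fraction >= 0 && cfg$clustered_fraction <= 1),
            cfg$error_rate >= 0, cfg$n_pairs >= 0)
  class(cfg) <- "sim_config"
  cfg
}

## point substitutions at per-site probability `d` (transition:transversion
## 2:1), plus indels at d * indel_ratio per site (single-base)
mutate_seq <- function(s, d, indel_ratio = 0) {
  if (d <= 0 || !nzchar(s)) return(s)
  ch <- seq_chars(s)
  n <- length(ch)
  hit <- which(runif(n) < d)
  if (length(hit)) {
    transit <- c(A = "G", G = "A", C = "T", T = "C")
    for (i in hit) {
      if (runif(1) < 2 / 3) {
        ch[i] <- transit[[ch[i]]]
      } else {
        ch[i] <- sample(setdiff(BASES, c(ch[i], transit[[ch[i]]])), 1)
      }
    }
  }
  if (indel_ratio > 0) {
    nid <- rbinom(1, n, d * indel_ratio)
    for (j in seq_len(nid)) {
      pos <- sample(length(ch), 1)
      if (runif(1) < 0.5 && length(ch) > 10) {
        ch <- ch[-pos]
      } else {
        ch <- append(ch, sample(BASES, 1), after = pos)
      }
    }
  }
  paste(ch, collapse = "")
}

#' Grow a monomer by duplication-divergence cycles
#'
#' Each cycle duplicates the current unit, diverges one copy at rate `d1`
#' (substitutions dominate; an occasional single-base indel), and with
#' probability `spacer_prob` inserts a short random spacer between the
#' copies.  The full construction record (every intermediate, boundaries,
#' spacers) is returned so downstream substructure analyses can be
#' validated against the truth.
#'
#' @param unit Starting DNA unit (>= 10 nt).
#' @param cycles Number of duplication cycles (>= 0).
#' @param d1 Subunit divergence applied to the new copy each cycle.
#' @param seed Optional seed (uses the current RNG stream when NULL).
#' @param spacer_prob Probability of a 0-30 nt spacer per cycle.
#' @param indel_ratio Indels per substitution during divergence.
#' @return A list with `sequence` (the final monomer) and `record`: a list
#'   of per-cycle entries (`before`, `after`, `spacer`, `boundary`).
#' @export
evolve_duplication_divergence <- function(unit, cycles, d1, seed = NULL,
                                          spacer_prob = 0.3,
                                          indel_ratio = 0.1) {
  check_dna(unit, "unit")
  if (nchar(unit) < 10) stop("unit must be at least 10 nt", call. = FALSE)
  run <- function() {
    cur <- unit
    record <- list()
    for (cy in seq_len(cycles)) {
      copy <- mutate_seq(cur, d1, indel_ratio)
      spacer <- if (runif(1) < spacer_prob)
        random_dna(sample(0:30, 1)) else ""
      nxt <- paste0(cur, spacer, copy)
      record[[cy]] <- list(before = cur, after = nxt, spacer = spacer,
                           boundary = nchar(cur) + nchar(spacer))
      cur <- nxt
    }
    list(sequence = cur, record = record)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## one evolving family state
new_family <- function(id, cfg) {
  ulen <- sample_range(cfg$ancestral_unit_length_range[1],
                       cfg$ancestral_unit_length_range[2])
  cycles <- sample_range(cfg$duplication_cycles_range[1],
                         cfg$duplication_cycles_range[2])
  built <- evolve_duplication_divergence(random_dna(ulen), cycles,
                                         cfg$cycle_divergence,
                                         indel_ratio = cfg$indel_ratio)
  list(ancestral_id = id,
       sequence = built$sequence,
       record = built$record,
       abundance = exp(runif(1, log(cfg$abundance_range[1]),
                             log(cfg$abundance_range[2]))),
       silenced = FALSE)
}

#' Evolve a satellite library along a species tree
#'
#' Creates `n_ancestral_families` at the root and walks every branch:
#' substitutions accumulate in each family proportionally to branch
#' length, amplification multipliers resample (log-normal, variance
#' proportional to branch length -- differential amplification under the
#' library hypothesis), and families may be silenced.  Each leaf receives
#' a catalog named by decreasing true abundance.
#'
#' @param cfg A [sim_config()].
#' @return A list with `catalogs` (named list of [catalog()]s),
#'   `truth` (data frame: `species`, `name` (`NA` for families lost from
#'   the catalog), `ancestral_id`, `abundance`, `present`, `silenced`,
#'   `clustered_fraction`, `array_divergence`) and `tree` (the
#'   `ape::phylo` object).  Families whose abundance walk fell below the
#'   detectability floor (the low end of `abundance_range`) are absent
#'   from the catalog but recorded in the truth.
#' @export
simulate_library_evolution <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = cfg$tree)),
                 error = function(e) NULL)
  if (is.null(tr) || is.null(tr$edge.length)) {
    stop("malformed newick tree: ", cfg$tree, call. = FALSE)
  }
  total_height <- max(ape::node.depth.edgelength(tr))
  if (total_height <= 0) total_height <- 1
  with_seed(cfg$seed, {
    ## distinct ancestral families must be mutually unrelated (the library
    ## hypothesis starts from independent families); coincidental
    ## similarity between two short random ancestors would propagate to
    ## every descendant pair, so redraw until families are dissimilar
    root_lib <- list()
    for (id in seq_len(cfg$n_ancestral_families)) {
      for (try in 1:50) {
        fam <- new_family(id, cfg)
        ok <- all(vapply(root_lib, function(ex) {
          sim <- monomer_similarity(ex$sequence, fam$sequence)
          sim$similarity < 40 ||
            !similarity_is_credible(sim, min_score = 12, max_evalue = 1e-2,
                                    max_gap_fraction = 0.05)
        }, logical(1)))
        if (ok) break
      }
      root_lib[[id]] <- fam
    }
    tr <- stats::reorder(tr, "cladewise")  # parents before children
    ntip <- ape::Ntip(tr)
    root <- ntip + 1L
    states <- list()
    states[[as.character(root)]] <- root_lib
    catalogs <- list()
    truth_rows <- list()
    for (ei in seq_len(nrow(tr$edge))) {
      from <- tr$edge[ei, 1]
      to <- tr$edge[ei, 2]
      len <- tr$edge.length[ei]
      lib <- states[[as.character(from)]]
      rel <- len / total_height
      lib <- lapply(lib, function(fam) {
        fam$sequence <- mutate_seq(fam$sequence, cfg$subst_rate * len,
                                   cfg$indel_ratio)
        fam$abundance <- fam$abundance *
          exp(rnorm(1, 0, cfg$amplification_sdlog * sqrt(rel)))
        if (!fam$silenced && runif(1) < cfg$silencing_prob) {
          fam$silenced <- TRUE
          fam$abundance <- fam$abundance * 0.05
        }
        fam
      })
      states[[as.character(to)]] <- lib
      if (to <= ntip) {
        sp <- tr$tip.label[to]
        ab_raw <- vapply(lib, `[[`, numeric(1), "abundance")
        ## a family whose amplification walk fell below the detectability
        ## floor is absent from this species' catalog (tandem-repeat
        ## discovery only sees sufficiently abundant families); every
        ## catalog keeps at least its three most abundant families
        present <- ab_raw >= cfg$abundance_range[1]
        if (sum(present) < 3) {
          present[order(-ab_raw)[seq_len(min(3, length(ab_raw)))]] <- TRUE
        }
        libp <- lib[present]
        ab <- pmin(ab_raw[present], cfg$abundance_range[2])
        fams <- data.frame(
          sequence = vapply(libp, `[[`, character(1), "sequence"),
          abundance = ab, stringsAsFactors = FALSE)
        cat_sp <- name_families(fams, sp)
        ## map named members back to ancestral ids via the sort order
        ord <- order(-fams$abundance, rep(0, nrow(fams)), fams$sequence)
        cf <- if (is.null(cfg$clustered_fraction))
          runif(nrow(fams), 0.5, 1) else
            rep(cfg$clustered_fraction, nrow(fams))
        tr_present <- data.frame(
          species = sp,
          name = names(cat_sp$members),
          ancestral_id = vapply(libp, `[[`, numeric(1), "ancestral_id")[ord],
          abundance = ab[ord],
          present = TRUE,
          silenced = vapply(libp, `[[`, logical(1), "silenced")[ord],
          clustered_fraction = cf,
          array_divergence = runif(nrow(fams),
                                   cfg$array_divergence_range[1],
                                   cfg$array_divergence_range[2]),
          stringsAsFactors = FALSE)
        if (any(!present)) {
          tr_lost <- data.frame(
            species = sp,
            name = NA_character_,
            ancestral_id = vapply(lib[!present], `[[`, numeric(1),
                                  "ancestral_id"),
            abundance = ab_raw[!present],
            present = FALSE,
            silenced = vapply(lib[!present], `[[`, logical(1), "silenced"),
            clustered_fraction = 0,
            array_divergence = NA_real_,
            stringsAsFactors = FALSE)
          tr_present <- rbind(tr_present, tr_lost)
        }
        truth_rows[[sp]] <- tr_present
        catalogs[[sp]] <- cat_sp
      }
    }
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    ## silenced families keep only scattered remnants
    truth$clustered_fraction[truth$silenced] <- 0
    list(catalogs = catalogs, truth = truth, tree = tr)
  })
}

#' Assemble a genome and paired-end reads for one species
#'
#' The genome is i.i.d. random background into which the generator plants,
#' at non-overlapping random positions: clustered tandem arrays (runs of
#' the family monomer, each copy independently diverged at the family's
#' array divergence), scattered short arrays for the remaining copies, and
#' `n_genes` unique single-copy genes.  Read pairs are sampled uniformly
#' (fragment length normal, substitution errors Bernoulli per base).  The
#' returned truth records the exact realized composition.
#'
#' @param cat A [catalog()] for one species.
#' @param truth The truth rows of [simulate_library_evolution()] for this
#'   species (columns `name`, `abundance`, `clustered_fraction`,
#'   `array_divergence`).
#' @param cfg A [sim_config()].
#' @param seed Optional integer; defaults to a species-specific value
#'   derived from `cfg$seed`.
#' @return A list with `genome` (DNA string), `reads` ([paired_reads()]),
#'   `genes` (named character vector), and `composition` (data frame:
#'   `component`, `nt`, `fraction`; families, genes and background sum to
#'   1).
#' @export
build_genome_and_reads <- function(cat, truth, cfg, seed = NULL) {
  stopifnot(inherits(cat, "sat_catalog"), inherits(cfg, "sim_config"))
  G <- as.integer(cfg$genome_length)
  if (G < cfg$insert_mean + 4 * cfg$insert_sd) {
    stop("genome shorter than the insert span", call. = FALSE)
  }
  if (is.null(seed)) {
    seed <- (cfg$seed + 7919L * utf8ToInt(substr(cat$species, 1, 1))) %%
      .Machine$integer.max
  }
  with_seed(seed, {
    rows <- truth[match(names(cat$members), truth$name), , drop = FALSE]
    blocks <- list()
    labels <- character()
    for (i in seq_along(cat$members)) {
      mon <- cat$members[[i]]$sequence
      rul <- nchar(mon)
      n_copies <- max(1L, round(rows$abundance[i] * G / rul))
      n_clust <- round(rows$clustered_fraction[i] * n_copies)
      d_arr <- rows$array_divergence[i]
      make_copies <- function(k) vapply(seq_len(k), function(j)
        mutate_seq(mon, d_arr, 0), character(1))
      left <- n_clust
      while (left > 0) {
        k <- min(left, sample_range(cfg$array_copy_range[1],
                                    cfg$array_copy_range[2]))
        blocks[[length(blocks) + 1]] <- paste(make_copies(k), collapse = "")
        labels <- c(labels, rows$name[i])
        left <- left - k
      }
      left <- n_copies - n_clust
      while (left > 0) {
        k <- min(left, sample_range(cfg$scattered_copy_range[1],
                                    cfg$scattered_copy_range[2]))
        blocks[[length(blocks) + 1]] <- paste(make_copies(k), collapse = "")
        labels <- c(labels, rows$name[i])
        left <- left - k
      }
    }
    genes <- setNames(vapply(seq_len(cfg$n_genes), function(i)
      random_dna(cfg$gene_length), character(1)),
      paste0("gene", seq_len(cfg$n_genes)))
    for (g in names(genes)) {
      blocks[[length(blocks) + 1]] <- genes[[g]]
      labels <- c(labels, g)
    }
    block_nt <- sum(nchar(unlist(blocks)))
    bg_total <- G - block_nt
    if (bg_total < length(blocks) + 1) {
      stop("genome_length too small for the requested satellite content",
           call. = FALSE)
    }
    ## random interleaving: background split into (n_blocks + 1) chunks
    ord <- sample(length(blocks))
    cuts <- sort(sample(0:bg_total, length(blocks), replace = TRUE))
    bg_sizes <- diff(c(0, cuts, bg_total))
    pieces <- character(2 * length(blocks) + 1)
    pieces[1] <- random_dna(bg_sizes[1])
    for (i in seq_along(ord)) {
      pieces[2 * i] <- blocks[[ord[i]]]
      pieces[2 * i + 1] <- random_dna(bg_sizes[i + 1])
    }
    genome <- paste(pieces, collapse = "")
    ## exact composition bookkeeping
    fam_nt <- vapply(names(cat$members), function(nmf)
      sum(nchar(unlist(blocks[labels == nmf]))), numeric(1))
    gene_nt <- sum(nchar(genes))
    comp <- data.frame(
      component = c(names(cat$members), "genes", "background"),
      nt = c(fam_nt, gene_nt, G - sum(fam_nt) - gene_nt))
    comp$fraction <- comp$nt / G
    ## paired-end reads
    n <- as.integer(cfg$n_pairs)
    rl <- cfg$read_length
    if (n > 0) {
      frag <- pmax(rl, round(rnorm(n, cfg$insert_mean, cfg$insert_sd)))
      frag <- pmin(frag, G)
      starts <- floor(runif(n, 0, G - frag + 1))
      r1 <- substring(genome, starts + 1, starts + rl)
      r2 <- as.character(Biostrings::reverseComplement(DNAStringSet(
        substring(genome, starts + frag - rl + 1, starts + frag))))
      if (cfg$error_rate > 0) {
        ## only the minority of reads carrying at least one error need a
        ## per-base pass
        for (rr in c("r1", "r2")) {
          v <- get(rr)
          n_err <- rbinom(n, rl, cfg$error_rate)
          for (i in which(n_err > 0)) {
            v[i] <- mutate_seq(v[i], n_err[i] / rl, 0)
          }
          assign(rr, v)
        }
      }
      reads <- paired_reads(r1, r2, insert_mean = cfg$insert_mean,
                            insert_sd = cfg$insert_sd,
                            source_label = paste0("sim:", cat$species))
    } else {
      reads <- paired_reads(DNAStringSet(), DNAStringSet(),
                            insert_mean = cfg$insert_mean,
                            insert_sd = cfg$insert_sd,
                            source_label = paste0("sim:", cat$species))
    }
    list(genome = genome, reads = reads, genes = genes, composition = comp)
  })
}
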