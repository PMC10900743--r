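## Orchestration, summary tables and the packaged Alligatoridae reference
## table.

#' Packaged Alligatoridae satellitome summary table
#'
#' The published per-family summary of the five Alligatoridae
#' satellitomes (39 satDNA families): species, intraspecific superfamily,
#' name, repeat unit length, A+T content, genomic abundance, Kimura
#' divergence, Tandem Structure Index and interspecific similarity group.
#' Two families carry TSI values that differ between the source's table
#' and running text; the table values are kept and the discrepancy is
#' noted in the file header.
#'
#' @return A data frame with columns `species`, `sf`, `name`, `rul`,
#'   `at_percent`, `abundance_percent`, `divergence_percent`, `tsi`,
#'   `group` (`sf` and `group` are `NA` where the source leaves them
#'   blank).
#' @export
alligatoridae_satellites <- function() {
  path <- system.file("extdata", "alligatoridae_satellitome.tsv",
                      package = "satellitome", mustWork = TRUE)
  df <- read_tsv(path)
  df$sf <- suppressWarnings(as.integer(df$sf))
  df$group <- suppressWarnings(as.integer(df$group))
  df
}

#' Summarize a quantified satellitome table
#'
#' Collapses a per-family table (the schema of
#' [alligatoridae_satellites()]) into the headline aggregates of a
#' comparative satellitome study: family counts, repeat-unit-length range,
#' mean A+T content, and per-group sizes and species spans.
#'
#' @param x Data frame with columns `species`, `sf`, `name`, `rul`,
#'   `at_percent`, `abundance_percent`, `divergence_percent`, `tsi`,
#'   `group`.
#' @param allow_incomplete Tolerate `NA` abundance/TSI columns (degraded
#'   catalogs-only runs); otherwise an `NA` quantification is an error
#'   naming the family.
#' @return An object of class `sat_summary`: a list with `table` (the
#'   input, row order normalized), and aggregates `n_families_total`,
#'   `n_families_per_species` (named), `rul_range`, `mean_at_percent`,
#'   `group_sizes` (named by group id), `group_species_span`,
#'   `n_groups`, `n_ungrouped`, `superfamilies_per_species`.
#' @export
summarize_catalogs <- function(x, allow_incomplete = FALSE) {
  req <- c("species", "sf", "name", "rul", "at_percent",
           "abundance_percent", "divergence_percent", "tsi", "group")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(x) == 0) {
    return(structure(list(table = x, n_families_total = 0L,
                          n_families_per_species = integer(),
                          rul_range = c(NA_integer_, NA_integer_),
                          mean_at_percent = NA_real_,
                          group_sizes = integer(),
                          group_species_span = integer(),
                          n_groups = 0L, n_ungrouped = 0L,
                          superfamilies_per_species = integer()),
                     class = "sat_summary"))
  }
  if (anyDuplicated(x$name)) {
    stop("duplicate family name: ", x$name[duplicated(x$name)][1],
         call. = FALSE)
  }
  suffix <- as.integer(sub(".*-", "", x$name))
  if (any(suffix != x$rul)) {
    stop("rul disagrees with name suffix for ",
         x$name[which(suffix != x$rul)[1]], call. = FALSE)
  }
  if (!allow_incomplete) {
    ## an NA TSI is a computed "undefined" (no mapped mates) and is kept;
    ## an NA abundance means the family was never quantified
    bad <- x$name[is.na(x$abundance_percent)]
    if (length(bad)) {
      stop("missing quantification for family ", bad[1], call. = FALSE)
    }
  }
  x <- x[order(x$species, x$name), , drop = FALSE]
  per_sp <- table(x$species)
  grp <- x$group[!is.na(x$group)]
  gsz <- sort(table(grp), decreasing = TRUE)
  span <- tapply(x$species[!is.na(x$group)], x$group[!is.na(x$group)],
                 function(s) length(unique(s)))
  sf_per_sp <- vapply(split(x$sf, x$species), function(s)
    length(unique(s[!is.na(s)])), integer(1))
  structure(list(
    table = x,
    n_families_total = nrow(x),
    n_families_per_species = setNames(as.integer(per_sp), names(per_sp)),
    rul_range = range(x$rul),
    mean_at_percent = mean(x$at_percent),
    group_sizes = setNames(as.integer(gsz), names(gsz)),
    group_species_span = setNames(as.integer(span), names(span)),
    n_groups = length(unique(grp)),
    n_ungrouped = sum(is.na(x$group)),
    superfamilies_per_species = sf_per_sp
  ), class = "sat_summary")
}

#' @export
print.sat_summary <- function(x, ...) {
  cat("sat_summary:", x$n_families_total, "families in",
      length(x$n_families_per_species), "species\n")
  cat("  per species:", paste(names(x$n_families_per_species),
                              x$n_families_per_species, collapse = ", "),
      "\n")
  cat("  RUL range:", paste(x$rul_range, collapse = "-"),
      " mean A+T:", sprintf("%.1f%%", x$mean_at_percent), "\n")
  cat("  groups:", x$n_groups, " sizes:",
      paste(x$group_sizes, collapse = "/"),
      " ungrouped:", x$n_ungrouped, "\n")
  invisible(x)
}

## assemble the per-family summary table from pipeline stage outputs
assemble_summary_table <- function(catalogs, tiers, groups, abundances,
                                   tsis, divergences) {
  rows <- lapply(names(catalogs), function(sp) {
    cat <- catalogs[[sp]]
    nm <- names(cat$members)
    tier <- tiers[[sp]]
    data.frame(
      species = sp,
      sf = tier$superfamily[match(nm, tier$name)],
      name = nm,
      rul = vapply(cat$members, `[[`, integer(1), "rul"),
      at_percent = round(100 * vapply(cat$members, `[[`, numeric(1),
                                      "at_fraction"), 1),
      abundance_percent = if (is.null(abundances)) NA_real_ else
        100 * abundances[[sp]]$abundance_fraction[
          match(nm, abundances[[sp]]$family)],
      divergence_percent = if (is.null(divergences)) NA_real_ else
        divergences[[sp]][nm],
      tsi = if (is.null(tsis)) NA_real_ else
        tsis[[sp]]$tsi[match(nm, tsis[[sp]]$family)],
      group = groups$group[match(nm, groups$name)],
      stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Run the full comparative satellitome pipeline
#'
#' Orchestrates simulate (optional) -> classify -> quantify ->
#' substructure -> summarize and writes every table as TSV together with
#' a run manifest (parameters, seed, input checksums, stage timings).
#' Re-running with identical inputs reproduces identical outputs.
#'
#' With `catalogs` but no reads (`reads_available = FALSE` mode), the
#' abundance, divergence-landscape and TSI columns are reported
#' unavailable (`NA`) while classification and substructure still run.
#'
#' @param config A [sim_config()] used to simulate inputs when `catalogs`
#'   is `NULL` (its seed drives everything); ignored for user-supplied
#'   catalogs except for masking parameters.
#' @param catalogs Optional named list of [catalog()]s (one per species).
#' @param reads Optional named list of [paired_reads()] aligned with
#'   `catalogs`.
#' @param genes Optional named list of single-copy gene vectors per
#'   species (required for normalization when reads are supplied).
#' @param outdir Output directory (created if needed).
#' @param max_divergence Masking divergence cutoff in percent.
#' @return Invisibly, a list with `summary` (a [summarize_catalogs()]
#'   result), `classification`, `groups`, `abundances`, `tsi`,
#'   `normalized`, `clustermap`, `substructure`, `truth` (simulation mode
#'   only) and `manifest`.
#' @export
run_full_pipeline <- function(config = NULL, catalogs = NULL, reads = NULL,
                              genes = NULL, outdir = tempfile("satrun"),
                              max_divergence = 20) {
  t_start <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (is.null(catalogs)) {
    if (is.null(config)) stop("either config or catalogs must be given",
                              call. = FALSE)
    sim <- stage("simulate", simulate_library_evolution(config))
    catalogs <- sim$catalogs
    truth <- sim$truth
    reads <- list()
    genes <- list()
    for (sp in names(catalogs)) {
      g <- stage("simulate",
                 build_genome_and_reads(catalogs[[sp]],
                                        truth[truth$species == sp, ],
                                        config))
      reads[[sp]] <- g$reads
      genes[[sp]] <- g$genes
    }
  }
  ## --- classify
  tiers <- stage("classify",
                 lapply(catalogs, classify_intraspecific))
  groups <- stage("classify", assign_groups(catalogs))
  ## --- quantify
  abundances <- tsis <- normalized <- cmap <- divergences <- NULL
  if (!is.null(reads) && length(reads) &&
      all(vapply(reads, length, integer(1)) > 0)) {
    union_members <- unlist(lapply(catalogs, function(x) x$members),
                            recursive = FALSE, use.names = FALSE)
    abundances <- list()
    tsis <- list()
    divergences <- list()
    for (sp in names(catalogs)) {
      ab <- stage("quantify", mask_reads(reads[[sp]], catalogs[[sp]],
                                         max_divergence = max_divergence))
      abundances[[sp]] <- ab
      profs <- attr(ab, "profiles")
      divergences[[sp]] <- vapply(names(profs), function(f) {
        p <- profs[[f]]
        if (sum(p$masked_nt) == 0) NA_real_ else
          sum((p$bin_percent + 0.5) * p$masked_nt) / sum(p$masked_nt)
      }, numeric(1))
      tsis[[sp]] <- stage("quantify",
                          compute_tsi(reads[[sp]], catalogs[[sp]],
                                      max_divergence = max_divergence))
    }
    ## species x union-of-families masked-count matrix for normalization
    all_names <- unlist(lapply(catalogs, function(x) names(x$members)),
                        use.names = FALSE)
    union_cat <- catalog_union(catalogs)
    counts <- matrix(0, nrow = length(catalogs), ncol = length(all_names),
                     dimnames = list(names(catalogs), all_names))
    gene_mat <- NULL
    if (!is.null(genes) && length(genes)) {
      gene_names <- names(genes[[1]])
      gene_mat <- matrix(0, nrow = length(catalogs),
                         ncol = length(gene_names),
                         dimnames = list(names(catalogs), gene_names))
    }
    for (sp in names(catalogs)) {
      abu <- stage("quantify", mask_reads(reads[[sp]], union_cat,
                                          max_divergence = max_divergence))
      counts[sp, abu$family] <- abu$masked_reads
      if (!is.null(gene_mat)) {
        gene_mat[sp, ] <- stage("normalize",
                                count_gene_hits(reads[[sp]], genes[[sp]]))
      }
    }
    if (!is.null(gene_mat)) {
      analyzed <- vapply(reads, function(r) 2L * length(r), integer(1))
      normalized <- stage("normalize", normalize_by_single_copy(
        counts, gene_mat,
        read_length = vapply(reads, `[[`, integer(1), "read_length"),
        gene_lengths = vapply(genes[[1]], nchar, integer(1)),
        analyzed_reads = analyzed))
      if (nrow(normalized) >= 2) {
        cmap <- stage("clustermap", clustermap_matrix(normalized))
      }
    }
  }
  ## --- substructure (monomers long enough to hold >= 2 repeats of the
  ## detected period)
  substructure <- stage("substructure", lapply(catalogs, function(cat) {
    out <- list()
    for (m in cat$members) {
      if (m$rul < 40) next
      periods <- detect_period(m$sequence)
      periods <- periods[periods <= m$rul / 2]
      if (!length(periods)) next
      out[[m$name]] <- decompose_subunits(m, periods[1])
    }
    out
  }))
  ## --- summarize
  summary_tab <- stage("summarize", assemble_summary_table(
    catalogs, tiers, groups, abundances, tsis, divergences))
  summ <- stage("summarize",
                summarize_catalogs(summary_tab,
                                   allow_incomplete = is.null(abundances)))
  ## --- write reports
  write_tsv(summary_tab, file.path(outdir, "summary.tsv"))
  write_classification(groups, file.path(outdir, "groups.tsv"),
                       file.path(outdir, "group_edges.tsv"))
  for (sp in names(tiers)) {
    write_tsv(as.data.frame(tiers[[sp]]),
              file.path(outdir, paste0("tiers_", sp, ".tsv")))
  }
  if (!is.null(abundances)) {
    for (sp in names(abundances)) {
      write_tsv(as.data.frame(abundances[[sp]]),
                file.path(outdir, paste0("abundance_", sp, ".tsv")))
      write_divergence_landscape(attr(abundances[[sp]], "profiles"),
                                 file.path(outdir,
                                           paste0("landscape_", sp, ".tsv")))
      write_tsv(as.data.frame(tsis[[sp]]),
                file.path(outdir, paste0("tsi_", sp, ".tsv")))
    }
  }
  if (!is.null(normalized)) {
    nm <- data.frame(species = rownames(normalized),
                     as.data.frame(unclass(normalized)),
                     check.names = FALSE)
    write_tsv(nm, file.path(outdir, "normalized_matrix.tsv"))
  }
  if (!is.null(cmap)) {
    writeLines(c(paste0("row_order\t", paste(cmap$row_order, collapse = ",")),
                 paste0("col_order\t", paste(cmap$col_order, collapse = ",")),
                 paste0("row_dendrogram\t", cmap$row_dendrogram %||% ""),
                 paste0("col_dendrogram\t", cmap$col_dendrogram %||% "")),
               file.path(outdir, "clustermap.tsv"))
  }
  if (!is.null(truth)) write_tsv(truth, file.path(outdir, "truth.tsv"))
  ## manifest: versions, seed, parameters, checksums of written outputs
  outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = as.character(utils::packageVersion("satellitome")),
    seed = if (!is.null(config)) config$seed else NA_integer_,
    parameters = list(max_divergence = max_divergence),
    species = names(catalogs),
    n_families = vapply(catalogs, length, integer(1)),
    outputs = setNames(as.list(unname(tools::md5sum(
      file.path(outdir, outputs)))), outputs),
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summ, classification = tiers, groups = groups,
                 abundances = abundances, tsi = tsis,
                 normalized = normalized, clustermap = cmap,
                 substructure = substructure, truth = truth,
                 manifest = manifest, outdir = outdir))
}

## merge per-species catalogs into one pseudo-catalog holding every
## monomer (used to build the species x union-of-families count matrix)
catalog_union <- function(catalogs) {
  members <- unlist(lapply(catalogs, function(x) x$members),
                    recursive = FALSE, use.names = FALSE)
  ## order by decreasing per-species abundance rank so masking tie-breaks
  ## stay abundance-like
  nn <- vapply(members, function(m)
    as.integer(sub("^[A-Za-z]{3}Sat([0-9]+)-.*$", "\\1", m$name)),
    integer(1))
  members <- members[order(nn)]
  out <- list(species = "ALL", members = members)
  names(out$members) <- vapply(members, `[[`, character(1), "name")
  class(out) <- "sat_catalog"
  out
}
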