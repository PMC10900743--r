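## Similarity-tier classification.
##
## Tiers follow the standard satellitome convention: monomers >= 95%
## similar are the same sequence variant, >= 80% are variants of one
## satDNA, and >= 50% within a species share a superfamily; interspecific
## links >= 50% define cross-species groups.  Components are single-linkage
## (connected components of the thresholded homology graph), which makes
## the tiers nest by construction.

## connected components of an undirected edge list over `nodes`;
## returns integer membership vector named by node
component_membership <- function(nodes, from, to) {
  if (length(from) == 0) {
    return(setNames(seq_along(nodes), nodes))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::components(g)$membership[nodes]
}

## All-pairs similarity edge list for a set of named sequences.  Edges
## must both clear the similarity floor and be unachievable by chance
## (see similarity_is_credible): without the gates, monomers a few dozen
## nt long reach the 50% tier against unrelated sequence through
## best-window selection alone.
##
## Pairs are batched by subject: every monomer in turn serves as the
## doubled subject for all monomers at least as long as itself, one
## vectorized alignment per strand, which preserves the exact per-pair
## semantics of monomer_similarity (subject = shorter monomer, ties keep
## the earlier node) at a fraction of the per-pair call overhead.
similarity_edges <- function(seqs, min_similarity = 0, max_evalue = 5e-4) {
  seqs <- vapply(seqs, as_sequence, character(1))
  nm <- names(seqs)
  n <- length(seqs)
  empty <- data.frame(a = character(), b = character(),
                      similarity = numeric(), strand = character(),
                      rotation_offset = integer())
  if (n < 2) return(empty)
  lens <- nchar(seqs)
  has_n <- grepl("N", seqs, fixed = TRUE)
  rows <- list()
  k <- 0L
  emit <- function(i, j, sim) {
    if (sim$similarity >= min_similarity &&
        similarity_is_credible(sim, max_evalue = max_evalue)) {
      k <<- k + 1L
      rows[[k]] <<- data.frame(
        a = nm[i], b = nm[j], similarity = sim$similarity,
        strand = sim$strand, rotation_offset = sim$rotation_offset,
        stringsAsFactors = FALSE)
    }
  }
  for (s in seq_len(n)) {
    ## partners for which monomer s is the subject under the tie rule
    partners <- which(lens > lens[s] | (lens == lens[s] & seq_len(n) > s))
    partners <- partners[partners != s]
    if (!length(partners)) next
    if (has_n[s] || any(has_n[partners])) {
      ## rare N-containing monomers keep the careful per-pair path
      for (t in partners) {
        pair <- sort(c(s, t))
        emit(pair[1], pair[2], monomer_similarity(seqs[[s]], seqs[[t]]))
      }
      next
    }
    L <- lens[s]
    doubled <- DNAString(paste0(seqs[[s]], seqs[[s]]))
    pats <- DNAStringSet(seqs[partners])
    stats <- vector("list", 2)
    for (st in 1:2) {
      pat <- if (st == 1) pats else Biostrings::reverseComplement(pats)
      aln <- pairwiseAlignment(pat, doubled, type = "local",
                               substitutionMatrix = sat_submat(),
                               gapOpening = GAP_OPEN,
                               gapExtension = GAP_EXT)
      ni <- Biostrings::nindel(aln)
      stats[[st]] <- data.frame(
        matches = nmatch(aln), mismatches = nmismatch(aln),
        gapw = Biostrings::insertion(ni)[, "WidthSum"] +
          Biostrings::deletion(ni)[, "WidthSum"],
        score = score(aln),
        s_start = start(subject(aln)), s_end = end(subject(aln)))
    }
    for (idx in seq_along(partners)) {
      t <- partners[idx]
      best <- list(similarity = 0, strand = "+", rotation_offset = 0L,
                   matches = 0L, shorter_length = L,
                   longer_length = lens[t], score = 0, gap_fraction = 0,
                   aligned_columns = 0L)
      for (st in 1:2) {
        x <- stats[[st]][idx, ]
        span <- min(x$s_end - x$s_start + 1L, L)
        if (span < 0.5 * L) next
        cols <- x$matches + x$mismatches + x$gapw
        sim_pct <- 100 * x$matches / max(cols, L)
        if (sim_pct > best$similarity) {
          best <- list(similarity = sim_pct,
                       strand = if (st == 1) "+" else "-",
                       rotation_offset = as.integer((x$s_start - 1L) %% L),
                       matches = x$matches, shorter_length = L,
                       longer_length = lens[t], score = x$score,
                       gap_fraction = if (cols > 0)
                         (cols - x$matches - x$mismatches) / cols else 0,
                       aligned_columns = as.integer(cols))
        }
      }
      pair <- sort(c(s, t))
      emit(pair[1], pair[2], best)
    }
  }
  if (k == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$a, out$b), , drop = FALSE]
}

## renumber component ids deterministically: by increasing catalog position
## of their first member (i.e. most abundant member first)
renumber_by_first <- function(membership) {
  first <- tapply(seq_along(membership), membership, min)
  rank <- setNames(rank(first, ties.method = "first"), names(first))
  as.integer(rank[as.character(membership)])
}

#' Intraspecific similarity tiers of one catalog
#'
#' Classifies the monomers of one species into nested similarity tiers:
#' same sequence variant (>= 95% similarity), variant of one satDNA
#' (>= 80%), and superfamily (>= 50%).  Components are single-linkage, so a
#' 95% component always lies inside an 80% component inside a 50%
#' component.  Superfamilies with a single member are reported as `NA`
#' (the field convention leaves the SF column blank for singletons).
#'
#' @param cat A [catalog()].
#' @param thresholds Named numeric vector with entries `same_variant`,
#'   `variant`, `superfamily` (percent similarities).
#' @return An object of class `tier_classification`: a data frame with
#'   columns `name`, `species`, `same_variant_id`, `variant_id`,
#'   `superfamily` (NA for singletons), `variant_of` (name of the most
#'   abundant member of the monomer's variant cluster); attribute `edges`
#'   holds the similarity edge list.
#' @export
classify_intraspecific <- function(cat,
                                   thresholds = c(same_variant = 95,
                                                  variant = 80,
                                                  superfamily = 50)) {
  stopifnot(inherits(cat, "sat_catalog"), length(cat) >= 1)
  seqs <- catalog_sequences(cat)
  nm <- names(seqs)
  edges <- similarity_edges(seqs, min_similarity = 0)
  tier <- function(th) {
    keep <- edges$similarity >= th
    component_membership(nm, edges$a[keep], edges$b[keep])
  }
  sv <- renumber_by_first(tier(thresholds[["same_variant"]]))
  va <- renumber_by_first(tier(thresholds[["variant"]]))
  sf_raw <- tier(thresholds[["superfamily"]])
  sf <- renumber_by_first(sf_raw)
  ## singleton superfamilies are blank by convention
  sizes <- table(sf)
  sf_out <- ifelse(sizes[as.character(sf)] > 1, sf, NA_integer_)
  ## renumber the surviving superfamilies compactly
  if (any(!is.na(sf_out))) {
    remap <- setNames(seq_along(sort(unique(sf_out[!is.na(sf_out)]))),
                      sort(unique(sf_out[!is.na(sf_out)])))
    sf_out <- ifelse(is.na(sf_out), NA_integer_,
                     as.integer(remap[as.character(sf_out)]))
  }
  variant_of <- vapply(seq_along(nm), function(i) nm[which(va == va[i])[1]],
                       character(1))
  structure(
    data.frame(name = nm, species = cat$species,
               same_variant_id = sv, variant_id = va,
               superfamily = as.integer(sf_out), variant_of = variant_of,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("tier_classification", "data.frame"),
    edges = edges)
}

#' Cross-species satellite DNA groups
#'
#' Builds the interspecific homology graph: edges connect monomers of
#' different species with similarity at or above `threshold` (default 50%).
#' Connected components are groups, numbered by decreasing member count
#' (ties: wider species span, then smallest member name); a group is
#' flagged `is_main` when it spans at least `main_span` species.  Monomers
#' with no qualifying interspecific edge are "ungrouped" (`NA`).
#'
#' @param catalogs List of [catalog()]s (>= 2 species).
#' @param threshold Minimum percent similarity for an edge (default 50).
#' @param main_span Species span required for the `is_main` flag
#'   (default 4).
#' @return An object of class `group_assignment`: a data frame with columns
#'   `name`, `species`, `group` (integer or NA), `is_main`; attributes
#'   `groups` (summary: `group`, `n_members`, `species_span`, `is_main`)
#'   and `edges` (interspecific edge list with similarity, strand, offset).
#' @export
assign_groups <- function(catalogs, threshold = 50, main_span = 4) {
  stopifnot(length(catalogs) >= 2)
  seqs <- list()
  species <- character()
  for (cat in catalogs) {
    stopifnot(inherits(cat, "sat_catalog"))
    s <- catalog_sequences(cat)
    seqs <- c(seqs, as.list(s))
    species <- c(species, rep(cat$species, length(s)))
    names(seqs)[(length(seqs) - length(s) + 1):length(seqs)] <- names(s)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate monomer names across catalogs", call. = FALSE)
  }
  species <- setNames(species, names(seqs))
  ## deterministic node order regardless of catalog input order
  ord <- order(names(seqs))
  seqs <- seqs[ord]
  species <- species[ord]
  nm <- names(seqs)
  edges <- similarity_edges(seqs, min_similarity = threshold)
  inter <- edges[species[edges$a] != species[edges$b], , drop = FALSE]
  membership <- component_membership(nm, inter$a, inter$b)
  ## groups = components holding at least one interspecific edge
  linked <- unique(c(inter$a, inter$b))
  comp_ids <- unique(membership[linked])
  info <- lapply(comp_ids, function(cid) {
    mem <- nm[membership == cid]
    data.frame(comp = cid, n_members = length(mem),
               species_span = length(unique(species[mem])),
               first = min(mem), stringsAsFactors = FALSE)
  })
  assignment <- rep(NA_integer_, length(nm))
  groups <- data.frame(group = integer(), n_members = integer(),
                       species_span = integer(), is_main = logical())
  if (length(info)) {
    info <- do.call(rbind, info)
    info <- info[order(-info$n_members, -info$species_span, info$first), ,
                 drop = FALSE]
    info$group <- seq_len(nrow(info))
    for (r in seq_len(nrow(info))) {
      assignment[membership == info$comp[r]] <- info$group[r]
    }
    groups <- data.frame(group = info$group, n_members = info$n_members,
                         species_span = info$species_span,
                         is_main = info$species_span >= main_span,
                         row.names = NULL)
  }
  structure(
    data.frame(name = nm, species = unname(species),
               group = assignment,
               is_main = !is.na(assignment) &
                 assignment %in% groups$group[groups$is_main],
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("group_assignment", "data.frame"),
    groups = groups, edges = inter)
}

#' Name satellite DNA families by decreasing abundance
#'
#' Applies the `<Sp>Sat<NN>-<RUL>` naming convention: families are ranked
#' by decreasing genomic abundance (ties: lower divergence, then
#' lexicographic consensus sequence) and numbered `01..n`.
#'
#' @param families Data frame with columns `sequence` and `abundance`
#'   (fraction or percent, any consistent scale) and optionally
#'   `divergence`.
#' @param species_code 3-letter species code.
#' @return A [catalog()] whose member order and names encode the abundance
#'   ranks.  The true abundances are attached as attribute `abundance`
#'   (named by monomer).
#' @export
name_families <- function(families, species_code) {
  stopifnot(is.data.frame(families), nrow(families) >= 1,
            all(c("sequence", "abundance") %in% names(families)))
  div <- families$divergence %||% rep(0, nrow(families))
  ord <- order(-families$abundance, div, families$sequence)
  families <- families[ord, , drop = FALSE]
  nm <- sprintf("%sSat%02d-%d", species_code, seq_len(nrow(families)),
                nchar(families$sequence))
  if (anyDuplicated(nm)) stop("naming collision: ", nm[duplicated(nm)][1],
                              call. = FALSE)
  members <- lapply(seq_along(nm), function(i)
    monomer_record(nm[i], families$sequence[i]))
  out <- catalog(members, species_code)
  attr(out, "abundance") <- setNames(families$abundance, nm)
  out
}

#' Write a tier/group classification as TSV
#'
#' @param classification A `tier_classification` or `group_assignment`.
#' @param path Output path for the per-monomer table.
#' @param edges_path Optional path for the edge list.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path, edges_path = NULL) {
  write_tsv(as.data.frame(classification), path)
  if (!is.null(edges_path)) write_tsv(attr(classification, "edges"), edges_path)
  invisible(path)
}
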