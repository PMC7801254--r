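#' Species-level clustering of a genome collection
#'
#' Two-stage clustering at the 95\% ANI species boundary. Stage one groups
#' genomes by single-linkage on Mash distance at \code{primary_distance}
#' (a recall-oriented pre-filter; it only needs to avoid splitting true
#' species across groups). Stage two clusters each primary group
#' greedily: genomes are ranked by representative score with isolates
#' always above MAGs; the highest-ranked unassigned genome seeds a
#' cluster, and every unassigned genome with ANI >= \code{ani_threshold}
#' and alignment fraction >= \code{af_threshold} to the seed joins it.
#' The seed is the cluster representative. With more genomes than
#' \code{chunk_size}, genomes are shuffled (seeded), chunks are clustered
#' independently, the chunk representatives are pooled and re-clustered,
#' and every non-representative genome follows its chunk representative
#' into the final cluster.
#'
#' @param gs A \code{\link{GenomeSet}} with sequences; all genomes must
#'   pass the quality filter.
#' @param sketches Optional precomputed sketches from
#'   \code{\link{sketchCollection}}.
#' @param primary_distance Mash distance cut for stage one (default 0.10).
#' @param ani_threshold ANI percentage for cluster membership (default 95).
#' @param af_threshold Alignment fraction for membership (default 0.30).
#' @param chunk_size Maximum genomes clustered in one pass
#'   (default Inf = single pass).
#' @param seed RNG seed for the chunk shuffle (default 1).
#' @param fragment_len Fragment length for ANI estimation (default 1000).
#' @return A \code{\link{SpeciesClusterSet}}.
#' @export
clusterSpecies <- function(gs, sketches = NULL, primary_distance = 0.10,
                           ani_threshold = 95, af_threshold = 0.30,
                           chunk_size = Inf, seed = 1, fragment_len = 1000) {
  ids <- genomeIds(gs)
  if (length(ids) == 0)
    return(.make_cluster_set(list()))
  if (!all(passesQualityFilter(gs)))
    stop("all genomes must pass the quality filter before clustering")
  if (is.null(sketches)) sketches <- sketchCollection(gs)
  rank_tab <- .genome_ranks(gs)

  if (length(ids) > chunk_size) {
    set.seed(seed)
    shuffled <- sample(ids)
    chunks <- split(shuffled, ceiling(seq_along(shuffled) / chunk_size))
    chunk_rep_of <- character(0)   # genome -> its chunk representative
    for (ch in chunks) {
      cl <- .cluster_once(ch, gs, sketches, rank_tab, primary_distance,
                          ani_threshold, af_threshold, fragment_len)
      for (grp in cl)
        chunk_rep_of[grp$members] <- grp$representative
    }
    pool <- unique(unname(chunk_rep_of))
    final <- .cluster_once(pool, gs, sketches, rank_tab, primary_distance,
                           ani_threshold, af_threshold, fragment_len)
    # members follow their chunk representative into its final cluster
    clusters <- lapply(final, function(grp) {
      mem <- names(chunk_rep_of)[chunk_rep_of %in% grp$members]
      list(representative = grp$representative, members = sort(mem))
    })
  } else {
    clusters <- .cluster_once(ids, gs, sketches, rank_tab, primary_distance,
                              ani_threshold, af_threshold, fragment_len)
  }
  .make_cluster_set(clusters)
}

# rank genomes: isolates above MAGs, then representative score, ties by id
.genome_ranks <- function(gs) {
  md <- genomeMeta(gs)
  score <- representativeScore(md$completeness, md$contamination, md$n50)
  data.frame(genome_id = md$genome_id,
             isolate = md$genome_type == "isolate",
             score = score, stringsAsFactors = FALSE)
}

.order_by_rank <- function(ids, rank_tab) {
  r <- rank_tab[match(ids, rank_tab$genome_id), ]
  ids[order(-r$isolate, -r$score, r$genome_id)]
}

.cluster_once <- function(ids, gs, sketches, rank_tab, primary_distance,
                          ani_threshold, af_threshold, fragment_len) {
  if (length(ids) == 1)
    return(list(list(representative = ids, members = ids)))
  d <- mashDistanceMatrix(sketches[ids])
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  grp <- stats::cutree(hc, h = primary_distance)
  clusters <- list()
  for (g in sort(unique(grp))) {
    gids <- .order_by_rank(ids[grp == g], rank_tab)
    unassigned <- gids
    while (length(unassigned)) {
      seed_id <- unassigned[1]
      unassigned <- unassigned[-1]
      members <- seed_id
      if (length(unassigned)) {
        joined <- vapply(unassigned, function(x) {
          r <- aniAf(gs, gs, query_id = x, target_id = seed_id,
                     fragment_len = fragment_len)
          !is.na(r$ani) && r$ani >= ani_threshold && r$af >= af_threshold
        }, logical(1))
        members <- c(members, unassigned[joined])
        unassigned <- unassigned[!joined]
      }
      clusters[[length(clusters) + 1L]] <-
        list(representative = seed_id, members = sort(members))
    }
  }
  clusters
}

.make_cluster_set <- function(clusters) {
  if (!length(clusters)) {
    return(new("SpeciesClusterSet",
               members = S4Vectors::DataFrame(genome_id = character(0),
                                              species_id = character(0)),
               species = S4Vectors::DataFrame(species_id = character(0),
                                              representative_id = character(0),
                                              n_members = integer(0),
                                              n_nonredundant = integer(0),
                                              cultured_status = character(0)),
               nonredundant = list()))
  }
  reps <- vapply(clusters, `[[`, character(1), "representative")
  clusters <- clusters[order(reps)]
  reps <- sort(reps)
  sp_ids <- sprintf("SPECIES%04d", seq_along(clusters))
  members <- do.call(rbind, lapply(seq_along(clusters), function(i)
    data.frame(genome_id = clusters[[i]]$members, species_id = sp_ids[i],
               stringsAsFactors = FALSE)))
  species <- data.frame(species_id = sp_ids, representative_id = reps,
                        n_members = vapply(clusters, function(x)
                          length(x$members), integer(1)),
                        n_nonredundant = NA_integer_,
                        cultured_status = NA_character_,
                        stringsAsFactors = FALSE)
  new("SpeciesClusterSet",
      members = S4Vectors::DataFrame(members),
      species = S4Vectors::DataFrame(species),
      nonredundant = list())
}

#' Dereplicate conspecific genomes and apply per-sample uniqueness
#'
#' Within each species cluster, members are visited in representative
#' score order (isolates first) and greedily collapsed: a genome whose
#' ANI to an already-kept genome is at least \code{ani_threshold} (99.9 by
#' default) is redundant. Afterwards at most one genome per sample is
#' retained (the best scored), so a species is counted once per sample.
#' The per-sample rule affects frequency counting and rarefaction input,
#' not catalog membership.
#'
#' @param gs The \code{\link{GenomeSet}}.
#' @param clusters A \code{\link{SpeciesClusterSet}}.
#' @param ani_threshold Dereplication ANI percentage (default 99.9).
#' @param fragment_len Fragment length for ANI estimation.
#' @return The \code{SpeciesClusterSet} with nonredundant member sets and
#'   \code{n_nonredundant} filled in.
#' @export
dereplicateConspecific <- function(gs, clusters, ani_threshold = 99.9,
                                   fragment_len = 1000) {
  rank_tab <- .genome_ranks(gs)
  md <- genomeMeta(gs)
  nonred <- list()
  sp <- as.data.frame(speciesTable(clusters))
  for (sid in sp$species_id) {
    mem <- .order_by_rank(clusterMembers(clusters, sid), rank_tab)
    kept <- character(0)
    for (g in mem) {
      redundant <- FALSE
      for (kg in kept) {
        r <- aniAf(gs, gs, query_id = g, target_id = kg,
                   fragment_len = fragment_len)
        if (!is.na(r$ani) && r$ani >= ani_threshold) {
          redundant <- TRUE; break
        }
      }
      if (!redundant) kept <- c(kept, g)
    }
    # one genome per sample: keep the first (best-ranked) per sample
    smp <- md$sample_id[match(kept, md$genome_id)]
    kept <- kept[!duplicated(smp)]
    nonred[[sid]] <- sort(kept)
  }
  sp$n_nonredundant <- vapply(nonred[sp$species_id], length, integer(1))
  new("SpeciesClusterSet", members = clusters@members,
      species = S4Vectors::DataFrame(sp), nonredundant = nonred)
}

#' Intraspecies dendrogram cluster counts
#'
#' Complete-linkage hierarchical clustering on pairwise Mash distances of
#' a species' members, cut at each distance cutoff (defaults 0.03, i.e.
#' 97\% ANI, and 0.01, i.e. 99\% ANI).
#'
#' @param gs The \code{\link{GenomeSet}} (or NULL when \code{sketches}
#'   given).
#' @param member_ids Genome ids of the species' members.
#' @param cutoffs Distance cutoffs (default c(0.03, 0.01)).
#' @param sketches Optional precomputed sketches.
#' @return List with \code{counts} (named by cutoff), \code{singleton}
#'   flag, and the \code{hclust} object (NULL for singletons).
#' @export
intraspeciesDendrogram <- function(gs, member_ids, cutoffs = c(0.03, 0.01),
                                   sketches = NULL) {
  if (length(member_ids) < 2)
    return(list(counts = stats::setNames(rep(1L, length(cutoffs)),
                                         as.character(cutoffs)),
                singleton = TRUE, hclust = NULL))
  if (is.null(sketches))
    sketches <- stats::setNames(lapply(member_ids, function(id)
      buildSketch(gs, id = id)), member_ids)
  d <- mashDistanceMatrix(sketches[member_ids])
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  counts <- vapply(cutoffs, function(h)
    length(unique(stats::cutree(hc, h = h))), integer(1))
  list(counts = stats::setNames(counts, as.character(cutoffs)),
       singleton = FALSE, hclust = hc)
}

#' Assign cultured status to species clusters
#'
#' A species is \code{cultured_in_collection} when any member is an
#' isolate genome; otherwise \code{cultured_external_match} when its
#' representative matches an external isolate reference at ANI >= 95 over
#' an alignment fraction >= 0.30; otherwise \code{uncultured}. The
#' alignment fraction here is anchored on the species representative's
#' genome length (coverage mode "query"), so a short reference covering
#' little of the species genome does not qualify.
#'
#' @param gs The \code{\link{GenomeSet}}.
#' @param clusters A \code{\link{SpeciesClusterSet}}.
#' @param external_refs Named list of external isolate reference genomes
#'   (character contigs or \code{DNAStringSet}); may be empty.
#' @param ani_threshold,af_threshold Match thresholds (defaults 95, 0.30).
#' @param fragment_len Fragment length for ANI estimation.
#' @return The \code{SpeciesClusterSet} with \code{cultured_status} set.
#' @export
assignCulturedStatus <- function(gs, clusters, external_refs = list(),
                                 ani_threshold = 95, af_threshold = 0.30,
                                 fragment_len = 1000) {
  md <- genomeMeta(gs)
  sp <- as.data.frame(speciesTable(clusters))
  status <- character(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    mem <- clusterMembers(clusters, sp$species_id[i])
    types <- md$genome_type[match(mem, md$genome_id)]
    if (any(types == "isolate")) {
      status[i] <- "cultured_in_collection"
      next
    }
    status[i] <- "uncultured"
    rep_seq <- genomeSeqs(gs, sp$representative_id[i])
    for (ref in external_refs) {
      r <- aniAf(rep_seq, ref, fragment_len = fragment_len,
                 coverage_mode = "query")
      if (!is.na(r$ani) && r$ani >= ani_threshold && r$af >= af_threshold) {
        status[i] <- "cultured_external_match"
        break
      }
    }
  }
  sp$cultured_status <- status
  new("SpeciesClusterSet", members = clusters@members,
      species = S4Vectors::DataFrame(sp),
      nonredundant = clusters@nonredundant)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting similarity, computed from the
#' contingency table of the two labelings.
#'
#' @param labels_a,labels_b Named vectors (same names = same genome
#'   universe) or unnamed equal-length vectors of cluster labels.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
compareClusterings <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("the two labelings cover different genome universes")
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop("labelings must cover the same genomes")
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)  # degenerate: both all-singletons etc.
  (sum_comb - expected) / (max_index - expected)
}
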