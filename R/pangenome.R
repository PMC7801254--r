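#' Greedy incremental protein clustering
#'
#' Sequences are sorted by decreasing length (ties by id); each sequence
#' joins the earliest-founded cluster whose centroid it matches at
#' identity >= \code{identity} over at least \code{coverage} of the
#' shorter sequence, otherwise it founds a new cluster. Identity is
#' computed from a glocal alignment (global on the shorter sequence
#' against a local window of the longer) as matches / alignment columns.
#' Member count is conserved across clusters.
#'
#' @param sequences An \code{AAStringSet} (named) or named character
#'   vector of amino-acid sequences, minimum length 10.
#' @param identity Identity threshold in (0, 1].
#' @param coverage Minimum aligned fraction of the shorter sequence
#'   (default 0.8).
#' @return data.frame with one row per sequence: \code{protein_id},
#'   \code{cluster_id}, \code{centroid_id}, \code{is_centroid}.
#' @export
clusterProteins <- function(sequences, identity, coverage = 0.8) {
  chars <- if (is.character(sequences)) sequences else
    as.character(sequences)   # XStringSet conversion keeps names
  if (is.null(names(chars)) || anyDuplicated(names(chars)))
    stop("sequences must carry unique names")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYBXZJUO*]", toupper(chars))
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(names(chars)[bad], collapse = ", "))
  if (any(nchar(chars) < 10))
    stop("sequences shorter than 10 residues: ",
         paste(names(chars)[nchar(chars) < 10], collapse = ", "))
  seqs <- Biostrings::AAStringSet(chars)

  ord <- order(-Biostrings::width(seqs), names(seqs))
  seqs <- seqs[ord]
  n <- length(seqs)
  assigned <- rep(NA_integer_, n)
  centroids <- integer(0)
  while (anyNA(assigned)) {
    ci <- which(is.na(assigned))[1]   # longest unassigned founds a cluster
    centroids <- c(centroids, ci)
    assigned[ci] <- length(centroids)
    rest <- which(is.na(assigned))
    if (!length(rest)) break
    hits <- .glocal_match(seqs[rest], seqs[[ci]], identity, coverage)
    assigned[rest[hits]] <- length(centroids)
  }
  ids <- names(seqs)
  data.frame(protein_id = ids,
             cluster_id = sprintf("PC%05d", assigned),
             centroid_id = ids[centroids[assigned]],
             is_centroid = seq_len(n) %in% centroids,
             stringsAsFactors = FALSE)[order(assigned, ids), ]
}

# identity scoring matrix over the AA alphabet (+2 match / -1 mismatch)
.aa_identity_matrix <- function() {
  letters <- Biostrings::AA_ALPHABET
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 2
  m
}

# batch glocal alignment of patterns against one (>= length) centroid;
# returns logical: identity >= threshold and coverage of the shorter met
.glocal_match <- function(patterns, centroid, identity, coverage) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = patterns, subject = centroid, type = "global-local",
    substitutionMatrix = .aa_identity_matrix(),
    gapOpening = 4, gapExtension = 2)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  gap_cols <- Biostrings::insertion(ind)[, "WidthSum"] +
    Biostrings::deletion(ind)[, "WidthSum"]
  cols <- nm + nmm + gap_cols
  aligned_pairs <- nm + nmm                   # columns aligning both seqs
  short_len <- pmin(Biostrings::width(patterns),
                    length(centroid))
  (nm / cols) >= identity & (aligned_pairs / short_len) >= coverage
}

#' Build a species pan-genome
#'
#' Clusters all proteins of a species' conspecific genomes at
#' \code{identity} (default 0.90) with 80\% coverage of the shorter
#' sequence, builds the gene-cluster x genome boolean presence matrix
#' (paralogs count once), and classifies each cluster by presence
#' fraction: core (>= 90\%), rare (< 10\%), else intermediate. The
#' "intraspecies" profile admits only near-complete genomes
#' (completeness >= 90) and requires at least \code{min_genomes}
#' conspecific genomes; species failing the gate are skipped (NULL with
#' a message).
#'
#' @param species_id Species identifier.
#' @param proteins \code{AAStringSet} of the species' proteins (named).
#' @param genome_of Named character vector: protein id -> genome id.
#' @param identity Protein clustering identity (default 0.90).
#' @param coverage Coverage threshold (default 0.8).
#' @param profile "all" (default) or "intraspecies".
#' @param completeness Named numeric (genome id -> completeness \%),
#'   required for the intraspecies profile.
#' @param min_genomes Minimum genomes for the intraspecies profile
#'   (default 10).
#' @return A \code{\link{PanGenome}}, or NULL when gated out.
#' @export
buildPangenome <- function(species_id, proteins, genome_of,
                           identity = 0.90, coverage = 0.8,
                           profile = c("all", "intraspecies"),
                           completeness = NULL, min_genomes = 10) {
  profile <- match.arg(profile)
  stopifnot(all(names(proteins) %in% names(genome_of)))
  genomes <- unique(unname(genome_of[names(proteins)]))
  if (profile == "intraspecies") {
    if (is.null(completeness))
      stop("the intraspecies profile needs per-genome completeness")
    genomes <- genomes[completeness[genomes] >= 90]
    if (length(genomes) < min_genomes) {
      message("species ", species_id, " skipped: ", length(genomes),
              " near-complete genomes < ", min_genomes)
      return(NULL)
    }
    proteins <- proteins[genome_of[names(proteins)] %in% genomes]
  }
  if (length(proteins) == 0) stop("no proteins for species ", species_id)
  cl <- clusterProteins(proteins, identity = identity, coverage = coverage)
  cl$genome_id <- unname(genome_of[cl$protein_id])
  cids <- unique(cl$cluster_id)
  presence <- matrix(FALSE, length(cids), length(genomes),
                     dimnames = list(cids, sort(genomes)))
  idx <- cbind(match(cl$cluster_id, cids),
               match(cl$genome_id, colnames(presence)))
  presence[idx] <- TRUE
  frac <- rowMeans(presence)
  info <- data.frame(
    cluster_id = cids,
    centroid_id = cl$centroid_id[match(cids, cl$cluster_id)],
    n_members = as.integer(table(cl$cluster_id)[cids]),
    presence_fraction = unname(frac),
    freq_class = ifelse(frac >= 0.9, "core",
                        ifelse(frac < 0.1, "rare", "intermediate")),
    stringsAsFactors = FALSE)
  new("PanGenome", species_id = species_id, presence = presence,
      cluster_info = S4Vectors::DataFrame(info))
}

#' Normalized pan-genome size
#'
#' Total number of gene clusters (core plus accessory) divided by the
#' number of genes in the species representative genome.
#'
#' @param pangenome A \code{\link{PanGenome}} (or a gene-cluster count).
#' @param representative_gene_count Gene count of the representative
#'   genome (>= 1).
#' @return Numeric ratio.
#' @export
normalizedPangenomeSize <- function(pangenome, representative_gene_count) {
  if (representative_gene_count < 1)
    stop("representative gene count must be >= 1")
  n <- if (is(pangenome, "PanGenome")) nrow(presenceMatrix(pangenome))
       else as.numeric(pangenome)
  n / representative_gene_count
}

#' High-quality subset of a protein catalog
#'
#' Keeps clusters supported by at least two proteins from different
#' genomes of the same species.
#'
#' @param membership data.frame from \code{\link{clusterProteins}} with
#'   added provenance columns \code{genome_id} and \code{species_id}.
#' @return Character vector of retained cluster ids.
#' @export
hqSubset <- function(membership) {
  stopifnot(all(c("cluster_id", "genome_id", "species_id") %in%
                colnames(membership)))
  keep <- vapply(split(membership, membership$cluster_id), function(m) {
    any(vapply(split(m$genome_id, m$species_id),
               function(g) length(unique(g)) >= 2, logical(1)))
  }, logical(1))
  sort(names(keep)[keep])
}

#' Merge two protein catalogs and report coverage statistics
#'
#' Co-clusters the union of the two catalogs' centroid sequences at
#' \code{identity} (80\% coverage of the shorter sequence). Overlap is
#' the number of merged clusters containing centroids from both
#' catalogs; the percent increase is
#' (total - |b|) / |b| x 100, rounded to the nearest integer, i.e. the
#' growth of the protein space relative to catalog b.
#'
#' @param catalog_a,catalog_b Named \code{AAStringSet} (or character)
#'   centroid sets; must be nonempty.
#' @param identity Clustering identity (default 0.90).
#' @param coverage Coverage threshold (default 0.8).
#' @return List: \code{total}, \code{overlap}, \code{pct_increase},
#'   \code{pct_b_covered}.
#' @export
mergeCatalogs <- function(catalog_a, catalog_b, identity = 0.90,
                          coverage = 0.8) {
  a <- Biostrings::AAStringSet(catalog_a)
  b <- Biostrings::AAStringSet(catalog_b)
  if (length(a) == 0 || length(b) == 0) stop("empty catalog")
  names(a) <- paste0("a|", names(a)); names(b) <- paste0("b|", names(b))
  cl <- clusterProteins(c(a, b), identity = identity, coverage = coverage)
  cl$origin <- substr(cl$protein_id, 1, 1)
  both <- vapply(split(cl$origin, cl$cluster_id),
                 function(o) all(c("a", "b") %in% o), logical(1))
  total <- length(unique(cl$cluster_id))
  mergeStatsFromCounts(length(b), total, sum(both))
}

#' Catalog-merge statistics from printed counts
#'
#' Counts-only replay of the merge arithmetic: given a baseline catalog
#' size, the merged cluster total and (optionally) the overlap, computes
#' the percent increase in protein-space coverage over the baseline and
#' the fraction of the baseline represented in the merge.
#'
#' @param baseline Cluster count of the baseline catalog (b).
#' @param merged_total Cluster count after merging.
#' @param overlap Clusters containing members of both catalogs (optional).
#' @return List: \code{total}, \code{overlap}, \code{pct_increase}
#'   (rounded to nearest integer), \code{pct_b_covered} (NA when overlap
#'   not given).
#' @export
mergeStatsFromCounts <- function(baseline, merged_total, overlap = NA) {
  if (baseline < 1) stop("baseline catalog must be nonempty")
  list(total = merged_total, overlap = overlap,
       pct_increase = round((merged_total - baseline) / baseline * 100),
       pct_b_covered = if (is.na(overlap)) NA_real_ else
         overlap / baseline * 100)
}
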