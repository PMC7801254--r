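#' @include AllClasses.R
NULL

#' Accessors for GenomeSet
#'
#' @param x A \code{GenomeSet}.
#' @param id Genome identifier.
#' @return \code{genomeIds}: character vector of genome ids;
#'   \code{genomeMeta}: the metadata \code{DataFrame}; \code{genomeSeqs}:
#'   the \code{DNAStringSet} of contigs for one genome; \code{nGenomes}:
#'   integer count; \code{hasSequences}: logical.
#' @aliases genomeIds genomeMeta genomeSeqs nGenomes hasSequences
#' @name GenomeSet-accessors
NULL

#' @rdname GenomeSet-accessors
#' @export
genomeIds <- function(x) as.character(x@metadata$genome_id)

#' @rdname GenomeSet-accessors
#' @export
genomeMeta <- function(x) x@metadata

#' @rdname GenomeSet-accessors
#' @export
genomeSeqs <- function(x, id) {
  if (!id %in% names(x@sequences))
    stop("no sequences stored for genome '", id, "'")
  x@sequences[[id]]
}

#' @rdname GenomeSet-accessors
#' @export
nGenomes <- function(x) nrow(x@metadata)

#' @rdname GenomeSet-accessors
#' @export
hasSequences <- function(x) length(x@sequences) > 0

#' Subset a GenomeSet by genome id or index
#'
#' @param x GenomeSet
#' @param i character ids or integer/logical index into the metadata rows
#' @param j,...,drop ignored
#' @export
setMethod("[", "GenomeSet", function(x, i, j, ..., drop = FALSE) {
  ids <- if (is.character(i)) i else genomeIds(x)[i]
  stopifnot(all(ids %in% genomeIds(x)))
  md <- x@metadata[match(ids, x@metadata$genome_id), , drop = FALSE]
  seqs <- x@sequences[intersect(ids, names(x@sequences))]
  new("GenomeSet", sequences = seqs, metadata = md)
})

setMethod("show", "GenomeSet", function(object) {
  md <- object@metadata
  cat("GenomeSet with", nrow(md), "genomes",
      if (length(object@sequences)) "" else "(metadata only)", "\n")
  if (nrow(md)) {
    cat("  genome types:",
        paste(names(table(md$genome_type)), table(md$genome_type),
              sep = ":", collapse = " "), "\n")
    cat("  study sets:", paste(unique(md$study_set), collapse = ", "), "\n")
  }
})

#' Accessors for SpeciesClusterSet
#'
#' @param x A \code{SpeciesClusterSet}.
#' @param species_id Species cluster identifier.
#' @return \code{speciesIds}: character vector; \code{nSpecies}: count;
#'   \code{clusterMembers}: genome ids of one cluster;
#'   \code{representativeOf}: representative genome id;
#'   \code{speciesTable}: the per-species \code{DataFrame};
#'   \code{membershipVector}: named character vector genome_id -> species_id;
#'   \code{nonredundantMembers}: nonredundant genome ids (after
#'   dereplication), or NULL if not yet computed.
#' @aliases speciesIds nSpecies clusterMembers representativeOf
#'   speciesTable membershipVector nonredundantMembers
#' @name SpeciesClusterSet-accessors
NULL

#' @rdname SpeciesClusterSet-accessors
#' @export
speciesIds <- function(x) as.character(x@species$species_id)

#' @rdname SpeciesClusterSet-accessors
#' @export
nSpecies <- function(x) nrow(x@species)

#' @rdname SpeciesClusterSet-accessors
#' @export
clusterMembers <- function(x, species_id)
  as.character(x@members$genome_id[x@members$species_id == species_id])

#' @rdname SpeciesClusterSet-accessors
#' @export
representativeOf <- function(x, species_id)
  as.character(x@species$representative_id[x@species$species_id == species_id])

#' @rdname SpeciesClusterSet-accessors
#' @export
speciesTable <- function(x) x@species

#' @rdname SpeciesClusterSet-accessors
#' @export
membershipVector <- function(x) {
  stats::setNames(as.character(x@members$species_id),
                  as.character(x@members$genome_id))
}

#' @rdname SpeciesClusterSet-accessors
#' @export
nonredundantMembers <- function(x, species_id) x@nonredundant[[species_id]]

setMethod("show", "SpeciesClusterSet", function(object) {
  cat("SpeciesClusterSet:", nrow(object@species), "species,",
      nrow(object@members), "genomes\n")
  sz <- table(object@members$species_id)
  cat("  cluster sizes: min", min(sz), "median", stats::median(sz),
      "max", max(sz), "\n")
  cs <- object@species$cultured_status
  if (!all(is.na(cs)))
    cat("  cultured status:",
        paste(names(table(cs)), table(cs), sep = ":", collapse = " "), "\n")
})

#' Accessors for PanGenome
#'
#' @param x A \code{PanGenome}.
#' @return \code{presenceMatrix}: logical gene cluster x genome matrix;
#'   \code{freqClass}: named character vector of frequency classes;
#'   \code{panSpecies}: the species id; \code{clusterInfo}: per-cluster
#'   \code{DataFrame}.
#' @aliases presenceMatrix freqClass panSpecies clusterInfo
#' @name PanGenome-accessors
NULL

#' @rdname PanGenome-accessors
#' @export
presenceMatrix <- function(x) x@presence

#' @rdname PanGenome-accessors
#' @export
freqClass <- function(x)
  stats::setNames(as.character(x@cluster_info$freq_class),
                  as.character(x@cluster_info$cluster_id))

#' @rdname PanGenome-accessors
#' @export
panSpecies <- function(x) x@species_id

#' @rdname PanGenome-accessors
#' @export
clusterInfo <- function(x) x@cluster_info

setMethod("show", "PanGenome", function(object) {
  tab <- table(object@cluster_info$freq_class)
  cat("PanGenome of", object@species_id, "-", nrow(object@presence),
      "gene clusters x", ncol(object@presence), "genomes\n")
  cat("  ", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})

#' Accessors for SNVCatalog
#'
#' @param x An \code{SNVCatalog}.
#' @return \code{snvTable}: the SNV \code{DataFrame}; \code{nSnvs}: record
#'   count; \code{snvSpecies}: the species id.
#' @aliases snvTable nSnvs snvSpecies
#' @name SNVCatalog-accessors
NULL

#' @rdname SNVCatalog-accessors
#' @export
snvTable <- function(x) x@snvs

#' @rdname SNVCatalog-accessors
#' @export
nSnvs <- function(x) nrow(x@snvs)

#' @rdname SNVCatalog-accessors
#' @export
snvSpecies <- function(x) x@species_id

setMethod("show", "SNVCatalog", function(object) {
  cat("SNVCatalog of", object@species_id, "-", nrow(object@snvs),
      "records\n")
  if (nrow(object@snvs))
    cat("  continent-specific:", sum(object@snvs$continent_specific),
        " type-specific:", sum(object@snvs$type_specific), "\n")
})
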