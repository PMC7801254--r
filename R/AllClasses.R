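#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom utils head tail
NULL

.META_COLS <- c("genome_id", "study_set", "genome_type", "sample_id",
                "country", "continent", "completeness", "contamination",
                "n_5S", "n_16S", "n_23S", "n_tRNA")

#' GenomeSet: a collection of genome assemblies with metadata
#'
#' Container pairing genome assemblies (one \code{DNAStringSet} of contigs
#' per genome) with per-genome metadata: study set, genome type (isolate or
#' MAG), sample and geographic origin, CheckM-style completeness and
#' contamination estimates, rRNA/tRNA annotation counts, and derived
#' assembly statistics (total length, N50, contig count). Sequences may be
#' absent ("metadata-only" mode) for operations that only need the
#' metadata, such as per-study count summaries.
#'
#' @slot sequences Named list of \code{DNAStringSet}, one per genome;
#'   may be empty in metadata-only mode.
#' @slot metadata A \code{DataFrame} with one row per genome; required
#'   columns \code{genome_id}, \code{study_set}, \code{genome_type},
#'   \code{sample_id}, \code{country}, \code{continent},
#'   \code{completeness}, \code{contamination}, \code{n_5S}, \code{n_16S},
#'   \code{n_23S}, \code{n_tRNA} plus derived \code{length}, \code{n50},
#'   \code{n_contigs}.
#' @exportClass GenomeSet
setClass("GenomeSet",
         representation(sequences = "list", metadata = "DataFrame"))

setValidity("GenomeSet", function(object) {
  md <- object@metadata
  miss <- setdiff(.META_COLS, colnames(md))
  if (length(miss))
    return(paste("metadata lacks columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(md$genome_id))
    return("duplicate genome_id in metadata")
  if (length(object@sequences)) {
    if (!all(names(object@sequences) %in% md$genome_id))
      return("sequences present for genomes absent from metadata")
    if (!all(vapply(object@sequences, function(x)
      is(x, "DNAStringSet") && length(x) > 0, logical(1))))
      return("each genome needs a nonempty DNAStringSet of contigs")
  }
  if (any(md$completeness < 0 | md$completeness > 100, na.rm = TRUE))
    return("completeness outside [0,100]")
  if (any(md$contamination < 0 | md$contamination > 100, na.rm = TRUE))
    return("contamination outside [0,100]")
  TRUE
})

#' SpeciesClusterSet: a species-level partition of a genome collection
#'
#' Result of ANI-based species clustering: every genome is assigned to
#' exactly one species cluster; each cluster has a representative chosen
#' by quality score with isolates prioritized over MAGs. Nonredundant
#' member sets (after 99.9\% ANI dereplication and per-sample uniqueness)
#' and cultured status are filled in by downstream steps.
#'
#' @slot members DataFrame (genome_id, species_id).
#' @slot species DataFrame (species_id, representative_id, n_members,
#'   n_nonredundant, cultured_status).
#' @slot nonredundant Named list: species_id -> nonredundant genome_ids.
#' @exportClass SpeciesClusterSet
setClass("SpeciesClusterSet",
         representation(members = "DataFrame", species = "DataFrame",
                        nonredundant = "list"))

setValidity("SpeciesClusterSet", function(object) {
  m <- object@members; s <- object@species
  if (anyDuplicated(m$genome_id))
    return("a genome is assigned to more than one species")
  if (!all(s$species_id %in% m$species_id) ||
      !all(m$species_id %in% s$species_id))
    return("species table and membership disagree")
  rep_in <- mapply(function(r, sid) r %in% m$genome_id[m$species_id == sid],
                   s$representative_id, s$species_id)
  if (length(rep_in) && !all(rep_in))
    return("a representative is not a member of its cluster")
  if (length(object@nonredundant)) {
    ok <- vapply(names(object@nonredundant), function(sid)
      all(object@nonredundant[[sid]] %in% m$genome_id[m$species_id == sid]),
      logical(1))
    if (!all(ok)) return("nonredundant sets contain non-members")
  }
  TRUE
})

#' PanGenome: gene-cluster presence/absence for one species
#'
#' Gene clusters from greedy protein clustering of all conspecific
#' genomes (90\% amino acid identity, 80\% coverage of the shorter
#' sequence by default), with a boolean cluster x genome presence matrix
#' and a frequency class per cluster: core (present in >= 90\% of
#' conspecific genomes), rare (< 10\%) or intermediate.
#'
#' @slot species_id Character scalar.
#' @slot presence Logical matrix, gene clusters x genomes.
#' @slot cluster_info DataFrame (cluster_id, centroid_id, n_members,
#'   presence_fraction, freq_class).
#' @exportClass PanGenome
setClass("PanGenome",
         representation(species_id = "character", presence = "matrix",
                        cluster_info = "DataFrame"))

setValidity("PanGenome", function(object) {
  if (!is.logical(object@presence)) return("presence matrix must be logical")
  if (nrow(object@presence) != nrow(object@cluster_info))
    return("presence matrix and cluster_info row mismatch")
  frac <- rowMeans(object@presence)
  cls <- ifelse(frac >= 0.9, "core", ifelse(frac < 0.1, "rare", "intermediate"))
  if (!all(cls == object@cluster_info$freq_class))
    return("freq_class inconsistent with presence fractions")
  TRUE
})

#' SNVCatalog: unified intraspecies single-nucleotide variants
#'
#' Per-species catalog of substitutions relative to the species
#' representative genome. A locus/allele enters the catalog only when the
#' alternate allele is carried by at least two conspecific genomes;
#' single-base insertions and deletions are never included. Records carry
#' the supporting genomes and specificity flags (alternate allele found
#' solely in one continent or one genome type).
#'
#' @slot species_id Character scalar.
#' @slot snvs DataFrame (contig, pos, ref, alt, n_support, supporting,
#'   continents, types, continent_specific, type_specific). Coordinates
#'   are 1-based on the representative genome's forward strand.
#' @exportClass SNVCatalog
setClass("SNVCatalog",
         representation(species_id = "character", snvs = "DataFrame"))

setValidity("SNVCatalog", function(object) {
  s <- object@snvs
  if (nrow(s) == 0) return(TRUE)
  if (any(s$ref == s$alt)) return("ref == alt in an SNV record")
  if (any(s$n_support < 2)) return("SNV with fewer than 2 supporting genomes")
  TRUE
})
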