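#' Read a genome collection from FASTA files and a metadata TSV
#'
#' The metadata TSV must have a header with the columns genome_id,
#' study_set, genome_type, sample_id, country, continent, completeness,
#' contamination, n_5S, n_16S, n_23S, n_tRNA. In sequence mode every row
#' must have a FASTA file \code{<genome_id>.fa} (or .fasta/.fa.gz/.fasta.gz)
#' under \code{fasta_dir}; the derived fields length, N50 and contig count
#' are computed from the sequences. With \code{metadata_only = TRUE} no
#' sequences are read (derived fields must then be present in the TSV or
#' are set NA); this mode supports count summaries over large published
#' collections.
#'
#' @param fasta_dir Directory of per-genome FASTA files.
#' @param metadata_tsv Path to the metadata TSV.
#' @param metadata_only Skip sequence loading (default FALSE).
#' @return A \code{\link{GenomeSet}}.
#' @export
readGenomeCollection <- function(fasta_dir, metadata_tsv,
                                 metadata_only = FALSE) {
  md <- utils::read.delim(metadata_tsv, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(genome_id = "character"))
  miss <- setdiff(.META_COLS, colnames(md))
  if (length(miss))
    stop("metadata TSV lacks required columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(md$genome_id))
    stop("duplicate genome_id in metadata: ",
         paste(unique(md$genome_id[duplicated(md$genome_id)]),
               collapse = ", "))
  seqs <- list()
  if (!metadata_only && nrow(md)) {
    exts <- c(".fa", ".fasta", ".fa.gz", ".fasta.gz")
    for (gid in md$genome_id) {
      path <- NULL
      for (e in exts) {
        p <- file.path(fasta_dir, paste0(gid, e))
        if (file.exists(p)) { path <- p; break }
      }
      if (is.null(path))
        stop("no FASTA file found for genome_id '", gid, "' in ", fasta_dir)
      dss <- Biostrings::readDNAStringSet(path)
      if (length(dss) == 0)
        stop("FASTA for genome_id '", gid, "' contains no sequences")
      seqs[[gid]] <- dss
    }
    lens <- lapply(seqs, function(x) Biostrings::width(x))
    md$length <- vapply(lens, sum, numeric(1))[md$genome_id]
    md$n50 <- vapply(lens, .n50, numeric(1))[md$genome_id]
    md$n_contigs <- vapply(lens, length, integer(1))[md$genome_id]
  } else {
    for (col in c("length", "n50", "n_contigs"))
      if (!col %in% colnames(md)) md[[col]] <- rep(NA_real_, nrow(md))
  }
  new("GenomeSet", sequences = seqs, metadata = S4Vectors::DataFrame(md))
}

#' Write a genome collection to per-genome FASTA files and a metadata TSV
#'
#' FASTA sequence lines are wrapped at 80 columns. Output is deterministic
#' (rows sorted by genome_id).
#'
#' @param gs A \code{\link{GenomeSet}} with sequences.
#' @param outdir Output directory (created if needed).
#' @param gzip Write gzipped FASTA (default FALSE).
#' @return Invisibly, the metadata TSV path.
#' @export
writeGenomeCollection <- function(gs, outdir, gzip = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  md <- as.data.frame(genomeMeta(gs))
  md <- md[order(md$genome_id), , drop = FALSE]
  for (gid in md$genome_id) {
    f <- file.path(outdir, paste0(gid, if (gzip) ".fa.gz" else ".fa"))
    Biostrings::writeXStringSet(genomeSeqs(gs, gid), f, width = 80,
                                compress = gzip)
  }
  tsv <- file.path(outdir, "metadata.tsv")
  utils::write.table(md, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv)
}

#' Write / read planted truth as JSON
#'
#' @param truth A \code{synthetic_truth}.
#' @param path JSON file path.
#' @return \code{writeTruth}: invisibly the path; \code{readTruth}: the
#'   \code{synthetic_truth}.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  x <- unclass(truth)
  x$config <- unclass(x$config)
  # named atomic vectors must travel as JSON objects, not arrays
  for (f in c("species_of", "deleted_fraction", "contamination_fraction",
              "ancestors"))
    x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$species_of <- unlist(x$species_of)
  x$snvs <- as.data.frame(x$snvs, stringsAsFactors = FALSE)
  x$contig_map <- as.data.frame(x$contig_map, stringsAsFactors = FALSE)
  x$gene_presence <- lapply(x$gene_presence, unlist)
  x$deleted_fraction <- unlist(x$deleted_fraction)
  x$contamination_fraction <- unlist(x$contamination_fraction)
  x$ancestors <- unlist(x$ancestors)
  x$config <- structure(x$config, class = "simulation_config")
  class(x) <- "synthetic_truth"
  x
}

#' Read a newick tree for phylogenetic-diversity accounting
#'
#' Thin validated wrapper over \code{ape::read.tree}: the tree must parse
#' and carry branch lengths (required for PD). Write-then-read round
#' trips preserve topology and branch lengths to within 1e-9.
#'
#' @param path Newick file path.
#' @param require_branch_lengths Error when branch lengths are absent
#'   (default TRUE).
#' @return An \code{ape::phylo}.
#' @export
readNewickTree <- function(path, require_branch_lengths = TRUE) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in '", path, "'")
  if (require_branch_lengths && is.null(tr$edge.length))
    stop("branch lengths required for PD")
  tr
}

#' Merged-collection size from per-study genome counts
#'
#' Sums quality-filtered genome counts over study sets; used to replay
#' published per-study tallies without the underlying assemblies.
#'
#' @param study_counts Named or unnamed numeric vector of per-study counts.
#' @return Total genome count.
#' @export
mergedCollectionSize <- function(study_counts) {
  if (any(study_counts < 0)) stop("counts must be nonnegative")
  sum(study_counts)
}
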