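#' @useDynLib gutcatalog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# fixed, recorded hash seed for all MinHash sketching
.HASH_SEED <- 42

#' Build a MinHash sketch of a genome
#'
#' Bottom-s MinHash over canonical k-mers (the lexicographic minimum of
#' each k-mer and its reverse complement), hashed with a seeded 64-bit
#' non-cryptographic hash. Defaults (k = 21, sketch size 1,000) follow the
#' conventions of standard genome-sketching tools.
#'
#' @param x A \code{DNAStringSet} of contigs, a character vector of contig
#'   sequences, or a \code{GenomeSet} with \code{id} naming one genome.
#' @param id Genome id when \code{x} is a GenomeSet.
#' @param k K-mer size (default 21).
#' @param sketch_size Maximum number of retained hashes (default 1000).
#' @return Object of class \code{sketch_profile}: list with
#'   \code{genome_id}, \code{k}, \code{sketch_size}, \code{hashes}
#'   (sorted ascending numeric vector).
#' @export
buildSketch <- function(x, id = NULL, k = 21, sketch_size = 1000) {
  if (is(x, "GenomeSet")) {
    contigs <- as.character(genomeSeqs(x, id))
  } else {
    contigs <- as.character(x)
    if (is.null(id)) id <- "genome"
  }
  if (sum(nchar(contigs)) < k)
    stop("genome shorter than k = ", k)
  hashes <- sketch_hashes_cpp(contigs, as.integer(k),
                              as.integer(sketch_size), .HASH_SEED)
  structure(list(genome_id = id, k = as.integer(k),
                 sketch_size = as.integer(sketch_size), hashes = hashes),
            class = "sketch_profile")
}

#' @export
print.sketch_profile <- function(x, ...) {
  cat("MinHash sketch of", x$genome_id, "- k =", x$k, ",",
      length(x$hashes), "/", x$sketch_size, "hashes\n")
  invisible(x)
}

#' Mash distance between two sketches
#'
#' Jaccard index j estimated from the merged bottom-s sketch (the s
#' smallest hashes of the union; shared hashes among them divided by s),
#' converted to a mutation-rate distance d = -ln(2j / (1 + j)) / k.
#' Zero shared hashes give d = 1 by convention.
#'
#' @param a,b \code{sketch_profile} objects with identical k and sketch size.
#' @return Distance in [0, 1].
#' @export
mashDistance <- function(a, b) {
  if (a$k != b$k || a$sketch_size != b$sketch_size)
    stop("sketches built with different k or sketch_size are not comparable")
  j <- .sketch_jaccard(a$hashes, b$hashes, a$sketch_size)
  if (j <= 0) return(1)
  min(1, -log(2 * j / (1 + j)) / a$k)
}

.sketch_jaccard <- function(ha, hb, s) {
  u <- sort(unique(c(ha, hb)))
  if (length(u) > s) u <- u[seq_len(s)]
  shared <- sum(u %in% ha & u %in% hb)
  shared / min(s, length(u))
}

#' Pairwise Mash distance matrix
#'
#' @param sketches List of \code{sketch_profile} objects.
#' @return Symmetric matrix of distances with genome ids as dimnames.
#' @export
mashDistanceMatrix <- function(sketches) {
  n <- length(sketches)
  ids <- vapply(sketches, `[[`, character(1), "genome_id")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(d)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- mashDistance(sketches[[i]], sketches[[j]])
    }
  d
}

#' Fragment-based ANI and alignment fraction
#'
#' Each genome is cut into non-overlapping fragments of
#' \code{fragment_len} bp; fragments are anchored onto the other genome by
#' shared k-mers (diagonal voting over both orientations) and scored by
#' column comparison on the winning diagonal. ANI is the mean identity of
#' mapped fragments (percent) over both directions; directional coverage
#' is mapped fragment length / genome length, and AF is reported per
#' \code{coverage_mode}: \code{"larger"} (default) takes the larger of
#' the two directional coverages, \code{"smaller"} the smaller,
#' \code{"query"} the query coverage only.
#'
#' @param query,target \code{DNAStringSet}/character contigs, or
#'   \code{GenomeSet} plus \code{query_id}/\code{target_id}.
#' @param query_id,target_id Genome ids when GenomeSets are given.
#' @param fragment_len Fragment length in bp (default 1000; tuned to
#'   desk-scale genomes of 50-500 kb).
#' @param k Anchor k-mer size (default 15).
#' @param min_anchors Minimum shared k-mers on the winning diagonal for a
#'   fragment to count as mapped (default 5).
#' @param coverage_mode "larger", "smaller" or "query".
#' @return List with \code{ani} (percent, NA when nothing maps),
#'   \code{af}, \code{n_fragments_mapped}, \code{coverage_query},
#'   \code{coverage_target}.
#' @export
aniAf <- function(query, target, query_id = NULL, target_id = NULL,
                  fragment_len = 1000, k = 15, min_anchors = 5,
                  coverage_mode = c("larger", "smaller", "query")) {
  coverage_mode <- match.arg(coverage_mode)
  qc <- if (is(query, "GenomeSet")) as.character(genomeSeqs(query, query_id))
        else as.character(query)
  tc <- if (is(target, "GenomeSet")) as.character(genomeSeqs(target, target_id))
        else as.character(target)
  if (sum(nchar(qc)) < fragment_len || sum(nchar(tc)) < fragment_len)
    stop("both genomes must be at least fragment_len = ", fragment_len, " bp")
  fwd <- ani_fragments_cpp(qc, tc, as.integer(fragment_len), as.integer(k),
                           as.integer(min_anchors))
  rev <- ani_fragments_cpp(tc, qc, as.integer(fragment_len), as.integer(k),
                           as.integer(min_anchors))
  idents <- c(fwd$identity, rev$identity)
  cov_q <- fwd$mapped_length / fwd$query_length
  cov_t <- rev$mapped_length / rev$query_length
  af <- switch(coverage_mode,
               larger = max(cov_q, cov_t),
               smaller = min(cov_q, cov_t),
               query = cov_q)
  list(ani = if (length(idents)) 100 * mean(idents) else NA_real_,
       af = af, n_fragments_mapped = length(idents),
       coverage_query = cov_q, coverage_target = cov_t)
}

#' Sketch every genome in a GenomeSet
#'
#' @param gs GenomeSet with sequences.
#' @param k,sketch_size Passed to \code{\link{buildSketch}}.
#' @return Named list of \code{sketch_profile}, in genome id order.
#' @export
sketchCollection <- function(gs, k = 21, sketch_size = 1000) {
  ids <- genomeIds(gs)
  stats::setNames(lapply(ids, function(id)
    buildSketch(gs, id = id, k = k, sketch_size = sketch_size)), ids)
}
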