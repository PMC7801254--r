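#' Genome quality score
#'
#' The standard MAG quality score: completeness minus five times
#' contamination, both in percent. Genomes are admitted to the catalog
#' when this score exceeds 50 (together with completeness > 50\% and
#' contamination < 5\%).
#'
#' @param completeness Completeness percentage in [0, 100].
#' @param contamination Contamination percentage in [0, 100].
#' @return Numeric score (may be negative). Vectorized.
#' @examples
#' qualityScore(90, 8)   # 50
#' @export
qualityScore <- function(completeness, contamination) {
  .check_pct(completeness, "completeness")
  .check_pct(contamination, "contamination")
  completeness - 5 * contamination
}

.check_pct <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 100))
    stop(what, " must be a percentage in [0, 100]")
  invisible(x)
}

#' Genome quality filter
#'
#' A genome passes when completeness > 50, contamination < 5 and quality
#' score (completeness - 5 x contamination) > 50. All three comparisons
#' are strict: a genome at exactly 50\% completeness or exactly 5\%
#' contamination fails.
#'
#' @param x A \code{GenomeSet}, or a numeric completeness vector.
#' @param contamination Contamination percentages (when \code{x} is numeric).
#' @return Logical vector, one element per genome.
#' @export
passesQualityFilter <- function(x, contamination = NULL) {
  if (is(x, "GenomeSet")) {
    md <- genomeMeta(x)
    cmp <- md$completeness; cnt <- md$contamination
  } else {
    cmp <- x; cnt <- contamination
  }
  cmp > 50 & cnt < 5 & qualityScore(cmp, cnt) > 50
}

#' Representative selection score
#'
#' Score used to rank conspecific genomes when choosing a species
#' representative: completeness - 5 x contamination + 0.5 x log(N50).
#' The log base defaults to 10 (configurable), matching the magnitude
#' conventions of genome-dereplication scoring.
#'
#' @param completeness,contamination Percentages in [0, 100].
#' @param n50 Assembly N50 in bp (>= 1).
#' @param log_base Base for the N50 log term (default 10).
#' @return Numeric score. Vectorized.
#' @examples
#' representativeScore(100, 0, 1e6)  # 103
#' @export
representativeScore <- function(completeness, contamination, n50,
                                log_base = 10) {
  if (any(!is.finite(n50) | n50 < 1)) stop("n50 must be >= 1")
  qualityScore(completeness, contamination) + 0.5 * log(n50, base = log_base)
}

#' Genomic Standards Consortium quality tier
#'
#' "high" quality requires completeness > 90, contamination < 5, presence
#' of the 5S, 16S and 23S rRNA genes and at least 18 of the standard
#' tRNAs; anything else that passed the catalog filter is "medium".
#'
#' @param x A \code{GenomeSet} or a data.frame/DataFrame with columns
#'   completeness, contamination, n_5S, n_16S, n_23S, n_tRNA.
#' @return Character vector "high"/"medium", one element per genome.
#' @export
gscQualityTier <- function(x) {
  md <- if (is(x, "GenomeSet")) genomeMeta(x) else x
  high <- md$completeness > 90 & md$contamination < 5 &
    md$n_5S >= 1 & md$n_16S >= 1 & md$n_23S >= 1 & md$n_tRNA >= 18
  ifelse(high, "high", "medium")
}

#' Strain heterogeneity from a read pileup
#'
#' Fraction (in percent) of qualifying pileup positions that are
#' polymorphic. A position qualifies when its depth, counting only bases
#' at or above \code{min_baseq}, is at least \code{min_depth}; it is
#' polymorphic when the minor allele fraction is at least
#' \code{minor_fraction}. At least \code{min_positions} qualifying
#' positions are required; otherwise the estimate is flagged as
#' insufficient. This is an annotation-free simplification of
#' codon-aware polymorphism callers: all positions are treated alike
#' rather than restricting to nonsynonymous coding changes.
#'
#' @param pileup data.frame with columns \code{pos}, allele counts
#'   \code{A,C,G,T} and mean base qualities \code{bq_A,bq_C,bq_G,bq_T}.
#' @param min_depth Minimum qualifying depth (default 10).
#' @param min_baseq Minimum base quality for a base to count (default 30).
#' @param min_positions Minimum number of qualifying positions (default 100).
#' @param minor_fraction Minor allele fraction calling a position
#'   polymorphic (default 0.2).
#' @return List with \code{heterogeneity} (percent, NA when insufficient),
#'   \code{n_positions} (qualifying positions), \code{sufficient} (logical).
#' @export
strainHeterogeneity <- function(pileup, min_depth = 10, min_baseq = 30,
                                min_positions = 100, minor_fraction = 0.2) {
  insufficient <- list(heterogeneity = NA_real_, n_positions = 0L,
                       sufficient = FALSE)
  if (is.null(pileup) || nrow(pileup) == 0) return(insufficient)
  cnt <- as.matrix(pileup[, c("A", "C", "G", "T")])
  bq <- as.matrix(pileup[, c("bq_A", "bq_C", "bq_G", "bq_T")])
  cnt[bq < min_baseq] <- 0L          # discard low-quality bases
  depth <- rowSums(cnt)
  ok <- depth >= min_depth
  n_ok <- sum(ok)
  if (n_ok < min_positions)
    return(list(heterogeneity = NA_real_, n_positions = as.integer(n_ok),
                sufficient = FALSE))
  cnt <- cnt[ok, , drop = FALSE]; depth <- depth[ok]
  minor <- depth - apply(cnt, 1, max)
  poly <- (minor / depth) >= minor_fraction
  list(heterogeneity = 100 * mean(poly), n_positions = as.integer(n_ok),
       sufficient = TRUE)
}
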