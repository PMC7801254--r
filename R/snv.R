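#' Align a conspecific genome to its species representative
#'
#' Anchor-chain-and-extend whole-genome alignment: unique k-mers of the
#' representative (default k = 19) anchor the member's contigs on both
#' strands; collinear anchors are chained, inter-anchor gaps are closed
#' by direct column comparison (equal gap lengths) or banded global
#' alignment (unequal, small gaps). Blocks are then filtered to a
#' one-to-one mapping: in decreasing score order a block is kept only if
#' it overlaps no kept block on either the representative or the member
#' axis, so no representative base is covered twice (the analogue of
#' reference- and query-side repeat filtering).
#'
#' @param member,representative \code{DNAStringSet}/character contigs, or
#'   \code{GenomeSet} with \code{member_id}/\code{representative_id}.
#' @param member_id,representative_id Genome ids when GenomeSets given.
#' @param k Anchor k-mer size (default 19).
#' @param max_gap Maximum inter-anchor gap chained into one block
#'   (default 2000 bp).
#' @return data.frame of blocks: rep_contig, member_contig (names),
#'   rep_start/rep_end, member_start/member_end (1-based, forward
#'   strand), strand, n_cols, n_match, n_indel1, n_indel_multi, plus a
#'   list-column \code{subs} of per-block substitution tables
#'   (rep_pos, member_pos, ref, alt; alt on the representative forward
#'   strand). Empty data.frame when nothing anchors.
#' @export
alignToRepresentative <- function(member, representative,
                                  member_id = NULL,
                                  representative_id = NULL,
                                  k = 19, max_gap = 2000) {
  mc <- if (is(member, "GenomeSet"))
    genomeSeqs(member, member_id) else Biostrings::DNAStringSet(member)
  rc <- if (is(representative, "GenomeSet"))
    genomeSeqs(representative, representative_id)
  else Biostrings::DNAStringSet(representative)
  mnames <- if (is.null(names(mc)))
    sprintf("member_%d", seq_along(mc)) else names(mc)
  rnames <- if (is.null(names(rc)))
    sprintf("rep_%d", seq_along(rc)) else names(rc)

  raw <- anchor_align_cpp(as.character(mc), as.character(rc),
                          as.integer(k), as.integer(max_gap))
  if (!length(raw)) return(.empty_blocks())
  blocks <- do.call(rbind, lapply(raw, function(b)
    data.frame(rep_contig = rnames[b$rep_contig],
               member_contig = mnames[b$member_contig],
               rep_start = b$rep_start, rep_end = b$rep_end,
               member_start = b$member_start, member_end = b$member_end,
               strand = b$strand, n_cols = b$n_cols, n_match = b$n_match,
               n_indel1 = b$n_indel1, n_indel_multi = b$n_indel_multi,
               stringsAsFactors = FALSE)))
  blocks$subs <- lapply(raw, function(b)
    data.frame(rep_pos = b$sub_rep_pos, member_pos = b$sub_member_pos,
               ref = b$sub_ref, alt = b$sub_alt, stringsAsFactors = FALSE))
  .filter_one_to_one(blocks)
}

.empty_blocks <- function() {
  b <- data.frame(rep_contig = character(0), member_contig = character(0),
                  rep_start = integer(0), rep_end = integer(0),
                  member_start = integer(0), member_end = integer(0),
                  strand = integer(0), n_cols = integer(0),
                  n_match = integer(0), n_indel1 = integer(0),
                  n_indel_multi = integer(0))
  b$subs <- list()
  b
}

# keep blocks greedily by score; reject any block overlapping a kept
# block on the representative or the member axis
.filter_one_to_one <- function(blocks) {
  ord <- order(-blocks$n_match, blocks$rep_contig, blocks$rep_start)
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      if (blocks$rep_contig[i] == blocks$rep_contig[j] &&
          blocks$rep_start[i] <= blocks$rep_end[j] &&
          blocks$rep_end[i] >= blocks$rep_start[j]) { clash <- TRUE; break }
      if (blocks$member_contig[i] == blocks$member_contig[j] &&
          blocks$member_start[i] <= blocks$member_end[j] &&
          blocks$member_end[i] >= blocks$member_start[j]) {
        clash <- TRUE; break
      }
    }
    if (!clash) kept <- c(kept, i)
  }
  out <- blocks[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call substitutions from one-to-one alignment blocks
#'
#' Emits every aligned column where the representative and member bases
#' differ and both are non-gap. Gap columns contribute nothing: single
#' base insertions and deletions are never counted as SNVs, and
#' multi-base indels only interrupt alignment columns.
#'
#' @param blocks Block table from \code{\link{alignToRepresentative}}.
#' @return data.frame: rep_contig, rep_pos, ref, alt, member_contig,
#'   member_pos, strand.
#' @export
callSnvs <- function(blocks) {
  if (!nrow(blocks))
    return(data.frame(rep_contig = character(0), rep_pos = integer(0),
                      ref = character(0), alt = character(0),
                      member_contig = character(0), member_pos = integer(0),
                      strand = integer(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    s <- blocks$subs[[i]]
    if (!nrow(s)) return(NULL)
    data.frame(rep_contig = blocks$rep_contig[i], rep_pos = s$rep_pos,
               ref = s$ref, alt = s$alt,
               member_contig = blocks$member_contig[i],
               member_pos = s$member_pos, strand = blocks$strand[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(callSnvs(.empty_blocks()))
  out[order(out$rep_contig, out$rep_pos), , drop = FALSE]
}

#' Build the unified SNV catalog of one species
#'
#' Aligns every conspecific member to the species representative, calls
#' substitutions, and unifies them by position on the representative: a
#' locus/alternate-allele pair enters the catalog only when at least two
#' members carry the alternate allele. Species with fewer than
#' \code{min_genomes} conspecific genomes (3, counting the
#' representative) are skipped. A member carrying two different
#' alternate alleles at one locus across its contigs contributes to each
#' allele independently.
#'
#' @param gs The \code{\link{GenomeSet}}.
#' @param clusters A \code{\link{SpeciesClusterSet}}.
#' @param species_id Which species to process.
#' @param min_genomes Minimum conspecific genomes (default 3).
#' @param k,max_gap Passed to \code{\link{alignToRepresentative}}.
#' @return An \code{\link{SNVCatalog}}, or NULL when the species is
#'   skipped.
#' @export
buildSpeciesSnvCatalog <- function(gs, clusters, species_id,
                                   min_genomes = 3, k = 19,
                                   max_gap = 2000) {
  members <- clusterMembers(clusters, species_id)
  if (length(members) < min_genomes) {
    message("species ", species_id, " skipped: ", length(members),
            " conspecific genomes < ", min_genomes)
    return(NULL)
  }
  rep_id <- representativeOf(clusters, species_id)
  per_member <- list()
  for (m in setdiff(members, rep_id)) {
    blocks <- alignToRepresentative(gs, gs, member_id = m,
                                    representative_id = rep_id,
                                    k = k, max_gap = max_gap)
    sn <- callSnvs(blocks)
    if (nrow(sn)) {
      sn$genome_id <- m
      per_member[[m]] <- sn[, c("rep_contig", "rep_pos", "ref", "alt",
                                "genome_id")]
    }
  }
  if (!length(per_member))
    return(new("SNVCatalog", species_id = species_id,
               snvs = S4Vectors::DataFrame(.empty_snv_table())))
  all_sub <- do.call(rbind, per_member)
  # one vote per (member, locus, alt)
  all_sub <- unique(all_sub)
  key <- paste(all_sub$rep_contig, all_sub$rep_pos, all_sub$alt, sep = "\r")
  recs <- lapply(split(all_sub, key), function(g) {
    supp <- sort(unique(g$genome_id))
    if (length(supp) < 2) return(NULL)
    data.frame(contig = g$rep_contig[1], pos = g$rep_pos[1],
               ref = g$ref[1], alt = g$alt[1],
               n_support = length(supp),
               supporting = paste(supp, collapse = ","),
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs)) recs <- .empty_snv_table()
  recs <- recs[order(recs$contig, recs$pos, recs$alt), , drop = FALSE]
  rownames(recs) <- NULL
  new("SNVCatalog", species_id = species_id,
      snvs = S4Vectors::DataFrame(recs))
}

.empty_snv_table <- function() {
  data.frame(contig = character(0), pos = integer(0), ref = character(0),
             alt = character(0), n_support = integer(0),
             supporting = character(0), stringsAsFactors = FALSE)
}

#' Tag continent- and genome-type-specific SNVs
#'
#' An SNV is continent specific when all carriers of the alternate allele
#' share one continent (likewise genome-type specific for isolate/MAG).
#' Carriers without continent metadata are excluded from the continent
#' determination and flagged. Per-continent normalized contribution =
#' (number of SNVs specific to continent c) / (number of genomes from c).
#'
#' @param catalog An \code{\link{SNVCatalog}}.
#' @param metadata The genome metadata \code{DataFrame} (or GenomeSet).
#' @param genome_ids Genomes over which per-continent genome counts are
#'   taken (default: all genomes in the metadata).
#' @return List: \code{catalog} (with continents, types,
#'   continent_specific, type_specific columns filled) and
#'   \code{continent_contribution} (named numeric).
#' @export
tagSpecificSnvs <- function(catalog, metadata, genome_ids = NULL) {
  md <- if (is(metadata, "GenomeSet")) genomeMeta(metadata) else metadata
  s <- as.data.frame(snvTable(catalog))
  if (is.null(genome_ids)) genome_ids <- as.character(md$genome_id)
  if (nrow(s)) {
    carr <- strsplit(s$supporting, ",")
    cont <- lapply(carr, function(g) {
      x <- md$continent[match(g, md$genome_id)]
      x[!is.na(x)]
    })
    type <- lapply(carr, function(g) md$genome_type[match(g, md$genome_id)])
    s$continents <- vapply(cont, function(x)
      paste(sort(unique(x)), collapse = ","), character(1))
    s$types <- vapply(type, function(x)
      paste(sort(unique(x)), collapse = ","), character(1))
    s$continent_specific <- vapply(cont, function(x)
      length(unique(x)) == 1, logical(1))
    s$type_specific <- vapply(type, function(x)
      length(unique(x)) == 1, logical(1))
  } else {
    s$continents <- character(0); s$types <- character(0)
    s$continent_specific <- logical(0); s$type_specific <- logical(0)
  }
  out <- new("SNVCatalog", species_id = snvSpecies(catalog),
             snvs = S4Vectors::DataFrame(s))
  n_per_cont <- table(md$continent[match(genome_ids, md$genome_id)])
  spec <- s$continents[s$continent_specific]
  contrib <- vapply(names(n_per_cont), function(cc)
    sum(spec == cc) / as.numeric(n_per_cont[[cc]]), numeric(1))
  list(catalog = out, continent_contribution = contrib)
}

#' Pairwise SNV density within a species
#'
#' Aligns all unordered pairs of a species' near-complete members
#' (completeness >= \code{min_completeness}) and reports the SNV density
#' of each pair as substitutions per kilobase of aligned representative
#' sequence. Species with fewer than \code{min_genomes} qualifying
#' genomes are skipped; species larger than \code{cap} are limited to the
#' \code{cap} best genomes by representative score (ties by genome id).
#' Pairs are annotated by genome-type composition (isolate-isolate,
#' mixed, MAG-MAG) and continent composition.
#'
#' @param gs The \code{\link{GenomeSet}}.
#' @param clusters A \code{\link{SpeciesClusterSet}}.
#' @param species_id Species to process.
#' @param min_completeness Completeness gate (default 90).
#' @param min_genomes Minimum qualifying genomes (default 10).
#' @param cap Maximum genomes aligned pairwise (default 1000).
#' @param denominator "aligned" (default: aligned representative bases)
#'   or "genome" (total length of the first genome of the pair).
#' @param k,max_gap Passed to \code{\link{alignToRepresentative}}.
#' @return data.frame: genome_a, genome_b, n_snvs, aligned_bp,
#'   density_per_kb, type_pair, continent_pair; or NULL when gated out.
#' @export
pairwiseSnvDensity <- function(gs, clusters, species_id,
                               min_completeness = 90, min_genomes = 10,
                               cap = 1000, denominator = c("aligned",
                                                           "genome"),
                               k = 19, max_gap = 2000) {
  denominator <- match.arg(denominator)
  md <- genomeMeta(gs)
  mem <- clusterMembers(clusters, species_id)
  cmp <- md$completeness[match(mem, md$genome_id)]
  mem <- mem[cmp >= min_completeness]
  if (length(mem) < min_genomes) {
    message("species ", species_id, " skipped: ", length(mem),
            " near-complete genomes < ", min_genomes)
    return(NULL)
  }
  if (length(mem) > cap) {
    rank_tab <- .genome_ranks(gs)
    mem <- .order_by_rank(mem, rank_tab)[seq_len(cap)]
  }
  mem <- sort(mem)
  pairs <- utils::combn(mem, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    blocks <- alignToRepresentative(gs, gs, member_id = b,
                                    representative_id = a,
                                    k = k, max_gap = max_gap)
    sn <- callSnvs(blocks)
    aligned <- sum(blocks$n_match) + sum(vapply(blocks$subs, nrow,
                                                integer(1)))
    denom <- if (denominator == "aligned") aligned else
      sum(md$length[match(a, md$genome_id)])
    ta <- md$genome_type[match(a, md$genome_id)]
    tb <- md$genome_type[match(b, md$genome_id)]
    ca <- md$continent[match(a, md$genome_id)]
    cb <- md$continent[match(b, md$genome_id)]
    data.frame(genome_a = a, genome_b = b, n_snvs = nrow(sn),
               aligned_bp = aligned,
               density_per_kb = if (denom > 0) nrow(sn) / (denom / 1000)
                                else NA_real_,
               type_pair = paste(sort(c(ta, tb)), collapse = "-"),
               continent_pair = if (ca == cb) "within" else "between",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
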