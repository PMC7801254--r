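#' Simulation configuration for a synthetic genome collection
#'
#' Defines the statistical structure of a synthetic gut-genome collection:
#' several species whose ancestral genomes are separated by more than 5\%
#' nucleotide divergence (so inter-species ANI stays below the 95\%
#' species boundary), conspecific genomes derived by point mutation at a
#' controlled SNV rate, contig fragmentation, assembly incompleteness
#' (block deletions at contig boundaries), optional cross-species
#' contamination by whole foreign contigs, isolate/MAG labels and
#' continent-stratified sample assignment.
#'
#' @param n_species Number of species (default 5).
#' @param genomes_per_species Length-2 integer (min, max) genomes per
#'   species, sampled uniformly (default c(10, 15)).
#' @param genome_length Ancestral genome length in bp (default 100000).
#' @param interspecies_divergence Per-species substitution fraction from a
#'   shared root; must exceed 0.05 so that every inter-species pair falls
#'   below 95\% ANI (default 0.10).
#' @param intraspecies_snv_rate Substitutions per bp per conspecific
#'   genome (default 0.002).
#' @param n_core_genes,n_accessory_genes Gene families per species
#'   (defaults 25 and 15).
#' @param accessory_presence_prob Per-genome carriage probability of each
#'   accessory family (default 0.3).
#' @param incompleteness_range Deleted genome fraction, sampled uniformly
#'   from this interval; must lie in [0, 0.5) (default c(0, 0.2)).
#' @param contamination_prob Probability a genome receives foreign contigs
#'   (default 0).
#' @param contamination_fraction Foreign sequence length as a fraction of
#'   genome length (default 0.03).
#' @param isolate_fraction Fraction of genomes labeled isolate
#'   (default 0.2).
#' @param continents Named numeric vector of continent sampling weights.
#' @param study_set Study set label for the metadata (default "SYN1").
#' @param seed Integer RNG seed; a fixed seed makes generation
#'   byte-reproducible.
#' @return Object of class \code{simulation_config} (a validated list).
#' @export
simulationConfig <- function(n_species = 5,
                             genomes_per_species = c(10, 15),
                             genome_length = 100000,
                             interspecies_divergence = 0.10,
                             intraspecies_snv_rate = 0.002,
                             n_core_genes = 25,
                             n_accessory_genes = 15,
                             accessory_presence_prob = 0.3,
                             incompleteness_range = c(0, 0.2),
                             contamination_prob = 0,
                             contamination_fraction = 0.03,
                             isolate_fraction = 0.2,
                             continents = c(Africa = 1, Asia = 2, Europe = 3,
                                            `North America` = 3,
                                            `South America` = 1, Oceania = 1),
                             study_set = "SYN1",
                             seed = 1) {
  cfg <- list(n_species = as.integer(n_species),
              genomes_per_species = as.integer(rep(genomes_per_species,
                                                   length.out = 2)),
              genome_length = as.integer(genome_length),
              interspecies_divergence = interspecies_divergence,
              intraspecies_snv_rate = intraspecies_snv_rate,
              n_core_genes = as.integer(n_core_genes),
              n_accessory_genes = as.integer(n_accessory_genes),
              accessory_presence_prob = accessory_presence_prob,
              incompleteness_range = incompleteness_range,
              contamination_prob = contamination_prob,
              contamination_fraction = contamination_fraction,
              isolate_fraction = isolate_fraction,
              continents = continents,
              study_set = study_set,
              seed = as.integer(seed))
  fr <- c(cfg$intraspecies_snv_rate, cfg$accessory_presence_prob,
          cfg$incompleteness_range, cfg$contamination_prob,
          cfg$contamination_fraction, cfg$isolate_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$interspecies_divergence <= 0.05)
    stop("interspecies_divergence must exceed 0.05: smaller values imply ",
         "inter-species ANI >= 95% and violate species separability")
  if (cfg$incompleteness_range[2] >= 0.5 || cfg$incompleteness_range[1] < 0)
    stop("incompleteness_range must lie in [0, 0.5)")
  if (cfg$n_species < 1 || any(cfg$genomes_per_species < 1))
    stop("need at least one species and one genome per species")
  class(cfg) <- "simulation_config"
  cfg
}

.random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# substitute at `pos` with random different bases; returns list(seq, alt)
.mutate_seq <- function(chars, pos) {
  if (!length(pos)) return(list(chars = chars, alt = character(0)))
  bases <- c("A", "C", "G", "T")
  ref <- chars[pos]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  chars[pos] <- alt
  list(chars = chars, alt = unname(alt))
}

#' Generate a synthetic genome collection with planted ground truth
#'
#' Per species, one ancestral sequence is derived from a shared root by
#' substitution at \code{interspecies_divergence}; conspecific genomes are
#' derived from the ancestor by point mutation at
#' \code{intraspecies_snv_rate} (each planted substitution is recorded
#' with its carrier), fragmented into contigs, degraded by deleting a
#' contiguous block at a contig boundary (the deleted fraction is recorded
#' and sets the completeness metadata), and optionally contaminated with
#' whole contigs from another species. Samples are assigned continents
#' i.i.d. with the configured weights; one sample may contain genomes of
#' several species.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return List with \code{genomes} (a \code{\link{GenomeSet}}) and
#'   \code{truth} (class \code{synthetic_truth}): species labels per
#'   genome, planted SNVs (ancestral coordinates, carriers, survival
#'   after deletion), per-genome contig-to-ancestor interval maps,
#'   per-genome gene-family presence, true deleted and contamination
#'   fractions, and the ancestral sequences.
#' @export
generateCollection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$genome_length
  bases <- c("A", "C", "G", "T")

  root <- strsplit(.random_dna(L), "")[[1]]
  sp_ids <- sprintf("species_%02d", seq_len(config$n_species))

  ancestors <- list()
  for (sp in sp_ids) {
    n_mut <- round(config$interspecies_divergence * L)
    pos <- sort(sample.int(L, n_mut))
    ancestors[[sp]] <- .mutate_seq(root, pos)$chars
  }

  gp <- seq.int(config$genomes_per_species[1], config$genomes_per_species[2])
  n_per <- if (length(gp) == 1) rep(gp, config$n_species) else
    sample(gp, config$n_species, replace = TRUE)
  n_total <- sum(n_per)
  gids <- sprintf("GUT_GENOME%05d", seq_len(n_total))

  # samples: one continent per sample, i.i.d. with configured weights
  n_samples <- max(3L, ceiling(n_total * 0.6))
  cont_names <- names(config$continents)
  sample_cont <- sample(cont_names, n_samples, replace = TRUE,
                        prob = config$continents / sum(config$continents))
  sample_ids <- sprintf("SAMPLE%04d", seq_len(n_samples))

  seqs <- list()
  md_rows <- list()
  snv_list <- list()
  contig_rows <- list()
  gene_presence <- list()
  truth_gen <- list()

  gi <- 0L
  for (si in seq_along(sp_ids)) {
    sp <- sp_ids[si]
    anc <- ancestors[[sp]]
    fam_core <- sprintf("%s_core%03d", sp, seq_len(config$n_core_genes))
    fam_acc <- sprintf("%s_acc%03d", sp, seq_len(config$n_accessory_genes))
    for (g in seq_len(n_per[si])) {
      gi <- gi + 1L
      gid <- gids[gi]

      # plant intraspecies substitutions
      n_mut <- stats::rbinom(1, L, config$intraspecies_snv_rate)
      pos <- sort(sample.int(L, n_mut))
      mut <- .mutate_seq(anc, pos)
      chars <- mut$chars
      if (n_mut > 0)
        snv_list[[length(snv_list) + 1L]] <-
          data.frame(species = sp, genome_id = gid, pos = pos,
                     ref = anc[pos], alt = mut$alt,
                     stringsAsFactors = FALSE)

      # fragment into contigs (random proportions, min ~2 kb)
      n_ctg <- sample(4:8, 1)
      w <- stats::runif(n_ctg, 0.5, 1.5)
      cuts <- round(L * cumsum(w) / sum(w))
      starts <- c(1L, utils::head(cuts, -1) + 1L)
      ends <- cuts
      keep <- ends - starts + 1 >= 500
      starts <- starts[keep]; ends <- ends[keep]; ends[length(ends)] <- L

      # deletion: contiguous block at the tail contig boundary
      del_frac <- stats::runif(1, config$incompleteness_range[1],
                               config$incompleteness_range[2])
      del_len <- round(del_frac * L)
      while (del_len > 0 && length(starts) > 1 &&
             (tail_len <- ends[length(ends)] - starts[length(starts)] + 1)
             <= del_len) {
        del_len <- del_len - tail_len
        starts <- starts[-length(starts)]; ends <- ends[-length(ends)]
      }
      if (del_len > 0)
        ends[length(ends)] <- ends[length(ends)] - del_len
      retained <- sum(ends - starts + 1)
      true_del <- 1 - retained / L

      contigs <- vapply(seq_along(starts), function(i)
        paste(chars[starts[i]:ends[i]], collapse = ""), character(1))
      ctg_ids <- sprintf("%s_%d", gid, seq_along(contigs))
      contig_rows[[length(contig_rows) + 1L]] <-
        data.frame(genome_id = gid, contig_id = ctg_ids,
                   anc_start = starts, anc_end = ends,
                   foreign = FALSE, stringsAsFactors = FALSE)

      # contamination: whole contigs from another species' ancestor
      contam_frac <- 0
      if (config$n_species > 1 &&
          stats::runif(1) < config$contamination_prob) {
        src <- sample(setdiff(sp_ids, sp), 1)
        clen <- round(config$contamination_fraction * L)
        cstart <- sample.int(L - clen, 1)
        cseq <- paste(ancestors[[src]][cstart:(cstart + clen - 1)],
                      collapse = "")
        cid <- sprintf("%s_%d", gid, length(contigs) + 1L)
        contigs <- c(contigs, cseq)
        ctg_ids <- c(ctg_ids, cid)
        contam_frac <- clen / (retained + clen)
        contig_rows[[length(contig_rows) + 1L]] <-
          data.frame(genome_id = gid, contig_id = cid,
                     anc_start = NA_integer_, anc_end = NA_integer_,
                     foreign = TRUE, stringsAsFactors = FALSE)
      }

      dss <- Biostrings::DNAStringSet(contigs)
      names(dss) <- ctg_ids
      seqs[[gid]] <- dss

      is_isolate <- stats::runif(1) < config$isolate_fraction
      smp <- sample(sample_ids, 1)
      continent <- sample_cont[match(smp, sample_ids)]
      if (is_isolate) {
        rna <- c(1L, 1L, 1L); ntrna <- 20L
      } else {
        rna <- stats::rbinom(3, 1, 0.3); ntrna <- sample(10:20, 1)
      }
      lens <- nchar(contigs)
      md_rows[[gi]] <- data.frame(
        genome_id = gid, study_set = config$study_set,
        genome_type = if (is_isolate) "isolate" else "MAG",
        sample_id = smp,
        country = paste0(gsub(" ", "", continent), "_country"),
        continent = continent,
        completeness = round(100 * (1 - true_del), 2),
        contamination = round(100 * contam_frac, 2),
        n_5S = rna[1], n_16S = rna[2], n_23S = rna[3], n_tRNA = ntrna,
        length = sum(lens), n50 = .n50(lens), n_contigs = length(lens),
        stringsAsFactors = FALSE)

      gene_presence[[gid]] <- c(fam_core,
                                fam_acc[stats::runif(length(fam_acc)) <
                                        config$accessory_presence_prob])
      truth_gen[[gid]] <- list(species = sp, deleted_fraction = true_del,
                               contamination_fraction = contam_frac)
    }
  }

  md <- S4Vectors::DataFrame(do.call(rbind, md_rows))
  gs <- new("GenomeSet", sequences = seqs, metadata = md)

  snvs <- if (length(snv_list)) do.call(rbind, snv_list) else
    data.frame(species = character(0), genome_id = character(0),
               pos = integer(0), ref = character(0), alt = character(0))
  cmap <- do.call(rbind, contig_rows)
  # survival: substitution retained iff its position lies in a kept contig
  if (nrow(snvs)) {
    snvs$survived <- vapply(seq_len(nrow(snvs)), function(i) {
      m <- cmap[cmap$genome_id == snvs$genome_id[i] & !cmap$foreign, ]
      any(snvs$pos[i] >= m$anc_start & snvs$pos[i] <= m$anc_end)
    }, logical(1))
  } else snvs$survived <- logical(0)

  truth <- list(
    species_of = vapply(truth_gen, `[[`, character(1), "species"),
    snvs = snvs,
    contig_map = cmap,
    gene_presence = gene_presence,
    deleted_fraction = vapply(truth_gen, `[[`, numeric(1),
                              "deleted_fraction"),
    contamination_fraction = vapply(truth_gen, `[[`, numeric(1),
                                    "contamination_fraction"),
    ancestors = vapply(ancestors, paste, character(1), collapse = ""),
    config = config)
  class(truth) <- "synthetic_truth"
  list(genomes = gs, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$species_of), "genomes,",
      length(unique(x$species_of)), "species,",
      sum(x$snvs$survived), "surviving planted substitutions\n")
  invisible(x)
}

.n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' Generate protein sequences for the planted gene families
#'
#' Each gene family of the synthetic collection receives a random
#' ancestral amino-acid sequence; every genome carrying the family (per
#' the planted gene-presence truth) contributes a copy mutated at
#' \code{within_family_divergence}. Families are mutually unrelated
#' (random sequences, expected pairwise identity far below 50\%).
#'
#' @param config The \code{\link{simulationConfig}} used for the collection.
#' @param truth The \code{synthetic_truth} from
#'   \code{\link{generateCollection}}.
#' @param within_family_divergence Substitution fraction within a family
#'   (default 0.02, i.e. about 98\% within-family identity).
#' @param length_range Amino-acid length range of family ancestors.
#' @return List with \code{proteins} (an \code{AAStringSet}, names
#'   "genome_id|family") and \code{mapping} (data.frame: protein_id,
#'   genome_id, family, species).
#' @export
generateProteinSet <- function(config, truth,
                               within_family_divergence = 0.02,
                               length_range = c(80, 200)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 7919L)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  fams <- sort(unique(unlist(truth$gene_presence)))
  anc <- lapply(stats::setNames(fams, fams), function(f) {
    n <- sample(seq(length_range[1], length_range[2]), 1)
    sample(aas, n, replace = TRUE)
  })
  out <- character(0); map <- list()
  for (gid in names(truth$gene_presence)) {
    for (f in truth$gene_presence[[gid]]) {
      a <- anc[[f]]
      n_mut <- stats::rbinom(1, length(a), within_family_divergence)
      if (n_mut > 0) {
        pos <- sample.int(length(a), n_mut)
        a[pos] <- vapply(a[pos], function(x) sample(setdiff(aas, x), 1),
                         character(1))
      }
      pid <- paste0(gid, "|", f)
      out[pid] <- paste(a, collapse = "")
      map[[length(map) + 1L]] <-
        data.frame(protein_id = pid, genome_id = gid, family = f,
                   species = unname(truth$species_of[gid]),
                   stringsAsFactors = FALSE)
    }
  }
  prot <- Biostrings::AAStringSet(out)
  list(proteins = prot, mapping = do.call(rbind, map))
}

#' Generate a synthetic read pileup with planted polymorphic positions
#'
#' Produces a per-position allele-count table of the kind consumed by
#' \code{\link{strainHeterogeneity}}. A planted fraction of positions is
#' polymorphic (minor allele at ~30\% frequency); the rest are
#' monoallelic. Base qualities are drawn per allele from a normal model.
#'
#' @param n_positions Number of pileup positions.
#' @param depth_distribution Either a single depth used everywhere, or a
#'   function(n) returning n integer depths.
#' @param polymorphic_fraction Fraction of positions made polymorphic.
#' @param baseq_model List with \code{mean} and \code{sd} of base
#'   qualities (default mean 35, sd 2).
#' @param seed RNG seed.
#' @return List with \code{pileup} (data.frame: pos, A, C, G, T, bq_A,
#'   bq_C, bq_G, bq_T) and \code{truth} (logical: planted polymorphic).
#' @export
generatePileup <- function(n_positions, depth_distribution = 50,
                           polymorphic_fraction = 0,
                           baseq_model = list(mean = 35, sd = 2),
                           seed = 1) {
  stopifnot(polymorphic_fraction >= 0, polymorphic_fraction <= 1)
  set.seed(seed)
  depth <- if (is.function(depth_distribution))
    as.integer(depth_distribution(n_positions))
  else rep(as.integer(depth_distribution), n_positions)
  poly <- stats::runif(n_positions) < polymorphic_fraction
  cnt <- matrix(0L, n_positions, 4, dimnames = list(NULL, c("A","C","G","T")))
  major <- sample.int(4, n_positions, replace = TRUE)
  for (i in seq_len(n_positions)) {
    if (poly[i] && depth[i] >= 2) {
      minor <- sample(setdiff(1:4, major[i]), 1)
      n_minor <- max(1L, round(0.3 * depth[i]))
      cnt[i, major[i]] <- depth[i] - n_minor
      cnt[i, minor] <- n_minor
    } else {
      cnt[i, major[i]] <- depth[i]
    }
  }
  bq <- matrix(round(stats::rnorm(4 * n_positions, baseq_model$mean,
                                  baseq_model$sd), 1),
               n_positions, 4)
  colnames(bq) <- c("bq_A", "bq_C", "bq_G", "bq_T")
  list(pileup = data.frame(pos = seq_len(n_positions), cnt, bq),
       truth = poly)
}

#' Expected SNV catalog from planted truth
#'
#' Derives, by pure bookkeeping on the planted truth (no alignment), the
#' SNV records the catalog builder should produce for one species given
#' its representative: for every ancestral position covered by the
#' representative, member alleles differing from the representative
#' allele are tallied over members whose retained contigs cover the
#' position, and alleles carried by at least two members are emitted in
#' representative coordinates.
#'
#' @param truth \code{synthetic_truth}.
#' @param species Species label in the truth.
#' @param rep_id Representative genome id (a member of the species).
#' @param member_ids Member genome ids (defaults to all genomes of the
#'   species); the representative is excluded from carrier counting.
#' @return data.frame (contig, pos, ref, alt, n_support, supporting) in
#'   1-based representative coordinates, sorted by contig and position.
#' @export
truthSnvCatalog <- function(truth, species, rep_id, member_ids = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(member_ids))
    member_ids <- names(truth$species_of)[truth$species_of == species]
  member_ids <- setdiff(member_ids, rep_id)
  anc <- strsplit(truth$ancestors[[species]], "")[[1]]
  cm <- truth$contig_map
  rep_map <- cm[cm$genome_id == rep_id & !cm$foreign, ]
  snvs <- truth$snvs[truth$snvs$species == species & truth$snvs$survived, ]

  covers <- function(gid, p) {
    m <- cm[cm$genome_id == gid & !cm$foreign, ]
    any(p >= m$anc_start & p <= m$anc_end)
  }
  rep_snv <- snvs[snvs$genome_id == rep_id, ]
  rep_allele <- function(p) {
    i <- match(p, rep_snv$pos)
    if (!is.na(i)) rep_snv$alt[i] else anc[p]
  }
  # candidate positions: any planted SNV position in the species
  cand <- sort(unique(snvs$pos))
  recs <- list()
  for (p in cand) {
    # position must be covered by the representative
    ri <- which(p >= rep_map$anc_start & p <= rep_map$anc_end)
    if (!length(ri)) next
    r <- rep_allele(p)
    at_p <- snvs[snvs$pos == p & snvs$genome_id %in% member_ids, ]
    alleles <- vapply(member_ids, function(gid) {
      if (!covers(gid, p)) return(NA_character_)
      i <- which(at_p$genome_id == gid)
      if (length(i)) at_p$alt[i] else anc[p]
    }, character(1))
    alleles <- alleles[!is.na(alleles)]
    for (a in unique(alleles[alleles != r])) {
      supp <- names(alleles)[alleles == a]
      if (length(supp) >= 2)
        recs[[length(recs) + 1L]] <- data.frame(
          contig = rep_map$contig_id[ri[1]],
          pos = p - rep_map$anc_start[ri[1]] + 1L,
          ref = r, alt = a, n_support = length(supp),
          supporting = paste(sort(supp), collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), n_support = integer(0),
               supporting = character(0))
  out[order(out$contig, out$pos, out$alt), , drop = FALSE]
}
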