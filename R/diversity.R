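#' Geographic diversity of a species (Shannon index over continents)
#'
#' For each continent c, p_c is the proportion of that continent's
#' samples containing the species. The proportions over continents with
#' p_c > 0 are renormalized to sum to one and the Shannon index
#' H = -sum(p log p) is computed in natural log units (nats). H is
#' highest for species found across all continents at similar
#' proportions; a species confined to one continent has H = 0.
#'
#' @param species_samples Character vector of sample ids in which the
#'   species was found.
#' @param sample_continent_map Named character vector: sample id ->
#'   continent (every sample must be mapped).
#' @param renormalize Renormalize proportions over observed continents
#'   before the entropy (default TRUE); with FALSE the raw per-continent
#'   prevalences are used directly.
#' @return List: \code{proportions} (per continent), \code{shannon}
#'   (nats).
#' @export
geographicDiversity <- function(species_samples, sample_continent_map,
                                renormalize = TRUE) {
  species_samples <- unique(species_samples)
  if (!length(species_samples))
    stop("species absent from all samples: diversity undefined")
  if (!all(species_samples %in% names(sample_continent_map)))
    stop("unmapped sample(s): ",
         paste(setdiff(species_samples, names(sample_continent_map)),
               collapse = ", "))
  tot <- table(sample_continent_map)
  hit <- table(factor(sample_continent_map[species_samples],
                      levels = names(tot)))
  p <- as.numeric(hit) / as.numeric(tot)
  names(p) <- names(tot)
  q <- p[p > 0]
  if (renormalize) q <- q / sum(q)
  list(proportions = p, shannon = -sum(q * log(q)))
}

#' Rarefaction curve of species detected versus genomes sampled
#'
#' Expected number of distinct species as a function of the number of
#' nonredundant genomes analyzed, averaged over \code{n_reps} random
#' permutations of the genomes. With \code{exclude_singletons}, species
#' represented by only one genome in the whole input are removed before
#' permuting.
#'
#' @param species_labels Character vector: the species of each
#'   nonredundant genome.
#' @param depths Genome depths at which to evaluate (default: 1..N).
#' @param n_reps Number of permutations (default 100).
#' @param seed RNG seed (mandatory).
#' @param exclude_singletons Drop species of global frequency 1
#'   (default FALSE).
#' @return data.frame: depth, mean_species, sd_species.
#' @export
rarefactionCurve <- function(species_labels, depths = NULL, n_reps = 100,
                             seed, exclude_singletons = FALSE) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (missing(seed)) stop("seed is mandatory")
  if (exclude_singletons) {
    freq <- table(species_labels)
    species_labels <- species_labels[
      species_labels %in% names(freq)[freq > 1]]
  }
  n <- length(species_labels)
  if (is.null(depths)) depths <- seq_len(n)
  depths <- depths[depths >= 1 & depths <= n]
  set.seed(seed)
  acc <- matrix(0, n_reps, length(depths))
  for (r in seq_len(n_reps)) {
    perm <- sample(species_labels)
    # distinct species among the first d genomes, for each depth d
    first_seen <- !duplicated(perm)
    cum <- cumsum(first_seen)
    acc[r, ] <- cum[depths]
  }
  data.frame(depth = depths, mean_species = colMeans(acc),
             sd_species = apply(acc, 2, stats::sd))
}

#' Closed-form expected rarefaction curve
#'
#' Hypergeometric expectation of the number of distinct species among n
#' sampled genomes: E[S_n] = sum_s (1 - C(N - N_s, n) / C(N, n)).
#' Serves as an independent check of the permutation estimate.
#'
#' @param species_labels Character vector of species labels.
#' @param depths Depths at which to evaluate.
#' @return Numeric vector of expectations.
#' @export
rarefactionExpected <- function(species_labels, depths) {
  N <- length(species_labels)
  Ns <- table(species_labels)
  vapply(depths, function(n)
    sum(1 - exp(lchoose(N - as.numeric(Ns), n) - lchoose(N, n))),
    numeric(1))
}

#' Classification-rate improvement
#'
#' Percent improvement of the classified-read proportion of a new
#' reference database over a baseline:
#' (p_new - p_ref) / p_ref x 100. Negative values (a decrease) are
#' allowed; samples with p_ref = 0 are flagged as undefined (NA).
#'
#' @param p_new,p_ref Proportions of reads classified (vectors allowed).
#' @return Percent improvement (NA where p_ref = 0).
#' @export
classificationImprovement <- function(p_new, p_ref) {
  ifelse(p_ref > 0, (p_new - p_ref) / p_ref * 100, NA_real_)
}

#' Phylogenetic diversity of cultured versus uncultured species
#'
#' PD_total is the sum of all branch lengths; PD_cultured is the branch
#' length sum of the subtree spanning the cultured leaves (branches on
#' paths between cultured leaves); PD exclusive to uncultured species is
#' PD_total - PD_cultured. Uncultured monophyletic groups are the
#' maximal internal nodes whose descendant leaves are all uncultured.
#'
#' @param tree An \code{ape::phylo} with branch lengths.
#' @param cultured_labels Named logical/character vector over all leaf
#'   labels: TRUE/"cultured" for cultured, FALSE/"uncultured" otherwise.
#' @return List: \code{pd_total}, \code{pd_cultured}, \code{pd_exclusive},
#'   \code{uncultured_groups} (list of leaf-label vectors, maximal
#'   all-uncultured clades of size >= 2).
#' @export
phylogeneticDiversity <- function(tree, cultured_labels) {
  if (is.null(tree$edge.length)) stop("branch lengths required for PD")
  tips <- tree$tip.label
  if (!all(tips %in% names(cultured_labels)))
    stop("unlabeled leaf/leaves: ",
         paste(setdiff(tips, names(cultured_labels)), collapse = ", "))
  lab <- cultured_labels[tips]
  cultured <- if (is.logical(lab)) lab else lab %in% c("cultured", "TRUE")
  names(cultured) <- tips

  pd_total <- sum(tree$edge.length)
  ctips <- tips[cultured]
  pd_cultured <- if (length(ctips) >= 2)
    sum(ape::keep.tip(tree, ctips)$edge.length)
  else if (length(ctips) == 1)
    0  # a single leaf spans no path
  else 0

  # maximal internal nodes with exclusively uncultured descendant leaves
  ntip <- length(tips)
  groups <- list()
  if (any(!cultured) && tree$Nnode >= 1) {
    desc <- vector("list", ntip + tree$Nnode)
    for (i in seq_len(ntip)) desc[[i]] <- i
    # accumulate descendants in postorder
    eo <- ape::reorder.phylo(tree, "postorder")$edge
    for (e in seq_len(nrow(eo)))
      desc[[eo[e, 1]]] <- c(desc[[eo[e, 1]]], desc[[eo[e, 2]]])
    all_unc <- vapply(desc, function(d) all(!cultured[tips[d]]), logical(1))
    parent_of <- integer(ntip + tree$Nnode)
    parent_of[tree$edge[, 2]] <- tree$edge[, 1]
    for (node in (ntip + 1):(ntip + tree$Nnode)) {
      if (!all_unc[node]) next
      par <- parent_of[node]
      if (par == 0 || !all_unc[par])   # maximal: parent is mixed (or root)
        groups[[length(groups) + 1L]] <- tips[sort(desc[[node]])]
    }
  }
  list(pd_total = pd_total, pd_cultured = pd_cultured,
       pd_exclusive = pd_total - pd_cultured,
       uncultured_groups = groups)
}
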