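#' Run the full catalog pipeline on a (synthetic) collection
#'
#' Executes the stages end to end: simulate (or accept a supplied
#' collection) -> quality filter -> sketch -> species clustering ->
#' conspecific dereplication -> per-species pan-genome -> SNV catalogs ->
#' diversity reports; returns all tables plus a run manifest (resolved
#' config, seed, stage timings, record counts, table checksums).
#' Deterministic: re-running with the same config reproduces identical
#' checksums.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param collection Optional list(genomes, truth) to analyse instead of
#'   simulating (truth may be NULL for real data).
#' @param chunk_size Chunk size for species clustering (default Inf).
#' @param pangenome Build per-species pan-genomes (default TRUE).
#' @param snv Build per-species SNV catalogs (default TRUE).
#' @return List: genomes, truth, clusters, pangenomes (named list),
#'   snv_catalogs (named list), reports (species table, geographic
#'   diversity, rarefaction), manifest.
#' @export
runPipeline <- function(config = simulationConfig(), collection = NULL,
                        chunk_size = Inf, pangenome = TRUE, snv = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  if (is.null(collection)) collection <- generateCollection(config)
  gs <- collection$genomes
  truth <- collection$truth
  tick("simulate")

  ok <- passesQualityFilter(gs)
  if (any(!ok))
    stop("stage qc: genomes failing the quality filter: ",
         paste(genomeIds(gs)[!ok], collapse = ", "))
  tick("qc")

  sketches <- sketchCollection(gs)
  tick("sketch")

  clusters <- clusterSpecies(gs, sketches = sketches,
                             chunk_size = chunk_size, seed = config$seed)
  tick("cluster")

  clusters <- dereplicateConspecific(gs, clusters)
  clusters <- assignCulturedStatus(gs, clusters)
  tick("dereplicate")

  pangenomes <- list()
  if (pangenome && !is.null(truth)) {
    prot <- generateProteinSet(config, truth)
    genome_of <- stats::setNames(prot$mapping$genome_id,
                                 prot$mapping$protein_id)
    for (sid in speciesIds(clusters)) {
      mem <- clusterMembers(clusters, sid)
      sel <- prot$mapping$genome_id %in% mem
      if (!any(sel)) next
      pangenomes[[sid]] <- buildPangenome(
        sid, prot$proteins[prot$mapping$protein_id[sel]], genome_of)
    }
  }
  tick("pangenome")

  snv_catalogs <- list()
  if (snv) {
    md <- genomeMeta(gs)
    for (sid in speciesIds(clusters)) {
      cat_s <- buildSpeciesSnvCatalog(gs, clusters, sid)
      if (!is.null(cat_s))
        snv_catalogs[[sid]] <- tagSpecificSnvs(cat_s, md)$catalog
    }
  }
  tick("snv")

  md <- as.data.frame(genomeMeta(gs))
  sample_cont <- stats::setNames(md$continent, md$sample_id)
  sample_cont <- sample_cont[!duplicated(names(sample_cont))]
  geo <- lapply(stats::setNames(speciesIds(clusters), speciesIds(clusters)),
                function(sid) {
    smp <- unique(md$sample_id[md$genome_id %in%
                               clusterMembers(clusters, sid)])
    geographicDiversity(smp, sample_cont)
  })
  sp_tab <- as.data.frame(speciesTable(clusters))
  sp_tab$shannon <- vapply(geo[sp_tab$species_id], `[[`, numeric(1),
                           "shannon")
  nonred_labels <- unlist(lapply(speciesIds(clusters), function(sid)
    rep(sid, length(nonredundantMembers(clusters, sid)))))
  rare <- rarefactionCurve(nonred_labels, n_reps = 50, seed = config$seed)
  tick("reports")

  reports <- list(species_table = sp_tab, geographic = geo,
                  rarefaction = rare)
  manifest <- list(
    config = unclass(config), seed = config$seed,
    timings_sec = unlist(timings),
    counts = c(genomes = nGenomes(gs), species = nSpecies(clusters),
               pangenomes = length(pangenomes),
               snv_catalogs = length(snv_catalogs),
               snv_records = sum(vapply(snv_catalogs, nSnvs, integer(1)))),
    checksums = c(
      membership = .table_checksum(as.data.frame(clusters@members)),
      species = .table_checksum(sp_tab),
      snv = .table_checksum(do.call(rbind, lapply(snv_catalogs, function(x)
        as.data.frame(snvTable(x))[, c("contig", "pos", "ref", "alt")])))))
  list(genomes = gs, truth = truth, clusters = clusters,
       pangenomes = pangenomes, snv_catalogs = snv_catalogs,
       reports = reports, manifest = manifest)
}

# md5 of a table's deterministic text rendering
.table_checksum <- function(df) {
  if (is.null(df) || !nrow(df)) return("empty")
  f <- tempfile()
  on.exit(unlink(f))
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  unname(tools::md5sum(f))
}

#' Species total from per-domain counts
#'
#' Counts-only replay of the species bookkeeping: total species =
#' bacterial + archaeal species counts.
#'
#' @param bacterial,archaeal Species counts.
#' @return Total species count.
#' @export
speciesTotalFromCounts <- function(bacterial, archaeal) {
  if (bacterial < 0 || archaeal < 0) stop("counts must be nonnegative")
  bacterial + archaeal
}
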