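test_that("config validation enforces species separability and fractions", {
  expect_error(simulationConfig(interspecies_divergence = 0.04),
               "ANI >= 95")
  expect_error(simulationConfig(incompleteness_range = c(0, 0.6)),
               "incompleteness")
  expect_error(simulationConfig(isolate_fraction = 1.2), "fractions")
  expect_s3_class(simulationConfig(), "simulation_config")
})

test_that("single perfect genome equals its ancestor with empty SNV truth", {
  cfg <- simulationConfig(n_species = 1, genomes_per_species = c(1, 1),
                          genome_length = 20000, intraspecies_snv_rate = 0,
                          incompleteness_range = c(0, 0), seed = 9)
  col <- generateCollection(cfg)
  expect_equal(nGenomes(col$genomes), 1L)
  gid <- genomeIds(col$genomes)
  whole <- paste(as.character(genomeSeqs(col$genomes, gid)), collapse = "")
  expect_identical(whole, unname(col$truth$ancestors[[1]]))
  expect_equal(nrow(col$truth$snvs), 0L)
})

test_that("zero SNV rate gives genomes identical to ancestor minus deletions", {
  cfg <- simulationConfig(n_species = 2, genomes_per_species = c(3, 3),
                          genome_length = 20000, intraspecies_snv_rate = 0,
                          seed = 10)
  col <- generateCollection(cfg)
  expect_equal(nrow(col$truth$snvs), 0L)
  cm <- col$truth$contig_map
  for (gid in genomeIds(col$genomes)) {
    anc <- strsplit(col$truth$ancestors[[col$truth$species_of[[gid]]]],
                    "")[[1]]
    m <- cm[cm$genome_id == gid & !cm$foreign, ]
    seqs <- as.character(genomeSeqs(col$genomes, gid))[m$contig_id]
    for (i in seq_len(nrow(m)))
      expect_identical(seqs[[i]],
                       paste(anc[m$anc_start[i]:m$anc_end[i]],
                             collapse = ""))
  }
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- simulationConfig(n_species = 3, genomes_per_species = c(10, 10),
                          interspecies_divergence = 0.10,
                          genome_length = 15000, seed = 42)
  a <- generateCollection(cfg)
  b <- generateCollection(cfg)
  expect_identical(lapply(genomeIds(a$genomes), function(g)
    as.character(genomeSeqs(a$genomes, g))),
    lapply(genomeIds(b$genomes), function(g)
      as.character(genomeSeqs(b$genomes, g))))
  expect_identical(a$truth$snvs, b$truth$snvs)
  expect_identical(as.data.frame(genomeMeta(a$genomes)),
                   as.data.frame(genomeMeta(b$genomes)))
})

test_that("planted truth bookkeeping matches the emitted sequences", {
  col <- fixture_collection()
  truth <- col$truth
  cm <- truth$contig_map
  # every emitted genome appears exactly once in the species map
  expect_setequal(names(truth$species_of), genomeIds(col$genomes))
  # surviving substitutions are exactly those within retained contigs,
  # and the emitted base at the mapped position is the alt allele
  sn <- truth$snvs[truth$snvs$survived, ]
  sn <- sn[sample.int(nrow(sn), min(200, nrow(sn))), ]
  for (i in seq_len(nrow(sn))) {
    m <- cm[cm$genome_id == sn$genome_id[i] & !cm$foreign, ]
    hit <- which(sn$pos[i] >= m$anc_start & sn$pos[i] <= m$anc_end)
    expect_length(hit, 1)
    ctg <- as.character(genomeSeqs(col$genomes,
                                   sn$genome_id[i]))[[m$contig_id[hit]]]
    expect_identical(substr(ctg, sn$pos[i] - m$anc_start[hit] + 1,
                            sn$pos[i] - m$anc_start[hit] + 1), sn$alt[i])
  }
  # deleted fraction recorded = 1 - retained/ancestral length
  L <- truth$config$genome_length
  for (gid in genomeIds(col$genomes)) {
    m <- cm[cm$genome_id == gid & !cm$foreign, ]
    expect_equal(truth$deleted_fraction[[gid]],
                 1 - sum(m$anc_end - m$anc_start + 1) / L)
  }
})

test_that("conspecific ANI is >= 99% and inter-species ANI < 95%", {
  col <- fixture_collection()
  sp <- col$truth$species_of
  ids <- genomeIds(col$genomes)
  one <- ids[sp[ids] == "species_01"][1:2]
  r <- aniAf(col$genomes, col$genomes, query_id = one[1],
             target_id = one[2])
  expect_gte(r$ani, 99)
  other <- ids[sp[ids] == "species_02"][1]
  r2 <- aniAf(col$genomes, col$genomes, query_id = one[1],
              target_id = other)
  expect_true(is.na(r2$ani) || r2$ani < 95 || r2$af < 0.30)
})

test_that("protein families have high within- and low between-family identity", {
  cfg <- simulationConfig(n_species = 1, genomes_per_species = c(4, 4),
                          genome_length = 12000, n_core_genes = 5,
                          n_accessory_genes = 0, seed = 12)
  col <- generateCollection(cfg)
  ps <- generateProteinSet(cfg, col$truth, within_family_divergence = 0)
  # zero divergence -> all family members identical
  by_fam <- split(as.character(ps$proteins), ps$mapping$family)
  for (f in names(by_fam))
    expect_length(unique(by_fam[[f]]), 1)
  # family present in k genomes -> exactly k sequences with that label
  expect_true(all(vapply(by_fam, length, integer(1)) == 4))
  # between-family identity below 0.5 under the package's aligner
  fams <- vapply(by_fam, `[`, character(1), 1)
  cl <- clusterProteins(stats::setNames(fams, names(by_fam)),
                        identity = 0.5)
  expect_equal(length(unique(cl$cluster_id)), length(fams))
})

test_that("pileup generator honors polymorphic fraction and determinism", {
  a <- generatePileup(300, depth_distribution = 40,
                      polymorphic_fraction = 0, seed = 5)
  cnt <- as.matrix(a$pileup[, c("A", "C", "G", "T")])
  expect_true(all(rowSums(cnt > 0) == 1))          # all monoallelic
  b <- generatePileup(300, depth_distribution = 40,
                      polymorphic_fraction = 0, seed = 5)
  expect_identical(a, b)
  c1 <- generatePileup(400, depth_distribution = 60,
                       polymorphic_fraction = 0.3, seed = 6)
  est <- strainHeterogeneity(c1$pileup)
  expect_true(est$sufficient)
  expect_equal(est$heterogeneity, 100 * mean(c1$truth), tolerance = 0.02)
})
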