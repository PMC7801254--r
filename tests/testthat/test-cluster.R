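test_that("degenerate inputs: empty collection and single genome", {
  empty <- gutcatalog:::.make_cluster_set(list())
  expect_equal(nSpecies(empty), 0L)

  g <- random_genome(12000, seed = 61)
  gs <- make_genome_set(list(G1 = g))
  cl <- clusterSpecies(gs)
  expect_equal(nSpecies(cl), 1L)
  expect_equal(representativeOf(cl, speciesIds(cl)), "G1")
  expect_equal(clusterMembers(cl, speciesIds(cl)), "G1")
})

test_that("an isolate outranks a higher-scoring MAG as representative", {
  g <- random_genome(15000, seed = 62)
  gs <- make_genome_set(list(MAGA = g, ISOB = g),
                        genome_type = c("MAG", "isolate"),
                        completeness = c(95, 80), contamination = c(0, 0))
  # MAG scores 95+, isolate 80+: the isolate must still be representative
  expect_gt(representativeScore(95, 0, 15000),
            representativeScore(80, 0, 15000))
  cl <- clusterSpecies(gs)
  expect_equal(nSpecies(cl), 1L)
  expect_equal(representativeOf(cl, speciesIds(cl)), "ISOB")
})

test_that("clustering recovers planted species exactly; partition property holds", {
  col <- fixture_collection()
  cl <- clusterSpecies(col$genomes)
  mv <- membershipVector(cl)
  expect_setequal(names(mv), genomeIds(col$genomes))  # exactly one cluster each
  expect_equal(compareClusterings(mv, col$truth$species_of), 1.0)
  # representative optimality: no member outranks its representative
  md <- as.data.frame(genomeMeta(col$genomes))
  rk <- data.frame(id = md$genome_id,
                   iso = md$genome_type == "isolate",
                   score = representativeScore(md$completeness,
                                               md$contamination, md$n50))
  for (sid in speciesIds(cl)) {
    rep_id <- representativeOf(cl, sid)
    ri <- rk[rk$id == rep_id, ]
    for (m in clusterMembers(cl, sid)) {
      mi <- rk[rk$id == m, ]
      expect_false(mi$iso > ri$iso ||
                   (mi$iso == ri$iso && mi$score > ri$score))
    }
  }
})

test_that("chunked and unchunked clustering give identical partitions", {
  col <- fixture_collection()
  cl1 <- clusterSpecies(col$genomes)
  cl2 <- clusterSpecies(col$genomes, chunk_size = 6, seed = 99)
  expect_equal(compareClusterings(membershipVector(cl1),
                                  membershipVector(cl2)), 1.0)
  cl3 <- clusterSpecies(col$genomes, chunk_size = 2, seed = 7)
  expect_equal(compareClusterings(membershipVector(cl1),
                                  membershipVector(cl3)), 1.0)
})

test_that("dereplication collapses identicals and respects the 99.9% boundary", {
  g <- random_genome(30000, seed = 63)
  near <- mutate_genome(g, 3, seed = 64)$seq       # ~99.99% ANI
  far <- mutate_genome(g, 300, seed = 65)$seq      # ~99% ANI
  gs <- make_genome_set(list(G1 = g, G2 = near, G3 = far),
                        sample_id = c("s1", "s2", "s3"))
  cl <- clusterSpecies(gs)
  expect_equal(nSpecies(cl), 1L)
  cl <- dereplicateConspecific(gs, cl)
  kept <- nonredundantMembers(cl, speciesIds(cl))
  # near-identical pair collapses despite different samples; 99% pair stays
  expect_equal(length(kept), 2L)
  expect_true("G3" %in% kept)

  # same-sample uniqueness: identical sample ids collapse to one
  gs2 <- make_genome_set(list(G1 = g, G3 = far), sample_id = c("s1", "s1"))
  cl2 <- dereplicateConspecific(gs2, clusterSpecies(gs2))
  expect_equal(length(nonredundantMembers(cl2, speciesIds(cl2))), 1L)
})

test_that("intraspecies dendrogram matches a naive complete-linkage oracle", {
  # forced two-genome case: distance 0.05 -> 2 clusters at both cutoffs
  two <- list(counts = NULL)
  d2 <- matrix(c(0, 0.05, 0.05, 0), 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  hc2 <- stats::hclust(stats::as.dist(d2), method = "complete")
  expect_equal(length(unique(stats::cutree(hc2, h = 0.03))), 2)
  expect_equal(length(unique(stats::cutree(hc2, h = 0.01))), 2)

  # random 10-point matrix vs O(n^3) naive agglomeration
  naive_complete <- function(d, h) {
    n <- nrow(d); groups <- as.list(seq_len(n))
    repeat {
      if (length(groups) == 1) break
      best <- c(NA, NA); bestd <- Inf
      for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
        dd <- max(d[groups[[i]], groups[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
      if (bestd > h) break
      groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[1]]])
      groups[[best[1]]] <- NULL
    }
    lab <- integer(n)
    for (i in seq_along(groups)) lab[groups[[i]]] <- i
    lab
  }
  set.seed(88)
  n <- 10
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.08)
  d <- d + t(d)
  dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  for (h in c(0.01, 0.03, 0.05)) {
    mine <- stats::cutree(hc, h = h)
    oracle <- naive_complete(d, h)
    expect_equal(compareClusterings(unname(mine), oracle), 1.0)
  }

  # singleton species flagged with count 1 by convention
  one <- intraspeciesDendrogram(NULL, "only")
  expect_true(one$singleton)
  expect_equal(unname(one$counts), c(1L, 1L))

  # all distances zero -> one cluster at both cutoffs
  col <- fixture_collection()
  g <- random_genome(12000, seed = 66)
  gs <- make_genome_set(list(A = g, B = g, C = g))
  res <- intraspeciesDendrogram(gs, c("A", "B", "C"))
  expect_equal(unname(res$counts), c(1L, 1L))
})

test_that("cultured status follows isolate membership then external matches", {
  g <- random_genome(20000, seed = 67)
  m <- mutate_genome(g, 200, seed = 68)$seq   # ~99% ANI to g

  # isolate member -> cultured_in_collection
  gs <- make_genome_set(list(A = g, B = m), genome_type = c("MAG", "isolate"))
  cl <- assignCulturedStatus(gs, clusterSpecies(gs))
  expect_equal(unique(speciesTable(cl)$cultured_status),
               "cultured_in_collection")

  # MAG-only cluster with a full-genome external match at ~99 ANI
  gs2 <- make_genome_set(list(A = g, B = m), genome_type = c("MAG", "MAG"))
  cl2 <- assignCulturedStatus(gs2, clusterSpecies(gs2),
                              external_refs = list(ref = m))
  expect_equal(unique(speciesTable(cl2)$cultured_status),
               "cultured_external_match")

  # external match with AF below 0.30 -> uncultured
  tiny_ref <- substr(g, 1, 4000)      # covers only 20% of the genome
  cl3 <- assignCulturedStatus(gs2, clusterSpecies(gs2),
                              external_refs = list(ref = tiny_ref),
                              af_threshold = 0.30)
  st3 <- unique(speciesTable(cl3)$cultured_status)
  expect_equal(st3, "uncultured")

  # no external refs at all -> uncultured
  cl4 <- assignCulturedStatus(gs2, clusterSpecies(gs2))
  expect_equal(unique(speciesTable(cl4)$cultured_status), "uncultured")
})

test_that("ARI agrees with the pair-counting formula and mclust", {
  expect_equal(compareClusterings(c(a = 1, b = 1, c = 2),
                                  c(a = 9, b = 9, c = 4)), 1.0)
  # label invariance under permuted cluster names
  set.seed(90)
  la <- sample(3, 20, replace = TRUE)
  expect_equal(compareClusterings(la, c(7, 9, 8)[la]), 1.0)

  ari_pairs <- function(x, y) {    # brute-force over all element pairs
    n11 <- n00 <- n10 <- n01 <- 0
    n <- length(x)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      if (sx && sy) n11 <- n11 + 1
      else if (!sx && !sy) n00 <- n00 + 1
      else if (sx) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
    2 * (n11 * n00 - n10 * n01) /
      ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
  }
  for (s in 1:5) {
    set.seed(s)
    x <- sample(4, 20, replace = TRUE)
    y <- sample(3, 20, replace = TRUE)
    expect_equal(compareClusterings(x, y), ari_pairs(x, y),
                 tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(compareClusterings(x, y),
                   unname(mclust::adjustedRandIndex(x, y)),
                   tolerance = 1e-12)
  }
  expect_error(compareClusterings(c(a = 1), c(b = 1)), "universe")
})
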