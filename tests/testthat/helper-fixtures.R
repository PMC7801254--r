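# shared fixtures, generated in code and cached per test run

.fx <- new.env()

# a small 3-species collection with planted truth (deterministic)
fixture_collection <- function() {
  if (is.null(.fx$col))
    .fx$col <- generateCollection(simulationConfig(
      n_species = 3, genomes_per_species = c(5, 6),
      genome_length = 40000, seed = 4))
  .fx$col
}

random_genome <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute n_sub random positions with different bases
mutate_genome <- function(seq, n_sub, seed, region = NULL) {
  set.seed(seed)
  x <- strsplit(seq, "")[[1]]
  idx <- if (is.null(region)) seq_along(x) else region
  pos <- sort(sample(idx, n_sub))
  x[pos] <- vapply(x[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  list(seq = paste(x, collapse = ""), pos = pos)
}

revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

# minimal metadata row(s) for hand-built GenomeSets
make_meta <- function(genome_id, genome_type = "MAG", sample_id = "S1",
                      continent = "Europe", completeness = 100,
                      contamination = 0, n50 = 10000, len = 10000,
                      n_contigs = 1) {
  S4Vectors::DataFrame(
    genome_id = genome_id, study_set = "TEST", genome_type = genome_type,
    sample_id = sample_id, country = "X", continent = continent,
    completeness = completeness, contamination = contamination,
    n_5S = 1L, n_16S = 1L, n_23S = 1L, n_tRNA = 20L,
    length = len, n50 = n50, n_contigs = n_contigs)
}

make_genome_set <- function(seqs, ...) {
  seqs <- lapply(seqs, Biostrings::DNAStringSet)
  md <- make_meta(genome_id = names(seqs), ...)
  md$length <- vapply(seqs, function(x) sum(Biostrings::width(x)), numeric(1))
  md$n50 <- vapply(seqs, function(x) {
    w <- sort(Biostrings::width(x), decreasing = TRUE)
    w[which(cumsum(w) >= sum(w) / 2)[1]]
  }, numeric(1))
  md$n_contigs <- vapply(seqs, length, integer(1))
  new("GenomeSet", sequences = seqs, metadata = md)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_prot <- function(n, seed) {
  set.seed(seed)
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

mutate_prot <- function(seq, n_sub, seed) {
  set.seed(seed)
  x <- strsplit(seq, "")[[1]]
  pos <- sample(length(x), n_sub)
  x[pos] <- vapply(x[pos], function(b) sample(setdiff(.AA20, b), 1),
                   character(1))
  paste(x, collapse = "")
}

# exact canonical k-mer set of a sequence (oracle for sketch tests)
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  kmers <- substring(seq, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  rc <- vapply(kmers, revcomp, character(1))
  unique(pmin(kmers, rc))
}
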