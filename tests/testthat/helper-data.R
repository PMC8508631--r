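# shared fixtures and independent oracles for the test suite

.test_cache <- new.env(parent = emptyenv())

# a small but complete simulation reused by several module tests
small_sim <- function() {
  if (is.null(.test_cache$sim)) {
    cfg <- simulation_config(seed = 101L, genome_length = 6e4,
                             n_orthologs = 8L, n_private_genes = 3L,
                             n_ht_events = 2L,
                             ht_recipient_counts = c(1L, 2L),
                             ht_donor_side = c("other", "focal"),
                             ht_classes = c("Copia", "Gypsy"),
                             n_te_families = 1L)
    .test_cache$sim <- simulate_genomes(cfg)
  }
  .test_cache$sim
}

fixtures <- function() {
  if (is.null(.test_cache$fx)) .test_cache$fx <- fixture_suite(7L)
  .test_cache$fx
}

rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# brute-force UPGMA oracle: cluster identities recomputed from the
# original matrix as plain means over all cross-cluster tip pairs --
# an independent path from the Lance-Williams update in the package
brute_upgma_values <- function(m) {
  clusters <- lapply(rownames(m), identity)
  vals <- numeric(0)
  while (length(clusters) > 1L) {
    best <- -Inf; bi <- 0L; bj <- 0L
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        avg <- mean(m[clusters[[i]], clusters[[j]]])
        if (avg > best) { best <- avg; bi <- i; bj <- j }
      }
    }
    vals <- c(vals, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  vals
}

random_identity_matrix <- function(n) {
  m <- matrix(runif(n * n, 60, 99.5), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 100
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}

# random additive distances from a random tree with positive branch lengths
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# substitute exactly k third-codon positions of a stop-free CDS, never
# creating a stop codon; returns the mutated CDS
mutate_third_positions <- function(cds, k) {
  v <- strsplit(cds, "")[[1L]]
  ncod <- length(v) %/% 3L
  picks <- sample.int(ncod, k)
  for (ci in picks) {
    p <- 3L * ci
    for (b in sample(setdiff(c("A", "C", "G", "T"), v[p]))) {
      codon <- paste0(v[p - 2L], v[p - 1L], b)
      if (!codon %in% c("TAA", "TAG", "TGA")) { v[p] <- b; break }
    }
  }
  paste(v, collapse = "")
}

# stop-free random CDS of n codons
rcds <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  paste(sample(names(gc)[gc != "*"], n, TRUE), collapse = "")
}

# CDS pair with exactly k third-position mismatches where both members
# resolve uniquely to frame 0 (frame-ambiguous draws are resampled)
rcds_pair_unique_frame <- function(n, k) {
  repeat {
    a <- rcds(n)
    if (!identical(infer_coding_frame(a), 0L)) next
    b <- mutate_third_positions(a, k)
    if (identical(infer_coding_frame(b), 0L)) return(list(a = a, b = b))
  }
}
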