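test_that("a sequence aligned to itself gives one full-length perfect hit", {
  set.seed(1)
  a <- rdna(1000)
  h <- local_search(c(q = a), c(s = a), search_params())
  expect_equal(nrow(h), 1L)
  expect_equal(h$pident, 100)
  expect_equal(h$length, 1000L)
  expect_equal(h$qstart, 0L)
  expect_equal(h$qend, 1000L)
  expect_equal(h$strand, "+")
})

test_that("identity equals the direct substitution count on mutated copies", {
  set.seed(2)
  a <- rdna(1000)
  # 90 substitutions at near-regular interior positions: runs of matches
  # stay long enough to seed, and no end cluster can trim the optimal
  # local alignment below the full span
  pos <- 8 + round(11.07 * 0:89) + rep(c(0, 3), 45)
  v <- strsplit(a, "")[[1]]
  v[pos] <- chartr("ACGT", "CATG", v[pos])
  b <- paste(v, collapse = "")
  direct <- 100 * mean(strsplit(a, "")[[1]] == v)
  expect_equal(direct, 91.0)
  p <- search_params(min_identity = 85, min_score = 300, min_length = 300)
  h <- local_search(c(q = a), c(s = b), p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$pident, 91.0)
  expect_equal(h$length, 1000L)
})

test_that("identity thresholds are strict, as in the screening protocol", {
  set.seed(3)
  a <- rdna(1000)
  b <- mutate_to_identity(a, 89)
  base <- search_params(min_score = 300, min_length = 300)
  base$min_identity <- 88
  expect_equal(nrow(local_search(c(q = a), c(s = b), base)), 1L)
  base$min_identity <- 90
  expect_equal(nrow(local_search(c(q = a), c(s = b), base)), 0L)
})

test_that("the match-length filter drops short perfect matches", {
  set.seed(4)
  a <- rdna(400)
  h <- local_search(c(q = a), c(s = a),
                    search_params(min_score = 100, min_length = 500))
  expect_equal(nrow(h), 0L)
})

test_that("empty inputs give empty hit tables, bad characters are rejected", {
  expect_equal(nrow(local_search(character(0), c(s = "ACGT"))), 0L)
  expect_error(local_search(c(q = "ACGU"), c(s = "ACGT")), "non-nucleotide")
})

test_that("best_hit_per_species returns one best hit per genome", {
  set.seed(5)
  el <- rdna(1500)
  copy_full <- el
  copy_trunc <- substr(mutate_to_identity(el, 97), 1, 800)
  gA <- genome_set("spA", c(c1 = paste0(rdna(2000), copy_full, rdna(1000),
                                        copy_trunc, rdna(500))))
  gB <- genome_set("spB", c(c1 = rdna(4000)))
  p <- search_params(min_identity = 80, min_score = 300, min_length = 300)
  bh <- best_hit_per_species(c(el = el), list(gA, gB), p)
  expect_equal(bh$species, "spA")      # spB absent
  expect_equal(bh$identity, 100)       # full copy outranks the truncated one
  expect_equal(bh$length, 1500L)
})

test_that("raising min_identity never increases the hit count", {
  set.seed(6)
  a <- rdna(1500)
  subj <- c(s1 = mutate_to_identity(a, 96), s2 = mutate_to_identity(a, 91),
            s3 = mutate_to_identity(a, 86))
  counts <- vapply(c(80, 85, 90, 95), function(mi) {
    nrow(local_search(c(q = a), subj,
                      search_params(min_identity = mi, min_score = 100,
                                    min_length = 100)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("reverse-complementing the subject flips strand but not identity", {
  set.seed(7)
  a <- rdna(1200)
  b <- mutate_to_identity(a, 93)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  p <- search_params(min_identity = 85, min_score = 300, min_length = 300)
  h1 <- local_search(c(q = a), c(s = b), p)
  h2 <- local_search(c(q = a), c(s = rc), p)
  expect_equal(h1$strand, "+")
  expect_equal(h2$strand, "-")
  expect_equal(h2$pident, h1$pident)
  expect_equal(h2$score, h1$score)
  expect_equal(h2$length, h1$length)
})

test_that("search is symmetric at the hit level on gap-free data", {
  set.seed(8)
  a <- rdna(1000)
  b <- mutate_to_identity(a, 92)
  p <- search_params(min_identity = 85, min_score = 300, min_length = 300)
  hab <- local_search(c(x = a), c(y = b), p)
  hba <- local_search(c(y = b), c(x = a), p)
  expect_equal(hab$pident, hba$pident)
  expect_equal(hab$length, hba$length)
  expect_equal(hab$score, hba$score)
})

test_that("hit identity matches a full dynamic-programming local alignment", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  set.seed(9)
  for (target in c(86, 90, 95)) {
    a <- rdna(1500)
    b <- mutate_to_identity(a, target)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    oracle <- round(100 * sum(pa == pb & pa != "-") / length(pa), 1)
    h <- local_search(c(q = a), c(s = b),
                      search_params(min_identity = 50, min_score = 200,
                                    min_length = 200))
    expect_equal(h$pident[1], oracle)
    expect_equal(h$score[1], Biostrings::score(aln))
  }
})

test_that("single_hsp keeps only the best HSP per sequence pair", {
  set.seed(10)
  core <- rdna(800)
  q <- paste0(core, rdna(3000), substr(core, 1, 400))  # two matching blocks
  s <- paste0(rdna(500), core, rdna(500))
  p <- search_params(min_identity = 80, min_score = 100, min_length = 100,
                     single_hsp = FALSE)
  multi <- local_search(c(q = q), c(s = s), p)
  expect_gte(nrow(multi), 2L)
  p$single_hsp <- TRUE
  one <- local_search(c(q = q), c(s = s), p)
  expect_equal(nrow(one), 1L)
  expect_equal(one$score, max(multi$score))
})

test_that("genomes round-trip through FASTA", {
  set.seed(12)
  g <- genome_set("spX", c(ctg1 = rdna(500), ctg2 = rdna(300)))
  tf <- tempfile(fileext = ".fasta")
  write_fasta(g$seqs, tf)
  back <- read_genome_fasta(tf, species = "spX")
  expect_equal(as.character(back$seqs), as.character(g$seqs))
  expect_equal(back$species, "spX")
  unlink(tf)
})

test_that("hit tables round-trip to 1-based TSV", {
  set.seed(11)
  a <- rdna(600)
  h <- local_search(c(q = a), c(s = a),
                    search_params(min_score = 100, min_length = 100))
  tf <- tempfile(fileext = ".tsv")
  write_hits_tsv(h, tf)
  out <- read.delim(tf, header = FALSE, comment.char = "#")
  expect_equal(out$V5, 1L)        # 1-based qstart
  expect_equal(out$V6, 600L)
  unlink(tf)
})
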