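test_that("coding-frame inference finds the unique stop-free frame", {
  # "ATGAAACCC" repeated is stop-free in frames 0 AND 2 (GAA ACC CAT...),
  # so the ambiguity rule returns NA rather than guessing
  expect_true(is.na(infer_coding_frame(strrep("ATGAAACCC", 10))))

  # clean CDS whose shifted readings both contain stops; prefixing one
  # base moves the clean reading to frame 1
  clean <- paste0("ATG", "TTA", "ATT", "ATT", "GAC", strrep("AAA", 10))
  expect_equal(infer_coding_frame(clean), 0L)
  expect_equal(infer_coding_frame(paste0("G", clean)), 1L)
  expect_equal(infer_coding_frame(paste0("GG", clean)), 2L)

  # stops in all three frames -> unresolved
  allstop <- strrep("TAATAGTGA", 6)
  expect_true(is.na(infer_coding_frame(allstop)))

  expect_error(infer_coding_frame("ATGAAA"), "shorter")
})

test_that("a terminal stop codon does not disqualify a frame", {
  cds <- paste0("ATG", "TTA", "ATT", "ATT", "GAC", strrep("AAA", 10), "TAA")
  expect_equal(infer_coding_frame(cds), 0L)
})

test_that("third-codon identity is exact on constructed codon pairs", {
  set.seed(60)
  # 100 codons, 30 third-position mismatches, no first/second mismatches
  pr100 <- rcds_pair_unique_frame(100, 30)
  pr <- ortholog_pair(pr100$a, pr100$b)
  expect_equal(pr$n_codons, 100L)
  expect_equal(pr$third_codon_identity, 70.0)
  expect_true(pr$reliable)

  expect_equal(ortholog_pair(pr100$a, pr100$a)$third_codon_identity, 100.0)

  pr200 <- rcds_pair_unique_frame(200, 55)
  expect_equal(ortholog_pair(pr200$a, pr200$b)$third_codon_identity, 72.5)
})

test_that("third-codon identity is symmetric and flags tiny alignments", {
  set.seed(61)
  pr80 <- rcds_pair_unique_frame(80, 20)
  expect_equal(ortholog_pair(pr80$a, pr80$b)$third_codon_identity,
               ortholog_pair(pr80$b, pr80$a)$third_codon_identity)
  short_a <- rcds(9) # passes the 30 bp precondition but aligns < 10 codons
  short_b <- mutate_third_positions(short_a, 1)
  pr <- ortholog_pair(paste0(short_a, "TAA"), paste0(short_b, "TAA"))
  expect_false(pr$reliable)
  expect_true(is.na(pr$third_codon_identity))
})

test_that("reciprocal best hits enforce reciprocity", {
  set.seed(62)
  p1 <- rcds_pair_unique_frame(150, 15)
  a2 <- p1$a; b1 <- p1$b                    # b1 closest to a2
  a1 <- mutate_third_positions(b1, 45)      # a1 best-hits b1, not vice versa
  p <- search_params(min_identity = 60, min_score = 100, min_length = 0,
                     max_evalue = 1e-3)
  rbh <- reciprocal_best_hits(c(a1 = a1, a2 = a2), c(b1 = b1), p)
  expect_equal(nrow(rbh), 1L)
  expect_equal(rbh$id_a, "a2")
  expect_equal(rbh$id_b, "b1")
})

test_that("RBH on the simulator recovers orthologs and skips private genes", {
  sim <- small_sim()
  rbh <- reciprocal_best_hits(sim$cds$focal1, sim$cds$focal2)
  expect_equal(nrow(rbh), sim$config$n_orthologs)
  expect_false(any(grepl("^priv", rbh$id_a)))
  # partial matching: no CDS paired twice
  expect_false(anyDuplicated(rbh$id_a) > 0)
  expect_false(anyDuplicated(rbh$id_b) > 0)
  expect_true(all(sub("_.*$", "", rbh$id_a) == sub("_.*$", "", rbh$id_b)))
})

test_that("concatenated species identity pools matches over gene lengths", {
  set.seed(63)
  lens <- c(100L, 150L, 250L)
  mism <- c(40L, 45L, 50L)
  prs <- Map(rcds_pair_unique_frame, lens, mism)
  cds_sets <- list(
    A = setNames(vapply(prs, `[[`, "", "a"), paste0("g", 1:3, "_A")),
    B = setNames(vapply(prs, `[[`, "", "b"), paste0("g", 1:3, "_B")))
  p <- search_params(min_identity = 50, min_score = 100, min_length = 0,
                     max_evalue = 1e-3)
  sm <- species_matrix(cds_sets, params = p)
  pooled <- round(100 * (sum(lens) - sum(mism)) / sum(lens), 1)
  expect_equal(sm$identity["A", "B"], pooled)
  expect_equal(sm$n_orthologs["A", "B"], 3L)
  expect_equal(sort(sm$per_gene[["A|B"]]),
               sort(round(100 * (lens - mism) / lens, 1)))
  expect_equal(diag(sm$identity), c(A = 100, B = 100))
})

test_that("species tree from concatenated third codons recovers topology", {
  sim <- small_sim()
  sp <- c("focal1", "focal2", "other4", "other6")
  aln <- concat_third_codon_alignment(sim$cds[sp], reference = "focal1")
  expect_true(all(rownames(aln) == sp))
  set.seed(64)
  st <- species_tree_upgma(aln, bootstraps = 30)
  # programmed: (focal1,focal2) cherry; other6 outermost
  nv <- node_values(st$tree)
  expect_length(nv, 3L)
  expect_equal(st$identity["focal1", "focal2"],
               max(st$identity[upper.tri(st$identity)]))
  cher <- ape::extract.clade(st$tree$phylo,
                             ape::getMRCA(st$tree$phylo,
                                          c("focal1", "focal2")))
  expect_setequal(cher$tip.label, c("focal1", "focal2"))
  expect_true(all(st$support$node.label >= 0))
  # realized pairwise identity tracks the programmed species distances
  prog <- sim$truth$programmed_identity[sp, sp]
  expect_lt(max(abs(st$identity - prog)), 2.5)
})

test_that("a two-species tree has a single node at the pair identity", {
  aln <- rbind(A = strsplit(strrep("ACGTT", 20), "")[[1]],
               B = strsplit(strrep("ACGTA", 20), "")[[1]])
  st <- species_tree_upgma(aln, bootstraps = 0)
  expect_equal(node_values(st$tree), 80)
})
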