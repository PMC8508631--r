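test_that("cross-genome screening isolates implanted and decoy regions only", {
  sim <- small_sim()
  species <- names(sim$genomes)
  focal <- sim$genomes[sim$config$focal_species]
  others <- sim$genomes[setdiff(species, sim$config$focal_species)]
  cands <- screen_candidates(focal, others, screen_config())
  expect_gt(nrow(cands$meta), 0L)
  # every candidate traces back to a truth insert (HT or decoy); nothing
  # is invented from background sequence
  ins <- sim$truth$inserts
  for (i in seq_len(nrow(cands$meta))) {
    m <- cands$meta[i, ]
    ov <- ins[ins$species == m$source_species & ins$contig == m$contig &
              ins$start <= m$end & ins$end >= m$start + 1L, ]
    expect_gt(nrow(ov), 0L)
  }
})

test_that("conserved decoys are labeled and removed, HT candidates retained", {
  sim <- small_sim()
  focal <- sim$genomes[sim$config$focal_species]
  others <- sim$genomes[setdiff(names(sim$genomes),
                                sim$config$focal_species)]
  cands <- screen_candidates(focal, others, screen_config())
  fl <- filter_conserved(cands, sim$decoy_library, screen_config())
  expect_gt(nrow(fl$removed$meta), 0L)
  expect_true(all(fl$removed$meta$conserved_label %in%
                  c("organelle", "ribosomal", "conserved_gene")))
  expect_true(all(fl$kept$meta$conserved_label == "none"))
  # everything kept overlaps an implanted HT sequence
  ins <- sim$truth$inserts[startsWith(sim$truth$inserts$type, "ht"), ]
  for (i in seq_len(nrow(fl$kept$meta))) {
    m <- fl$kept$meta[i, ]
    ov <- ins[ins$species == m$source_species & ins$contig == m$contig &
              ins$start <= m$end & ins$end >= m$start + 1L, ]
    expect_gt(nrow(ov), 0L)
  }
})

test_that("an empty decoy library passes candidates through with a warning", {
  sim <- small_sim()
  focal <- sim$genomes[sim$config$focal_species]
  others <- sim$genomes[setdiff(names(sim$genomes),
                                sim$config$focal_species)]
  cands <- screen_candidates(focal, others, screen_config())
  expect_warning(fl <- filter_conserved(cands, character(0)), "empty decoy")
  expect_equal(nrow(fl$kept$meta), nrow(cands$meta))
})

test_that("a candidate at 85% identity to a conserved-gene decoy is removed", {
  set.seed(70)
  decoy <- rdna(800)
  cand_seq <- mutate_to_identity(decoy, 85)
  cands <- horizTE:::new_candidates(
    data.frame(cand_id = "c1", source_species = "x", partner_species = "y",
               contig = "ctg", start = 0L, end = 800L, identity = 95,
               score = 700L, conserved_label = "none",
               stringsAsFactors = FALSE),
    c(c1 = cand_seq))
  fl <- filter_conserved(cands, c("conserved_gene|gene1" = decoy),
                         screen_config())
  expect_equal(nrow(fl$kept$meta), 0L)
  expect_equal(fl$removed$meta$conserved_label, "conserved_gene")
})

test_that("redundancy collapse is single linkage over the >90% hit graph", {
  set.seed(71)
  B <- rdna(2000)
  A <- mutate_to_identity(B, 92)
  C <- mutate_to_identity(B, 92)   # A~C about 85: linked only through B
  ab <- 100 * mean(strsplit(A, "")[[1]] == strsplit(C, "")[[1]])
  expect_lt(ab, 90)
  unrelated <- rdna(2000)
  meta <- data.frame(cand_id = c("A", "B", "C", "U"),
                     source_species = "x", partner_species = "y",
                     contig = "ctg", start = 0L, end = 2000L,
                     identity = 95, score = 1500L, conserved_label = "none",
                     stringsAsFactors = FALSE)
  cands <- horizTE:::new_candidates(meta, c(A = A, B = B, C = C,
                                            U = unrelated))
  ev <- collapse_redundant(cands, screen_config())
  expect_length(ev, 2L)     # {A,B,C} via the chain, {U} alone
  sizes <- sort(unname(vapply(ev, function(e) length(e$members), 0L)))
  expect_equal(sizes, c(1L, 3L))
})

test_that("mutually distinct candidates stay distinct events", {
  set.seed(72)
  meta <- data.frame(cand_id = c("A", "B"), source_species = "x",
                     partner_species = "y", contig = "ctg", start = 0L,
                     end = 1500L, identity = 95, score = 1000L,
                     conserved_label = "none", stringsAsFactors = FALSE)
  cands <- horizTE:::new_candidates(meta, c(A = rdna(1500), B = rdna(1500)))
  ev <- collapse_redundant(cands, screen_config())
  expect_length(ev, 2L)
})

test_that("event expansion applies the scan and retention thresholds", {
  set.seed(73)
  el <- rdna(2500)
  g_self <- genome_set("src", c(c1 = paste0(rdna(3000), el, rdna(3000))))
  g_hi <- genome_set("hi", c(c1 = paste0(rdna(1000),
                                         mutate_to_identity(el, 94),
                                         rdna(1000))))
  g_mid <- genome_set("mid", c(c1 = paste0(rdna(1000),
                                           mutate_to_identity(el, 89),
                                           rdna(1000))))
  g_none <- genome_set("none", c(c1 = rdna(6000)))
  ev <- horizTE:::new_ht_event("Src_HT-1", c(el = el), "src")
  exp_ev <- expand_event(ev, list(g_self, g_hi, g_mid, g_none),
                         screen_config())
  ps <- exp_ev$per_species
  expect_setequal(ps$species, c("src", "hi", "mid"))   # scan records > 88
  expect_equal(ps$identity[ps$species == "src"], 100)
  expect_true(ps$retained[ps$species == "hi"])
  expect_false(ps$retained[ps$species == "mid"])        # 89 < retention 90
  # raising the retention threshold never adds species
  cfg95 <- screen_config(retention_identity = 95)
  exp95 <- expand_event(ev, list(g_self, g_hi, g_mid, g_none), cfg95)
  expect_lte(sum(exp95$per_species$retained), sum(ps$retained))
})

test_that("batch expansion equals per-event expansion", {
  sim <- small_sim()
  cfg <- screen_config()
  focal <- sim$genomes[sim$config$focal_species]
  others <- sim$genomes[setdiff(names(sim$genomes),
                                sim$config$focal_species)]
  cands <- screen_candidates(focal, others, cfg)
  kept <- filter_conserved(cands, sim$decoy_library, cfg)$kept
  events <- collapse_redundant(kept, cfg)
  batch <- expand_events(events, sim$genomes, cfg)
  for (id in names(batch)) {
    single <- expand_event(events[[id]], sim$genomes, cfg)
    expect_equal(batch[[id]]$per_species, single$per_species)
  }
})

test_that("identity histogram bins are half-open with a closed top bin", {
  ev <- horizTE:::new_ht_event("X_HT-1", c(e = strrep("ACGT", 100)), "a")
  ev$per_species <- data.frame(
    species = c("a", "b", "c", "d"), sseqid = "c", identity = c(100, 91.2, 91.8, 95.1),
    score = 1L, length = 1L, sstart = 0L, send = 1L, strand = "+",
    retained = TRUE, stringsAsFactors = FALSE)
  h <- event_identity_histogram(list(ev), bin_width = 1)
  expect_equal(h$count[h$bin_lo == 91], 2L)
  expect_equal(h$count[h$bin_lo == 95], 1L)
  expect_equal(sum(h$count), 3L)       # self entry dropped
  h2 <- event_identity_histogram(list(ev), bin_width = 1, drop_self = FALSE)
  expect_equal(sum(h2$count), 4L)
  expect_equal(h2$count[h2$bin_lo == 99], 1L)  # identity 100 in closed top bin
  expect_equal(nrow(event_identity_histogram(list())), 0L)
})

test_that("TE classification labels events from a reference library", {
  sim <- small_sim()
  tr <- sim$truth$ht_events
  el <- sim$truth$ancestors[[paste0(tr$family[1], "_element")]]
  ev <- horizTE:::new_ht_event("X_HT-1", c(e = el), "a")
  ev <- classify_te(list(`X_HT-1` = ev), sim$te_library)
  expect_equal(ev[["X_HT-1"]]$te_class, tr$te_class[1])
})

test_that("conserved filtering before or after collapse gives the same events", {
  sim <- small_sim()
  cfg <- screen_config()
  focal <- sim$genomes[sim$config$focal_species]
  others <- sim$genomes[setdiff(names(sim$genomes),
                                sim$config$focal_species)]
  cands <- screen_candidates(focal, others, cfg)
  # route A: filter then collapse
  evA <- collapse_redundant(filter_conserved(cands, sim$decoy_library,
                                             cfg)$kept, cfg)
  # route B: collapse, then drop events whose element matches a decoy
  evB_all <- collapse_redundant(cands, cfg)
  elcands <- horizTE:::new_candidates(
    data.frame(cand_id = names(evB_all),
               source_species = vapply(evB_all, function(e) e$element_source, ""),
               partner_species = "", contig = "", start = 0L, end = 0L,
               identity = 0, score = 0L, conserved_label = "none",
               stringsAsFactors = FALSE),
    setNames(vapply(evB_all, function(e) unname(e$element), ""),
             names(evB_all)))
  evB <- filter_conserved(elcands, sim$decoy_library, cfg)
  expect_equal(length(evA), sum(evB$kept$meta$conserved_label == "none"))
})
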