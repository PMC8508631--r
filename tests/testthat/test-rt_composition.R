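# shared RT scaffolding: a superfamily core, family variants, and a
# profile built from them
rt_setup <- function(seed = 90) {
  set.seed(seed)
  core <- horizTE:::rand_protein(92L)
  fams <- vapply(1:6, function(i) horizTE:::mutate_protein(core, 0.15), "")
  names(fams) <- paste0("fam", 1:6, "|Copia|ref")
  list(core = core, fams = fams,
       profile = build_profile(Biostrings::AAStringSet(fams)))
}

test_that("profile scoring separates true RT from shuffled sequence", {
  s <- rt_setup()
  true_score <- profile_score(s$profile, s$fams[[1]])
  set.seed(91)
  shuf <- paste(sample(strsplit(s$fams[[1]], "")[[1]]), collapse = "")
  expect_gt(true_score, profile_score(s$profile, shuf))
  expect_gt(true_score, s$profile$threshold)
})

test_that("a single-residue column scores that residue maximally", {
  aligned <- Biostrings::AAStringSet(rep(strrep("A", 100), 6))
  prof <- build_profile(aligned)
  col <- prof$pssm[, 1]
  expect_equal(names(which.max(col)), "A")
})

test_that("profiles need at least 92 informative columns", {
  short <- Biostrings::AAStringSet(rep(strrep("A", 50), 6))
  expect_error(build_profile(short), "92")
})

test_that("extract_rt finds implanted RT domains on both strands only", {
  s <- rt_setup()
  rt_nt <- horizTE:::reverse_translate(s$fams[[2]])
  el_fwd <- paste0(horizTE:::rand_dna(700), rt_nt, horizTE:::rand_dna(500))
  el_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(el_fwd)))
  truncated <- horizTE:::rand_dna(1400)     # element without an RT domain
  g <- genome_set("sp", c(
    c1 = paste0(horizTE:::rand_dna(2000), el_fwd, horizTE:::rand_dna(1000),
                truncated, horizTE:::rand_dna(500)),
    c2 = paste0(horizTE:::rand_dna(800), el_rev, horizTE:::rand_dna(800))))
  rts <- extract_rt(g, s$profile)
  expect_equal(nrow(rts), 2L)
  expect_setequal(rts$strand, c("+", "-"))
  # reported nt spans re-translate to the reported aa windows
  for (i in seq_len(nrow(rts))) {
    nt <- rts$nt[i]
    if (rts$strand[i] == "-")
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    expect_equal(horizTE:::translate_cds(nt), rts$aa[i])
  }
  # a genome without TEs yields nothing
  g0 <- genome_set("none", c(c1 = horizTE:::rand_dna(5000)))
  expect_equal(nrow(extract_rt(g0, s$profile)), 0L)
})

test_that("family classification assigns the best reference, ties go lexicographic", {
  s <- rt_setup()
  rt_nt <- horizTE:::reverse_translate(s$fams[[3]])
  g <- genome_set("sp", c(c1 = paste0(horizTE:::rand_dna(500), rt_nt,
                                      horizTE:::rand_dna(500))))
  rts <- extract_rt(g, s$profile)
  rts <- classify_family(rts, s$fams)
  expect_equal(rts$family, "fam3")
  expect_equal(rts$superfamily, "Copia")
  # exact tie between two identical references
  tie_ref <- c("famB|Copia|x" = s$fams[[3]], "famA|Copia|x" = s$fams[[3]])
  expect_message(rts2 <- classify_family(rts, tie_ref), "tie")
  expect_equal(rts2$family, "famA")
})

test_that("HT flagging marks RT domains inside event elements", {
  s <- rt_setup()
  rt_nt <- horizTE:::reverse_translate(s$fams[[4]])
  element <- paste0(horizTE:::rand_dna(400), rt_nt, horizTE:::rand_dna(300))
  native_nt <- horizTE:::reverse_translate(s$fams[[5]])
  g <- genome_set("sp", c(
    c1 = paste0(horizTE:::rand_dna(500), element, horizTE:::rand_dna(800),
                horizTE:::rand_dna(300), native_nt,
                horizTE:::rand_dna(500))))
  rts <- extract_rt(g, s$profile)
  expect_equal(nrow(rts), 2L)
  ev <- horizTE:::new_ht_event("E_HT-1", c(el = element), "sp")
  flagged <- flag_ht(rts, list(`E_HT-1` = ev))
  expect_equal(sum(flagged$ht_flag), 1L)
  # the flagged domain is the one inside the element
  hit <- flagged[flagged$ht_flag, ]
  expect_true(grepl(hit$nt, element, fixed = TRUE))
  # zero events -> no flags
  expect_equal(sum(flag_ht(rts, list())$ht_flag), 0L)
})

test_that("composition report counts, splits and rounds correctly", {
  rts <- structure(data.frame(
    species = rep(c("v1", "v2"), c(100, 40)),
    contig = "c", start = 0L, end = 1L, strand = "+", frame = 0L,
    score = 1, profile = "Copia", aa = "A", nt = "A",
    family = c(rep("Tork", 100), rep("CRM", 40)),
    superfamily = c(rep("Copia", 100), rep("Gypsy", 40)),
    ht_flag = c(rep(TRUE, 5), rep(FALSE, 95), rep(FALSE, 40)),
    stringsAsFactors = FALSE), class = c("rt_domains", "data.frame"))
  rep_ <- composition_report(rts)
  tork_v1 <- rep_[rep_$species == "v1" & rep_$family == "Tork", ]
  expect_equal(tork_v1$total, 100L)
  expect_equal(tork_v1$ht, 5L)
  expect_equal(tork_v1$ht_percent, 5.0)
  # absent family in a species still gets a zero row
  crm_v1 <- rep_[rep_$species == "v1" & rep_$family == "CRM", ]
  expect_equal(crm_v1$total, 0L)
  expect_equal(crm_v1$ht_percent, 0)
  # totals match the domain table, nothing double-counted
  expect_equal(sum(rep_$total), nrow(rts))
  expect_true(all(rep_$ht <= rep_$total))
})

test_that("differential proliferation shows an HT peak in burst species only", {
  fx <- fixtures()$differential_proliferation
  peaks <- logical(0)
  for (sp in names(fx$genomes)) {
    ps <- mine_paralogs(fx$probe, fx$genomes[[sp]])
    flags <- flag_members_by_truth(ps, fx$inserts)
    layers <- layered_activity_history(ps$members, flags, sp)
    peaks[sp] <- has_ht_peak(layers)
  }
  expect_true(all(peaks[fx$burst_species]))
  expect_false(peaks[[fx$quiet_species]])
})
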