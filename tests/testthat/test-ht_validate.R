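# constructed homolog trees: tips "species__k", branch lengths in
# p-distance units
tree_txt <- function(txt) ape::read.tree(text = txt)

test_that("nesting_test reads sister-clade composition on a midpoint root", {
  # recipients form a clade sister to part of the donor's copies
  t1 <- tree_txt(paste0("((R__1:0.01,R__2:0.01):0.02,",
                        "(D__1:0.05,(D__2:0.02,D__3:0.02):0.04):0.03);"))
  expect_equal(nesting_test(t1, "R"), "D")
  # interleaved tips: no monophyletic focal group
  t2 <- tree_txt("(R__1:0.05,(D__1:0.04,(R__2:0.02,D__2:0.02):0.02):0.02);")
  expect_equal(nesting_test(t2, "R"), character(0))
  # sister clade composed of two species
  t3 <- tree_txt(paste0("((A__1:0.01,A__2:0.01):0.06,",
                        "((B__1:0.02,B__2:0.02):0.02,",
                        "(C__1:0.02,C__2:0.02):0.02):0.02);"))
  expect_setequal(nesting_test(t3, "A"), c("B", "C"))
  expect_error(nesting_test(t1, "Z"), "absent")
})

test_that("mixed_branch_test detects non-monophyletic species", {
  clean <- tree_txt(paste0("((A__1:0.01,A__2:0.01):0.05,",
                           "(B__1:0.01,B__2:0.01):0.05);"))
  expect_false(mixed_branch_test(clean))
  mixed <- tree_txt(paste0("((A__1:0.01,B__1:0.012):0.05,",
                           "(A__2:0.01,(A__3:0.008,B__2:0.011):0.004):0.05);"))
  expect_true(mixed_branch_test(mixed))
})

test_that("nested_species flags species coalescing inside another's diversity", {
  # D's copies span 0.10; R's closest copy is 0.06 from a D copy
  t <- tree_txt(paste0("((D__1:0.05,D__2:0.05):0.001,",
                       "(D__3:0.01,(R__1:0.005,R__2:0.005):0.01):0.04);"))
  ns <- nested_species(t)
  expect_true("R" %in% ns$D)
  expect_false("D" %in% ns$R)
})

test_that("the donor fixture yields the correct donor and recipient", {
  fx <- fixtures()$donor_recipient
  cfg <- screen_config()
  ev <- expand_event(fx$event, fx$genomes, cfg)
  expect_true(all(ev$per_species$retained))
  hom <- gather_homologs(ev, fx$genomes)
  expect_equal(hom$donorA$n, 7L)     # 6 old copies + the element
  expect_equal(hom$recB$n, 4L)       # element + 3 burst copies
  hists <- lapply(hom, activity_history)
  expect_true(as.logical(has_activity_below(hists$donorA, 90)))
  expect_false(as.logical(has_activity_below(hists$recB, 90)))
  tr <- homolog_tree(hom)
  ra <- classify_roles(ev, hists, tr, threshold = 90)
  expect_equal(ra$role[ra$species == "donorA"], "donor")
  expect_equal(ra$role[ra$species == "recB"], "recipient")
  expect_true(attr(ra, "validated"))
})

test_that("without old activity every role is undetermined, kept via mixed branches", {
  fx <- fixtures()$undetermined
  cfg <- screen_config()
  ev <- expand_event(fx$event, fx$genomes, cfg)
  hom <- gather_homologs(ev, fx$genomes)
  hists <- lapply(hom, activity_history)
  expect_true(all(!vapply(hists, function(h)
    as.logical(has_activity_below(h, 90)), TRUE)))
  tr <- homolog_tree(hom)
  ra <- classify_roles(ev, hists, tr, threshold = 90)
  expect_true(all(ra$role == "undetermined"))
  expect_true(attr(ra, "mixed_branches"))
  expect_true(attr(ra, "validated"))
})

test_that("removing below-threshold node values flips the donor to undetermined", {
  fx <- fixtures()$donor_recipient
  cfg <- screen_config()
  ev <- expand_event(fx$event, fx$genomes, cfg)
  hom <- gather_homologs(ev, fx$genomes)
  hists <- lapply(hom, activity_history)
  tr <- homolog_tree(hom)
  # counterfactual: censor the donor's old activity
  hists$donorA$node_values <- hists$donorA$node_values[
    hists$donorA$node_values >= 90]
  ra <- classify_roles(ev, hists, tr, threshold = 90)
  expect_false(any(ra$role == "donor"))
  expect_equal(unique(ra$role), "undetermined")
})

test_that("classification is invariant to tip order of the homolog tree", {
  fx <- fixtures()$donor_recipient
  cfg <- screen_config()
  ev <- expand_event(fx$event, fx$genomes, cfg)
  hom <- gather_homologs(ev, fx$genomes)
  hists <- lapply(hom, activity_history)
  tr <- homolog_tree(hom)
  tr2 <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
    tr, rev(sort(tr$tip.label)))))
  r1 <- classify_roles(ev, hists, tr, 90)
  r2 <- classify_roles(ev, hists, tr2, 90)
  expect_equal(r1$role[order(r1$species)], r2$role[order(r2$species)])
})

test_that("multi-recipient events are summarised per donor", {
  fx <- fixtures()$multi_recipient
  cfg <- screen_config()
  ev <- expand_event(fx$event, fx$genomes, cfg)
  hom <- gather_homologs(ev, fx$genomes)
  hists <- lapply(hom, activity_history)
  tr <- homolog_tree(hom)
  ra <- classify_roles(ev, hists, tr, 90)
  expect_equal(ra$role[ra$species == "focalD"], "donor")
  expect_equal(sum(ra$role == "recipient"), 3L)
  ms <- multi_recipient_summary(list(ra))
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$n_recipients, 3L)
  expect_equal(ms$donor, "focalD")
  # pairwise-only events produce an empty table
  pair <- ra[ra$species %in% c("focalD", "rec1"), ]
  attr(pair, "event_id") <- "pair"
  expect_equal(nrow(multi_recipient_summary(list(pair))), 0L)
})

test_that("a species can never be both donor and recipient", {
  fx <- fixtures()$multi_recipient
  cfg <- screen_config()
  ev <- expand_event(fx$event, fx$genomes, cfg)
  hom <- gather_homologs(ev, fx$genomes)
  hists <- lapply(hom, activity_history)
  tr <- homolog_tree(hom)
  ra <- classify_roles(ev, hists, tr, 90)
  expect_equal(anyDuplicated(ra$species), 0L)
  expect_true(all(table(ra$species, ra$role) <= 1))
})
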