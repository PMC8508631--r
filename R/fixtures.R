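new_ht_event <- function(event_id, element, element_source,
                         te_class = "Copia") {
  structure(list(event_id = event_id,
                 element = element, element_source = element_source,
                 te_class = te_class, members = names(element),
                 per_species = NULL), class = "ht_event")
}

#' Curated small ground-truth scenarios
#'
#' Deterministic miniature data sets exercising the qualitatively distinct
#' HT configurations the validator must distinguish:
#'
#' * `donor_recipient` — the donor carries old (pre-transfer) paralogs
#'   whose mutual identity sits below the detection threshold plus the
#'   transferred element; the recipient carries only post-transfer burst
#'   copies. The donor is recoverable from activity + nesting.
#' * `undetermined` — every species carries only recent copies (all
#'   activity above threshold) but the homolog tree interleaves species,
#'   so the event validates through mixed branches with all roles
#'   undetermined.
#' * `multi_recipient` — one focal donor, three recipients of the same
#'   element.
#' * `differential_proliferation` — one TE family in four species: native
#'   copies everywhere with spread (steady) activity, plus a horizontally
#'   acquired lineage that proliferated in three species but stayed a
#'   single copy in the fourth.
#'
#' @param seed integer seed.
#' @param genome_length background length per species genome.
#' @return named list of scenarios (see Details); each scenario holds
#'   `genomes` (named list of [genome_set()]) plus scenario-specific
#'   truth fields.
#' @export
fixture_suite <- function(seed = 42L, genome_length = 4e4) {
  set.seed(seed)
  out <- list()

  build <- function(species, ins_list) {
    genomes <- list(); coords <- list()
    for (sp in species) {
      ins <- ins_list[[sp]]
      g <- assemble_genome(sp, ins, genome_length, 2L)
      genomes[[sp]] <- genome_set(sp, g$contigs)
      coords[[sp]] <- g$coords
    }
    list(genomes = genomes, inserts = do.call(rbind, unname(coords)))
  }

  # ---- donor / recipient ----
  A <- rand_dna(3000L)
  ins <- list(donorA = NULL, recB = NULL)
  for (k in 1:6)
    ins$donorA <- rbind(ins$donorA, new_insert(paste0("old", k),
                        copy_at_pairwise(A, 86.5), "ht_old_copy"))
  EL <- mutate_to_identity(A, 96)   # aged active lineage
  Ed <- copy_at_pairwise(EL, 93)
  ins$donorA <- rbind(ins$donorA, new_insert("element_donor", Ed, "ht_element"))
  Er <- copy_at_pairwise(EL, 93)
  ins$recB <- rbind(ins$recB, new_insert("element_rec", Er, "ht_element"))
  for (k in 1:3)
    ins$recB <- rbind(ins$recB, new_insert(paste0("post", k),
                      copy_at_pairwise(Er, 95), "ht_post_copy"))
  b <- build(c("donorA", "recB"), ins)
  out$donor_recipient <- list(
    genomes = b$genomes, inserts = b$inserts,
    event = new_ht_event("Don_HT-1", setNames(Ed, "element_donor"), "donorA"),
    donor = "donorA", recipients = "recB")

  # ---- undetermined (mixed branches, no old activity) ----
  E <- rand_dna(3000L)
  EA1 <- copy_at_pairwise(E, 92); EA2 <- copy_at_pairwise(E, 92)
  EB <- mutate_to_identity(EA1, 97.5)
  EC <- mutate_to_identity(EA2, 99)
  ins <- list(
    uA = rbind(new_insert("EA1", EA1, "ht_element"),
               new_insert("EA2", EA2, "ht_element"),
               new_insert("EA1c", copy_at_pairwise(EA1, 97), "ht_post_copy"),
               new_insert("EA2c", copy_at_pairwise(EA2, 97), "ht_post_copy")),
    uB = rbind(new_insert("EB", EB, "ht_element"),
               new_insert("EBc1", copy_at_pairwise(EB, 96), "ht_post_copy"),
               new_insert("EBc2", copy_at_pairwise(EB, 96), "ht_post_copy")),
    uC = rbind(new_insert("EC", EC, "ht_element"),
               new_insert("ECc1", copy_at_pairwise(EC, 96), "ht_post_copy"),
               new_insert("ECc2", copy_at_pairwise(EC, 96), "ht_post_copy")))
  b <- build(c("uA", "uB", "uC"), ins)
  out$undetermined <- list(
    genomes = b$genomes, inserts = b$inserts,
    event = new_ht_event("Ua_HT-1", setNames(EA1, "EA1"), "uA"))

  # ---- multi-recipient ----
  A2 <- rand_dna(3000L)
  ins <- list(focalD = NULL, rec1 = NULL, rec2 = NULL, rec3 = NULL)
  for (k in 1:6)
    ins$focalD <- rbind(ins$focalD, new_insert(paste0("old", k),
                        copy_at_pairwise(A2, 86.5), "ht_old_copy"))
  EL2 <- mutate_to_identity(A2, 96)
  Ed2 <- copy_at_pairwise(EL2, 93)
  ins$focalD <- rbind(ins$focalD, new_insert("element_donor", Ed2, "ht_element"))
  for (r in c("rec1", "rec2", "rec3")) {
    Err <- copy_at_pairwise(EL2, 93)
    ins[[r]] <- rbind(ins[[r]], new_insert(paste0("element_", r), Err,
                                           "ht_element"))
    for (k in 1:2)
      ins[[r]] <- rbind(ins[[r]], new_insert(paste0("post_", r, k),
                        copy_at_pairwise(Err, 95.5), "ht_post_copy"))
  }
  b <- build(c("focalD", "rec1", "rec2", "rec3"), ins)
  out$multi_recipient <- list(
    genomes = b$genomes, inserts = b$inserts,
    event = new_ht_event("Foc_HT-1", setNames(Ed2, "element_donor"), "focalD"),
    donor = "focalD", recipients = c("rec1", "rec2", "rec3"))

  # ---- differential proliferation (one family, native + HT layers) ----
  AF <- rand_dna(3000L)
  Eht <- copy_at_pairwise(AF, 90)      # the horizontally acquired lineage
  spread <- c(85, 87, 89, 91, 93, 93)
  ins <- list()
  for (sp in c("s1", "s2", "s3", "s4")) {
    native <- NULL
    for (k in seq_along(spread))
      native <- rbind(native, new_insert(sprintf("nat_%s_%d", sp, k),
                      copy_at_pairwise(AF, spread[k]), "native_te"))
    ins[[sp]] <- native
    Esp <- mutate_to_identity(Eht, 98.5)
    ins[[sp]] <- rbind(ins[[sp]],
                       new_insert(paste0("htel_", sp), Esp, "ht_element"))
    if (sp != "s4") {
      for (k in 1:12)
        ins[[sp]] <- rbind(ins[[sp]], new_insert(sprintf("htc_%s_%d", sp, k),
                           copy_at_pairwise(Esp, 96), "ht_post_copy"))
    }
  }
  b <- build(c("s1", "s2", "s3", "s4"), ins)
  out$differential_proliferation <- list(
    genomes = b$genomes, inserts = b$inserts,
    probe = extract_probe(setNames(AF, "familyF")),
    burst_species = c("s1", "s2", "s3"), quiet_species = "s4")

  out
}

#' Flag mined paralog members as HT-derived from ground-truth coordinates
#'
#' Marks each member of a [mine_paralogs()] result whose genomic span
#' overlaps a ground-truth insert of an HT type (`ht_element`,
#' `ht_post_copy`, `ht_old_copy`).
#'
#' @param ps a `paralog_set`.
#' @param inserts truth insert table (`species, contig, start, end, type`,
#'   1-based inclusive), from [simulate_genomes()] or [fixture_suite()].
#' @return logical vector parallel to `ps$members`.
#' @export
flag_members_by_truth <- function(ps, inserts) {
  if (is.null(ps$coords)) return(logical(0))
  tr <- inserts[inserts$species == ps$species &
                startsWith(inserts$type, "ht"), , drop = FALSE]
  vapply(seq_len(nrow(ps$coords)), function(i) {
    any(tr$contig == ps$coords$contig[i] &
        tr$start <= ps$coords$end[i] & tr$end >= ps$coords$start[i] + 1L)
  }, TRUE)
}
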