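#' Configuration for the synthetic multi-species genome simulator
#'
#' The simulator emulates the data regime the HT pipeline is designed for:
#' a set of focal species plus more distant species, random genome
#' backgrounds, native TE families with proliferation bursts, implanted HT
#' events at controlled transfer identity, ortholog CDS sets whose
#' third-codon identity follows a programmed species phylogeny, and
#' conserved decoy sequences (organelle-like, rDNA-like, conserved genes)
#' shared across all species at high identity.
#'
#' All divergence is parameterised in percent-identity space, matching the
#' units the analysis operates in. The species tree is a newick string
#' whose cophenetic distances are identity differences: the programmed
#' third-codon identity of a species pair is `100 -` the patristic
#' distance between them.
#'
#' @param seed integer seed fixing all randomness.
#' @param species,focal_species species labels; focal species are the
#'   screening side of the pipeline.
#' @param species_tree newick; see above for units.
#' @param genome_length background bp per species (default 500 kb).
#' @param contigs_per_genome number of contigs the background is split into.
#' @param n_te_families,te_family_copies,te_burst_identity native TE
#'   families per species, copies per family, and the pairwise identity
#'   range of the burst copies.
#' @param te_length TE element length in bp.
#' @param n_ht_events number of implanted HT events.
#' @param ht_identity_range transfer identity range (percent) between donor
#'   and recipient copies of the element.
#' @param ht_recipient_counts recipients per event (length `n_ht_events`).
#' @param ht_donor_side `"focal"` or `"other"` per event; a focal donor
#'   always gets at least one non-focal recipient and vice versa.
#' @param ht_classes TE class per event (`Copia`/`Gypsy` elements carry a
#'   reverse-transcriptase region; `MuDR` does not).
#' @param element_age_identity identity of the actively transferring
#'   element lineage to the family ancestor; the age gap separating the
#'   donor's old paralogs from every transferred copy.
#' @param donor_pre_copies,donor_pre_identity pre-HT paralog copies in the
#'   donor genome and their mutual identity range (below the 88% scan
#'   threshold, above the 85% paralog-cluster threshold).
#' @param recipient_post_copies,recipient_post_identity post-HT burst
#'   copies per recipient and their mutual identity range.
#' @param n_orthologs,ortholog_codons,n_private_genes ortholog CDS sets
#'   evolved along the species tree; private genes are species-specific.
#' @param nonsyn_rate_factor substitution rate at codon positions 1 and 2
#'   relative to position 3 (synonymous-biased divergence).
#' @param decoys named counts per conserved-decoy category.
#' @param decoy_identity cross-species identity of decoy copies.
#' @param decoy_length length per decoy category (bp).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
    species = c(paste0("focal", 1:4), paste0("other", 1:6)),
    focal_species = paste0("focal", 1:4),
    species_tree = paste0(
      "((((focal1:0.5,focal2:0.5):0.8,(focal3:0.8,focal4:0.8):0.5):19.7,",
      "((((other1:10,other2:10):2.5,other3:12.5):3.5,other4:16):3,",
      "other5:19):2):3,other6:24);"),
    genome_length = 5e5, contigs_per_genome = 5L,
    n_te_families = 2L, te_family_copies = 5L,
    te_burst_identity = c(93, 97), te_length = 3000L,
    n_ht_events = 8L, ht_identity_range = c(91, 96),
    ht_recipient_counts = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L),
    ht_donor_side = c("other", "other", "other", "other", "other",
                      "focal", "focal", "focal"),
    ht_classes = c("Copia", "Copia", "Copia", "Copia", "Copia", "Copia",
                   "Gypsy", "MuDR"),
    element_age_identity = 96,
    donor_pre_copies = 6L, donor_pre_identity = c(86, 87.5),
    recipient_post_copies = 3L, recipient_post_identity = c(94, 97),
    n_orthologs = 60L, ortholog_codons = 300L, n_private_genes = 8L,
    nonsyn_rate_factor = 0.15,
    decoys = c(organelle = 2L, ribosomal = 2L, conserved_gene = 2L),
    decoy_identity = 97,
    decoy_length = c(organelle = 3000L, ribosomal = 2000L,
                     conserved_gene = 1500L)) {
  stopifnot(length(ht_recipient_counts) == n_ht_events,
            length(ht_donor_side) == n_ht_events,
            length(ht_classes) == n_ht_events,
            all(focal_species %in% species),
            seed == as.integer(seed), abs(seed) < 2^31)
  structure(as.list(environment()), class = "simulation_config")
}

# ---- identity-space mutation machinery --------------------------------

#' Mutate a sequence to an exact target identity
#'
#' Substitutes exactly `round(L * (1 - target/100))` distinct positions to
#' a different base (uniform positions and bases), so the gap-free identity
#' of the result to the input equals the target up to rounding. Repeated
#' application composes with back-mutation, i.e. two rounds at 95% give an
#' expected identity slightly above 90% because a doubly-mutated site can
#' revert or coincide.
#'
#' @param seq single sequence (character string).
#' @param target_identity percent in (0, 100].
#' @return mutated sequence string.
#' @export
mutate_to_identity <- function(seq, target_identity) {
  stopifnot(is.character(seq), length(seq) == 1L,
            target_identity > 0, target_identity <= 100)
  L <- nchar(seq)
  n <- round(L * (1 - target_identity / 100))
  if (n > 0.75 * L)
    stop("mutate_to_identity: target ", target_identity,
         "% needs more substitutions than 75% of sites (saturation)")
  if (n == 0L) return(seq)
  v <- strsplit(seq, "")[[1L]]
  pos <- sample.int(L, n)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    v[p] <- sample(setdiff(bases, v[p]), 1L)
  }
  paste(v, collapse = "")
}

# per-side substituted fraction q such that two independent copies at q
# have expected mutual identity t (0-1): (1-q)^2 + q^2/3 = t
half_divergence_fraction <- function(t) {
  stopifnot(t > 0.25, t <= 1)
  if (t == 1) return(0)
  uniroot(function(q) (1 - q)^2 + q^2 / 3 - t, c(0, 0.75), tol = 1e-12)$root
}

# one independent copy such that two such copies have mutual identity
# `pairwise` percent; identity of the copy to `seq` is 100*(1-q)
copy_at_pairwise <- function(seq, pairwise) {
  q <- half_divergence_fraction(pairwise / 100)
  mutate_to_identity(seq, 100 * (1 - q))
}

# Jukes-Cantor distance (substitutions/site) for identity fraction t
jc_div <- function(t) {
  stopifnot(t > 0.25, t <= 1)
  -0.75 * log((4 * t - 1) / 3)
}

jc_pchange <- function(d) 0.75 * (1 - exp(-4 * d / 3))

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
STOPS <- c("TAA", "TAG", "TGA")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

mutate_protein <- function(p, rate) {
  v <- strsplit(p, "")[[1L]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1L)
  paste(v, collapse = "")
}

# sample one coding nucleotide sequence for a protein (uniform codon choice)
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  v <- strsplit(protein, "")[[1L]]
  paste(vapply(v, function(a) sample(by_aa[[a]], 1L), ""), collapse = "")
}

# random CDS of n codons, stop-free in frame 0
rand_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# Evolve a CDS along one branch: third positions substitute with
# probability jc_pchange(d3), first/second with jc_pchange(d12); any
# substitution creating an in-frame stop codon is redirected to a non-stop
# base (or dropped if impossible). Per-branch uniform-other substitution
# composes across branches to an exact Jukes-Cantor process.
evolve_cds <- function(cds, d3, d12) {
  v <- strsplit(cds, "")[[1L]]
  L <- length(v)
  ncod <- L %/% 3L
  p3 <- jc_pchange(d3); p12 <- jc_pchange(d12)
  pos <- seq_len(ncod * 3L)
  is3 <- (pos %% 3L) == 0L
  pr <- ifelse(is3, p3, p12)
  hit <- which(runif(length(pos)) < pr)
  bases <- c("A", "C", "G", "T")
  for (p in hit) {
    cod_i <- (p - 1L) %/% 3L
    alt <- sample(setdiff(bases, v[p]))
    for (b in alt) {
      cand <- v
      cand[p] <- b
      codon <- paste(cand[(cod_i * 3L + 1L):(cod_i * 3L + 3L)], collapse = "")
      if (!(codon %in% STOPS)) { v[p] <- b; break }
    }
  }
  paste(v, collapse = "")
}

# node identity levels (percent) of an ultrametric identity-unit tree
tree_node_identities <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)   # root-to-node path length
  tipd <- max(depth[seq_along(phy$tip.label)])
  100 - 2 * (tipd - depth)
}

#' Programmed pairwise species identities of a simulation config
#'
#' @param cfg a [simulation_config()].
#' @return symmetric matrix of target third-codon identities (percent).
#' @export
programmed_identity <- function(cfg) {
  phy <- ape::read.tree(text = cfg$species_tree)
  d <- ape::cophenetic.phylo(phy)
  m <- 100 - d
  diag(m) <- 100
  m[cfg$species, cfg$species]
}

# evolve one ancestor CDS along the species tree; returns named character
evolve_along_tree <- function(phy, ancestor, nonsyn_factor) {
  ids <- tree_node_identities(phy)
  # JC half-path height per node (0 at tips)
  hjc <- vapply(ids, function(I) jc_div(max(I, 26) / 100) / 2, 0)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + phy$Nnode)
  seqs[[root]] <- ancestor
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    d3 <- hjc[par] - hjc[child]
    seqs[[child]] <- evolve_cds(seqs[[par]], d3, d3 * nonsyn_factor)
  }
  setNames(unlist(seqs[seq_len(ntip)]), phy$tip.label)
}

# ---- genome assembly ---------------------------------------------------

# inserts: data.frame(name, type, event, ancestor, identity) + list column seq
# returns list(contigs = named character, coords = data.frame)
assemble_genome <- function(species, inserts, genome_length, n_contigs) {
  per_contig_bg <- floor(genome_length / n_contigs)
  contig_names <- sprintf("%s_ctg%d", species, seq_len(n_contigs))
  n_ins <- if (is.null(inserts)) 0L else nrow(inserts)
  assignment <- if (n_ins) sample.int(n_contigs, n_ins, replace = TRUE)
                else integer(0)
  contigs <- character(n_contigs)
  coords <- list()
  for (ci in seq_len(n_contigs)) {
    idx <- which(assignment == ci)
    bg <- rand_dna(per_contig_bg)
    if (!length(idx)) { contigs[ci] <- bg; next }
    cuts <- sort(sample.int(per_contig_bg - 1L, length(idx)))
    segs <- substring(bg, c(1L, cuts + 1L), c(cuts, per_contig_bg))
    pieces <- character(0)
    pos <- 0L
    for (k in seq_along(idx)) {
      pieces <- c(pieces, segs[k])
      pos <- pos + nchar(segs[k])
      ins <- inserts[idx[k], ]
      w <- nchar(ins$seq[[1L]])
      coords[[length(coords) + 1L]] <- data.frame(
        species = species, contig = contig_names[ci],
        start = pos + 1L, end = pos + w, type = ins$type, name = ins$name,
        event = ins$event, ancestor = ins$ancestor,
        identity = ins$identity, stringsAsFactors = FALSE)
      pieces <- c(pieces, ins$seq[[1L]])
      pos <- pos + w
    }
    pieces <- c(pieces, segs[length(idx) + 1L])
    contigs[ci] <- paste(pieces, collapse = "")
  }
  list(contigs = setNames(contigs, contig_names),
       coords = if (length(coords)) do.call(rbind, coords) else NULL)
}

new_insert <- function(name, seq, type, event = NA_character_,
                       ancestor = NA_character_, identity = NA_real_) {
  data.frame(name = name, type = type, event = event, ancestor = ancestor,
             identity = identity, seq = I(list(seq)),
             stringsAsFactors = FALSE)
}

# ---- the simulator -----------------------------------------------------

#' Simulate a multi-species genome set with ground truth
#'
#' Generates random background genomes per species, implants native TE
#' families, HT events (donor pre-HT paralogs, transferred element copies,
#' recipient post-HT burst copies), and conserved decoys, and evolves
#' ortholog CDS sets along the programmed species tree. Every implanted
#' sequence is recorded in the returned truth tables together with its
#' ancestor sequence and programmed identity, so each pipeline stage can be
#' validated against known ground truth. Fully deterministic for a fixed
#' `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `genomes` (list of [genome_set()]), `cds`
#'   (named list species -> named character vector of CDS), `decoy_library`
#'   (named character, headers `category|name`), `te_library` (named
#'   character, headers `name#class`), `rt_reference` (list of aligned RT
#'   protein sets per superfamily), `rt_family_reference` (named character,
#'   headers `family|superfamily|id`), `truth` (list: `ht_events`,
#'   `inserts`, `ancestors`, `programmed_identity`, `rt_region`), and
#'   `config`.
#' @export
simulate_genomes <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  phy <- ape::read.tree(text = cfg$species_tree)
  species <- cfg$species
  others <- setdiff(species, cfg$focal_species)
  prog <- programmed_identity(cfg)

  inserts <- setNames(vector("list", length(species)), species)
  add_insert <- function(sp, ins) inserts[[sp]] <<- rbind(inserts[[sp]], ins)
  ancestors <- list()

  # RT superfamily cores and per-family proteins (92 aa, alignment-free
  # columns: all reference proteins are full length so the "alignment" is
  # the trivially gapless one)
  cores <- list(Copia = rand_protein(92L), Gypsy = rand_protein(92L))
  rt_proteins <- list(Copia = character(0), Gypsy = character(0))
  rt_region <- c(start = 1001L, end = 1276L)     # 1-based, within ancestors

  make_te_ancestor <- function(class, fam_name) {
    seq <- rand_dna(cfg$te_length)
    if (class %in% c("Copia", "Gypsy")) {
      prot <- mutate_protein(cores[[class]], 0.15)
      rt_proteins[[class]][fam_name] <<- prot
      nt <- reverse_translate(prot)
      seq <- paste0(substr(seq, 1L, rt_region["start"] - 1L), nt,
                    substr(seq, rt_region["end"] + 1L, nchar(seq)))
    }
    seq
  }

  # ---- HT events ----
  ht_rows <- list()
  for (e in seq_len(cfg$n_ht_events)) {
    class <- cfg$ht_classes[e]
    fam <- sprintf("HTfam%d", e)
    A <- make_te_ancestor(class, fam)
    ancestors[[fam]] <- A
    # the transferred element is itself an aged lineage of the family:
    # old paralogs diverged from the family ancestor, the active element
    # again from the ancestor, so pre-HT copies stay clearly below the
    # retention threshold relative to every transferred copy
    E <- mutate_to_identity(A, cfg$element_age_identity)
    ancestors[[paste0(fam, "_element")]] <- E
    side <- cfg$ht_donor_side[e]
    donor <- sample(if (side == "focal") cfg$focal_species else others, 1L)
    n_rec <- cfg$ht_recipient_counts[e]
    opposite <- if (side == "focal") others else cfg$focal_species
    recipients <- sample(opposite, 1L)
    if (n_rec > 1L) {
      pool <- setdiff(species, c(donor, recipients))
      recipients <- c(recipients, sample(pool, n_rec - 1L))
    }
    t_transfer <- runif(1L, cfg$ht_identity_range[1L], cfg$ht_identity_range[2L])
    half_id <- 100 * (1 - half_divergence_fraction(t_transfer / 100))

    # donor: pre-HT paralogs (old, below the scan threshold mutually)
    t_old <- runif(1L, cfg$donor_pre_identity[1L], cfg$donor_pre_identity[2L])
    old_id <- 100 * (1 - half_divergence_fraction(t_old / 100))
    for (k in seq_len(cfg$donor_pre_copies)) {
      add_insert(donor, new_insert(sprintf("%s_old%d", fam, k),
                                   copy_at_pairwise(A, t_old), "ht_old_copy",
                                   fam, fam, old_id))
    }
    # donor-side copy of the element at the transfer point
    add_insert(donor, new_insert(paste0(fam, "_donor"),
                                 copy_at_pairwise(E, t_transfer),
                                 "ht_element", fam, paste0(fam, "_element"),
                                 half_id))
    # recipient copies + post-HT burst
    for (r in recipients) {
      Er <- copy_at_pairwise(E, t_transfer)
      ancestors[[sprintf("%s_in_%s", fam, r)]] <- Er
      add_insert(r, new_insert(sprintf("%s_rec_%s", fam, r), Er,
                               "ht_element", fam, paste0(fam, "_element"),
                               half_id))
      t_post <- runif(1L, cfg$recipient_post_identity[1L],
                      cfg$recipient_post_identity[2L])
      post_id <- 100 * (1 - half_divergence_fraction(t_post / 100))
      for (k in seq_len(cfg$recipient_post_copies)) {
        add_insert(r, new_insert(sprintf("%s_post_%s_%d", fam, r, k),
                                 copy_at_pairwise(Er, t_post), "ht_post_copy",
                                 fam, sprintf("%s_in_%s", fam, r), post_id))
      }
    }
    ht_rows[[e]] <- data.frame(
      family = fam, te_class = class, donor = donor,
      recipients = paste(recipients, collapse = ","),
      transfer_identity = t_transfer, stringsAsFactors = FALSE)
  }

  # ---- native TE families ----
  for (sp in species) {
    for (f in seq_len(cfg$n_te_families)) {
      class <- sample(c("Copia", "Gypsy"), 1L)
      fam <- sprintf("%s_native%d", sp, f)
      A <- make_te_ancestor(class, fam)
      ancestors[[fam]] <- A
      t_burst <- runif(1L, cfg$te_burst_identity[1L], cfg$te_burst_identity[2L])
      burst_id <- 100 * (1 - half_divergence_fraction(t_burst / 100))
      for (k in seq_len(cfg$te_family_copies)) {
        add_insert(sp, new_insert(sprintf("%s_c%d", fam, k),
                                  copy_at_pairwise(A, t_burst), "native_te",
                                  fam, fam, burst_id))
      }
    }
  }

  # ---- conserved decoys (shared across all species) ----
  decoy_library <- character(0)
  for (cat in names(cfg$decoys)) {
    for (d in seq_len(cfg$decoys[[cat]])) {
      nm <- sprintf("%s_decoy%d", cat, d)
      A <- rand_dna(cfg$decoy_length[[cat]])
      ancestors[[nm]] <- A
      decoy_library[paste0(cat, "|", nm)] <- A
      dec_id <- 100 * (1 - half_divergence_fraction(cfg$decoy_identity / 100))
      for (sp in species) {
        add_insert(sp, new_insert(paste0(nm, "_", sp),
                                  copy_at_pairwise(A, cfg$decoy_identity),
                                  paste0("decoy_", cat), nm, nm, dec_id))
      }
    }
  }

  # ---- genomes ----
  genomes <- list(); coords <- list()
  for (sp in species) {
    g <- assemble_genome(sp, inserts[[sp]], cfg$genome_length,
                         cfg$contigs_per_genome)
    genomes[[sp]] <- genome_set(sp, g$contigs)
    if (!is.null(g$coords)) coords[[sp]] <- g$coords
  }

  # ---- ortholog + private CDS sets ----
  cds <- setNames(lapply(species, function(s) character(0)), species)
  for (g in seq_len(cfg$n_orthologs)) {
    anc <- rand_cds(cfg$ortholog_codons)
    tips <- evolve_along_tree(phy, anc, cfg$nonsyn_rate_factor)
    for (sp in species)
      cds[[sp]][sprintf("orth%03d_%s", g, sp)] <- tips[[sp]]
  }
  for (sp in species) {
    for (g in seq_len(cfg$n_private_genes))
      cds[[sp]][sprintf("priv%02d_%s", g, sp)] <- rand_cds(cfg$ortholog_codons)
  }

  # ---- reference libraries ----
  te_library <- setNames(
    unlist(ancestors[vapply(ht_rows, function(r) r$family, "")]),
    vapply(ht_rows, function(r) paste0(r$family, "#", r$te_class), ""))
  native_fams <- grep("_native", names(ancestors), value = TRUE)
  if (length(native_fams)) {
    nat_class <- vapply(native_fams, function(f) {
      if (f %in% names(rt_proteins$Copia)) "Copia" else "Gypsy"
    }, "")
    te_library <- c(te_library,
                    setNames(unlist(ancestors[native_fams]),
                             paste0(native_fams, "#", nat_class)))
  }
  rt_family_reference <- character(0)
  for (sf in c("Copia", "Gypsy")) {
    ps <- rt_proteins[[sf]]
    if (length(ps))
      rt_family_reference[paste0(names(ps), "|", sf, "|ref")] <- unname(ps)
  }

  truth <- list(
    ht_events = do.call(rbind, ht_rows),
    inserts = do.call(rbind, unname(coords)),
    ancestors = ancestors,
    programmed_identity = prog,
    rt_region = rt_region)
  rownames(truth$inserts) <- NULL

  list(genomes = genomes, cds = cds, decoy_library = decoy_library,
       te_library = te_library,
       rt_reference = lapply(rt_proteins, function(p)
         if (length(p)) Biostrings::AAStringSet(p) else NULL),
       rt_family_reference = rt_family_reference,
       truth = truth, config = cfg)
}

#' Write a simulation to standard files
#'
#' Emits per-species genome and CDS FASTA, the decoy / TE / RT reference
#' libraries as FASTA, the ground truth as JSON, and the configuration as
#' YAML, so the simulated data can be consumed by external tools or
#' re-run later.
#'
#' @param sim a [simulate_genomes()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$genomes)) {
    write_fasta(sim$genomes[[sp]]$seqs,
                file.path(dir, paste0(sp, "_genome.fasta")))
    write_fasta(sim$cds[[sp]], file.path(dir, paste0(sp, "_cds.fasta")))
  }
  write_fasta(sim$decoy_library, file.path(dir, "decoy_library.fasta"))
  write_fasta(sim$te_library, file.path(dir, "te_library.fasta"))
  if (length(sim$rt_family_reference))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(sim$rt_family_reference),
      file.path(dir, "rt_reference.fasta"))
  jsonlite::write_json(
    list(ht_events = sim$truth$ht_events, inserts = sim$truth$inserts,
         programmed_identity = sim$truth$programmed_identity,
         rt_region = sim$truth$rt_region),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
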