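#' Gather homolog (paralog) sets of an event in every retained species
#'
#' Extracts the event's probe fragment and mines true paralogous copies in
#' each retained species with [mine_paralogs()]. A species whose mining
#' returns nothing but whose best hit exists is represented by that single
#' best-hit fragment, flagged single-copy.
#'
#' @param event an expanded `ht_event`.
#' @param genomes list of [genome_set()] (all species; only retained ones
#'   are mined).
#' @param params an [activity_params()].
#' @param rt_region optional RT-region coordinates within the element for
#'   probe extraction.
#' @return named list species -> [mine_paralogs()] `paralog_set` (possibly
#'   with a single member and attribute `single_copy = TRUE`), plus
#'   attribute `probe`.
#' @export
gather_homologs <- function(event, genomes, params = activity_params(),
                            rt_region = NULL) {
  stopifnot(inherits(event, "ht_event"), !is.null(event$per_species))
  probe <- extract_probe(setNames(event$element, event$event_id),
                         rt_region = rt_region, params = params)
  keep <- event$per_species[event$per_species$retained, , drop = FALSE]
  gmap <- setNames(genomes, vapply(genomes, function(g) g$species, ""))
  out <- list()
  for (i in seq_len(nrow(keep))) {
    sp <- keep$species[i]
    ps <- mine_paralogs(probe, gmap[[sp]], params)
    if (ps$n == 0L) {
      # fall back to the best-hit span recorded during expansion
      ctg <- keep$sseqid[i]
      frag <- substr(as.character(gmap[[sp]]$seqs[[ctg]]),
                     keep$sstart[i] + 1L, keep$send[i])
      id <- sprintf("%s:%s:%d-%d", sp, ctg, keep$sstart[i], keep$send[i])
      ps$members <- setNames(frag, id)
      ps$n <- 1L
      attr(ps, "single_copy") <- TRUE
    }
    out[[sp]] <- ps
  }
  attr(out, "probe") <- probe
  out
}

# project a member onto probe columns via global alignment (insertions
# relative to the probe are discarded); returns a probe-length string
project_on_probe <- function(member, probe) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(member), Biostrings::DNAString(probe),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  keep <- sb != "-"
  paste(sa[keep], collapse = "")
}

#' Homolog tree of an event across species
#'
#' Aligns all homolog fragments to the event probe (star alignment in
#' probe coordinates), computes p-distances with pairwise deletion, and
#' builds a neighbor-joining tree. Tip labels are `species__k`; the
#' species of a tip is recoverable with [tip_species()].
#'
#' @param homologs result of [gather_homologs()].
#' @return `phylo` tree (unrooted), >= 2 species among the tips.
#' @export
homolog_tree <- function(homologs) {
  probe <- attr(homologs, "probe")
  seqs <- character(0)
  for (sp in names(homologs)) {
    mem <- homologs[[sp]]$members
    for (k in seq_along(mem))
      seqs[sprintf("%s__%d", sp, k)] <- project_on_probe(mem[[k]], probe)
  }
  if (length(unique(tip_species(names(seqs)))) < 2L)
    stop("homolog_tree: need homologs from at least two species")
  if (length(seqs) < 3L)
    stop("homolog_tree: need at least three homolog fragments")
  D <- p_distance(seqs, deletion = "pairwise")
  nj_tree(D)
}

#' Species label of homolog-tree tips
#' @param x `phylo` tree or character vector of tip labels (`species__k`).
#' @return character vector of species.
#' @export
tip_species <- function(x) {
  labs <- if (inherits(x, "phylo")) x$tip.label else x
  sub("__[0-9]+$", "", labs)
}

midpoint_rooted <- function(t) {
  if (ape::Ntip(t) < 3L) return(t)
  phangorn::midpoint(t)
}

#' Which species' homologs is a focal species nested within?
#'
#' Midpoint-roots the tree; if the focal species' tips form a monophyletic
#' group, returns the species composing its sister clade (the lineages the
#' focal copies are nested within). An empty set means the focal tips are
#' interleaved with other species (mixed) or sit at the root.
#'
#' @param t homolog tree (`phylo`, tips `species__k`).
#' @param focal_species species label present among the tips.
#' @return character vector of species (possibly empty).
#' @export
nesting_test <- function(t, focal_species) {
  sp <- tip_species(t)
  if (!focal_species %in% sp) stop("nesting_test: ", focal_species,
                                   " absent from the tree")
  if (all(sp == focal_species)) stop("nesting_test: all tips are focal")
  tr <- midpoint_rooted(t)
  sp <- tip_species(tr)
  tips <- which(sp == focal_species)
  if (!ape::is.monophyletic(tr, tips)) return(character(0))
  mrca <- if (length(tips) == 1L) tips else ape::getMRCA(tr, tips)
  root <- ape::Ntip(tr) + 1L
  if (mrca == root) return(character(0))
  parent <- tr$edge[tr$edge[, 2L] == mrca, 1L]
  sibs <- setdiff(phangorn::Descendants(tr, parent, "tips")[[1L]], tips)
  unique(sp[sibs])
}

#' Do the species mix across branches of the homolog tree?
#'
#' TRUE iff, after midpoint rooting, at least one species with two or more
#' tips is non-monophyletic — i.e. some species' minimal spanning clade
#' contains another species' tips. A tree in which every species is
#' monophyletic (mirroring vertical inheritance) returns FALSE.
#'
#' @param t homolog tree (`phylo`).
#' @return logical.
#' @export
mixed_branch_test <- function(t) {
  sp <- tip_species(t)
  stopifnot(length(unique(sp)) >= 2L)
  tr <- midpoint_rooted(t)
  sp <- tip_species(tr)
  for (s in unique(sp)) {
    tips <- which(sp == s)
    if (length(tips) >= 2L && !ape::is.monophyletic(tr, tips)) return(TRUE)
  }
  FALSE
}

#' Which species coalesce within another species' homolog diversity?
#'
#' Rooting-free nestedness on patristic distances: species `u` nests
#' within species `s` when the closest `u` homolog sits closer to an `s`
#' homolog than the two most divergent `s` homologs sit to each other,
#' i.e. `u`'s copies coalesce inside `s`'s own paralog diversity. This is
#' the tree-metric counterpart of judging, by eye, that one species'
#' copies are nested among another's: it does not depend on where the
#' unrooted homolog tree is rooted.
#'
#' @param t homolog tree (`phylo`, tips `species__k`).
#' @return named list: species -> character vector of other species
#'   nesting within it (empty for single-tip species).
#' @export
nested_species <- function(t) {
  sp <- tip_species(t)
  D <- ape::cophenetic.phylo(t)
  out <- list()
  for (s in unique(sp)) {
    tips_s <- which(sp == s)
    if (length(tips_s) < 2L) { out[[s]] <- character(0); next }
    diam <- max(D[tips_s, tips_s])
    inside <- character(0)
    for (u in setdiff(unique(sp), s)) {
      tips_u <- which(sp == u)
      if (min(D[tips_u, tips_s]) < diam) inside <- c(inside, u)
    }
    out[[s]] <- inside
  }
  out
}

#' Classify donor and recipient species of an HT event
#'
#' A species is the donor when its activity history reaches below the
#' identity threshold (old, pre-transfer activity) AND at least one other
#' species' homologs nest within its homolog diversity in the tree
#' ([nested_species()]). A species whose history stays entirely above the
#' threshold is a recipient. A species with below-threshold activity but
#' no topological support — or with insufficient data — is undetermined.
#' When no species shows below-threshold activity the transfer direction
#' is unknowable and every role is undetermined; such an event is only
#' retained as a validated HT if the homolog tree shows mixed branches.
#'
#' @param event an expanded `ht_event`.
#' @param histories named list species -> [activity_history()].
#' @param t homolog tree from [homolog_tree()].
#' @param threshold identity threshold (default 90).
#' @return object of class `role_assignment`: data.frame `species, role,
#'   activity_below, insufficient` with attributes `event_id`,
#'   `mixed_branches`, `nesting` (list), `validated`.
#' @export
classify_roles <- function(event, histories, t, threshold = 90) {
  species <- names(histories)
  below <- logical(length(species)); insuff <- logical(length(species))
  for (i in seq_along(species)) {
    b <- has_activity_below(histories[[i]], threshold)
    below[i] <- as.logical(b)
    insuff[i] <- isTRUE(attr(b, "insufficient"))
  }
  nesting <- nested_species(t)
  role <- rep("undetermined", length(species))
  for (i in seq_along(species)) {
    s <- species[i]
    hosts_another <- s %in% names(nesting) && length(nesting[[s]]) > 0L
    if (below[i] && !insuff[i] && hosts_another) {
      role[i] <- "donor"
    } else if (!below[i] && !insuff[i]) {
      role[i] <- "recipient"
    }
  }
  # a species cannot be both; below-threshold activity excludes the
  # recipient branch by construction. When no species shows old activity
  # the direction is unknowable (recipients-from-unknown-donor vs donor
  # with erased old activity), so every role collapses to undetermined.
  mixed <- mixed_branch_test(t)
  validated <- any(role == "donor") || mixed
  if (!any(below & !insuff)) role[] <- "undetermined"
  out <- data.frame(species = species, role = role,
                    activity_below = below, insufficient = insuff,
                    stringsAsFactors = FALSE)
  structure(out, class = c("role_assignment", "data.frame"),
            event_id = event$event_id, mixed_branches = mixed,
            nesting = nesting, validated = validated)
}

#' Events with two or more recipients
#'
#' @param assignments list of [classify_roles()] results.
#' @param events optional named list of the corresponding `ht_event`s (for
#'   TE classes).
#' @return data.frame `event_id, donor, n_recipients, te_class`, one row
#'   per event with >= 2 recipients.
#' @export
multi_recipient_summary <- function(assignments, events = NULL) {
  rows <- lapply(assignments, function(a) {
    nrec <- sum(a$role == "recipient")
    if (nrec < 2L) return(NULL)
    ev_id <- attr(a, "event_id")
    data.frame(event_id = ev_id,
               donor = paste(a$species[a$role == "donor"], collapse = ","),
               n_recipients = nrec,
               te_class = if (!is.null(events) && ev_id %in% names(events))
                 events[[ev_id]]$te_class else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(event_id = character(), donor = character(),
                      n_recipients = integer(), te_class = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export role assignments as TSV
#' @param assignments list of [classify_roles()] results.
#' @param path output file.
#' @export
write_roles_tsv <- function(assignments, path) {
  rows <- lapply(assignments, function(a) {
    data.frame(event_id = attr(a, "event_id"), species = a$species,
               role = a$role, activity_below = a$activity_below,
               insufficient = a$insufficient,
               mixed_branches = attr(a, "mixed_branches"),
               validated = attr(a, "validated"), stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
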