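#' Configuration of the HT screening pipeline
#'
#' Thresholds of the four-stage screen: (1) cross-genome search between
#' focal and other genomes, (2) conserved-sequence filtering against a
#' decoy library, (3) redundancy collapse by single-linkage clustering,
#' (4) per-event expansion across all involved species.
#'
#' @param screening [search_params()] for the cross-genome screen
#'   (defaults: identity > 90, score > 500, length > 500 bp,
#'   e-value < 1e-10, single HSP).
#' @param cluster_identity redundancy clusters link candidates with a
#'   pairwise hit above this identity (default 90).
#' @param expansion_scan_identity best-hit scan threshold when expanding an
#'   event across species (default 88); hits above it are recorded.
#' @param retention_identity species are retained in an event only above
#'   this identity (default 90).
#' @param paralog_identity single-linkage threshold for true paralog
#'   clusters in the activity analysis (default 85).
#' @param conserved [search_params()] for decoy matching (identity > 80,
#'   length > 200 bp); conserved decoys must be caught even across distant
#'   species, hence the permissive thresholds.
#' @return object of class `screen_config`.
#' @export
screen_config <- function(screening = search_params(),
                          cluster_identity = 90,
                          expansion_scan_identity = 88,
                          retention_identity = 90,
                          paralog_identity = 85,
                          conserved = search_params(min_identity = 80,
                                                    min_score = 50,
                                                    min_length = 200,
                                                    max_evalue = 1e-5)) {
  stopifnot(expansion_scan_identity <= retention_identity,
            cluster_identity > 0, cluster_identity <= 100,
            paralog_identity > 0, paralog_identity < 100)
  structure(list(screening = screening, cluster_identity = cluster_identity,
                 expansion_scan_identity = expansion_scan_identity,
                 retention_identity = retention_identity,
                 paralog_identity = paralog_identity, conserved = conserved),
            class = "screen_config")
}

new_candidates <- function(meta, seqs) {
  structure(list(meta = meta, seqs = seqs), class = "ht_candidates")
}

#' @export
print.ht_candidates <- function(x, ...) {
  cat(sprintf("<ht_candidates> %d candidate region(s) from %d species\n",
              nrow(x$meta), length(unique(x$meta$source_species))))
  invisible(x)
}

#' Stage 1: isolate candidate HT regions from cross-genome hits
#'
#' Searches every focal genome against every other genome and isolates the
#' hit regions from the non-focal genomes; overlapping hit regions on the
#' same subject contig are merged into one candidate, annotated with its
#' best overlapping hit.
#'
#' @param focal,others lists of [genome_set()] objects.
#' @param cfg a [screen_config()].
#' @return `ht_candidates` object: `meta` data.frame (`cand_id,
#'   source_species, partner_species, contig, start, end, identity, score,
#'   conserved_label`; coordinates 0-based half-open on the source contig)
#'   plus `seqs` (named character vector of the candidate sequences).
#' @export
screen_candidates <- function(focal, others, cfg = screen_config()) {
  stopifnot(length(focal) >= 1L, length(others) >= 1L)
  qseqs <- unlist(lapply(focal, function(gs) {
    v <- as.character(gs$seqs)
    names(v) <- paste0(gs$species, "\r", names(v))
    v
  }))
  meta <- list(); seqs <- character(0)
  for (gs in others) {
    hits <- local_search(qseqs, gs, cfg$screening)
    if (nrow(hits) == 0L) next
    for (ctg in unique(hits$sseqid)) {
      h <- hits[hits$sseqid == ctg, , drop = FALSE]
      rg <- IRanges::reduce(IRanges::IRanges(start = h$sstart + 1L,
                                             end = h$send))
      for (k in seq_along(rg)) {
        s0 <- IRanges::start(rg)[k] - 1L; e0 <- IRanges::end(rg)[k]
        ov <- h[h$sstart < e0 & h$send > s0, , drop = FALSE]
        best <- ov[which.max(ov$score), ]
        cid <- sprintf("%s:%s:%d-%d", gs$species, ctg, s0, e0)
        meta[[length(meta) + 1L]] <- data.frame(
          cand_id = cid, source_species = gs$species,
          partner_species = sub("\r.*$", "", best$qseqid),
          contig = ctg, start = s0, end = e0,
          identity = best$pident, score = best$score,
          conserved_label = "none", stringsAsFactors = FALSE)
        seqs[cid] <- substr(as.character(gs$seqs[[ctg]]), s0 + 1L, e0)
      }
    }
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(cand_id = character(), source_species = character(),
               partner_species = character(), contig = character(),
               start = integer(), end = integer(), identity = numeric(),
               score = integer(), conserved_label = character(),
               stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  new_candidates(meta, seqs)
}

#' Stage 2: remove candidates matching conserved decoy sequences
#'
#' Candidates hitting any decoy-library sequence (organelle-like,
#' ribosomal, conserved gene) above the permissive `cfg$conserved`
#' thresholds are labeled with the decoy's category and removed.
#'
#' @param cands `ht_candidates` from [screen_candidates()].
#' @param decoys decoy library: [genome_set()], `DNAStringSet` or named
#'   character vector; names carry the category as a `category|name`
#'   prefix (`organelle`, `ribosomal` or `conserved_gene`).
#' @param cfg a [screen_config()].
#' @return list with `kept` (`ht_candidates`, labels `none`) and `removed`
#'   (`ht_candidates` with `conserved_label` filled).
#' @export
filter_conserved <- function(cands, decoys, cfg = screen_config()) {
  stopifnot(inherits(cands, "ht_candidates"))
  if (is.null(decoys) || length(decoys) == 0L ||
      (inherits(decoys, "genome_set") && length(decoys$seqs) == 0L)) {
    warning("filter_conserved: empty decoy library; passing all candidates through")
    return(list(kept = cands, removed = new_candidates(cands$meta[0, ],
                                                       character(0))))
  }
  if (nrow(cands$meta) == 0L) return(list(kept = cands, removed = cands))
  dec <- as_seq_vector(decoys, "decoys")
  hits <- local_search(cands$seqs, dec, cfg$conserved)
  lab <- setNames(rep("none", nrow(cands$meta)), cands$meta$cand_id)
  if (nrow(hits)) {
    cat_of <- sub("\\|.*$", "", hits$sseqid)
    first <- !duplicated(hits$qseqid)   # hits are score-ordered
    lab[hits$qseqid[first]] <- cat_of[first]
  }
  cands$meta$conserved_label <- unname(lab[cands$meta$cand_id])
  keep <- cands$meta$conserved_label == "none"
  list(kept = new_candidates(cands$meta[keep, , drop = FALSE],
                             cands$seqs[cands$meta$cand_id[keep]]),
       removed = new_candidates(cands$meta[!keep, , drop = FALSE],
                                cands$seqs[cands$meta$cand_id[!keep]]))
}

# connected components by union-find over an edge list of ids
single_linkage_clusters <- function(ids, from, to) {
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (k in seq_along(from)) {
    a <- find(match(from[k], ids)); b <- find(match(to[k], ids))
    if (a != b) parent[[b]] <- a
  }
  roots <- vapply(seq_along(ids), find, 0L)
  split(ids, roots)
}

#' Stage 3: collapse redundant candidates into HT events
#'
#' All-to-all search among the candidates; candidates joined by a hit above
#' `cfg$cluster_identity` form single-linkage clusters (the connected
#' components of the hit graph), each contributing one event whose element
#' is the cluster's longest candidate. Event ids follow the
#' `<Src>_HT-<n>` convention, using the first three letters of the
#' representative's source species.
#'
#' @param cands `ht_candidates` surviving [filter_conserved()].
#' @param cfg a [screen_config()].
#' @return list of `ht_event` objects (element sequence + provenance);
#'   `per_species` is filled later by [expand_event()].
#' @export
collapse_redundant <- function(cands, cfg = screen_config()) {
  stopifnot(inherits(cands, "ht_candidates"))
  ids <- cands$meta$cand_id
  if (length(ids) == 0L) return(list())
  params <- cfg$screening
  params$single_hsp <- TRUE
  hits <- local_search(cands$seqs, cands$seqs, params)
  hits <- hits[hits$qseqid != hits$sseqid &
               hits$pident > cfg$cluster_identity, , drop = FALSE]
  clusters <- single_linkage_clusters(ids, hits$qseqid, hits$sseqid)
  events <- list()
  i <- 0L
  for (cl in clusters) {
    i <- i + 1L
    lens <- nchar(cands$seqs[cl])
    rep_id <- cl[which.max(lens)]
    m <- cands$meta[cands$meta$cand_id == rep_id, ]
    prefix <- paste0(toupper(substr(m$source_species, 1L, 1L)),
                     substr(m$source_species, 2L, 3L))
    ev <- structure(list(
      event_id = sprintf("%s_HT-%d", prefix, i),
      element = setNames(cands$seqs[[rep_id]], rep_id),
      element_source = m$source_species,
      te_class = "unknown",
      members = cl,
      per_species = NULL), class = "ht_event")
    events[[ev$event_id]] <- ev
  }
  events
}

#' @export
print.ht_event <- function(x, ...) {
  ret <- if (is.null(x$per_species)) 0L else sum(x$per_species$retained)
  cat(sprintf("<ht_event> %s (%s): element %d bp, %d retained species\n",
              x$event_id, x$te_class, nchar(x$element), ret))
  invisible(x)
}

#' Stage 4: expand one event across all genomes
#'
#' Scans the event's element against every genome with the best-hit rule
#' at the expansion scan threshold (default > 88% identity) and retains a
#' species in the event only when its best-hit identity exceeds the
#' retention threshold (default > 90%).
#'
#' @param event an `ht_event` from [collapse_redundant()].
#' @param all_genomes list of [genome_set()] covering every species.
#' @param cfg a [screen_config()].
#' @return the event with `per_species` filled (data.frame `species,
#'   identity, sseqid, sstart, send, strand, retained`); `NULL` (with a
#'   message) when no genome has a qualifying hit.
#' @export
expand_event <- function(event, all_genomes, cfg = screen_config()) {
  stopifnot(inherits(event, "ht_event"))
  params <- cfg$screening
  params$min_identity <- cfg$expansion_scan_identity
  bh <- best_hit_per_species(event$element, all_genomes, params)
  if (nrow(bh) == 0L) {
    message("expand_event: ", event$event_id,
            ": element absent from all genomes; event dropped")
    return(NULL)
  }
  bh$retained <- bh$identity > cfg$retention_identity
  event$per_species <- bh
  event
}

#' Expand several events across all genomes in one pass
#'
#' Equivalent to calling [expand_event()] on each event, but batches all
#' elements into a single search per genome so each genome is indexed
#' once. Events with fewer than one qualifying hit are dropped with a
#' message.
#'
#' @param events list of `ht_event`s.
#' @param all_genomes list of [genome_set()].
#' @param cfg a [screen_config()].
#' @return named list of expanded events.
#' @export
expand_events <- function(events, all_genomes, cfg = screen_config()) {
  if (length(events) == 0L) return(events)
  params <- cfg$screening
  params$min_identity <- cfg$expansion_scan_identity
  params$single_hsp <- TRUE
  elements <- vapply(events, function(ev) unname(ev$element), "")
  names(elements) <- vapply(events, function(ev) ev$event_id, "")
  per_event <- setNames(vector("list", length(events)), names(elements))
  for (gs in all_genomes) {
    hits <- local_search(elements, gs, params)
    if (nrow(hits) == 0L) next
    hits <- hits[order(-hits$score, -hits$pident), , drop = FALSE]
    hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
    for (k in seq_len(nrow(hits))) {
      h <- hits[k, ]
      per_event[[h$qseqid]] <- rbind(per_event[[h$qseqid]], data.frame(
        species = gs$species, sseqid = h$sseqid, identity = h$pident,
        score = h$score, length = h$length, sstart = h$sstart,
        send = h$send, strand = h$strand, stringsAsFactors = FALSE))
    }
  }
  out <- list()
  for (id in names(per_event)) {
    bh <- per_event[[id]]
    if (is.null(bh)) {
      message("expand_events: ", id,
              ": element absent from all genomes; event dropped")
      next
    }
    bh$retained <- bh$identity > cfg$retention_identity
    ev <- events[[id]]
    ev$per_species <- bh
    out[[id]] <- ev
  }
  out
}

#' Per-species best-hit identity histogram over HT events
#'
#' Counts the retained per-species best-hit identities of all events in
#' half-open bins `[lo, lo + width)` over \[88, 100\] (the last bin is
#' closed so identity 100 is counted). The element's self-hit in its own
#' source species is excluded by default.
#'
#' @param events list of expanded `ht_event`s.
#' @param bin_width bin width in percent (default 1).
#' @param drop_self exclude the element's self-species entry.
#' @return data.frame `bin_lo, bin_hi, count`; zero rows if no identities.
#' @export
event_identity_histogram <- function(events, bin_width = 1, drop_self = TRUE) {
  vals <- unlist(lapply(events, function(ev) {
    if (is.null(ev$per_species)) return(numeric(0))
    ps <- ev$per_species[ev$per_species$retained, , drop = FALSE]
    if (drop_self) ps <- ps[ps$species != ev$element_source, , drop = FALSE]
    ps$identity
  }))
  identity_histogram(vals, bin_width, lo = 88, hi = 100)
}

# shared binning helper: half-open [lo, lo+w) bins, last bin closed
identity_histogram <- function(vals, bin_width = 1, lo = NULL, hi = 100) {
  if (length(vals) == 0L)
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0), density = numeric(0)))
  if (is.null(lo)) lo <- floor(min(vals))
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  idx <- findInterval(vals, edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx < length(edges)]
  cnt <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
             count = cnt, density = cnt / sum(cnt))
}

#' Classify event elements against a TE reference library
#'
#' Assigns each event the class of its best library hit (Repbase-style
#' headers `name#Class`), or `"unknown"` when nothing passes.
#'
#' @param events list of `ht_event`s.
#' @param te_library named character vector / `DNAStringSet`; names
#'   formatted `name#Class`.
#' @param params [search_params()] for the classification search.
#' @return the events, with `te_class` filled.
#' @export
classify_te <- function(events, te_library,
                        params = search_params(min_identity = 80,
                                               min_score = 100,
                                               min_length = 100,
                                               max_evalue = 1e-10)) {
  if (length(events) == 0L || length(te_library) == 0L) return(events)
  lib <- as_seq_vector(te_library, "te_library")
  for (i in seq_along(events)) {
    h <- local_search(setNames(events[[i]]$element, "q"), lib, params)
    if (nrow(h)) events[[i]]$te_class <- sub("^.*#", "", h$sseqid[1L])
  }
  events
}

#' Export expanded events as a tab-separated table
#'
#' One row per retained (event, species); 1-based inclusive coordinates.
#'
#' @param events list of expanded `ht_event`s.
#' @param path output file.
#' @export
write_events_tsv <- function(events, path) {
  rows <- lapply(events, function(ev) {
    if (is.null(ev$per_species)) return(NULL)
    ps <- ev$per_species[ev$per_species$retained, , drop = FALSE]
    if (nrow(ps) == 0L) return(NULL)
    data.frame(event_id = ev$event_id, te_class = ev$te_class,
               species = ps$species, identity = ps$identity,
               contig = ps$sseqid, start = ps$sstart + 1L, end = ps$send,
               strand = ps$strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
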