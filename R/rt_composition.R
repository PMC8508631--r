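#' Build a position-specific scoring profile from aligned RT proteins
#'
#' Columns with more than 50% gaps are dropped, the alignment is trimmed
#' to its central 92 columns, and per-column log2-odds scores are computed
#' with pseudocounts against a uniform background. The detection threshold
#' is calibrated from a shuffled-residue null: profile scores of random
#' windows drawn from the alignment's own residue pool, cut at the null
#' mean plus six null standard deviations. A genome scan evaluates
#' millions of windows, so this per-window rate keeps the expected number
#' of false discoveries effectively at zero (well inside a 1% false
#' discovery share) while true domains score an order of magnitude above
#' the null spread.
#'
#' @param aligned `AAStringSet` (or named character vector) of aligned RT
#'   protein sequences, >= 5 sequences, >= 92 informative columns.
#' @param pseudocount Dirichlet pseudocount per residue.
#' @param n_null number of null windows for threshold calibration (drawn
#'   with the current RNG state; seed for reproducibility).
#' @return object of class `rt_profile`: `pssm` (20 x 92 matrix),
#'   `threshold`, `width`.
#' @export
build_profile <- function(aligned, pseudocount = 1, n_null = 500L) {
  if (is.character(aligned)) aligned <- Biostrings::AAStringSet(aligned)
  stopifnot(methods::is(aligned, "AAStringSet"), length(aligned) >= 5L)
  M <- as_alignment_matrix(as.character(aligned))
  keep <- colMeans(M == "-") <= 0.5
  M <- M[, keep, drop = FALSE]
  if (ncol(M) < 92L)
    stop("build_profile: alignment has fewer than 92 informative columns")
  start <- (ncol(M) - 92L) %/% 2L
  M <- M[, (start + 1L):(start + 92L), drop = FALSE]
  bg <- 1 / 20
  pssm <- matrix(0, 20L, 92L, dimnames = list(AA20, NULL))
  for (j in seq_len(92L)) {
    col <- M[, j]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    p <- (cnt + pseudocount * bg) / (sum(cnt) + pseudocount)
    pssm[, j] <- log2(as.numeric(p) / bg)
  }
  pool <- M[M %in% AA20]
  null_scores <- vapply(seq_len(n_null), function(i) {
    idx <- cbind(match(sample(pool, 92L, replace = TRUE), AA20), seq_len(92L))
    sum(pssm[idx])
  }, 0)
  structure(list(pssm = pssm,
                 threshold = mean(null_scores) + 6 * stats::sd(null_scores),
                 width = 92L), class = "rt_profile")
}

#' Score an amino-acid sequence against an RT profile
#'
#' @param profile an [build_profile()] result.
#' @param aa protein sequence (string); must be at least profile width.
#' @return best 92-aa window score (log2-odds).
#' @export
profile_score <- function(profile, aa) {
  v <- match(strsplit(toupper(aa), "")[[1L]], AA20)
  v[is.na(v)] <- 0L
  sc <- cpp_pssm_scan(as.integer(v - 1L), profile$pssm)
  if (length(sc) == 0L) return(-Inf)
  max(sc)
}

#' Extract reverse-transcriptase domains from a genome
#'
#' Six-frame translation (stopping at stop codons: an RT window never
#' crosses an in-frame stop, so heavily degraded elements are not
#' counted), sliding 92-aa profile windows, and per-locus merging of
#' overlapping above-threshold windows; the best window per locus is
#' reported with its forward-strand nucleotide coordinates.
#'
#' @param genome a [genome_set()].
#' @param profile an [build_profile()] result (or a named list of profiles,
#'   e.g. one per superfamily; the best-scoring profile labels the hit).
#' @param min_len minimum domain length in aa (windows are fixed at 92,
#'   retained for interface completeness).
#' @return object of class `rt_domains`: data.frame `species, contig,
#'   start, end, strand, frame, score, profile, aa, nt, family,
#'   superfamily, ht_flag` (0-based half-open nt coordinates).
#' @export
extract_rt <- function(genome, profile, min_len = 50L) {
  stopifnot(inherits(genome, "genome_set"))
  profiles <- if (inherits(profile, "rt_profile")) list(profile = profile)
              else profile
  W <- 92L
  rows <- list()
  for (ctg in names(genome$seqs)) {
    fwd <- as.character(genome$seqs[[ctg]])
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else reverse_complement(setNames(fwd, "x"))
      for (frame in 0:2) {
        n <- (nchar(s) - frame) %/% 3L
        if (n < W) next
        aa <- translate_cds(substr(s, frame + 1L, frame + 3L * n))
        # segments between stop codons
        segs <- strsplit(aa, "*", fixed = TRUE)[[1L]]
        off <- 0L
        for (seg in segs) {
          if (nchar(seg) >= W) {
            v <- match(strsplit(seg, "")[[1L]], AA20)
            v[is.na(v)] <- 0L
            best_sc <- -Inf; best_prof <- NA_character_; best_scores <- NULL
            for (pn in names(profiles)) {
              sc <- cpp_pssm_scan(as.integer(v - 1L), profiles[[pn]]$pssm)
              if (max(sc) > best_sc) {
                best_sc <- max(sc); best_prof <- pn; best_scores <- sc
              }
            }
            thr <- profiles[[best_prof]]$threshold
            above <- which(best_scores > thr)
            if (length(above)) {
              # merge runs of overlapping windows, keep best window each
              grp <- cumsum(c(1L, diff(above) > W))
              for (g in split(above, grp)) {
                w0 <- g[which.max(best_scores[g])]     # 1-based aa window
                aa_start <- off + w0 - 1L              # 0-based aa on frame
                nt_start <- frame + 3L * aa_start      # 0-based on strand s
                nt_end <- nt_start + 3L * W
                if (strand == "-") {
                  tmp <- L - nt_end
                  nt_end <- L - nt_start
                  nt_start <- tmp
                }
                rows[[length(rows) + 1L]] <- data.frame(
                  species = genome$species, contig = ctg,
                  start = nt_start, end = nt_end, strand = strand,
                  frame = frame, score = best_scores[w0],
                  profile = best_prof,
                  aa = substr(seg, w0, w0 + W - 1L),
                  nt = substr(fwd, nt_start + 1L, nt_end),
                  family = "unclassified", superfamily = best_prof,
                  ht_flag = FALSE, stringsAsFactors = FALSE)
              }
            }
          }
          off <- off + nchar(seg) + 1L
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               frame = integer(), score = numeric(), profile = character(),
               aa = character(), nt = character(), family = character(),
               superfamily = character(), ht_flag = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("rt_domains", "data.frame"))
}

#' Classify RT domains into families by best protein hit
#'
#' Each RT amino-acid sequence is compared to every reference protein by
#' local alignment (BLOSUM62, affine gaps); the best hit above
#' `min_score` assigns `family` and `superfamily` from the reference
#' header (`family|superfamily|id`). Exact score ties go to the
#' lexicographically smaller family (reported with a message).
#'
#' @param rts an [extract_rt()] result.
#' @param reference `AAStringSet` or named character vector, names
#'   `family|superfamily|id`.
#' @param min_score minimal local-alignment score (BLOSUM62 units).
#' @return the `rt_domains` object with `family`/`superfamily` filled.
#' @export
classify_family <- function(rts, reference, min_score = 60) {
  stopifnot(inherits(rts, "rt_domains"))
  if (is.character(reference)) reference <- Biostrings::AAStringSet(reference)
  stopifnot(length(reference) > 0L)
  refs <- as.character(reference)
  fams <- sub("\\|.*$", "", names(refs))
  sups <- vapply(strsplit(names(refs), "|", fixed = TRUE), `[`, "", 2L)
  for (i in seq_len(nrow(rts))) {
    sc <- vapply(refs, function(r)
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(rts$aa[i]), Biostrings::AAString(r),
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
        type = "local", scoreOnly = TRUE), 0)
    best <- max(sc)
    if (best > min_score) {
      cand <- which(sc == best)
      if (length(cand) > 1L) {
        cand <- cand[order(fams[cand])]
        message("classify_family: score tie; assigning ", fams[cand[1L]])
      }
      rts$family[i] <- fams[cand[1L]]
      rts$superfamily[i] <- sups[cand[1L]]
    }
  }
  rts
}

#' Flag RT domains derived from horizontally transferred elements
#'
#' An RT domain is HT-derived when its nucleotide sequence hits any
#' event element above the flagging thresholds (protocol: single HSP,
#' score > 200).
#'
#' @param rts an [extract_rt()] result.
#' @param events list of `ht_event`s (validated).
#' @param params [search_params()] for the flagging search.
#' @return `rt_domains` with `ht_flag` set.
#' @export
flag_ht <- function(rts, events,
                    params = search_params(min_identity = 0, min_score = 200,
                                           min_length = 0,
                                           max_evalue = 1e-10)) {
  stopifnot(inherits(rts, "rt_domains"))
  if (length(events) == 0L || nrow(rts) == 0L) return(rts)
  elements <- vapply(events, function(ev) unname(ev$element), "")
  names(elements) <- vapply(events, function(ev) ev$event_id, "")
  q <- setNames(rts$nt, sprintf("rt%d", seq_len(nrow(rts))))
  hits <- local_search(q, elements, params)
  if (nrow(hits)) {
    idx <- as.integer(sub("^rt", "", unique(hits$qseqid)))
    rts$ht_flag[idx] <- TRUE
  }
  rts
}

#' Per-species, per-family LTR retrotransposon composition report
#'
#' Counts RT domains per (species, family), splits them into native and
#' HT-derived, and reports the HT percentage (half-up, one decimal).
#'
#' @param rts an `rt_domains` table (one or several species).
#' @return data.frame `species, superfamily, family, total, ht,
#'   ht_percent`, including zero rows for families absent from a species.
#' @export
composition_report <- function(rts) {
  stopifnot(inherits(rts, "rt_domains"))
  species <- unique(rts$species)
  fams <- unique(rts[, c("family", "superfamily")])
  rows <- list()
  for (sp in species) for (k in seq_len(nrow(fams))) {
    sel <- rts$species == sp & rts$family == fams$family[k]
    tot <- sum(sel); ht <- sum(sel & rts$ht_flag)
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, superfamily = fams$superfamily[k],
      family = fams$family[k], total = tot, ht = ht,
      ht_percent = if (tot > 0) round_half_up(100 * ht / tot, 1) else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Native vs HT-derived layered activity history
#'
#' Splits a family's member fragments into a native and an HT-derived
#' layer and computes an activity history for each, the layered display
#' used to show differential proliferation of horizontally acquired
#' elements across species.
#'
#' @param members named character vector of member fragments (one species).
#' @param ht_flags logical vector parallel to `members`.
#' @param species species label.
#' @param params an [activity_params()].
#' @return list with `native` and `ht` [activity_history()] objects.
#' @export
layered_activity_history <- function(members, ht_flags, species,
                                     params = activity_params()) {
  stopifnot(length(members) == length(ht_flags))
  mk <- function(sub) {
    ps <- structure(list(species = species, probe = NULL, members = sub,
                         n = length(sub), coords = NULL),
                    class = "paralog_set")
    activity_history(ps, params)
  }
  list(native = mk(members[!ht_flags]), ht = mk(members[ht_flags]))
}

#' Does the HT layer show a proliferation peak?
#'
#' TRUE iff the HT layer's modal histogram bin holds at least
#' `min_count` node values and at least `ratio` times the native layer's
#' count in that same bin (native counts are floored at 1 so a peak must
#' be substantial in absolute terms, not only relative).
#'
#' @param layers result of [layered_activity_history()].
#' @param ratio required HT/native ratio in the modal bin (default 3).
#' @param min_count minimum node values in the modal bin (default 3).
#' @return logical.
#' @export
has_ht_peak <- function(layers, ratio = 3, min_count = 3L) {
  ht <- layers$ht$histogram
  if (nrow(ht) == 0L || sum(ht$count) == 0L) return(FALSE)
  mode_i <- which.max(ht$count)
  ht_count <- ht$count[mode_i]
  nat <- layers$native$histogram
  nat_count <- 0L
  if (nrow(nat)) {
    j <- which(nat$bin_lo == ht$bin_lo[mode_i])
    if (length(j)) nat_count <- nat$count[j]
  }
  ht_count >= min_count && ht_count >= ratio * max(1L, nat_count)
}
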