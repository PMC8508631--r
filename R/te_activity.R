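#' Parameters of the TE paralog activity-history analysis
#'
#' @param fragment_len_range probe fragment length range in bp (small
#'   fragments avoid split local alignments); the probe is cut at the
#'   midpoint of the range.
#' @param paralog_search [search_params()] for paralog mining and the
#'   all-to-all comparison (protocol: single HSP, score > 60,
#'   e-value < 1e-8; no identity floor — clustering applies it).
#' @param cluster_identity single-linkage threshold separating true
#'   paralogs from other families (default 85 percent).
#' @param hist_bin_width activity histogram bin width (percent).
#' @return object of class `activity_params`.
#' @export
activity_params <- function(fragment_len_range = c(260L, 280L),
                            paralog_search = search_params(min_identity = 0,
                                                           min_score = 60,
                                                           min_length = 0,
                                                           max_evalue = 1e-8),
                            cluster_identity = 85,
                            hist_bin_width = 1) {
  stopifnot(fragment_len_range[1L] >= 50, fragment_len_range[2L] <= 1000,
            fragment_len_range[1L] <= fragment_len_range[2L],
            cluster_identity > 0, cluster_identity < 100)
  structure(list(fragment_len_range = as.integer(fragment_len_range),
                 paralog_search = paralog_search,
                 cluster_identity = cluster_identity,
                 hist_bin_width = hist_bin_width),
            class = "activity_params")
}

#' Extract the probe fragment from a TE element
#'
#' Cuts a probe of length `mean(fragment_len_range)` (270 bp by default)
#' centered on the reverse-transcriptase region when one is provided,
#' otherwise on the element's center (a deterministic stand-in for an
#' arbitrary position). Elements shorter than the minimum fragment length
#' are used whole, with a warning.
#'
#' @param element named sequence (length-1 named character vector or
#'   `list(id=, seq=)`).
#' @param rt_region optional integer c(start, end), 1-based inclusive
#'   coordinates of the RT region within the element.
#' @param params an [activity_params()].
#' @return named character vector of length 1 (the probe).
#' @export
extract_probe <- function(element, rt_region = NULL,
                          params = activity_params()) {
  el <- as_seq_vector(element, "element")
  stopifnot(length(el) == 1L)
  L <- nchar(el)
  want <- as.integer(round(mean(params$fragment_len_range)))
  if (L < params$fragment_len_range[1L]) {
    warning("extract_probe: element shorter than ",
            params$fragment_len_range[1L], " bp; using whole element")
    return(setNames(unname(el), paste0(names(el), "_probe")))
  }
  center <- if (!is.null(rt_region)) {
    cc <- floor((rt_region[1L] + rt_region[2L]) / 2)
    # keep the probe inside the RT region when it fits
    min(max(cc, rt_region[1L] + floor(want / 2)),
        rt_region[2L] - ceiling(want / 2))
  } else floor(L / 2)
  start <- max(1L, min(center - floor(want / 2) + 1L, L - want + 1L))
  probe <- substr(unname(el), start, start + want - 1L)
  setNames(probe, paste0(names(el), "_probe"))
}

#' Mine true paralogous copies of a probe in one genome
#'
#' Hits of the probe against the genome give candidate fragments (trimmed
#' to the hit span so identities are length-comparable); candidates plus
#' the probe are then compared all-to-all and single-linkage clustered at
#' `cluster_identity`; the cluster containing the probe is the set of true
#' paralogous copies. An empty result is valid (the species lacks the
#' family).
#'
#' @param probe named probe sequence from [extract_probe()].
#' @param genome a [genome_set()].
#' @param params an [activity_params()].
#' @return object of class `paralog_set`: `species`, `probe`, `members`
#'   (named character vector of genomic fragments), `n`, `coords`
#'   (data.frame of member locations, 0-based half-open).
#' @export
mine_paralogs <- function(probe, genome, params = activity_params()) {
  stopifnot(inherits(genome, "genome_set"))
  pr <- as_seq_vector(probe, "probe")
  sp <- params$paralog_search
  sp$single_hsp <- FALSE       # one probe may hit several copies per contig
  hits <- local_search(pr, genome, sp)
  empty <- structure(list(species = genome$species, probe = pr,
                          members = character(0), n = 0L,
                          coords = NULL), class = "paralog_set")
  if (nrow(hits) == 0L) return(empty)
  # de-overlap hit spans per contig, keeping distinct genomic loci
  frags <- character(0); coords <- list()
  for (ctg in unique(hits$sseqid)) {
    h <- hits[hits$sseqid == ctg, , drop = FALSE]
    rg <- IRanges::reduce(IRanges::IRanges(start = h$sstart + 1L,
                                           end = h$send))
    for (k in seq_along(rg)) {
      s0 <- IRanges::start(rg)[k] - 1L; e0 <- IRanges::end(rg)[k]
      id <- sprintf("%s:%s:%d-%d", genome$species, ctg, s0, e0)
      frags[id] <- substr(as.character(genome$seqs[[ctg]]), s0 + 1L, e0)
      coords[[id]] <- data.frame(member = id, contig = ctg, start = s0,
                                 end = e0, stringsAsFactors = FALSE)
    }
  }
  # all-to-all among candidates + probe, single linkage at cluster_identity
  pool <- c(pr, frags)
  aa <- params$paralog_search
  aa$single_hsp <- TRUE
  ah <- local_search(pool, pool, aa)
  ah <- ah[ah$qseqid != ah$sseqid &
           ah$pident > params$cluster_identity, , drop = FALSE]
  clusters <- single_linkage_clusters(names(pool), ah$qseqid, ah$sseqid)
  probe_cl <- clusters[[which(vapply(clusters, function(cl)
    names(pr) %in% cl, TRUE))]]
  members <- frags[setdiff(probe_cl, names(pr))]
  if (length(members) == 0L) return(empty)
  structure(list(species = genome$species, probe = pr, members = members,
                 n = length(members),
                 coords = do.call(rbind, coords[names(members)])),
            class = "paralog_set")
}

#' @export
print.paralog_set <- function(x, ...) {
  cat(sprintf("<paralog_set> %s: %d member(s)\n", x$species, x$n))
  invisible(x)
}

# all-to-all identity matrix among members; self = 100; pairs without a
# qualifying hit are imputed as min(observed) - 1 so that unlinked members
# merge last without fabricating precision
member_identity_matrix <- function(members, params) {
  n <- length(members)
  m <- matrix(NA_real_, n, n, dimnames = list(names(members), names(members)))
  diag(m) <- 100
  sp <- params$paralog_search
  sp$single_hsp <- TRUE
  hits <- local_search(members, members, sp)
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  for (k in seq_len(nrow(hits))) {
    a <- hits$qseqid[k]; b <- hits$sseqid[k]
    v <- hits$pident[k]
    if (is.na(m[a, b]) || v > m[a, b]) m[a, b] <- m[b, a] <- v
  }
  off <- m[upper.tri(m)]
  if (any(is.na(off))) {
    imp <- if (all(is.na(off))) 0 else max(min(off, na.rm = TRUE) - 1, 0)
    m[is.na(m)] <- imp
  }
  m
}

#' Activity history of a paralog set
#'
#' All-to-all identities among the members (self-matches removed), UPGMA
#' clustering from the highest to the lowest identity, and the multiset of
#' internal-node identities binned into the activity histogram. Node
#' values below the species-divergence threshold indicate activity
#' predating the relevant speciations (donor-like history).
#'
#' @param ps a [mine_paralogs()] result.
#' @param params an [activity_params()].
#' @return object of class `activity_history`: `species`, `n_paralogs`,
#'   `node_values` (length `n - 1`, empty when `n < 2`), `histogram`
#'   (data.frame `bin_lo, bin_hi, count, density`), `tree` (`upgma_tree`
#'   or `NULL`).
#' @export
activity_history <- function(ps, params = activity_params()) {
  stopifnot(inherits(ps, "paralog_set"))
  if (ps$n < 2L) {
    return(structure(list(species = ps$species, n_paralogs = ps$n,
                          node_values = numeric(0),
                          histogram = identity_histogram(numeric(0)),
                          tree = NULL), class = "activity_history"))
  }
  m <- member_identity_matrix(ps$members, params)
  tr <- upgma_identity(m)
  nv <- node_values(tr)
  structure(list(species = ps$species, n_paralogs = ps$n, node_values = nv,
                 histogram = identity_histogram(nv, params$hist_bin_width),
                 tree = tr), class = "activity_history")
}

#' @export
print.activity_history <- function(x, ...) {
  cat(sprintf("<activity_history> %s: %d paralog(s), %d node value(s)\n",
              x$species, x$n_paralogs, length(x$node_values)))
  invisible(x)
}

#' Does an activity history reach below a threshold?
#'
#' TRUE iff any UPGMA node value lies below `threshold`. An empty history
#' (fewer than two paralogs) returns FALSE with `insufficient = TRUE`, so
#' callers can distinguish "no old activity" from "no data".
#'
#' @param h an [activity_history()].
#' @param threshold percent identity (default 90, the HT detection
#'   threshold).
#' @return logical with attribute `insufficient`.
#' @export
has_activity_below <- function(h, threshold = 90) {
  stopifnot(inherits(h, "activity_history"))
  if (length(h$node_values) == 0L)
    return(structure(FALSE, insufficient = TRUE))
  structure(any(h$node_values < threshold), insufficient = FALSE)
}

#' Export activity node values and histogram as TSV
#' @param h an [activity_history()].
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_hist.tsv`.
#' @export
write_activity_tsv <- function(h, prefix) {
  write.table(data.frame(species = h$species, node_value = h$node_values),
              paste0(prefix, "_nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(h$histogram, paste0(prefix, "_hist.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
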