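#' Validate a pairwise identity matrix
#'
#' @param m square numeric matrix of percent identities with dimnames;
#'   symmetric, diagonal 100, entries in \[0, 100\].
#' @return the matrix, invisibly checked.
#' @export
identity_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2,
            !is.null(rownames(m)), identical(rownames(m), colnames(m)))
  if (any(is.na(m)) || any(m < 0) || any(m > 100))
    stop("identity_matrix: entries must be in [0, 100] and complete")
  if (max(abs(m - t(m))) > 1e-8) stop("identity_matrix: not symmetric")
  if (max(abs(diag(m) - 100)) > 1e-8) stop("identity_matrix: diagonal must be 100")
  m
}

#' UPGMA clustering in percent-identity units
#'
#' Classical (size-weighted) UPGMA run directly on an identity matrix:
#' the pair with the highest identity merges first, and the identity of a
#' merged cluster to any other cluster is the arithmetic mean of its
#' members' identities weighted by cluster sizes. Each internal node stores
#' its merge identity; these node values are the divergence points used for
#' TE activity histories. Ties on the maximal identity are broken by the
#' lexicographically smallest pair of cluster labels, so output is
#' deterministic.
#'
#' The returned tree is ultrametric in identity units: a tip sits at
#' identity 100 and the branch from a child at identity `Ic` (100 for tips)
#' to its parent at `Ip` has length `(Ic - Ip) / 2`, so the cophenetic
#' distance between two tips is `100 -` their merge identity.
#'
#' @param m identity matrix (see [identity_matrix()]), n >= 2.
#' @return object of class `upgma_tree`: list with `phylo` (an
#'   [ape::read.tree()] tree), `node_values` (merge identities in merge
#'   order, non-increasing), and `newick`.
#' @export
upgma_identity <- function(m) {
  m <- identity_matrix(m)
  n <- nrow(m)
  labels <- rownames(m)
  active <- labels            # cluster label = lexicographically smallest member
  sizes <- setNames(rep(1L, n), labels)
  newick <- setNames(labels, labels)
  heights <- setNames(rep(100, n), labels)  # tip "identity" level
  D <- m
  node_values <- numeric(0)
  while (length(active) > 1L) {
    sub <- D[active, active, drop = FALSE]
    diag(sub) <- -Inf
    best <- max(sub)
    idx <- which(sub == best, arr.ind = TRUE)
    pairs <- t(apply(idx, 1L, function(ij) sort(c(active[ij[1L]], active[ij[2L]]))))
    pairs <- unique(pairs)
    ord <- order(pairs[, 1L], pairs[, 2L])
    a <- pairs[ord[1L], 1L]; b <- pairs[ord[1L], 2L]
    node_values <- c(node_values, best)
    bl_a <- (heights[[a]] - best) / 2
    bl_b <- (heights[[b]] - best) / 2
    lab <- a  # a < b lexicographically
    merged_nwk <- sprintf("(%s:%.10g,%s:%.10g)", newick[[a]], bl_a,
                          newick[[b]], bl_b)
    others <- setdiff(active, c(a, b))
    for (k in others) {
      D[lab, k] <- D[k, lab] <-
        (sizes[[a]] * D[a, k] + sizes[[b]] * D[b, k]) / (sizes[[a]] + sizes[[b]])
    }
    sizes[[lab]] <- sizes[[a]] + sizes[[b]]
    newick[[lab]] <- merged_nwk
    heights[[lab]] <- best
    active <- c(others, lab)
  }
  nwk <- paste0(newick[[active]], ";")
  structure(list(phylo = ape::read.tree(text = nwk),
                 node_values = node_values, newick = nwk),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d tips, node identities %s\n",
              length(x$phylo$tip.label),
              paste(round(x$node_values, 1), collapse = ", ")))
  invisible(x)
}

#' Internal-node identity values of a UPGMA tree
#'
#' The multiset of merge identities, one per internal node (n - 1 values
#' for n tips), in merge order (non-increasing). These are the divergence
#' points histogrammed as a TE activity history.
#'
#' @param t an `upgma_tree` from [upgma_identity()].
#' @return numeric vector of percent identities.
#' @export
node_values <- function(t) {
  stopifnot(inherits(t, "upgma_tree"))
  t$node_values
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining. Negative branch lengths are clamped to
#' zero with the excess moved to the sister branch (the pair sum is
#' preserved), so additive matrices are reconstructed exactly and
#' near-additive ones stay non-negative. Ties in the Q criterion are broken
#' by the lexicographically smallest label pair.
#'
#' @param d symmetric distance matrix with dimnames (e.g. p-distances), or
#'   a `dist` object; n >= 3.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3,
            !is.null(rownames(d)))
  if (any(is.na(d))) stop("nj_tree: distance matrix has undefined entries")
  labels <- rownames(d)
  sub <- setNames(labels, labels)      # partial newick per active node
  D <- d
  active <- labels
  while (length(active) > 3L) {
    n <- length(active)
    A <- D[active, active, drop = FALSE]
    r <- rowSums(A)
    Q <- (n - 2) * A - outer(r, r, "+")
    diag(Q) <- Inf
    best <- min(Q)
    idx <- which(Q <= best + 1e-12, arr.ind = TRUE)
    pairs <- unique(t(apply(idx, 1L, function(ij)
      sort(c(active[ij[1L]], active[ij[2L]])))))
    ord <- order(pairs[, 1L], pairs[, 2L])
    a <- pairs[ord[1L], 1L]; b <- pairs[ord[1L], 2L]
    dab <- D[a, b]
    ba <- dab / 2 + (r[[a]] - r[[b]]) / (2 * (n - 2))
    bb <- dab - ba
    if (ba < 0) { bb <- dab; ba <- 0 }
    if (bb < 0) { ba <- dab; bb <- 0 }
    u <- paste0(a, "\r", b)  # internal label, never collides with tips
    for (k in setdiff(active, c(a, b))) {
      D <- add_row_col(D, u, k, (D[a, k] + D[b, k] - dab) / 2)
    }
    if (!(u %in% rownames(D))) D <- add_row_col(D, u, NULL, NULL)
    sub[[u]] <- sprintf("(%s:%.12g,%s:%.12g)", sub[[a]], ba, sub[[b]], bb)
    active <- c(setdiff(active, c(a, b)), u)
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  ba <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  bb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  bc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  ba <- max(ba, 0); bb <- max(bb, 0); bc <- max(bc, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", sub[[a]], ba,
                 sub[[b]], bb, sub[[c3]], bc)
  ape::read.tree(text = nwk)
}

add_row_col <- function(D, u, k, val) {
  if (!(u %in% rownames(D))) {
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- u
  }
  if (!is.null(k)) D[u, k] <- D[k, u] <- val
  D
}

#' Pairwise p-distance from an alignment
#'
#' Proportion of differing sites between aligned sequences under one of
#' three gap-deletion rules: `pairwise` (each pair drops its own gapped
#' columns), `complete` (columns with any gap are dropped for everyone),
#' or `partial` (columns with site coverage below `cutoff` are dropped,
#' then pairwise deletion on the rest).
#'
#' @param aln character matrix (rows = taxa, gap = "-"), or named character
#'   vector of equal-length aligned strings.
#' @param deletion one of `"pairwise"`, `"complete"`, `"partial"`.
#' @param cutoff site-coverage cutoff for partial deletion (default 0.8).
#' @return symmetric matrix of p-distances.
#' @export
p_distance <- function(aln, deletion = c("pairwise", "complete", "partial"),
                       cutoff = 0.8) {
  deletion <- match.arg(deletion)
  A <- as_alignment_matrix(aln)
  gap <- A == "-" | A == "N" | is.na(A)
  if (deletion == "complete") {
    keep <- colSums(gap) == 0L
    A <- A[, keep, drop = FALSE]; gap <- gap[, keep, drop = FALSE]
  } else if (deletion == "partial") {
    keep <- colMeans(!gap) >= cutoff
    A <- A[, keep, drop = FALSE]; gap <- gap[, keep, drop = FALSE]
  }
  n <- nrow(A)
  D <- matrix(0, n, n, dimnames = list(rownames(A), rownames(A)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("p_distance: no comparable columns for pair ", rownames(A)[i],
           " / ", rownames(A)[j])
    D[i, j] <- D[j, i] <- mean(A[i, ok] != A[j, ok])
  }
  D
}

as_alignment_matrix <- function(aln) {
  if (is.matrix(aln)) {
    if (is.null(rownames(aln))) rownames(aln) <- paste0("t", seq_len(nrow(aln)))
    return(aln)
  }
  if (methods::is(aln, "DNAStringSet") || methods::is(aln, "AAStringSet"))
    aln <- as.character(aln)
  stopifnot(is.character(aln), length(unique(nchar(aln))) == 1L)
  if (is.null(names(aln))) names(aln) <- paste0("t", seq_along(aln))
  do.call(rbind, lapply(setNames(aln, names(aln)), function(s)
    strsplit(s, "")[[1L]]))
}

#' Write / read a square distance matrix in PHYLIP format
#'
#' Standard PHYLIP square format: a count line, then one line per taxon
#' with the (possibly truncated to 10 characters) label and its row.
#'
#' @param d symmetric numeric matrix with dimnames.
#' @param path file path.
#' @return `write_phylip_matrix` returns the path invisibly;
#'   `read_phylip_matrix` returns the matrix.
#' @export
write_phylip_matrix <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(substr(rownames(d)[i], 1L, 10L), width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_phylip_matrix
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    labs[i] <- parts[1L]
    d[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(d) <- list(labs, labs)
  d
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `builder`, and attaches per-clade support (percent of
#' replicates containing each clade) as node labels of the builder's tree
#' on the full alignment. Seeded by the caller via [set.seed()];
#' bit-reproducible for a fixed seed.
#'
#' @param aln alignment (matrix or aligned strings, >= 10 columns).
#' @param builder function(alignment matrix) -> `phylo` (or `upgma_tree`).
#' @param n_reps number of replicates; 0 returns the tree without supports.
#' @return list with `tree` (phylo, node.label = percent support) and
#'   `replicates` (list of phylo).
#' @export
bootstrap_support <- function(aln, builder, n_reps = 100) {
  A <- as_alignment_matrix(aln)
  stopifnot(ncol(A) >= 10)
  as_phylo <- function(x) if (inherits(x, "upgma_tree")) x$phylo else x
  main <- as_phylo(builder(A))
  if (n_reps <= 0) return(list(tree = main, replicates = list()))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol(A), ncol(A), replace = TRUE)
    reps[[r]] <- as_phylo(builder(A[, idx, drop = FALSE]))
  }
  cnt <- ape::prop.clades(main, reps, rooted = ape::is.rooted(main))
  cnt[is.na(cnt)] <- 0
  main$node.label <- round(100 * cnt / n_reps, 1)
  list(tree = main, replicates = reps)
}
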