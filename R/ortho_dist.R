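#' Reciprocal best hits between two CDS sets
#'
#' Orthologs are paired when a's best hit in set B is b and b's best hit in
#' set A is a, under the thresholds in `params` (protocol defaults:
#' single HSP, identity > 60, e-value < 1e-5, score > 200). Best hits are
#' ranked by score, then identity, then lexicographic subject id, so the
#' pairing is deterministic.
#'
#' @param cds_a,cds_b named character vectors / `DNAStringSet` of
#'   nucleotide CDS.
#' @param params a [search_params()].
#' @return data.frame `id_a, id_b, identity` (identity of the a-vs-b best
#'   hit). The pairing is a partial matching: no CDS appears twice.
#' @export
reciprocal_best_hits <- function(cds_a, cds_b,
                                 params = search_params(min_identity = 60,
                                                        min_score = 200,
                                                        min_length = 0,
                                                        max_evalue = 1e-5)) {
  a <- as_seq_vector(cds_a, "cds_a")
  b <- as_seq_vector(cds_b, "cds_b")
  stopifnot(length(a) > 0L, length(b) > 0L)
  best_of <- function(hits) {
    if (nrow(hits) == 0L) return(hits)
    hits <- hits[order(-hits$score, -hits$pident, hits$sseqid), , drop = FALSE]
    hits[!duplicated(hits$qseqid), , drop = FALSE]
  }
  ab <- best_of(local_search(a, b, params))
  ba <- best_of(local_search(b, a, params))
  if (nrow(ab) == 0L || nrow(ba) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  back <- setNames(ba$sseqid, ba$qseqid)
  keep <- !is.na(back[ab$sseqid]) & back[ab$sseqid] == ab$qseqid
  out <- data.frame(id_a = ab$qseqid[keep], id_b = ab$sseqid[keep],
                    identity = ab$pident[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Infer the coding frame of a CDS
#'
#' Translates the three forward frames with the standard genetic code and
#' returns the unique frame whose translation has zero internal stop
#' codons (the final codon is not tested, so a terminal stop is allowed).
#' Returns `NA` when no frame or more than one frame qualifies; ambiguous
#' sequences are dropped from distance computations rather than risking a
#' misaligned codon structure.
#'
#' @param seq nucleotide sequence (single string), length >= 30.
#' @return integer 0, 1 or 2, or `NA_integer_`.
#' @export
infer_coding_frame <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 30L) stop("infer_coding_frame: sequence shorter than 30 bp")
  seq <- toupper(seq)
  ok <- integer(0)
  for (f in 0:2) {
    n <- nchar(seq) - f
    n <- n - n %% 3L
    if (n < 6L) next
    starts <- seq(f + 1L, f + n - 3L, by = 3L)  # internal codons only
    codons <- substring(seq, starts, starts + 2L)
    if (!any(codons %in% STOPS)) ok <- c(ok, f)
  }
  if (length(ok) == 1L) ok else NA_integer_
}

trim_to_frame <- function(seq, frame) {
  n <- nchar(seq) - frame
  n <- n - n %% 3L
  substr(seq, frame + 1L, frame + n)
}

# standard-code translation via a plain codon lookup (unknown or
# ambiguous codons translate to X); much lighter than S4 dispatch when
# called per gene in tight loops
translate_cds <- function(seq) {
  code <- .horizTE_cache$genetic_code
  if (is.null(code)) {
    code <- Biostrings::GENETIC_CODE
    .horizTE_cache$genetic_code <- code
  }
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  starts <- seq(1L, n - 2L, 3L)
  aa <- unname(code[substring(seq, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Protein-guided codon alignment of two in-frame CDS
#'
#' Aligns the two translations with affine-gap global alignment (BLOSUM62)
#' and back-maps the gaps onto codons; codon columns containing a gap on
#' either side are removed entirely, leaving the gap-free codon-aligned
#' region used for identity computation.
#'
#' @param cds_a,cds_b in-frame nucleotide sequences (already trimmed to
#'   their coding frame, lengths divisible by 3).
#' @return list with `codons_a`, `codons_b`: equal-length character
#'   vectors of aligned codons, gap-free.
#' @export
codon_align <- function(cds_a, cds_b) {
  stopifnot(nchar(cds_a) %% 3L == 0L, nchar(cds_b) %% 3L == 0L)
  pa <- translate_cds(cds_a); pb <- translate_cds(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  cod_a <- substring(cds_a, seq(1L, nchar(cds_a) - 2L, 3L),
                     seq(3L, nchar(cds_a), 3L))
  cod_b <- substring(cds_b, seq(1L, nchar(cds_b) - 2L, 3L),
                     seq(3L, nchar(cds_b), 3L))
  ia <- cumsum(sa != "-"); ib <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  list(codons_a = cod_a[ia[keep]], codons_b = cod_b[ib[keep]])
}

#' Build an ortholog pair with third-codon identity
#'
#' Resolves the coding frame of both sequences, codon-aligns them, removes
#' gapped codon columns, and computes the percent identity over third
#' codon positions.
#'
#' @param cds_a,cds_b nucleotide CDS (single strings).
#' @param min_codons pairs with fewer gap-free codons are flagged
#'   unreliable (`identity = NA`).
#' @return list of class `ortholog_pair`: `frame_a`, `frame_b`,
#'   `n_codons`, `third_codon_identity` (percent, one decimal; `NA` when
#'   a frame is unresolved or too few codons align), `reliable`.
#' @export
ortholog_pair <- function(cds_a, cds_b, min_codons = 10L) {
  fa <- infer_coding_frame(cds_a); fb <- infer_coding_frame(cds_b)
  out <- list(frame_a = fa, frame_b = fb, n_codons = 0L,
              third_codon_identity = NA_real_, reliable = FALSE)
  class(out) <- "ortholog_pair"
  if (is.na(fa) || is.na(fb)) return(out)
  al <- codon_align(trim_to_frame(cds_a, fa), trim_to_frame(cds_b, fb))
  out$n_codons <- length(al$codons_a)
  if (out$n_codons < min_codons) return(out)
  out$third_codon_identity <- third_codon_identity(al)
  out$reliable <- TRUE
  out
}

#' Percent identity at third codon positions
#'
#' @param aln gap-free codon alignment from [codon_align()] (list with
#'   `codons_a`, `codons_b`).
#' @return percent identity over third codon positions, rounded to one
#'   decimal. Symmetric in its arguments.
#' @export
third_codon_identity <- function(aln) {
  stopifnot(length(aln$codons_a) == length(aln$codons_b),
            length(aln$codons_a) > 0L)
  t_a <- substr(aln$codons_a, 3L, 3L)
  t_b <- substr(aln$codons_b, 3L, 3L)
  round(100 * mean(t_a == t_b), 1)
}

#' Pairwise species distances from third-codon identity of orthologs
#'
#' For every species pair, identifies reciprocal-best-hit orthologs,
#' resolves frames, codon-aligns, and computes third-codon identities.
#' `per_gene` keeps the per-ortholog distribution (box-plot material);
#' `concatenated` pools matches over genes, i.e. the length-weighted
#' identity of the concatenated gap-free third-codon columns.
#'
#' @param cds_sets named list: species -> named character vector of CDS.
#' @param params RBH search parameters.
#' @param min_codons reliability cutoff per pair.
#' @return list with `identity` (symmetric percent matrix, diagonal 100,
#'   `NA` where a pair has no reliable ortholog), `per_gene` (named list
#'   `"A|B"` -> numeric vector), `n_orthologs` (matrix of pair counts).
#' @export
species_matrix <- function(cds_sets,
                           params = search_params(min_identity = 60,
                                                  min_score = 200,
                                                  min_length = 0,
                                                  max_evalue = 1e-5),
                           min_codons = 10L) {
  sp <- names(cds_sets)
  stopifnot(!is.null(sp), length(sp) >= 2L)
  m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  diag(m) <- 100
  nmat <- matrix(0L, length(sp), length(sp), dimnames = list(sp, sp))
  per_gene <- list()
  for (i in seq_along(sp)[-length(sp)]) for (j in (i + 1L):length(sp)) {
    rbh <- reciprocal_best_hits(cds_sets[[i]], cds_sets[[j]], params)
    idents <- numeric(0); match3 <- 0L; total3 <- 0L
    for (k in seq_len(nrow(rbh))) {
      fa <- infer_coding_frame(cds_sets[[i]][[rbh$id_a[k]]])
      fb <- infer_coding_frame(cds_sets[[j]][[rbh$id_b[k]]])
      if (is.na(fa) || is.na(fb)) next
      al <- codon_align(trim_to_frame(cds_sets[[i]][[rbh$id_a[k]]], fa),
                        trim_to_frame(cds_sets[[j]][[rbh$id_b[k]]], fb))
      if (length(al$codons_a) < min_codons) next
      idents <- c(idents, third_codon_identity(al))
      match3 <- match3 + sum(substr(al$codons_a, 3L, 3L) ==
                             substr(al$codons_b, 3L, 3L))
      total3 <- total3 + length(al$codons_a)
    }
    per_gene[[paste(sp[i], sp[j], sep = "|")]] <- idents
    nmat[i, j] <- nmat[j, i] <- length(idents)
    if (total3 > 0L)
      m[i, j] <- m[j, i] <- round(100 * match3 / total3, 1)
  }
  list(identity = m, per_gene = per_gene, n_orthologs = nmat)
}

#' Concatenated third-codon alignment across species
#'
#' Builds a multi-species third-codon alignment by reciprocal-best-hit
#' orthology against a reference species: genes with an RBH partner in
#' every species are codon-aligned pairwise to the reference and projected
#' onto the reference codon coordinates (positions deleted in a partner
#' become gaps). Third-codon characters are then concatenated per species.
#'
#' @param cds_sets named list: species -> named character vector of CDS.
#' @param reference reference species name (default: first).
#' @param params RBH search parameters.
#' @param n_genes optional cap: randomly sample this many shared genes
#'   (seeded by the caller).
#' @return character matrix (species x third-codon sites, gap `-`).
#' @export
concat_third_codon_alignment <- function(cds_sets, reference = names(cds_sets)[1L],
                                         params = search_params(min_identity = 60,
                                                                min_score = 200,
                                                                min_length = 0,
                                                                max_evalue = 1e-5),
                                         n_genes = NULL) {
  sp <- names(cds_sets)
  stopifnot(reference %in% sp)
  others <- setdiff(sp, reference)
  maps <- list()
  for (s in others) {
    rbh <- reciprocal_best_hits(cds_sets[[reference]], cds_sets[[s]], params)
    maps[[s]] <- setNames(rbh$id_b, rbh$id_a)
  }
  shared <- Reduce(intersect, lapply(maps, names))
  if (!is.null(n_genes) && length(shared) > n_genes)
    shared <- sort(sample(shared, n_genes))
  cols <- list()
  for (g in shared) {
    ref_seq <- cds_sets[[reference]][[g]]
    fr <- infer_coding_frame(ref_seq)
    if (is.na(fr)) next
    ref_cds <- trim_to_frame(ref_seq, fr)
    ncod <- nchar(ref_cds) %/% 3L
    block <- matrix("-", length(sp), ncod, dimnames = list(sp, NULL))
    ref3 <- substr(substring(ref_cds, seq(1L, nchar(ref_cds) - 2L, 3L),
                             seq(3L, nchar(ref_cds), 3L)), 3L, 3L)
    block[reference, ] <- ref3
    ok <- TRUE
    for (s in others) {
      oth_seq <- cds_sets[[s]][[maps[[s]][[g]]]]
      fo <- infer_coding_frame(oth_seq)
      if (is.na(fo)) { ok <- FALSE; break }
      al <- codon_align_indexed(ref_cds, trim_to_frame(oth_seq, fo))
      block[s, al$ref_index] <- substr(al$codons_b, 3L, 3L)
    }
    if (ok) cols[[g]] <- block
  }
  if (!length(cols)) stop("concat_third_codon_alignment: no usable shared genes")
  do.call(cbind, cols)
}

# codon_align variant that also returns the reference codon index of each
# retained column
codon_align_indexed <- function(cds_a, cds_b) {
  pa <- translate_cds(cds_a); pb <- translate_cds(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  cod_b <- substring(cds_b, seq(1L, nchar(cds_b) - 2L, 3L),
                     seq(3L, nchar(cds_b), 3L))
  ia <- cumsum(sa != "-"); ib <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  list(ref_index = ia[keep], codons_b = cod_b[ib[keep]])
}

#' Species tree from a concatenated third-codon alignment
#'
#' Computes the pairwise identity matrix under complete deletion (any
#' column with a gap in any species is dropped), builds the UPGMA tree in
#' identity units, and attaches bootstrap supports by resampling alignment
#' columns.
#'
#' @param aln character matrix from [concat_third_codon_alignment()]
#'   (species x sites), or any alignment accepted by [p_distance()].
#' @param bootstraps number of bootstrap replicates (default 100).
#' @return list with `tree` (`upgma_tree` on the full alignment),
#'   `identity` (the complete-deletion identity matrix), and `support`
#'   (phylo with node labels = percent support), `NULL` when
#'   `bootstraps = 0`.
#' @export
species_tree_upgma <- function(aln, bootstraps = 100) {
  A <- as_alignment_matrix(aln)
  ident <- function(M) {
    D <- p_distance(M, deletion = "complete")
    m <- 100 * (1 - D); diag(m) <- 100; m
  }
  main <- upgma_identity(ident(A))
  sup <- NULL
  if (bootstraps > 0) {
    bs <- bootstrap_support(A, function(M) upgma_identity(ident(M)),
                            n_reps = bootstraps)
    sup <- bs$tree
  }
  list(tree = main, identity = ident(A), support = sup)
}
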