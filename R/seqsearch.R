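#' Search parameter set for the local similarity engine
#'
#' Bundles the thresholds and scoring scheme used by [local_search()].
#' Scores are in engine units (`match`/`mismatch` per aligned column), so a
#' perfect 500 bp match scores 500 under the defaults; the default
#' `min_score` values used throughout the package are calibrated to these
#' units. All `min_*` thresholds are strict (a hit must exceed them),
#' matching the ">90% identity, score > 500, match length > 500 bp"
#' convention of the screening protocol; `max_evalue` is strict the other
#' way (`evalue < max_evalue`).
#'
#' @param min_identity minimum percent identity, exclusive (0-100).
#' @param min_score minimum alignment score, exclusive, in engine units.
#' @param min_length minimum aligned length in bp, exclusive.
#' @param max_evalue maximum e-value, exclusive. The e-value is advisory
#'   (Karlin-Altschul with lambda fitted to the scoring scheme and K = 0.3);
#'   the score cutoff is the binding filter.
#' @param single_hsp keep only the best-scoring HSP per (query, subject)
#'   sequence pair.
#' @param match,mismatch integer match reward and mismatch penalty.
#' @param gap_open,gap_extend gap penalties, retained for interface
#'   completeness; the engine reports ungapped HSPs (see Details).
#' @param seed_length exact-match seed length for the seed-and-extend scan.
#' @param xdrop x-drop termination threshold for seed extension, in score
#'   units.
#'
#' @details The engine finds exact `seed_length`-mers shared between query
#' and subject (both strands) and extends each seed without gaps in both
#' directions under an x-drop criterion, reporting the maximal-scoring
#' extent. Identity is matches / aligned columns. Ungapped HSPs are exact
#' for the substitution-only divergence model the rest of the package works
#' in; alignment-sensitive steps (codon alignment of orthologs, homolog-tree
#' alignments) use full dynamic programming instead of this engine.
#'
#' @return an object of class `search_params`.
#' @export
search_params <- function(min_identity = 90, min_score = 500, min_length = 500,
                          max_evalue = 1e-10, single_hsp = TRUE,
                          match = 1L, mismatch = -2L,
                          gap_open = -5L, gap_extend = -2L,
                          seed_length = 12L, xdrop = 40L) {
  stopifnot(min_identity >= 0, min_identity <= 100, min_length >= 0,
            max_evalue > 0, match > 0, mismatch < 0, seed_length >= 4)
  structure(list(min_identity = min_identity, min_score = min_score,
                 min_length = min_length, max_evalue = max_evalue,
                 single_hsp = isTRUE(single_hsp),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seed_length = as.integer(seed_length),
                 xdrop = as.integer(xdrop)),
            class = "search_params")
}

#' A set of sequences belonging to one species
#'
#' The basic container all searches run over: a species label plus named
#' contig (or CDS) sequences.
#'
#' @param species single species label.
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   non-empty sequences with unique names.
#' @return object of class `genome_set` with elements `species` and `seqs`
#'   (a `DNAStringSet`).
#' @export
genome_set <- function(species, seqs) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(methods::is(seqs, "DNAStringSet"), length(seqs) > 0L)
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("genome_set: sequences must have unique non-empty names")
  if (sum(Biostrings::width(seqs)) <= 0L) stop("genome_set: total length must be > 0")
  structure(list(species = species, seqs = seqs), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %s: %d sequence(s), %s bp total\n", x$species,
              length(x$seqs), format(sum(Biostrings::width(x$seqs)), big.mark = ",")))
  invisible(x)
}

# normalise query/subject inputs to a named character vector
as_seq_vector <- function(x, arg = "input") {
  if (inherits(x, "genome_set")) x <- x$seqs
  if (methods::is(x, "DNAStringSet") || methods::is(x, "AAStringSet"))
    x <- as.character(x)
  if (is.list(x) && !is.null(x$seq)) { # single record list(id=, seq=)
    v <- as.character(x$seq); names(v) <- x$id; x <- v
  }
  if (!is.character(x)) stop(arg, ": cannot interpret as sequences")
  if (length(x) == 0L) return(setNames(character(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(arg, ": sequences must be named")
  bad <- grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", x)
  if (any(bad))
    stop(arg, ": non-nucleotide characters in ", paste(names(x)[bad], collapse = ", "))
  toupper(x)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Karlin-Altschul lambda for an ungapped match/mismatch scheme under
# uniform base composition; cached per scheme. K is taken as 0.3.
ka_lambda <- function(match, mismatch) {
  key <- paste0("lambda_", match, "_", mismatch)
  if (!is.null(.horizTE_cache[[key]])) return(.horizTE_cache[[key]])
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lam <- uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  .horizTE_cache[[key]] <- lam
  lam
}

KA_K <- 0.3

raw_to_hits <- function(raw, qnames, snames, qlens, slens, strand,
                        params, subject_total) {
  if (nrow(raw) == 0L) {
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      strand = character(), score = integer(),
                      matches = integer(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  qs <- raw$qstart; qe <- raw$qend
  if (strand == "-") { # query was searched reverse-complemented
    L <- qlens[raw$qidx]
    qs <- L - raw$qend; qe <- L - raw$qstart
  }
  lam <- ka_lambda(params$match, params$mismatch)
  data.frame(qseqid = qnames[raw$qidx], sseqid = snames[raw$sidx],
             pident = round(100 * raw$matches / raw$length, 1),
             length = raw$length,
             qstart = qs, qend = qe,
             sstart = raw$sstart, send = raw$send,
             strand = strand, score = raw$score, matches = raw$matches,
             evalue = KA_K * qlens[raw$qidx] * subject_total *
               exp(-lam * raw$score),
             stringsAsFactors = FALSE)
}

#' BLAST-like local similarity search
#'
#' Seed-and-extend local search of every query sequence against every
#' subject sequence, on both strands, with hits filtered by the thresholds
#' in `params`. Coordinates are 0-based half-open and always reported on
#' the forward strand of both sequences; `strand == "-"` means the reverse
#' complement of the query region aligns to the forward subject region.
#'
#' @param query,subject a [genome_set()], `DNAStringSet`, or named
#'   character vector of nucleotide sequences.
#' @param params a [search_params()] object.
#' @return `data.frame` with columns `qseqid, sseqid, pident, length,
#'   qstart, qend, sstart, send, strand, score, matches, evalue`, ordered
#'   by decreasing score. Empty input gives an empty frame.
#' @export
local_search <- function(query, subject, params = search_params()) {
  stopifnot(inherits(params, "search_params"))
  q <- as_seq_vector(query, "query")
  s <- as_seq_vector(subject, "subject")
  if (length(q) == 0L || length(s) == 0L) {
    return(raw_to_hits(data.frame(), character(), character(), integer(),
                       integer(), "+", params, 0))
  }
  qlens <- nchar(q); slens <- nchar(s)
  subject_total <- sum(as.numeric(slens))
  min_raw <- as.integer(max(params$min_score + 1L, params$seed_length))
  fwd <- cpp_seed_search(unname(q), unname(s), params$seed_length,
                         params$match, params$mismatch, params$xdrop, min_raw)
  rev <- cpp_seed_search(unname(reverse_complement(q)), unname(s),
                         params$seed_length, params$match, params$mismatch,
                         params$xdrop, min_raw)
  hits <- rbind(
    raw_to_hits(fwd, names(q), names(s), qlens, slens, "+", params, subject_total),
    raw_to_hits(rev, names(q), names(s), qlens, slens, "-", params, subject_total))
  hits <- hits[hits$pident > params$min_identity &
               hits$score > params$min_score &
               hits$length > params$min_length &
               hits$evalue < params$max_evalue, , drop = FALSE]
  if (nrow(hits) > 1L) {
    hits <- hits[order(-hits$score, -hits$pident, hits$qseqid, hits$sseqid), ,
                 drop = FALSE]
    # a plus and minus pass can rediscover the same region pair; also
    # collapse duplicate extensions of one HSP
    key <- with(hits, paste(qseqid, sseqid, qstart, qend, sstart, send))
    hits <- hits[!duplicated(key), , drop = FALSE]
    if (params$single_hsp) {
      hits <- hits[!duplicated(paste(hits$qseqid, hits$sseqid)), , drop = FALSE]
    }
  }
  rownames(hits) <- NULL
  hits
}

#' Best hit of one element in each of several genomes
#'
#' For each genome, returns at most one row: the highest-scoring hit of the
#' element passing all thresholds in `params` (ties broken by identity).
#'
#' @param element single named sequence (length-1 named character vector,
#'   `DNAStringSet` of length 1, or `list(id=, seq=)`).
#' @param genomes list of [genome_set()] objects.
#' @param params a [search_params()]; set `min_identity` to the scan
#'   threshold the caller needs (88 for HT-event expansion scans, 90 for
#'   retention).
#' @return `data.frame` with one row per species that has a qualifying hit:
#'   `species, sseqid, identity, score, length, sstart, send, strand`.
#' @export
best_hit_per_species <- function(element, genomes, params = search_params()) {
  stopifnot(is.list(genomes), length(genomes) > 0L)
  rows <- lapply(genomes, function(gs) {
    stopifnot(inherits(gs, "genome_set"))
    h <- local_search(element, gs, params)
    if (nrow(h) == 0L) return(NULL)
    h <- h[order(-h$score, -h$pident), , drop = FALSE][1L, , drop = FALSE]
    data.frame(species = gs$species, sseqid = h$sseqid, identity = h$pident,
               score = h$score, length = h$length, sstart = h$sstart,
               send = h$send, strand = h$strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(species = character(), sseqid = character(),
                                      identity = numeric(), score = integer(),
                                      length = integer(), sstart = integer(),
                                      send = integer(), strand = character(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a FASTA file into a genome_set
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param species species label; defaults to the file base name.
#' @return a [genome_set()].
#' @export
read_genome_fasta <- function(path, species = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(species))
    species <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  genome_set(species, seqs)
}

#' Write sequences to FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Export a hit table as tab-separated text
#'
#' Columns follow the familiar 12-ish column tabular layout
#' (`qseqid sseqid pident length qstart qend sstart send evalue bitscore
#' strand`); coordinates in the file are 1-based inclusive on the forward
#' strand (internal representation is 0-based half-open), and `bitscore`
#' carries the raw engine score. A header line starting with `#` documents
#' this.
#'
#' @param hits hit table from [local_search()].
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(qseqid = hits$qseqid, sseqid = hits$sseqid,
                    pident = hits$pident, length = hits$length,
                    qstart = hits$qstart + 1L, qend = hits$qend,
                    sstart = hits$sstart + 1L, send = hits$send,
                    evalue = signif(hits$evalue, 3), bitscore = hits$score,
                    strand = hits$strand, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", paste(names(out), collapse = "\t"),
                   "(1-based inclusive, forward-strand coordinates; bitscore = raw engine score)"),
             con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
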