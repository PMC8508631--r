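#' Round half-up to a fixed number of decimals
#'
#' Percentage reporting uses half-up rounding (0.05 at one decimal always
#' rounds up), unlike R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Summary statistics of a set of classified, validated HT events
#'
#' Computes the headline composition numbers: events per TE class, the
#' share of LTR-retrotransposon events (Copia + Gypsy) that are Copia, the
#' number of events with a determined donor, focal-taxon donor/recipient
#' counts, and the Copia share among multi-recipient events. Percentages
#' are half-up, one decimal.
#'
#' Either supply `events` + `assignments` (pipeline outputs) or the
#' pre-tabulated `class_counts` / `multi_recipient_counts` directly.
#'
#' @param events named list of classified `ht_event`s.
#' @param assignments list of [classify_roles()] results.
#' @param class_counts named integer vector of event counts per TE class
#'   (e.g. `c(Copia = 30, Gypsy = 4, MuDR = 1)`).
#' @param multi_recipient_counts length-2 vector `c(total, copia)`:
#'   multi-recipient events and how many of them involve Copia elements.
#' @param focal_species species counted for the focal-taxon role tallies.
#' @return object of class `ht_summary` (a list of counts and
#'   percentages; see Details).
#' @export
summarize_ht <- function(events = NULL, assignments = NULL,
                         class_counts = NULL, multi_recipient_counts = NULL,
                         focal_species = character(0)) {
  if (is.null(class_counts)) {
    stopifnot(!is.null(events))
    cls <- vapply(events, function(ev) ev$te_class, "")
    class_counts <- table(cls)
  }
  class_counts <- setNames(as.integer(class_counts), names(class_counts))
  n_events <- sum(class_counts)
  ltr <- sum(class_counts[names(class_counts) %in% c("Copia", "Gypsy")])
  copia <- sum(class_counts[names(class_counts) == "Copia"])
  copia_share <- if (ltr > 0) round_half_up(100 * copia / ltr, 1) else 0

  n_donor_determined <- NA_integer_
  n_focal_recipient <- NA_integer_; n_focal_donor <- NA_integer_
  if (!is.null(assignments)) {
    has_donor <- vapply(assignments, function(a) any(a$role == "donor"), TRUE)
    n_donor_determined <- sum(has_donor)
    n_focal_recipient <- sum(vapply(assignments, function(a)
      any(a$role == "recipient" & a$species %in% focal_species), TRUE))
    n_focal_donor <- sum(vapply(assignments, function(a)
      any(a$role == "donor" & a$species %in% focal_species), TRUE))
    if (is.null(multi_recipient_counts)) {
      mr <- multi_recipient_summary(assignments, events)
      multi_recipient_counts <- c(nrow(mr),
                                  sum(mr$te_class == "Copia", na.rm = TRUE))
    }
  }
  mr_total <- if (is.null(multi_recipient_counts)) NA_integer_
              else multi_recipient_counts[1L]
  mr_copia <- if (is.null(multi_recipient_counts)) NA_integer_
              else multi_recipient_counts[2L]
  mr_share <- if (!is.na(mr_total) && mr_total > 0)
    round_half_up(100 * mr_copia / mr_total, 1) else NA_real_

  structure(list(n_events = n_events, class_counts = class_counts,
                 ltr_events = ltr, copia_share_of_ltr = copia_share,
                 n_donor_determined = n_donor_determined,
                 n_focal_recipient = n_focal_recipient,
                 n_focal_donor = n_focal_donor,
                 n_multi_recipient = unname(mr_total),
                 multi_recipient_copia_share = unname(mr_share)),
            class = "ht_summary")
}

#' @export
print.ht_summary <- function(x, ...) {
  cat("<ht_summary>\n")
  cat(sprintf("  events: %d (%s)\n", x$n_events,
              paste(names(x$class_counts), x$class_counts, sep = ":",
                    collapse = ", ")))
  cat(sprintf("  Copia share of LTR events: %.1f%%\n", x$copia_share_of_ltr))
  if (!is.na(x$n_donor_determined))
    cat(sprintf("  donor determined: %d; focal recipient: %d; focal donor: %d\n",
                x$n_donor_determined, x$n_focal_recipient, x$n_focal_donor))
  if (!is.na(x$n_multi_recipient))
    cat(sprintf("  multi-recipient events: %d (Copia share %.1f%%)\n",
                x$n_multi_recipient, x$multi_recipient_copia_share))
  invisible(x)
}

#' Run the full HT detection pipeline on simulated or provided genomes
#'
#' Executes screen -> conserved filter -> redundancy collapse -> expansion
#' -> TE classification -> activity histories -> validation/role
#' classification -> summary, caching each stage as an RDS file under
#' `outdir` so a rerun resumes after the last completed stage. Writes the
#' event table, role table and a JSON run manifest.
#'
#' @param sim a [simulate_genomes()] result, or a list with elements
#'   `genomes` (list of [genome_set()]), optional `decoy_library`,
#'   `te_library`, and `config` (for `focal_species`).
#' @param focal_species focal species labels (defaults to
#'   `sim$config$focal_species`).
#' @param cfg a [screen_config()].
#' @param act an [activity_params()].
#' @param threshold donor/recipient identity threshold.
#' @param outdir output directory (created); `NULL` disables caching and
#'   file output.
#' @param resume reuse cached stage outputs when present.
#' @return list with `candidates`, `filtered`, `events` (expanded,
#'   classified), `histories`, `trees`, `assignments`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(sim, focal_species = sim$config$focal_species,
                         cfg = screen_config(), act = activity_params(),
                         threshold = 90, outdir = NULL, resume = TRUE) {
  t0 <- Sys.time()
  timings <- list()
  cache <- function(name, expr) {
    if (!is.null(outdir)) {
      path <- file.path(outdir, paste0(name, ".rds"))
      if (resume && file.exists(path)) return(readRDS(path))
    }
    tic <- Sys.time()
    val <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), tic, units = "secs"))
    if (!is.null(outdir)) saveRDS(val, file.path(outdir, paste0(name, ".rds")))
    val
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genomes <- sim$genomes
  species <- vapply(genomes, function(g) g$species, "")
  names(genomes) <- species
  focal <- genomes[intersect(species, focal_species)]
  others <- genomes[setdiff(species, focal_species)]
  stopifnot(length(focal) >= 1L, length(others) >= 1L)

  cands <- cache("stage1_screen", screen_candidates(focal, others, cfg))
  filtered <- cache("stage2_filter", {
    if (!is.null(sim$decoy_library) && length(sim$decoy_library)) {
      filter_conserved(cands, sim$decoy_library, cfg)
    } else list(kept = cands, removed = NULL)
  })
  events <- cache("stage3_collapse", collapse_redundant(filtered$kept, cfg))
  events <- cache("stage4_expand", {
    ev <- expand_events(events, genomes, cfg)
    ev <- Filter(function(e) sum(e$per_species$retained) >= 2L, ev)
    if (!is.null(sim$te_library) && length(sim$te_library))
      ev <- classify_te(ev, sim$te_library)
    ev
  })
  validated <- cache("stage5_validate", {
    hist_all <- list(); trees <- list(); assignments <- list()
    for (ev in events) {
      hom <- gather_homologs(ev, genomes, act)
      hists <- lapply(hom, activity_history, params = act)
      tr <- tryCatch(homolog_tree(hom), error = function(e) NULL)
      if (is.null(tr)) next
      assignments[[ev$event_id]] <- classify_roles(ev, hists, tr, threshold)
      hist_all[[ev$event_id]] <- hists
      trees[[ev$event_id]] <- tr
    }
    list(histories = hist_all, trees = trees, assignments = assignments)
  })
  assignments <- Filter(function(a) isTRUE(attr(a, "validated")),
                        validated$assignments)
  events <- events[names(assignments)]
  summary <- summarize_ht(events, assignments, focal_species = focal_species)

  manifest <- list(
    package_version = as.character(utils::packageVersion("horizTE")),
    seed = if (!is.null(sim$config)) sim$config$seed else NA,
    n_species = length(genomes), focal_species = unname(focal_species),
    thresholds = list(screening_identity = cfg$screening$min_identity,
                      retention = cfg$retention_identity,
                      expansion_scan = cfg$expansion_scan_identity,
                      cluster = cfg$cluster_identity,
                      paralog = act$cluster_identity,
                      role = threshold),
    stage_counts = list(candidates = nrow(cands$meta),
                        after_conserved_filter = nrow(filtered$kept$meta),
                        events_collapsed = length(events),
                        events_validated = length(assignments)),
    timings_sec = timings,
    started = format(t0, "%Y-%m-%d %H:%M:%S %Z"))
  if (!is.null(outdir)) {
    write_events_tsv(events, file.path(outdir, "events.tsv"))
    if (length(assignments))
      write_roles_tsv(assignments, file.path(outdir, "roles.tsv"))
    for (id in names(validated$trees))
      ape::write.tree(validated$trees[[id]],
                      file.path(outdir, paste0(id, "_homologs.nwk")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(candidates = cands, filtered = filtered, events = events,
       histories = validated$histories, trees = validated$trees,
       assignments = assignments, summary = summary, manifest = manifest)
}

#' Match validated events to simulation ground truth
#'
#' Assigns each pipeline event to the implanted HT family whose ancestor
#' its element matches best (identity > 80), and reports per-family
#' recovery plus any events not attributable to an implanted element.
#'
#' @param events named list of `ht_event`s from [run_pipeline()].
#' @param sim the [simulate_genomes()] result.
#' @return list with `matched` (data.frame `event_id, family, donor_true,
#'   recipients_true`), `n_true`, `n_recovered` (distinct implanted
#'   families recovered), `n_unmatched` (events matching no implant).
#' @export
match_events_to_truth <- function(events, sim) {
  fams <- sim$truth$ht_events$family
  lib <- setNames(unlist(sim$truth$ancestors[fams]), fams)
  params <- search_params(min_identity = 80, min_score = 100,
                          min_length = 100, max_evalue = 1e-10)
  rows <- list()
  unmatched <- 0L
  for (ev in events) {
    h <- local_search(setNames(ev$element, "q"), lib, params)
    if (nrow(h) == 0L) { unmatched <- unmatched + 1L; next }
    fam <- h$sseqid[1L]
    tr <- sim$truth$ht_events[sim$truth$ht_events$family == fam, ]
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = ev$event_id, family = fam, donor_true = tr$donor,
      recipients_true = tr$recipients, stringsAsFactors = FALSE)
  }
  matched <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(), family = character(),
               donor_true = character(), recipients_true = character(),
               stringsAsFactors = FALSE)
  list(matched = matched, n_true = length(fams),
       n_recovered = length(unique(matched$family)),
       n_unmatched = unmatched)
}
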