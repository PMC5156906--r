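# The candidate-substrate filter funnel: motif scan -> disordered-window
# filter -> (phosphosite presence | PxIxIT co-occurrence in disorder) ->
# intersection.

#' Funnel configuration
#'
#' @param motif_name Name of the motif to scan for (a key of
#'   [build_motif_library()]); default `"expanded_pilxvp"`.
#' @param disorder_threshold Per-residue disorder score threshold in \[0, 1\]
#'   defining "disordered"; default 0.4.
#' @param disorder_aggregation How a motif window's scores are aggregated
#'   before thresholding: `"mean"` (default; robust to single-residue dips),
#'   `"all"` (every residue must pass) or `"any"` (one residue suffices).
#' @param pxixit_dialects Non-empty subset of `c("short", "long")`; default
#'   both.
#' @param require_pxixit_in_idr Logical; when `TRUE` (default) a PxIxIT site
#'   only counts if its own window passes the same disorder criterion.
#' @return A `funnel_config` list.
#' @export
funnel_config <- function(motif_name = "expanded_pilxvp",
                          disorder_threshold = 0.4,
                          disorder_aggregation = c("mean", "all", "any"),
                          pxixit_dialects = c("short", "long"),
                          require_pxixit_in_idr = TRUE) {
  if (!is.numeric(disorder_threshold) || length(disorder_threshold) != 1L ||
      disorder_threshold < 0 || disorder_threshold > 1)
    stop("disorder_threshold must be a single value in [0, 1]")
  disorder_aggregation <- match.arg(disorder_aggregation)
  pxixit_dialects <- unique(match.arg(pxixit_dialects, c("short", "long"),
                                      several.ok = TRUE))
  if (length(pxixit_dialects) == 0L) stop("pxixit_dialects must be non-empty")
  structure(list(motif_name = motif_name,
                 disorder_threshold = disorder_threshold,
                 disorder_aggregation = disorder_aggregation,
                 pxixit_dialects = pxixit_dialects,
                 require_pxixit_in_idr = isTRUE(require_pxixit_in_idr)),
            class = "funnel_config")
}

.window_disordered <- function(scores, start, end, threshold, aggregation) {
  w <- scores[start:end]
  agg <- switch(aggregation,
                mean = mean(w),
                all = min(w),
                any = max(w))
  agg >= threshold
}

#' Keep motif matches whose window lies in a disordered region
#'
#' A match survives iff the aggregation (per `config$disorder_aggregation`)
#' of the per-residue disorder scores over its `[start, end]` window meets
#' `config$disorder_threshold`.
#'
#' @param matches Match table with `protein_id`, `start`, `end`.
#' @param profiles Named list of per-residue score vectors.
#' @param config A [funnel_config()].
#' @return The surviving subset of `matches`.
#' @export
idr_filter <- function(matches, profiles, config = funnel_config()) {
  if (nrow(matches) == 0L) return(matches)
  missing <- setdiff(unique(matches$protein_id), names(profiles))
  if (length(missing) > 0L)
    stop("no disorder profile for protein(s): ",
         paste(missing, collapse = ", "))
  keep <- vapply(seq_len(nrow(matches)), function(i) {
    .window_disordered(profiles[[matches$protein_id[[i]]]],
                       matches$start[[i]], matches$end[[i]],
                       config$disorder_threshold,
                       config$disorder_aggregation)
  }, logical(1))
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep proteins with at least one annotated pSer/pThr residue
#'
#' @param protein_ids Character vector of candidate ids.
#' @param phospho Phosphosite table (`protein_id`, `position`, `residue`).
#' @return The subset of `protein_ids` with >= 1 phosphosite anywhere in the
#'   protein, original order preserved.
#' @export
phospho_filter <- function(protein_ids, phospho) {
  protein_ids[protein_ids %in% unique(phospho$protein_id)]
}

#' Keep proteins that also carry a PxIxIT site (optionally in disorder)
#'
#' @param protein_ids Candidate ids.
#' @param proteome A `proteome` holding their sequences.
#' @param profiles Disorder profiles (needed when
#'   `config$require_pxixit_in_idr`).
#' @param config A [funnel_config()].
#' @return The subset of `protein_ids` whose sequence contains >= 1 PxIxIT
#'   match of the selected dialects passing the disorder criterion.
#' @export
pxixit_cooccurrence <- function(protein_ids, proteome, profiles = NULL,
                                config = funnel_config()) {
  keep <- vapply(protein_ids, function(id) {
    if (!id %in% names(proteome))
      stop("no sequence for protein: ", id)
    m <- scan_pxixit(proteome[[id]]$sequence, config$pxixit_dialects)
    if (nrow(m) == 0L) return(FALSE)
    if (!config$require_pxixit_in_idr) return(TRUE)
    if (is.null(profiles) || !id %in% names(profiles))
      stop("no disorder profile for protein: ", id)
    any(vapply(seq_len(nrow(m)), function(i) {
      .window_disordered(profiles[[id]], m$start[[i]], m$end[[i]],
                         config$disorder_threshold,
                         config$disorder_aggregation)
    }, logical(1)))
  }, logical(1))
  protein_ids[keep]
}

#' Run the full candidate-substrate funnel
#'
#' Stages, in order: raw motif scan; disordered-window (IDR) filter; then,
#' branching in parallel from the IDR-stage protein set, the phosphosite
#' filter and the PxIxIT co-occurrence filter; finally their intersection.
#' The report carries per-stage match and protein counts, the surviving id
#' sets, and the set-algebra cross-tabs between the two parallel branches.
#'
#' @param proteome A `proteome`.
#' @param profiles Named list of disorder score vectors covering it.
#' @param phospho Phosphosite table.
#' @param config A [funnel_config()].
#' @param motif Optional [motif_def()] overriding `config$motif_name`.
#' @return A `funnel_report` object; see [print.funnel_report()].
#' @export
run_funnel <- function(proteome, profiles, phospho,
                       config = funnel_config(), motif = NULL) {
  if (is.null(motif)) {
    lib <- build_motif_library()
    if (!config$motif_name %in% names(lib))
      stop("unknown motif '", config$motif_name, "'; available: ",
           paste(names(lib), collapse = ", "))
    motif <- lib[[config$motif_name]]
  }
  raw <- scan_proteome(proteome, motif)
  idr <- idr_filter(raw, profiles, config)
  idr_ids <- unique(idr$protein_id)
  phospho_ids <- phospho_filter(idr_ids, phospho)
  pxixit_ids <- pxixit_cooccurrence(idr_ids, proteome, profiles, config)
  both_ids <- intersect(phospho_ids, pxixit_ids)

  stage <- function(name, matches, ids = unique(matches$protein_id)) {
    list(name = name, motif_count = nrow(matches),
         protein_count = length(ids), matches = matches, protein_ids = ids)
  }
  restrict <- function(matches, ids)
    { out <- matches[matches$protein_id %in% ids, , drop = FALSE]
      rownames(out) <- NULL; out }

  stages <- list(
    raw = stage("raw", raw),
    idr = stage("idr", idr),
    phospho = stage("phospho", restrict(idr, phospho_ids), phospho_ids),
    pxixit = stage("pxixit", restrict(idr, pxixit_ids), pxixit_ids),
    intersection = stage("intersection", restrict(idr, both_ids), both_ids)
  )
  multi <- sum(table(idr$protein_id) >= 2L)
  structure(list(
    stages = stages,
    both_count = length(both_ids),
    pxixit_only_count = length(setdiff(pxixit_ids, phospho_ids)),
    phospho_only_count = length(setdiff(phospho_ids, pxixit_ids)),
    neither_count = length(setdiff(idr_ids, union(phospho_ids, pxixit_ids))),
    multi_motif_protein_count = as.integer(multi),
    motif_name = motif$name,
    config = unclass(config),
    proteome_ids = names(proteome),
    schema_version = 1L
  ), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report> motif:", x$motif_name, "\n")
  for (s in x$stages)
    cat(sprintf("  %-13s %5d motifs in %5d proteins\n",
                s$name, s$motif_count, s$protein_count))
  cat(sprintf("  both pSer/pThr & PxIxIT: %d;  PxIxIT only: %d;  phospho only: %d;  neither: %d\n",
              x$both_count, x$pxixit_only_count, x$phospho_only_count,
              x$neither_count))
  cat("  proteins with multiple motifs (IDR stage):",
      x$multi_motif_protein_count, "\n")
  invisible(x)
}

#' Serialize / load a funnel report (versioned JSON)
#'
#' @param report A `funnel_report`.
#' @param path JSON file path.
#' @param provenance Optional named list merged into the JSON (e.g. tool
#'   version, config hash, seed).
#' @export
write_funnel_report <- function(report, path, provenance = NULL) {
  obj <- list(
    schema_version = report$schema_version,
    motif_name = report$motif_name,
    config = report$config,
    stages = lapply(report$stages, function(s) {
      list(name = s$name, motif_count = s$motif_count,
           protein_count = s$protein_count,
           protein_ids = as.list(s$protein_ids),
           matches = s$matches)
    }),
    both_count = report$both_count,
    pxixit_only_count = report$pxixit_only_count,
    phospho_only_count = report$phospho_only_count,
    neither_count = report$neither_count,
    multi_motif_protein_count = report$multi_motif_protein_count,
    proteome_ids = as.list(report$proteome_ids)
  )
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_funnel_report
#' @export
read_funnel_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stages <- lapply(obj$stages, function(s) {
    m <- as.data.frame(s$matches, stringsAsFactors = FALSE)
    if (nrow(m) == 0L)
      m <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      motif = character(), stringsAsFactors = FALSE)
    m$start <- as.integer(m$start); m$end <- as.integer(m$end)
    list(name = s$name, motif_count = as.integer(s$motif_count),
         protein_count = as.integer(s$protein_count), matches = m,
         protein_ids = as.character(unlist(s$protein_ids)))
  })
  structure(list(
    stages = stages,
    both_count = as.integer(obj$both_count),
    pxixit_only_count = as.integer(obj$pxixit_only_count),
    phospho_only_count = as.integer(obj$phospho_only_count),
    neither_count = as.integer(obj$neither_count),
    multi_motif_protein_count = as.integer(obj$multi_motif_protein_count),
    motif_name = obj$motif_name,
    config = obj$config,
    proteome_ids = as.character(unlist(obj$proteome_ids)),
    schema_version = as.integer(obj$schema_version)
  ), class = "funnel_report")
}

#' Raw motif search over a confirmed-interactor set
#'
#' Scans every interactor sequence for the named motif with no disorder or
#' phosphosite filtering — a plain presence/absence search used to gauge how
#' well a motif definition recovers proteins already known to bind the
#' phosphatase, and to collect matched instances for logo building.
#'
#' @param interactors A `proteome` (or named sequence vector) of confirmed
#'   interactors; must be non-empty and every id must have a sequence.
#' @param motif_name Key into [build_motif_library()], or a [motif_def()].
#' @return List with `hit_count` (proteins with >= 1 match), `n_interactors`,
#'   `matches` (full match table) and `hit_ids`.
#' @export
validate_conserved <- function(interactors, motif_name = "structural_pilxvp") {
  seqs <- .as_sequence_vector(interactors)
  if (length(seqs) == 0L) stop("interactor set must be non-empty")
  if (any(is.na(seqs) | !nzchar(seqs)))
    stop("interactor id(s) without sequence")
  if (inherits(motif_name, "slim_motif")) {
    motif <- motif_name
  } else {
    lib <- build_motif_library()
    if (!motif_name %in% names(lib))
      stop("unknown motif '", motif_name, "'; available: ",
           paste(names(lib), collapse = ", "))
    motif <- lib[[motif_name]]
  }
  matches <- scan_proteome(seqs, motif)
  hit_ids <- unique(matches$protein_id)
  list(hit_count = length(hit_ids), n_interactors = length(seqs),
       matches = matches, hit_ids = hit_ids)
}
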