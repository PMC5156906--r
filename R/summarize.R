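# Post-funnel analytics: phosphosite distance/orientation summaries,
# position probability matrices (sequence-logo numerics) and localization
# breakdowns.

#' Phosphosite distance configuration
#'
#' The per-orientation cutoffs describe how far a phosphosite must sit from
#' the docking motif to be mechanistically reachable by the phosphatase
#' active site (about 30 angstroms away from the motif pocket): at least 9
#' residues C-terminal, at least 20 residues N-terminal. `cutoff_mode = "max"`
#' flips the reading so the cutoffs bound the distance from above instead.
#'
#' @param min_cterm_offset Minimum (or with `"max"`, maximum) residue
#'   separation C-terminal of the motif end; default 9.
#' @param min_nterm_offset Same for sites N-terminal of the motif start;
#'   default 20.
#' @param near_window Window (residues) for the "nearby phosphosite"
#'   fraction; default 50.
#' @param cutoff_mode `"min"` (default) or `"max"`.
#' @return A `distance_config` list.
#' @export
distance_config <- function(min_cterm_offset = 9, min_nterm_offset = 20,
                            near_window = 50,
                            cutoff_mode = c("min", "max")) {
  stopifnot(min_cterm_offset >= 0, min_nterm_offset >= 0, near_window >= 0)
  structure(list(min_cterm_offset = min_cterm_offset,
                 min_nterm_offset = min_nterm_offset,
                 near_window = near_window,
                 cutoff_mode = match.arg(cutoff_mode)),
            class = "distance_config")
}

#' Distances from one motif match to its qualifying phosphosites
#'
#' Distances are anchored at the motif's nearest edge: for a site C-terminal
#' of the motif, `position - end`; for a site N-terminal, `start - position`.
#' Sites inside the motif are ignored. A site qualifies if its distance
#' satisfies the orientation's cutoff (see [distance_config()]). The nearest
#' qualifying site per orientation is reported, and the match's overall
#' orientation is that of the nearer of the two (ties resolve C-terminal,
#' the dominant orientation).
#'
#' @param match One-row match (list or data frame row) with `start`, `end`.
#' @param phospho_positions Integer vector of 1-based phosphosite positions
#'   in the same protein.
#' @param config A [distance_config()].
#' @return One-row data frame: `start`, `end`, `cterm_distance`,
#'   `nterm_distance` (NA when no qualifying site on that side),
#'   `orientation` (`"C"`, `"N"` or NA) and `distance` (the nearest
#'   qualifying distance).
#' @export
phospho_distances <- function(match, phospho_positions,
                              config = distance_config()) {
  start <- as.integer(match$start); end <- as.integer(match$end)
  pos <- as.integer(phospho_positions)
  cd <- pos[pos > end] - end
  nd <- start - pos[pos < start]
  qualifies <- function(d, cutoff) {
    if (config$cutoff_mode == "min") d[d >= cutoff] else d[d <= cutoff]
  }
  cd <- qualifies(cd, config$min_cterm_offset)
  nd <- qualifies(nd, config$min_nterm_offset)
  cbest <- if (length(cd) > 0L) min(cd) else NA_integer_
  nbest <- if (length(nd) > 0L) min(nd) else NA_integer_
  if (is.na(cbest) && is.na(nbest)) {
    orient <- NA_character_; dist <- NA_integer_
  } else if (is.na(nbest) || (!is.na(cbest) && cbest <= nbest)) {
    orient <- "C"; dist <- cbest
  } else {
    orient <- "N"; dist <- nbest
  }
  data.frame(start = start, end = end,
             cterm_distance = cbest, nterm_distance = nbest,
             orientation = orient, distance = dist,
             stringsAsFactors = FALSE)
}

#' Distance records for a whole match table
#'
#' @param matches Match table with `protein_id`, `start`, `end`.
#' @param phospho Phosphosite table (`protein_id`, `position`).
#' @param config A [distance_config()].
#' @return Data frame of per-match records (see [phospho_distances()]) with
#'   `protein_id` prepended.
#' @export
phospho_distance_table <- function(matches, phospho,
                                   config = distance_config()) {
  by_prot <- split(phospho$position, phospho$protein_id)
  rows <- lapply(seq_len(nrow(matches)), function(i) {
    id <- matches$protein_id[[i]]
    rec <- phospho_distances(matches[i, ], by_prot[[id]], config)
    cbind(data.frame(protein_id = id, stringsAsFactors = FALSE), rec)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), cterm_distance = integer(),
                      nterm_distance = integer(), orientation = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Aggregate per-match distance records
#'
#' Orientation fractions are computed over matches with at least one
#' qualifying site; `fraction_within_near_window` is the share of those whose
#' nearest qualifying site lies within `config$near_window` residues.
#'
#' @param records Data frame from [phospho_distance_table()] (or rbind of
#'   [phospho_distances()] rows).
#' @param config A [distance_config()].
#' @return List: `n_assigned`, `fraction_cterm`, `fraction_nterm`,
#'   `fraction_within_near_window`, `mean_first_distance`.
#' @export
aggregate_distances <- function(records, config = distance_config()) {
  rec <- records[!is.na(records$orientation), , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no match has a qualifying phosphosite")
  list(n_assigned = nrow(rec),
       fraction_cterm = mean(rec$orientation == "C"),
       fraction_nterm = mean(rec$orientation == "N"),
       fraction_within_near_window = mean(rec$distance <= config$near_window),
       mean_first_distance = mean(rec$distance))
}

#' Position probability matrix of aligned motif instances
#'
#' Plain per-column frequencies (no pseudocounts or small-sample correction),
#' plus per-column information content `log2(20) - H_j` in bits, where `H_j`
#' is the Shannon entropy of column `j` — the numeric core of a sequence
#' logo.
#'
#' @param instances Character vector of equal-length motif strings.
#' @return A `ppm` object: 20 x L probability matrix (`prob`), information
#'   content vector (`ic`), `instance_count`, `length`.
#' @export
build_ppm <- function(instances) {
  instances <- toupper(as.character(instances))
  if (length(instances) == 0L) stop("need at least one instance")
  lens <- nchar(instances)
  if (length(unique(lens)) != 1L)
    stop("instances must all have the same length")
  L <- lens[[1]]
  mat <- matrix(0, nrow = length(AA_ALPHABET), ncol = L,
                dimnames = list(AA_ALPHABET, seq_len(L)))
  chars <- do.call(rbind, strsplit(instances, ""))
  for (j in seq_len(L)) {
    counts <- table(factor(chars[, j], levels = AA_ALPHABET))
    mat[, j] <- as.numeric(counts) / length(instances)
  }
  ic <- apply(mat, 2, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  structure(list(prob = mat, ic = unname(ic),
                 instance_count = length(instances), length = L),
            class = "ppm")
}

#' @export
print.ppm <- function(x, ...) {
  cat("<ppm> ", x$length, " columns from ", x$instance_count,
      " instances; information content (bits): ",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Export a PPM in MEME minimal-motif format
#'
#' @param ppm A `ppm` object.
#' @param path Output path.
#' @param name Motif name written to the file.
#' @export
write_meme <- function(ppm, path, name = "motif") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste("ALPHABET=", paste(AA_ALPHABET, collapse = ""))," ",
               paste("MOTIF", name),
               sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
                       ppm$length, ppm$instance_count)), con)
  for (j in seq_len(ppm$length))
    writeLines(paste(sprintf("%.6f", ppm$prob[, j]), collapse = " "), con)
  invisible(path)
}

#' Export a PPM as TSV (residues x columns, plus an information-content row)
#' @param ppm A `ppm` object.
#' @param path Output path.
#' @export
write_ppm_tsv <- function(ppm, path) {
  df <- as.data.frame(ppm$prob)
  names(df) <- paste0("pos", seq_len(ppm$length))
  df <- cbind(data.frame(residue = rownames(ppm$prob),
                         stringsAsFactors = FALSE), df)
  ic <- c(residue = "IC_bits", as.list(ppm$ic))
  df <- rbind(df, as.data.frame(ic, col.names = names(df),
                                stringsAsFactors = FALSE))
  .write_tsv(df, path)
}

#' Subcellular localization breakdown of a protein set
#'
#' @param protein_ids Non-empty character vector.
#' @param localization Localization table (`protein_id`, `category`);
#'   proteins absent from it are binned as `other`.
#' @return Data frame over [LOCALIZATION_VOCAB]: `category`, `count`,
#'   `fraction`; counts sum to `length(unique(protein_ids))`, fractions to 1.
#' @export
localization_breakdown <- function(protein_ids, localization) {
  ids <- unique(protein_ids)
  if (length(ids) == 0L) stop("protein id set must be non-empty")
  cat_map <- localization$category[match(ids, localization$protein_id)]
  cat_map[is.na(cat_map)] <- "other"
  counts <- table(factor(cat_map, levels = LOCALIZATION_VOCAB))
  data.frame(category = LOCALIZATION_VOCAB,
             count = as.integer(counts),
             fraction = as.numeric(counts) / length(ids),
             stringsAsFactors = FALSE)
}
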