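# Readers/writers for the pipeline's file formats: FASTA proteomes and
# tab-delimited disorder, phosphosite, localization and match tables.

#' Fixed subcellular-localization vocabulary
#'
#' Categories a protein may carry; proteins absent from the localization
#' table, or carrying an unmapped label, fall into `other`.
#' @export
LOCALIZATION_VOCAB <- c("nucleus", "membrane", "intracellular_transport",
                        "cytoplasm", "mitochondrion", "secreted",
                        "cytoskeleton", "other")

#' Read a proteome from FASTA
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased. Gap characters (`-`, `.`) are rejected: the
#' pipeline scans unaligned sequences.
#'
#' @param path Path to a FASTA file.
#' @return A `proteome`: named list of records, each a list with `id`,
#'   `sequence` and `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate protein id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(aa))
  if (any(grepl("[-.]", seqs)))
    stop("gap characters in FASTA sequences; provide unaligned sequences")
  recs <- lapply(seq_along(ids), function(i) {
    list(id = ids[[i]], sequence = unname(seqs[[i]]),
         length = nchar(seqs[[i]]))
  })
  names(recs) <- ids
  structure(recs, class = "proteome")
}

#' Write a proteome to FASTA
#' @param proteome A `proteome` (or named character vector of sequences).
#' @param path Output path.
#' @export
write_fasta <- function(proteome, path) {
  seqs <- .as_sequence_vector(proteome)
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @export
print.proteome <- function(x, ...) {
  lens <- vapply(x, `[[`, numeric(1), "length")
  cat("<proteome> ", length(x), " proteins, ",
      sum(lens), " residues (median length ", stats::median(lens), ")\n",
      sep = "")
  invisible(x)
}

#' Read per-residue disorder scores
#'
#' Expects a header row and columns `protein_id`, `position`, `score`.
#' Positions must run contiguously from 1 within each protein and scores lie
#' in \[0, 1\]. Scores come from any per-residue disorder predictor (e.g.
#' IUPRED in either mode) or from the synthetic generator; the pipeline only
#' thresholds them.
#'
#' @param path Path to the TSV file.
#' @param proteome Optional `proteome`; when given, profile lengths are
#'   validated against sequence lengths.
#' @return Named list of numeric score vectors, one per protein.
#' @export
read_disorder_tsv <- function(path, proteome = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "score")
  if (!all(need %in% names(tab)))
    stop("disorder TSV must have columns: ", paste(need, collapse = ", "))
  if (any(tab$score < 0 | tab$score > 1))
    stop("disorder scores must lie in [0, 1]")
  profiles <- split(tab[, c("position", "score")], tab$protein_id)
  out <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    p <- p[order(p$position), , drop = FALSE]
    if (!identical(as.integer(p$position), seq_len(nrow(p))))
      stop("positions for protein '", id, "' are not contiguous from 1")
    p$score
  })
  names(out) <- names(profiles)
  if (!is.null(proteome)) {
    for (id in names(out)) {
      if (!id %in% names(proteome)) next
      if (length(out[[id]]) != proteome[[id]]$length)
        stop("disorder profile length for '", id,
             "' does not match sequence length")
    }
  }
  out
}

#' Write per-residue disorder scores
#' @param profiles Named list of numeric vectors in \[0, 1\].
#' @param path Output path.
#' @export
write_disorder_tsv <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    data.frame(protein_id = id, position = seq_along(profiles[[id]]),
               score = profiles[[id]], stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}

#' Read phosphosite annotations
#'
#' Columns `protein_id`, `position` (1-based), `residue` (S or T). When a
#' proteome is supplied, every row is checked against the sequence: the
#' residue at the stated position must equal the stated residue, and the
#' position must be in range; offending rows are listed in the error.
#'
#' @param path Path to the TSV file.
#' @param proteome Optional `proteome` for validation.
#' @return Data frame with columns `protein_id`, `position`, `residue`.
#' @export
read_phospho_tsv <- function(path, proteome = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(residue = "character"))
  need <- c("protein_id", "position", "residue")
  if (!all(need %in% names(tab)))
    stop("phospho TSV must have columns: ", paste(need, collapse = ", "))
  tab$residue <- toupper(tab$residue)
  if (!all(tab$residue %in% c("S", "T")))
    stop("phospho residues must be S or T")
  if (!is.null(proteome) && nrow(tab) > 0L) {
    bad <- character()
    for (i in seq_len(nrow(tab))) {
      id <- tab$protein_id[[i]]; pos <- tab$position[[i]]
      if (!id %in% names(proteome)) next
      seqv <- proteome[[id]]$sequence
      if (pos < 1L || pos > nchar(seqv) ||
          substr(seqv, pos, pos) != tab$residue[[i]])
        bad <- c(bad, sprintf("%s:%d(%s)", id, pos, tab$residue[[i]]))
    }
    if (length(bad) > 0L)
      stop("phospho rows disagree with sequences: ",
           paste(bad, collapse = ", "))
  }
  tab[, need]
}

#' Write phosphosite annotations
#' @param phospho Data frame as returned by [read_phospho_tsv()].
#' @param path Output path.
#' @export
write_phospho_tsv <- function(phospho, path) .write_tsv(phospho, path)

#' Read subcellular localization labels
#'
#' Columns `protein_id`, `category`. One primary category per protein
#' (duplicates are an error). Labels outside the fixed vocabulary are first
#' passed through `mapping` (a named character vector, raw label ->
#' vocabulary term); anything still unrecognized collapses to `other`.
#'
#' @param path Path to the TSV file.
#' @param mapping Optional named character vector remapping raw labels.
#' @return Data frame with columns `protein_id`, `category`.
#' @export
read_localization_tsv <- function(path, mapping = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "category")
  if (!all(need %in% names(tab)))
    stop("localization TSV must have columns: ", paste(need, collapse = ", "))
  dup <- tab$protein_id[duplicated(tab$protein_id)]
  if (length(dup) > 0L)
    stop("multiple localization rows for: ", paste(unique(dup), collapse = ", "))
  cat_raw <- tab$category
  if (!is.null(mapping)) {
    hit <- cat_raw %in% names(mapping)
    cat_raw[hit] <- unname(mapping[cat_raw[hit]])
  }
  cat_raw[!cat_raw %in% LOCALIZATION_VOCAB] <- "other"
  tab$category <- cat_raw
  tab[, need]
}

#' Write subcellular localization labels
#' @param localization Data frame with `protein_id`, `category`.
#' @param path Output path.
#' @export
write_localization_tsv <- function(localization, path)
  .write_tsv(localization, path)

#' Read a plain list of protein ids (one per line, `#` comments ignored)
#' @param path Path to the id list.
#' @return Character vector of unique ids.
#' @export
read_id_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Write / read a motif match table as TSV
#'
#' Columns: `protein_id`, `motif`, `start`, `end`, `sequence`, and `dialect`
#' when present. Round-trips are identity.
#'
#' @param matches Match table (data frame).
#' @param path File path.
#' @export
write_matches_tsv <- function(matches, path) {
  cols <- c("protein_id", "motif", "start", "end", "sequence")
  if ("dialect" %in% names(matches)) cols <- c(cols, "dialect")
  .write_tsv(matches[, cols, drop = FALSE], path)
}

#' @rdname write_matches_tsv
#' @export
read_matches_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
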