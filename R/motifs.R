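# Position-class motif definitions and scanning (PROSITE-style exact matching).

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter codes accepted at constrained motif positions. Ambiguity
#' codes (X, B, Z, U, O) are deliberately excluded: they fail every constrained
#' position and satisfy only wildcards, so a match is never claimed on an
#' unknown residue.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a residue class
#'
#' A residue class is one position of a position-class motif: either a set of
#' allowed canonical residues, or a wildcard (`x`) that accepts any residue.
#'
#' @param allowed Character vector of one-letter amino-acid codes. Ignored
#'   when `wildcard = TRUE` (the class then stands for all 20).
#' @param wildcard Logical; `TRUE` makes the position unconstrained.
#' @return An object of class `residue_class` with fields `allowed` and
#'   `wildcard`.
#' @export
residue_class <- function(allowed = character(), wildcard = FALSE) {
  if (wildcard) {
    allowed <- AA_ALPHABET
  } else {
    allowed <- toupper(as.character(allowed))
    if (length(allowed) == 1L && nchar(allowed) > 1L)
      allowed <- strsplit(allowed, "")[[1]]
    if (length(allowed) == 0L)
      stop("residue class must be non-empty unless wildcard")
    bad <- setdiff(allowed, AA_ALPHABET)
    if (length(bad) > 0L)
      stop("non-canonical residue code(s) in class: ", paste(bad, collapse = ", "))
  }
  structure(list(allowed = allowed, wildcard = wildcard),
            class = "residue_class")
}

#' Construct a motif definition
#'
#' @param name Motif identifier, unique within a library.
#' @param positions List of [residue_class()] objects, N- to C-terminal.
#' @return An object of class `slim_motif` with fields `name`, `positions`
#'   and `length`.
#' @export
motif_def <- function(name, positions) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(positions) == 0L) stop("motif must have at least one position")
  if (!all(vapply(positions, inherits, logical(1), "residue_class")))
    stop("all positions must be residue_class objects")
  structure(list(name = name, positions = positions,
                 length = length(positions)),
            class = "slim_motif")
}

#' @export
print.slim_motif <- function(x, ...) {
  cat("<slim_motif> ", x$name, ": ", as_prosite(x), "\n", sep = "")
  invisible(x)
}

#' Build the calcineurin docking-motif library
#'
#' Returns the six position-class motifs the pipeline scans for:
#' \describe{
#'   \item{core_lxvp}{`L-x-V-P`, the minimal historical LxVP core.}
#'   \item{canonical_pilxvp}{`[NQDESRTH]-[YTDFILV]-L-x-V-P` — a polar
#'     hydrogen-bond donor/acceptor at -2 and a hydrophobic residue at -1
#'     preceding the LxVP core.}
#'   \item{structural_pilxvp}{`[NQDESRTH]-[YTDFILV]-L-x-[VPLIH]-x` — the
#'     Val pocket relaxed to the residues it accommodates sterically, the
#'     shallow Pro pocket left unconstrained.}
#'   \item{expanded_pilxvp}{`[NQDESRTH]-[YTDFILV]-L-x-[VPL]-[PK]` — the
#'     optimized definition combining structural and confirmed-interactor
#'     evidence.}
#'   \item{pxixit_short}{`[P]-x-x-x-[IV]-[TDH]`, NFAT/PVIVIT-like.}
#'   \item{pxixit_long}{`[P]-x-x-x-x-[IV]-[TDH]`, AKAP79-like, one extra
#'     spacer residue.}
#' }
#' The three pi-phi-LxVP definitions are nested: every canonical match is an
#' expanded match, and every expanded match is a structural match.
#'
#' @return Named list of [motif_def()] objects.
#' @export
build_motif_library <- function() {
  pi_cls <- residue_class(c("N", "Q", "D", "E", "S", "R", "T", "H"))
  phi_cls <- residue_class(c("Y", "T", "D", "F", "I", "L", "V"))
  x <- residue_class(wildcard = TRUE)
  L <- residue_class("L")
  defs <- list(
    core_lxvp = motif_def("core_lxvp", list(
      L, x, residue_class("V"), residue_class("P"))),
    canonical_pilxvp = motif_def("canonical_pilxvp", list(
      pi_cls, phi_cls, L, x, residue_class("V"), residue_class("P"))),
    structural_pilxvp = motif_def("structural_pilxvp", list(
      pi_cls, phi_cls, L, x, residue_class(c("V", "P", "L", "I", "H")), x)),
    expanded_pilxvp = motif_def("expanded_pilxvp", list(
      pi_cls, phi_cls, L, x, residue_class(c("V", "P", "L")),
      residue_class(c("P", "K")))),
    pxixit_short = motif_def("pxixit_short", list(
      residue_class("P"), x, x, x, residue_class(c("I", "V")),
      residue_class(c("T", "D", "H")))),
    pxixit_long = motif_def("pxixit_long", list(
      residue_class("P"), x, x, x, x, residue_class(c("I", "V")),
      residue_class(c("T", "D", "H"))))
  )
  defs
}

#' Serialize a motif to a PROSITE-style pattern string
#'
#' Single-residue classes print as the bare letter, wildcards as `x`,
#' multi-residue classes in brackets, positions joined by `-`. The member
#' order inside brackets is preserved, so serialize/parse round-trips are
#' bit-exact.
#'
#' @param motif A [motif_def()] object.
#' @return Pattern string such as `"[NQDESRTH]-[YTDFILV]-L-x-[VPL]-[PK]"`.
#' @export
as_prosite <- function(motif) {
  stopifnot(inherits(motif, "slim_motif"))
  toks <- vapply(motif$positions, function(p) {
    if (p$wildcard) return("x")
    if (length(p$allowed) == 1L) return(p$allowed)
    paste0("[", paste(p$allowed, collapse = ""), "]")
  }, character(1))
  paste(toks, collapse = "-")
}

#' Parse a PROSITE-style pattern string into a motif definition
#'
#' @param pattern Pattern string as produced by [as_prosite()].
#' @param name Name for the resulting motif.
#' @return A [motif_def()] object.
#' @export
parse_prosite <- function(pattern, name = pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  positions <- lapply(toks, function(tok) {
    if (tok == "x" || tok == "X") return(residue_class(wildcard = TRUE))
    if (grepl("^\\[[A-Za-z]+\\]$", tok))
      return(residue_class(strsplit(substr(tok, 2L, nchar(tok) - 1L), "")[[1]]))
    if (grepl("^[A-Za-z]$", tok)) return(residue_class(tok))
    stop("cannot parse pattern token: '", tok, "'")
  })
  motif_def(name, positions)
}

# Per-position acceptance matrix for a character vector of residues:
# constrained positions accept only their canonical members, wildcards accept
# anything (including ambiguity codes).
.position_ok <- function(chars, cls) {
  if (cls$wildcard) rep(TRUE, length(chars)) else chars %in% cls$allowed
}

#' Scan a sequence for a position-class motif
#'
#' Every window is tested independently, so overlapping matches are all
#' reported. Coordinates are 1-based and inclusive. Sequences are uppercased
#' before matching; ambiguity codes (X, B, Z, U, O) fail constrained positions
#' and satisfy wildcards.
#'
#' @param sequence Amino-acid string (one-letter codes).
#' @param motif A [motif_def()] object.
#' @return Data frame with columns `start`, `end`, `sequence`, `motif`, one
#'   row per match, ascending by `start`; zero rows when nothing matches.
#' @examples
#' lib <- build_motif_library()
#' scan_motif("DDQYLAVPQH", lib$canonical_pilxvp)
#' @export
scan_motif <- function(sequence, motif) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  stopifnot(inherits(motif, "slim_motif"))
  seq <- toupper(sequence)
  n <- nchar(seq)
  L <- motif$length
  empty <- data.frame(start = integer(), end = integer(),
                      sequence = character(), motif = character(),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  chars <- strsplit(seq, "")[[1]]
  cand <- seq_len(n - L + 1L)
  for (j in seq_len(L)) {
    ok <- .position_ok(chars, motif$positions[[j]])
    cand <- cand[ok[cand + j - 1L]]
    if (length(cand) == 0L) return(empty)
  }
  data.frame(start = cand, end = cand + L - 1L,
             sequence = substring(seq, cand, cand + L - 1L),
             motif = motif$name, stringsAsFactors = FALSE)
}

#' Scan a whole proteome for one motif
#'
#' @param proteome List of protein records as returned by [read_fasta()], or
#'   a named character vector of sequences.
#' @param motif A [motif_def()] object.
#' @return Match table with a `protein_id` column prepended; proteins are
#'   visited in their stored order, matches within a protein ascending.
#' @export
scan_proteome <- function(proteome, motif) {
  seqs <- .as_sequence_vector(proteome)
  out <- lapply(names(seqs), function(id) {
    m <- scan_motif(seqs[[id]], motif)
    if (nrow(m) == 0L) return(NULL)
    cbind(data.frame(protein_id = id, stringsAsFactors = FALSE), m)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      motif = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify a hexamer into the nested pi-phi-LxVP motif classes
#'
#' Precedence follows language containment (canonical is a subset of expanded,
#' expanded of structural), so the labels are mutually exclusive and
#' exhaustive: `canonical` if the hexamer satisfies the canonical definition,
#' else `expanded_only`, else `structural_only`, else `no_match`.
#'
#' @param hexamer A 6-residue string; case is ignored.
#' @return One of `"canonical"`, `"expanded_only"`, `"structural_only"`,
#'   `"no_match"`.
#' @examples
#' classify_hexamer("SFLKVP")  # canonical
#' classify_hexamer("NTLqLP")  # expanded_only (case marks nothing)
#' @export
classify_hexamer <- function(hexamer) {
  if (!is.character(hexamer) || length(hexamer) != 1L || nchar(hexamer) != 6L)
    stop("hexamer must be a single 6-residue string")
  lib <- .motif_library_cache()
  hits <- function(m) nrow(scan_motif(hexamer, m)) > 0L
  if (hits(lib$canonical_pilxvp)) return("canonical")
  if (hits(lib$expanded_pilxvp)) return("expanded_only")
  if (hits(lib$structural_pilxvp)) return("structural_only")
  "no_match"
}

.motif_library_env <- new.env(parent = emptyenv())
.motif_library_cache <- function() {
  if (is.null(.motif_library_env$lib))
    .motif_library_env$lib <- build_motif_library()
  .motif_library_env$lib
}

#' Scan a sequence for PxIxIT docking sites
#'
#' Two pattern dialects exist: `short` (`[P]-x-x-x-[IV]-[TDH]`,
#' NFAT/PVIVIT-like) and `long` (`[P]-x-x-x-x-[IV]-[TDH]`, AKAP79-like). The
#' union of the selected dialects is returned, deduplicated by
#' (start, dialect) and labeled with the dialect that produced each match.
#'
#' @param sequence Amino-acid string.
#' @param dialects Non-empty subset of `c("short", "long")`.
#' @return Match table with columns `start`, `end`, `sequence`, `motif`,
#'   `dialect`, ordered by `start` then dialect.
#' @export
scan_pxixit <- function(sequence, dialects = c("short", "long")) {
  dialects <- unique(match.arg(dialects, c("short", "long"),
                               several.ok = TRUE))
  if (length(dialects) == 0L) stop("dialect set must be non-empty")
  lib <- .motif_library_cache()
  out <- lapply(dialects, function(d) {
    m <- scan_motif(sequence, lib[[paste0("pxixit_", d)]])
    if (nrow(m) == 0L) return(NULL)
    m$dialect <- d
    m
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), motif = character(),
                      dialect = character(), stringsAsFactors = FALSE))
  out <- out[!duplicated(out[, c("start", "dialect")]), , drop = FALSE]
  out <- out[order(out$start, out$dialect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of distinct sequences in a motif's match language
#'
#' The product of the per-position class sizes; divided by `20^length` it is
#' the exact per-window match probability under an iid uniform residue
#' background.
#'
#' @param motif A [motif_def()] object.
#' @return Integer count (as double, products can exceed .Machine$integer.max).
#' @export
motif_language_size <- function(motif) {
  stopifnot(inherits(motif, "slim_motif"))
  prod(vapply(motif$positions, function(p) length(p$allowed), numeric(1)))
}

# Coerce proteome-like inputs to a named character vector of sequences.
.as_sequence_vector <- function(proteome) {
  if (is.character(proteome)) {
    if (is.null(names(proteome)) || anyNA(names(proteome)))
      stop("sequence vector must be named by protein id")
    return(proteome)
  }
  if (is.list(proteome)) {
    ids <- vapply(proteome, `[[`, character(1), "id")
    seqs <- vapply(proteome, `[[`, character(1), "sequence")
    names(seqs) <- ids
    return(seqs)
  }
  stop("cannot interpret proteome input")
}
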