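# Shared fixtures: a reference panel of characterized docking-site hexamers,
# an independent brute-force scanner, and constructors for hand-built data.

# Hexamers from characterized calcineurin-binding sites with their known
# motif-class labels: 11 canonical pi-phi-LxVP sites and 17 sites matching
# only the [VPL]-[PK]-relaxed definition.
reference_hexamers <- function() {
  rbind(
    data.frame(hexamer = c("QYLAVP", "SFLKVP", "NILDVP", "SYLSVP", "SYLGVP",
                           "SVLAVP", "DLLSVP", "NTLGVP", "RVLSVP", "RFLKVP",
                           "TDLTVP"),
               label = "canonical", stringsAsFactors = FALSE),
    data.frame(hexamer = c("QLLTVK", "RDLQPP", "NYLDLK", "SVLIPP", "DYLRLK",
                           "QVLAVK", "DLLIPP", "RDLPPP", "RILRLK", "TILTPK",
                           "QLLPLP", "NILLLP", "TLLSPK", "RDLMPK", "SLLQPP",
                           "NTLQLP", "NFLCVK"),
               label = "expanded_only", stringsAsFactors = FALSE)
  )
}

# Independent oracle: naive per-window, per-position set-membership check,
# character by character. Returns match start positions.
oracle_scan_starts <- function(sequence, motif) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  L <- motif$length
  if (n < L) return(integer())
  starts <- integer()
  for (s in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      ch <- substr(sequence, s + j - 1L, s + j - 1L)
      cls <- motif$positions[[j]]
      if (!cls$wildcard && !(ch %in% cls$allowed)) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

random_seq <- function(n, alphabet = slimfunnel::AA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A random position-class motif for property tests.
random_motif <- function(len = sample(4:7, 1L)) {
  positions <- lapply(seq_len(len), function(i) {
    if (runif(1) < 0.3) return(residue_class(wildcard = TRUE))
    residue_class(sample(slimfunnel::AA_ALPHABET, sample(1:8, 1L)))
  })
  motif_def(paste0("rand", len), positions)
}

# Hand-built proteome from a named character vector of sequences.
proteome_from_seqs <- function(seqs) {
  recs <- lapply(names(seqs), function(id)
    list(id = id, sequence = unname(seqs[[id]]), length = nchar(seqs[[id]])))
  names(recs) <- names(seqs)
  structure(recs, class = "proteome")
}

# Vectorized membership of many hexamers (character matrix, one row each)
# in a 6-position motif; independent of scan_motif's candidate filtering.
hexamers_satisfy <- function(chmat, motif) {
  stopifnot(ncol(chmat) == motif$length)
  ok <- rep(TRUE, nrow(chmat))
  for (j in seq_len(motif$length)) {
    cls <- motif$positions[[j]]
    if (!cls$wildcard) ok <- ok & chmat[, j] %in% cls$allowed
  }
  ok
}
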