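# Seeded synthetic proteomes with planted docking motifs, block-model
# disorder profiles, phosphosite annotations and localization labels, plus
# the ground-truth manifest used to score funnel recovery.

#' Synthetic proteome generator configuration
#'
#' Defaults emulate the statistical shape of a curated proteome run through a
#' disorder predictor: iid background residues, disorder as high-scoring
#' blocks on a low baseline, phosphosites annotated on most proteins with a
#' strong C-terminal orientation preference relative to planted motifs, and
#' localization labels dominated by nucleus / membrane / intracellular
#' transport.
#'
#' @param seed Integer seed; mandatory, every draw derives from it.
#' @param n_proteins Number of proteins; default 300.
#' @param length_range Uniform protein length range (residues); default
#'   c(200, 800).
#' @param background Residue sampling probabilities over the 20 canonical
#'   amino acids; default uniform (which makes the analytic per-window match
#'   rates exact). `background = "human"` selects a human-proteome-like
#'   composition preset.
#' @param idr_mean_blocks Expected disordered blocks per protein (Poisson);
#'   default 3.
#' @param idr_block_length Block length range; default c(30, 80).
#' @param idr_score_range Per-residue score range inside blocks; default
#'   c(0.5, 1.0) (comfortably above the 0.4 threshold).
#' @param ordered_score_range Score range outside blocks; default c(0, 0.3).
#' @param phospho_presence_prob Probability a background (non-host) protein
#'   carries annotated phosphosites; default 0.8.
#' @param phospho_orientation_prob_c Probability a planted phosphosite sits
#'   C-terminal of its motif; default 0.8.
#' @param phospho_cterm_range Planted C-terminal distance range; default
#'   c(9, 50) (reachable yet within the near window).
#' @param phospho_nterm_range Planted N-terminal distance range; default
#'   c(20, 50).
#' @param localization_probs Named category probabilities; default
#'   nucleus 0.33, membrane 0.18, intracellular_transport 0.13, other 0.36.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed,
                         n_proteins = 300,
                         length_range = c(200, 800),
                         background = NULL,
                         idr_mean_blocks = 3,
                         idr_block_length = c(30, 80),
                         idr_score_range = c(0.5, 1.0),
                         ordered_score_range = c(0.0, 0.3),
                         phospho_presence_prob = 0.8,
                         phospho_orientation_prob_c = 0.8,
                         phospho_cterm_range = c(9, 50),
                         phospho_nterm_range = c(20, 50),
                         localization_probs = c(nucleus = 0.33,
                                                membrane = 0.18,
                                                intracellular_transport = 0.13,
                                                other = 0.36)) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("an integer seed is mandatory")
  if (identical(background, "human")) background <- HUMAN_AA_FREQS
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(length(background) == 20L,
            abs(sum(background) - 1) < 1e-6,
            length_range[1] <= length_range[2],
            phospho_presence_prob >= 0, phospho_presence_prob <= 1,
            phospho_orientation_prob_c >= 0, phospho_orientation_prob_c <= 1,
            all(names(localization_probs) %in% LOCALIZATION_VOCAB),
            abs(sum(localization_probs) - 1) < 1e-6)
  structure(list(seed = as.integer(seed), n_proteins = n_proteins,
                 length_range = length_range, background = background,
                 idr_mean_blocks = idr_mean_blocks,
                 idr_block_length = idr_block_length,
                 idr_score_range = idr_score_range,
                 ordered_score_range = ordered_score_range,
                 phospho_presence_prob = phospho_presence_prob,
                 phospho_orientation_prob_c = phospho_orientation_prob_c,
                 phospho_cterm_range = phospho_cterm_range,
                 phospho_nterm_range = phospho_nterm_range,
                 localization_probs = localization_probs),
            class = "synth_config")
}

#' Human-proteome-like amino-acid frequencies (UniProt/Swiss-Prot order of
#' magnitude, rounded and renormalized) for realism testing.
#' @export
HUMAN_AA_FREQS <- local({
  f <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.4, V = 6.0, W = 1.2, Y = 2.7)
  f / sum(f)
})

#' Specify motif plants for the generator
#'
#' Each row asks for `count` instances of one motif class, each planted in a
#' distinct protein, with switches controlling whether the instance fully
#' qualifies for the funnel or is deliberately defective at one stage.
#'
#' @param motif_class One of `"canonical"`, `"expanded_only"`,
#'   `"structural_only"` — the classification the planted hexamer will have.
#' @param count Number of instances.
#' @param in_idr Plant inside a disordered block (`TRUE`, default) or fully
#'   inside an ordered gap.
#' @param give_phospho Annotate a phosphosite at a model-drawn distance.
#' @param give_pxixit Plant a PxIxIT site (short dialect) inside a
#'   disordered block; when `FALSE`, chance PxIxIT matches are scrubbed from
#'   the host so the plant is lost at exactly this stage.
#' @return A `plant_spec` data frame; rbind rows to combine.
#' @export
plant_spec <- function(motif_class = c("canonical", "expanded_only",
                                       "structural_only"),
                       count = 1L, in_idr = TRUE, give_phospho = TRUE,
                       give_pxixit = TRUE) {
  motif_class <- match.arg(motif_class)
  stopifnot(count >= 0)
  structure(data.frame(motif_class = motif_class, count = as.integer(count),
                       in_idr = in_idr, give_phospho = give_phospho,
                       give_pxixit = give_pxixit, stringsAsFactors = FALSE),
            class = c("plant_spec", "data.frame"))
}

# Uniform integer draw on [lo, hi]; safe for degenerate ranges (base
# sample() would treat a scalar as a range size).
.runif_int <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(lo:hi, 1L)
}

.pi_set <- c("N", "Q", "D", "E", "S", "R", "T", "H")
.phi_set <- c("Y", "T", "D", "F", "I", "L", "V")

# Sample a hexamer uniformly from the requested class's language (for the
# *_only classes, uniformly from the set difference, by rejection).
.sample_hexamer <- function(motif_class) {
  repeat {
    p5 <- switch(motif_class,
                 canonical = "V",
                 expanded_only = sample(c("V", "P", "L"), 1L),
                 structural_only = sample(c("V", "P", "L", "I", "H"), 1L))
    p6 <- switch(motif_class,
                 canonical = "P",
                 expanded_only = sample(c("P", "K"), 1L),
                 structural_only = sample(AA_ALPHABET, 1L))
    hex <- paste0(sample(.pi_set, 1L), sample(.phi_set, 1L), "L",
                  sample(AA_ALPHABET, 1L), p5, p6)
    if (classify_hexamer(hex) == motif_class) return(hex)
  }
}

.sample_pxixit <- function() {
  paste0("P", paste(sample(AA_ALPHABET, 3L, replace = TRUE), collapse = ""),
         sample(c("I", "V"), 1L), sample(c("T", "D", "H"), 1L))
}

# Place up to `k` non-overlapping [start,end] blocks avoiding `forbidden`
# windows (a list of c(start,end)); returns list of c(start,end).
.place_blocks <- function(n, k, len_range, forbidden = list(),
                          existing = list()) {
  blocks <- existing
  overlaps <- function(a, ws)
    any(vapply(ws, function(w) a[1] <= w[2] && w[1] <= a[2], logical(1)))
  for (i in seq_len(k)) {
    for (attempt in 1:50) {
      len <- .runif_int(len_range[1], len_range[2])
      if (n < len) break
      s <- sample.int(n - len + 1L, 1L)
      cand <- c(s, s + len - 1L)
      if (!overlaps(cand, blocks) && !overlaps(cand, forbidden)) {
        blocks <- c(blocks, list(cand))
        break
      }
    }
  }
  blocks
}

.scores_from_blocks <- function(n, blocks, idr_range, ordered_range) {
  sc <- stats::runif(n, ordered_range[1], ordered_range[2])
  for (b in blocks)
    sc[b[1]:b[2]] <- stats::runif(b[2] - b[1] + 1L, idr_range[1], idr_range[2])
  sc
}

# Destroy every PxIxIT match (both dialects) in `chars` by mutating one
# constrained position per match to G, never touching `protected` positions.
# Mutating to G can only remove matches (wildcards already accept anything),
# so the loop terminates.
.scrub_pxixit <- function(chars, protected) {
  for (round in 1:200) {
    m <- scan_pxixit(paste(chars, collapse = ""))
    if (nrow(m) == 0L) return(chars)
    done <- FALSE
    for (i in seq_len(nrow(m))) {
      L <- m$end[[i]] - m$start[[i]] + 1L
      anchors <- m$start[[i]] + c(0L, L - 2L, L - 1L)  # P, [IV], [TDH]
      free <- setdiff(anchors, protected)
      if (length(free) > 0L) {
        chars[free[[1]]] <- "G"
        done <- TRUE
        break
      }
    }
    if (!done) stop("cannot scrub PxIxIT matches without touching plants")
  }
  stop("PxIxIT scrubbing did not converge")
}

#' Generate a synthetic annotated proteome with planted ground truth
#'
#' Background sequences are drawn iid from the configured residue
#' frequencies; disorder profiles follow a block model (high-scoring blocks
#' on a low baseline); phosphosites and localization labels are drawn from
#' the configured rates. Plants (see [plant_spec()]) are placed one per
#' protein, in the first proteins of the set, each hexamer sampled uniformly
#' from its class's language and positioned with at least the near-window
#' margin to both protein ends so planted phosphosite distances are never
#' truncated. Planted windows never straddle a disorder-block boundary. The
#' emitted truth manifest is re-verified against the emitted data before
#' return.
#'
#' @param config A [synth_config()].
#' @param plants Optional `plant_spec` (rbind rows for several classes).
#' @return A `synth_dataset` list: `proteome`, `profiles`, `phospho`,
#'   `localization`, `truth` (data frame), `config`.
#' @export
generate_dataset <- function(config, plants = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  margin <- 50L  # near-window margin kept clear of protein ends
  plant_rows <- NULL
  if (!is.null(plants) && sum(plants$count) > 0L) {
    idx <- rep(seq_len(nrow(plants)), plants$count)
    plant_rows <- plants[idx, , drop = FALSE]
    if (nrow(plant_rows) > config$n_proteins)
      stop("more plants than proteins")
    if (config$length_range[1] < 2L * margin + 100L)
      stop("proteins too short to host plants; increase length_range")
  }
  n_host <- if (is.null(plant_rows)) 0L else nrow(plant_rows)
  # ids carry the seed so truth manifests and funnel reports from different
  # generated datasets cannot be silently cross-scored
  ids <- sprintf("s%d_p%04d", config$seed, seq_len(config$n_proteins))

  recs <- vector("list", config$n_proteins)
  profiles <- vector("list", config$n_proteins)
  phospho_rows <- list()
  truth_rows <- list()

  for (p in seq_len(config$n_proteins)) {
    id <- ids[[p]]
    n <- .runif_int(config$length_range[1], config$length_range[2])
    chars <- sample(AA_ALPHABET, n, replace = TRUE,
                    prob = config$background)
    host <- p <= n_host

    if (!host) {
      blocks <- .place_blocks(n, stats::rpois(1L, config$idr_mean_blocks),
                              config$idr_block_length)
      profiles[[p]] <- .scores_from_blocks(n, blocks, config$idr_score_range,
                                           config$ordered_score_range)
      if (stats::runif(1) < config$phospho_presence_prob) {
        k <- sample(1:3, 1L)
        pos <- sample.int(n, k)
        res <- sample(c("S", "T"), k, replace = TRUE)
        chars[pos] <- res
        phospho_rows[[length(phospho_rows) + 1L]] <-
          data.frame(protein_id = id, position = pos, residue = res,
                     stringsAsFactors = FALSE)
      }
      recs[[p]] <- list(id = id, sequence = paste(chars, collapse = ""),
                        length = n)
      next
    }

    spec <- plant_rows[p, ]
    hex <- .sample_hexamer(spec$motif_class)
    ms <- .runif_int(margin + 1L, n - 5L - margin)
    mw <- c(ms, ms + 5L)
    chars[ms:(ms + 5L)] <- strsplit(hex, "")[[1]]

    # Disorder blocks: when in-IDR, one anchor block strictly containing the
    # motif window; remaining blocks avoid the window so it never straddles
    # a boundary.
    blocks <- list()
    if (spec$in_idr) {
      blen <- .runif_int(config$idr_block_length[1],
                         config$idr_block_length[2])
      lo <- max(1L, mw[2] - blen + 1L)
      hi <- min(mw[1], n - blen + 1L)
      bs <- .runif_int(lo, hi)
      blocks <- list(c(bs, bs + blen - 1L))
    }
    blocks <- .place_blocks(n, stats::rpois(1L, config$idr_mean_blocks),
                            config$idr_block_length,
                            forbidden = list(mw), existing = blocks)

    # PxIxIT plant inside some disordered block segment clear of the motif.
    px <- c(NA_integer_, NA_integer_)
    if (spec$give_pxixit) {
      seg_ok <- NULL
      for (b in sample(blocks)) {
        segs <- list(b)
        if (mw[1] <= b[2] && b[1] <= mw[2])  # carve motif window out
          segs <- Filter(function(s) s[2] - s[1] + 1L >= 6L,
                         list(c(b[1], mw[1] - 1L), c(mw[2] + 1L, b[2])))
        segs <- Filter(function(s) s[1] >= 1L && s[2] <= n &&
                                   s[2] - s[1] + 1L >= 6L, segs)
        if (length(segs) > 0L) { seg_ok <- sample(segs, 1L)[[1]]; break }
      }
      if (is.null(seg_ok)) {
        blocks2 <- .place_blocks(n, 5L, config$idr_block_length,
                                 forbidden = list(mw), existing = blocks)
        added <- setdiff(seq_along(blocks2), seq_along(blocks))
        if (length(added) == 0L) stop("no room to plant PxIxIT in '", id, "'")
        seg_ok <- blocks2[[added[[1]]]]
        blocks <- blocks2
      }
      ps <- .runif_int(seg_ok[1], seg_ok[2] - 5L)
      px <- c(ps, ps + 5L)
      chars[ps:(ps + 5L)] <- strsplit(.sample_pxixit(), "")[[1]]
    }

    # Phosphosite at a model-drawn distance and orientation.
    ph_pos <- NA_integer_; ph_orient <- NA_character_; ph_dist <- NA_integer_
    if (spec$give_phospho) {
      for (attempt in 1:100) {
        orient <- if (stats::runif(1) < config$phospho_orientation_prob_c)
          "C" else "N"
        rng <- if (orient == "C") config$phospho_cterm_range
               else config$phospho_nterm_range
        d <- .runif_int(rng[1], rng[2])
        pos <- if (orient == "C") mw[2] + d else mw[1] - d
        bad <- pos < 1L || pos > n ||
          (pos >= mw[1] && pos <= mw[2]) ||
          (!is.na(px[1]) && pos %in% (px[1] + c(0L, 4L, 5L)))
        if (!bad) {
          ph_pos <- pos; ph_orient <- orient; ph_dist <- d
          break
        }
      }
      if (is.na(ph_pos)) stop("could not place phosphosite in '", id, "'")
      res <- sample(c("S", "T"), 1L)
      chars[ph_pos] <- res
      phospho_rows[[length(phospho_rows) + 1L]] <-
        data.frame(protein_id = id, position = ph_pos, residue = res,
                   stringsAsFactors = FALSE)
    }

    if (!spec$give_pxixit)
      chars <- .scrub_pxixit(chars, protected = c(mw[1]:mw[2], ph_pos))

    profiles[[p]] <- .scores_from_blocks(n, blocks, config$idr_score_range,
                                         config$ordered_score_range)
    recs[[p]] <- list(id = id, sequence = paste(chars, collapse = ""),
                      length = n)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      protein_id = id, start = mw[1], end = mw[2], hexamer = hex,
      motif_class = spec$motif_class, in_idr = spec$in_idr,
      has_phospho = spec$give_phospho, phospho_position = ph_pos,
      phospho_orientation = ph_orient, phospho_distance = ph_dist,
      has_pxixit = spec$give_pxixit, pxixit_start = px[1], pxixit_end = px[2],
      stringsAsFactors = FALSE)
  }

  names(recs) <- ids
  names(profiles) <- ids
  proteome <- structure(recs, class = "proteome")
  phospho <- if (length(phospho_rows) > 0L) do.call(rbind, phospho_rows)
    else data.frame(protein_id = character(), position = integer(),
                    residue = character(), stringsAsFactors = FALSE)
  localization <- data.frame(
    protein_id = ids,
    category = sample(names(config$localization_probs), config$n_proteins,
                      replace = TRUE, prob = config$localization_probs),
    stringsAsFactors = FALSE)
  truth <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows)
    else data.frame(protein_id = character(), start = integer(),
                    end = integer(), hexamer = character(),
                    motif_class = character(), in_idr = logical(),
                    has_phospho = logical(), phospho_position = integer(),
                    phospho_orientation = character(),
                    phospho_distance = integer(), has_pxixit = logical(),
                    pxixit_start = integer(), pxixit_end = integer(),
                    stringsAsFactors = FALSE)
  rownames(phospho) <- rownames(truth) <- NULL
  ds <- structure(list(proteome = proteome, profiles = profiles,
                       phospho = phospho, localization = localization,
                       truth = truth, config = config),
                  class = "synth_dataset")
  verify_truth(ds)
  ds
}

#' Cross-check a dataset's truth manifest against its emitted data
#'
#' Asserts, for every planted instance: the hexamer is present at the stated
#' coordinates and classifies to the stated class; the disorder window
#' respects the `in_idr` flag under every aggregation (all residues on one
#' side of the threshold); the phosphosite annotation exists at the stated
#' offset; the PxIxIT site matches the short dialect inside a disordered
#' window.
#'
#' @param dataset A `synth_dataset`.
#' @return Invisibly `TRUE`; stops on the first inconsistency.
#' @export
verify_truth <- function(dataset) {
  tr <- dataset$truth
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    seqv <- dataset$proteome[[r$protein_id]]$sequence
    hex <- substr(seqv, r$start, r$end)
    if (hex != r$hexamer)
      stop("truth hexamer mismatch at ", r$protein_id, ":", r$start)
    if (classify_hexamer(hex) != r$motif_class)
      stop("truth class mismatch at ", r$protein_id, ":", r$start)
    w <- dataset$profiles[[r$protein_id]][r$start:r$end]
    if (r$in_idr && min(w) < 0.4)
      stop("in_idr plant has low disorder at ", r$protein_id, ":", r$start)
    if (!r$in_idr && max(w) >= 0.4)
      stop("ordered plant has high disorder at ", r$protein_id, ":", r$start)
    if (r$has_phospho) {
      hit <- dataset$phospho$protein_id == r$protein_id &
        dataset$phospho$position == r$phospho_position
      if (!any(hit))
        stop("truth phosphosite missing at ", r$protein_id, ":",
             r$phospho_position)
      d <- if (r$phospho_orientation == "C") r$phospho_position - r$end
           else r$start - r$phospho_position
      if (d != r$phospho_distance)
        stop("truth phospho distance inconsistent at ", r$protein_id)
    }
    if (r$has_pxixit) {
      site <- substr(seqv, r$pxixit_start, r$pxixit_end)
      if (nrow(scan_pxixit(site, "short")) == 0L)
        stop("truth PxIxIT invalid at ", r$protein_id, ":", r$pxixit_start)
      pw <- dataset$profiles[[r$protein_id]][r$pxixit_start:r$pxixit_end]
      if (min(pw) < 0.4)
        stop("planted PxIxIT not in disorder at ", r$protein_id)
    }
  }
  invisible(TRUE)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `proteome.fasta`, `disorder.tsv`, `phospho.tsv`,
#' `localization.tsv` and `truth.json`.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "proteome.fasta"),
             disorder = file.path(dir, "disorder.tsv"),
             phospho = file.path(dir, "phospho.tsv"),
             localization = file.path(dir, "localization.tsv"),
             truth = file.path(dir, "truth.json"))
  write_fasta(dataset$proteome, paths[["fasta"]])
  write_disorder_tsv(dataset$profiles, paths[["disorder"]])
  write_phospho_tsv(dataset$phospho, paths[["phospho"]])
  write_localization_tsv(dataset$localization, paths[["localization"]])
  jsonlite::write_json(dataset$truth, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(paths)
}

#' Score funnel recovery against planted truth
#'
#' Recall is computed over fully-qualifying plants (in a disordered block,
#' with a phosphosite and an in-disorder PxIxIT): the fraction whose motif
#' instance survives to the funnel's intersection stage. Precision treats
#' every surviving match not present in the truth manifest as a false
#' positive. The loss table attributes each non-surviving plant to the
#' filter(s) that removed it.
#'
#' @param report A `funnel_report` from [run_funnel()] on the same dataset.
#' @param truth The dataset's truth manifest (data frame).
#' @param require_plants When `TRUE` (default) an absence of fully-qualifying
#'   plants is an error (recall undefined); with `FALSE`, recall is `NA` and
#'   precision is still reported.
#' @return List: `recall`, `precision`, `n_survivors`, `loss_table` (data
#'   frame with one row per plant and its `lost_at` stage, one of `none`,
#'   `idr`, `phospho`, `pxixit`, `phospho+pxixit`).
#' @export
evaluate_recovery <- function(report, truth, require_plants = TRUE) {
  if (nrow(truth) > 0L &&
      !all(truth$protein_id %in% report$proteome_ids))
    stop("truth manifest and funnel report come from different datasets")
  key <- function(df) paste(df$protein_id, df$start)
  final <- report$stages$intersection$matches
  idr <- report$stages$idr$matches
  phospho_ids <- report$stages$phospho$protein_ids
  pxixit_ids <- report$stages$pxixit$protein_ids

  full <- truth[truth$in_idr & truth$has_phospho & truth$has_pxixit, ,
                drop = FALSE]
  if (nrow(full) == 0L && require_plants)
    stop("no fully-qualifying plants: recall is undefined")
  recall <- if (nrow(full) == 0L) NA_real_
    else mean(key(full) %in% key(final))

  precision <- if (nrow(final) == 0L) NA_real_
    else mean(key(final) %in% key(truth))

  lost_at <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    k <- paste(r$protein_id, r$start)
    if (k %in% key(final)) { lost_at[[i]] <- "none"; next }
    if (!k %in% key(idr)) { lost_at[[i]] <- "idr"; next }
    miss_ph <- !r$protein_id %in% phospho_ids
    miss_px <- !r$protein_id %in% pxixit_ids
    lost_at[[i]] <- if (miss_ph && miss_px) "phospho+pxixit"
      else if (miss_ph) "phospho" else if (miss_px) "pxixit" else "none"
  }
  loss_table <- cbind(truth[, c("protein_id", "start", "motif_class",
                                "in_idr", "has_phospho", "has_pxixit"),
                            drop = FALSE],
                      data.frame(lost_at = lost_at, stringsAsFactors = FALSE))
  list(recall = recall, precision = precision,
       n_survivors = nrow(final), loss_table = loss_table)
}
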