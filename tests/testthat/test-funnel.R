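lib <- build_motif_library()

toy_matches <- function(windows, id = "p1") {
  data.frame(protein_id = id,
             start = as.integer(vapply(windows, `[[`, numeric(1), 1L)),
             end = as.integer(vapply(windows, `[[`, numeric(1), 2L)),
             sequence = "QYLAVP", motif = "canonical_pilxvp",
             stringsAsFactors = FALSE)
}

test_that("disordered-window filter honors threshold and aggregation", {
  prof <- list(p1 = c(rep(0.9, 6), 0.5, 0.5, 0.5, 0.5, 0.5, 0.0))
  high <- toy_matches(list(c(1L, 6L)))
  dip <- toy_matches(list(c(7L, 12L)))  # scores 0.5 x5 then 0.0, mean 0.4166

  for (agg in c("mean", "all", "any"))
    expect_equal(nrow(idr_filter(high, prof,
                                 funnel_config(disorder_aggregation = agg))),
                 1L, info = agg)
  expect_equal(nrow(idr_filter(dip, prof, funnel_config())), 1L)
  expect_equal(nrow(idr_filter(dip, prof,
                               funnel_config(disorder_aggregation = "all"))),
               0L)
  expect_equal(nrow(idr_filter(dip, prof,
                               funnel_config(disorder_aggregation = "any"))),
               1L)
  # threshold 0 keeps everything; out-of-range threshold is rejected
  expect_equal(nrow(idr_filter(dip, prof,
                               funnel_config(disorder_threshold = 0))), 1L)
  expect_error(funnel_config(disorder_threshold = 1.01), "\\[0, 1\\]")
  expect_error(idr_filter(toy_matches(list(c(1L, 6L)), id = "ghost"), prof,
                          funnel_config()),
               "ghost")
})

test_that("raising the disorder threshold never adds survivors", {
  set.seed(42)
  prof <- list(p1 = runif(100))
  matches <- toy_matches(lapply(seq(1, 90, by = 4),
                                function(s) c(s, s + 5L)))
  prev <- Inf
  for (t in seq(0, 1, by = 0.1)) {
    n <- nrow(idr_filter(matches, prof, funnel_config(disorder_threshold = t)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("phospho filter keeps exactly the annotated proteins", {
  phospho <- data.frame(protein_id = paste0("p", 1:6), position = 1L,
                        residue = "S", stringsAsFactors = FALSE)
  ids <- paste0("p", 1:10)
  expect_equal(phospho_filter(ids, phospho), paste0("p", 1:6))
  expect_equal(phospho_filter("p7", phospho), character())
})

test_that("PxIxIT co-occurrence respects dialects and the disorder gate", {
  seqs <- c(hit = paste0(strrep("A", 30), "PTSPVT", strrep("A", 30)),
            none = strrep("A", 66))
  prot <- proteome_from_seqs(seqs)
  prof_hi <- list(hit = rep(0.9, 66), none = rep(0.9, 66))
  prof_lo <- list(hit = rep(0.0, 66), none = rep(0.0, 66))
  cfg <- funnel_config()
  expect_equal(pxixit_cooccurrence(c("hit", "none"), prot, prof_hi, cfg),
               "hit")
  expect_equal(pxixit_cooccurrence("hit", prot, prof_lo, cfg), character())
  cfg_any <- funnel_config(require_pxixit_in_idr = FALSE)
  expect_equal(pxixit_cooccurrence("hit", prot, prof_lo, cfg_any), "hit")
  # long-dialect-only site is invisible to a short-only configuration
  prot2 <- proteome_from_seqs(c(x = paste0("PAAAAVT", strrep("G", 20))))
  prof2 <- list(x = rep(0.9, 27))
  expect_equal(pxixit_cooccurrence("x", prot2, prof2,
                                   funnel_config(pxixit_dialects = "long")),
               "x")
  expect_equal(pxixit_cooccurrence("x", prot2, prof2,
                                   funnel_config(pxixit_dialects = "short")),
               character())
})

test_that("funnel report algebra holds and branches are parallel", {
  ds <- generate_dataset(
    synth_config(seed = 11, n_proteins = 60, length_range = c(200, 400)),
    rbind(plant_spec("canonical", 5),
          plant_spec("expanded_only", 4, give_phospho = FALSE),
          plant_spec("expanded_only", 3, give_pxixit = FALSE),
          plant_spec("canonical", 2, in_idr = FALSE)))
  rep <- run_funnel(ds$proteome, ds$profiles, ds$phospho)
  st <- rep$stages
  expect_true(all(st$idr$protein_ids %in% st$raw$protein_ids))
  expect_true(all(st$phospho$protein_ids %in% st$idr$protein_ids))
  expect_true(all(st$pxixit$protein_ids %in% st$idr$protein_ids))
  expect_true(all(st$intersection$protein_ids %in% st$phospho$protein_ids))
  expect_true(all(st$intersection$protein_ids %in% st$pxixit$protein_ids))
  for (s in st) expect_gte(s$motif_count, s$protein_count)
  expect_equal(rep$both_count + rep$pxixit_only_count,
               st$pxixit$protein_count)
  expect_equal(rep$both_count + rep$phospho_only_count,
               st$phospho$protein_count)
  expect_equal(rep$both_count, st$intersection$protein_count)
  # the defective-at-phospho plants must appear in the PxIxIT-only margin
  expect_gte(rep$pxixit_only_count, 4L)
})

test_that("a protein with two motifs counts once in protein tallies", {
  seqv <- paste0(strrep("G", 10), "QYLAVP", strrep("G", 10), "SFLKVP",
                 strrep("G", 10), "PAAAIVT", strrep("G", 5))
  prot <- proteome_from_seqs(c(dbl = seqv, bg = strrep("G", 50)))
  profs <- list(dbl = rep(0.9, nchar(seqv)), bg = rep(0.9, 50))
  phospho <- data.frame(protein_id = "dbl", position = 1L, residue = "G",
                        stringsAsFactors = FALSE)
  phospho$residue <- "S"  # place a real site
  p <- prot$dbl$sequence
  substr(p, 1, 1) <- "S"
  prot$dbl$sequence <- p
  rep <- run_funnel(prot, profs, phospho,
                    funnel_config(motif_name = "canonical_pilxvp"))
  expect_equal(rep$stages$idr$motif_count, 2L)
  expect_equal(rep$stages$idr$protein_count, 1L)
  expect_equal(rep$multi_motif_protein_count, 1L)
})

test_that("an empty proteome gives an all-zero report", {
  empty <- structure(list(), class = "proteome")
  rep <- run_funnel(empty, list(),
                    data.frame(protein_id = character(),
                               position = integer(), residue = character()))
  for (s in rep$stages) {
    expect_equal(s$motif_count, 0L)
    expect_equal(s$protein_count, 0L)
  }
  expect_equal(rep$both_count, 0L)
})

test_that("unknown motif names are rejected with the available list", {
  ds <- generate_dataset(synth_config(seed = 3, n_proteins = 5,
                                      length_range = c(200, 250)))
  expect_error(run_funnel(ds$proteome, ds$profiles, ds$phospho,
                          funnel_config(motif_name = "nope")),
               "unknown motif.*canonical_pilxvp")
})

test_that("conserved-interactor search is raw presence/absence", {
  ints <- proteome_from_seqs(c(
    a = paste0(strrep("G", 5), "QYLAVP", strrep("G", 5)),
    b = paste0("QYLAVP", strrep("G", 10)),
    c = strrep("G", 16)))
  res <- validate_conserved(ints, "canonical_pilxvp")
  expect_equal(res$hit_count, 2L)
  expect_equal(res$n_interactors, 3L)
  expect_setequal(res$hit_ids, c("a", "b"))

  # NTLQLP satisfies the structural definition but not the canonical one
  ints2 <- proteome_from_seqs(c(x = "GGNTLQLPGG", y = "NTLQLPAAA"))
  expect_equal(validate_conserved(ints2, "structural_pilxvp")$hit_count, 2L)
  expect_equal(validate_conserved(ints2, "canonical_pilxvp")$hit_count, 0L)

  expect_error(validate_conserved(structure(list(), class = "proteome")),
               "non-empty")
  expect_error(validate_conserved(c(a = "QYLAVP", b = "")), "without sequence")
  expect_error(validate_conserved(ints2, "nope"), "unknown motif")
})
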