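test_that("per-match phosphosite distances follow the edge-anchored convention", {
  cfg <- distance_config()  # min 9 C-terminal, min 20 N-terminal
  m <- list(start = 10L, end = 15L)
  r <- phospho_distances(m, 25L, cfg)
  expect_equal(r$cterm_distance, 10L)
  expect_equal(r$orientation, "C")
  r <- phospho_distances(m, 20L, cfg)  # distance 5 < 9: unreachable
  expect_true(is.na(r$orientation))
  r <- phospho_distances(list(start = 30L, end = 35L), 5L, cfg)
  expect_equal(r$nterm_distance, 25L)
  expect_equal(r$orientation, "N")
  # sites inside the motif are ignored
  r <- phospho_distances(m, 12L, cfg)
  expect_true(is.na(r$orientation))
})

test_that("nearest site wins; ties resolve C-terminal; max mode flips cutoffs", {
  cfg0 <- distance_config(min_cterm_offset = 0, min_nterm_offset = 0)
  m <- list(start = 50L, end = 55L)
  r <- phospho_distances(m, c(30L, 65L), cfg0)  # N dist 20, C dist 10
  expect_equal(r$orientation, "C")
  r <- phospho_distances(m, c(40L, 65L), cfg0)  # both distance 10
  expect_equal(r$orientation, "C")
  r <- phospho_distances(m, c(45L, 70L), cfg0)  # N 5 beats C 15
  expect_equal(r$orientation, "N")

  cfg_max <- distance_config(min_cterm_offset = 9, cutoff_mode = "max")
  r <- phospho_distances(m, 70L, cfg_max)  # C distance 15 > 9: excluded
  expect_true(is.na(r$cterm_distance))
  r <- phospho_distances(m, 60L, cfg_max)  # C distance 5 <= 9: kept
  expect_equal(r$cterm_distance, 5L)
})

test_that("aggregation counts orientations and the near window", {
  rec <- data.frame(orientation = c(rep("C", 8), rep("N", 2)),
                    distance = c(10, 20, 30, 40, 45, 48, 60, 70, 25, 30),
                    stringsAsFactors = FALSE)
  s <- aggregate_distances(rec)
  expect_equal(s$fraction_cterm, 0.8)
  expect_equal(s$fraction_nterm, 0.2)
  expect_equal(s$fraction_cterm + s$fraction_nterm, 1)
  expect_equal(s$fraction_within_near_window, 0.8)
  far <- data.frame(orientation = "C", distance = 200)
  expect_equal(aggregate_distances(far)$fraction_within_near_window, 0)
  none <- data.frame(orientation = NA_character_, distance = NA_integer_)
  expect_error(aggregate_distances(none), "qualifying")
})

test_that("orientation fractions ignore phosphosite list order", {
  cfg <- distance_config()
  m <- list(start = 100L, end = 105L)
  pos <- c(115L, 130L, 70L, 160L)
  expect_equal(phospho_distances(m, pos, cfg),
               phospho_distances(m, rev(pos), cfg))
  expect_equal(phospho_distances(m, sample(pos), cfg),
               phospho_distances(m, pos, cfg))
})

test_that("mirroring a protein swaps the orientation fractions", {
  set.seed(9)
  n <- 500L
  cfg_sym <- distance_config(min_cterm_offset = 9, min_nterm_offset = 9)
  starts <- sample(60:(n - 70), 12)
  matches <- data.frame(protein_id = "p", start = starts, end = starts + 5L)
  sites <- sample(setdiff(1:n, unlist(Map(seq, starts, starts + 5L))), 40)
  phospho <- data.frame(protein_id = "p", position = sites)

  fwd <- aggregate_distances(phospho_distance_table(matches, phospho,
                                                    cfg_sym), cfg_sym)
  mirror <- data.frame(protein_id = "p",
                       start = n - matches$end + 1L,
                       end = n - matches$start + 1L)
  phospho_m <- data.frame(protein_id = "p", position = n - sites + 1L)
  rev_ <- aggregate_distances(phospho_distance_table(mirror, phospho_m,
                                                     cfg_sym), cfg_sym)
  # ties resolve C in both frames, so allow the tied matches to move
  tab <- phospho_distance_table(matches, phospho, cfg_sym)
  tied <- sum(!is.na(tab$cterm_distance) & !is.na(tab$nterm_distance) &
                tab$cterm_distance == tab$nterm_distance)
  expect_lte(abs(rev_$fraction_cterm - fwd$fraction_nterm),
             tied / fwd$n_assigned)
  expect_lte(abs(rev_$fraction_nterm - fwd$fraction_cterm),
             tied / fwd$n_assigned)
  expect_equal(rev_$n_assigned, fwd$n_assigned)
})

test_that("position probability matrices match hand-computed entropies", {
  ppm <- build_ppm(rep("QYLAVP", 5))
  expect_true(all(abs(colSums(ppm$prob) - 1) < 1e-9))
  occupied <- ppm$prob[cbind(c("Q", "Y", "L", "A", "V", "P"), 1:6)]
  expect_equal(occupied, rep(1, 6))
  expect_equal(ppm$ic, rep(log2(20), 6), tolerance = 1e-12)

  two <- build_ppm(c("QYLAVP", "SYLGVP"))
  expect_equal(two$prob["Q", 1], 0.5)
  expect_equal(two$prob["S", 1], 0.5)
  expect_equal(two$ic[1], log2(20) - 1, tolerance = 1e-12)
  expect_equal(two$ic[2], log2(20), tolerance = 1e-12)
  expect_equal(two$instance_count, 2L)

  expect_error(build_ppm(c("QYLAVP", "QYLAV")), "same length")
  expect_error(build_ppm(character()), "at least one")
})

test_that("PPM normalization and entropy bounds hold for random instance sets", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    L <- sample(4:8, 1)
    inst <- replicate(n, random_seq(L))
    ppm <- build_ppm(inst)
    expect_true(all(abs(colSums(ppm$prob) - 1) < 1e-9))
    expect_true(all(ppm$ic >= -1e-12 & ppm$ic <= log2(20) + 1e-12))
  }
})

test_that("MEME and TSV exports carry the probabilities", {
  ppm <- build_ppm(c("QYLAVP", "SYLGVP", "NTLQLP"))
  meme <- withr::local_tempfile(fileext = ".meme")
  write_meme(ppm, meme, name = "pilxvp")
  lines <- readLines(meme)
  expect_true(any(grepl("^MOTIF pilxvp$", lines)))
  hdr <- grep("letter-probability matrix", lines)
  expect_match(lines[hdr], "alength= 20 w= 6 nsites= 3")
  mat <- do.call(rbind, lapply(lines[(hdr + 1):(hdr + 6)], function(l)
    as.numeric(strsplit(l, " +")[[1]])))
  expect_equal(mat, t(unname(ppm$prob)), tolerance = 1e-6)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ppm_tsv(ppm, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), 21L)  # 20 residues + information-content row
  expect_equal(as.numeric(tab$pos1[tab$residue == "Q"]), 1 / 3,
               tolerance = 1e-9)
})

test_that("localization breakdown bins unknowns as other and sums to one", {
  loc <- data.frame(protein_id = c("a", "b", "c", "d"),
                    category = c("nucleus", "nucleus", "nucleus", "membrane"),
                    stringsAsFactors = FALSE)
  bk <- localization_breakdown(c("a", "b", "c", "d"), loc)
  expect_equal(bk$fraction[bk$category == "nucleus"], 0.75)
  expect_equal(sum(bk$fraction), 1)
  expect_equal(sum(bk$count), 4L)

  bk2 <- localization_breakdown(c("x", "y"), loc)
  expect_equal(bk2$fraction[bk2$category == "other"], 1)
  expect_error(localization_breakdown(character(), loc), "non-empty")
})

test_that("localization fractions recover the generator's probabilities", {
  ds <- generate_dataset(synth_config(seed = 21, n_proteins = 400,
                                      length_range = c(200, 220)))
  bk <- localization_breakdown(names(ds$proteome), ds$localization)
  probs <- ds$config$localization_probs
  for (cat in names(probs)) {
    p <- probs[[cat]]
    sd4 <- 4 * sqrt(p * (1 - p) / 400)
    expect_lt(abs(bk$fraction[bk$category == cat] - p), sd4 + 1e-12,
              label = cat)
  }
})
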