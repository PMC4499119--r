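test_that("k-mer table matches a brute-force scan of both converted strands", {
  g <- fixture_genome(len = 400L, control = 0L, seed = 21)
  tab <- build_kmer_table(g, k = 15)
  want <- oracle_kmer_counts(g, k = 15)
  expect_identical(length(tab$counts), length(want))
  expect_identical(tab$counts[sort(names(tab$counts))],
                   setNames(as.integer(want[sort(names(want))]),
                            sort(names(want))))
  # total stored count formula: 2 * (L - k + 1) per contig, no Ns here
  expect_identical(sum(tab$counts), 2L * (400L - 15L + 1L))
})

test_that("all-T contig k-mers count per strand (bottom strand is all A)", {
  g <- c(chr = strrep("T", 16))
  tab <- build_kmer_table(g, k = 15)
  expect_identical(kmer_lookup(tab, strrep("T", 15)), 2L)
  expect_identical(kmer_lookup(tab, strrep("A", 15)), 2L)
  expect_identical(sum(tab$counts), 4L)
  # absent k-mer looks up as zero
  expect_identical(kmer_lookup(tab, strrep("G", 15)), 0L)
})

test_that("contigs shorter than k are skipped with a warning", {
  expect_warning(tab <- build_kmer_table(c(chr = strrep("A", 14)), k = 15),
                 "shorter than k")
  expect_identical(length(tab$counts), 0L)
})

test_that("repeat score is the mean k-mer frequency of the probe", {
  g <- fixture_genome(len = 300L, control = 0L, seed = 22)
  tab <- build_kmer_table(g)
  # a probe drawn from the fully converted unique genome: every k-mer count 1
  probe <- bs_convert(substr(g[["chr1"]], 101, 160))
  expect_equal(repeat_score(probe, tab), 1.0)
  # constructed table with counts 2 and 4 -> mean 3
  tab2 <- structure(list(k = 15L, counts = c(2L, 4L)), class = "kmer_table")
  names(tab2$counts) <- c(strrep("A", 15), paste0(strrep("A", 14), "T"))
  expect_equal(repeat_score(paste0(strrep("A", 15), "T"), tab2), 3.0)
  expect_error(repeat_score("ACGT", tab), "shorter than k")
})

test_that("homopolymer score is the longest single-base run", {
  expect_identical(as.integer(homopolymer_score("AAAACGT")), 4L)
  expect_identical(as.integer(homopolymer_score("ACGT")), 1L)
  expect_identical(as.integer(homopolymer_score("TTTTTTTTTT")), 10L)
  runs <- attr(homopolymer_score("AACCCGT"), "runs")
  expect_identical(unname(runs[c("A", "C", "G", "T")]), c(2L, 3L, 1L, 1L))
  expect_error(homopolymer_score(""), "non-empty")
})

test_that("melting temperature is deterministic and GC-monotone", {
  gc50 <- strrep("GC", 25)
  at50 <- strrep("AT", 25)
  expect_gt(melting_temperature(gc50), melting_temperature(at50))
  expect_identical(melting_temperature(gc50), melting_temperature(gc50))
  # hand evaluation of the GC formula: 64.9 + 41 * (30 - 16.4) / 60
  seq60 <- paste0(strrep("G", 15), strrep("C", 15), strrep("A", 15),
                  strrep("T", 15))
  expect_equal(melting_temperature(seq60), 64.9 + 41 * (30 - 16.4) / 60)
  expect_equal(melting_temperature("ACGT", method = "wallace"), 2 * 2 + 4 * 2)
  expect_error(melting_temperature("ACNGT"), "N")
})

test_that("mapping-location counting is bisulfite-asymmetric", {
  set.seed(31)
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  segment <- spacer(80)
  g <- c(chr1 = paste0(spacer(150), segment, spacer(150), segment,
                       spacer(150)),
         chr2 = paste0(spacer(120), segment, spacer(100), segment,
                       spacer(120)))
  probe <- bs_convert(segment)
  got <- count_mapping_locations(probe, g)
  expect_identical(got, oracle_mapping_count(probe, g))
  expect_identical(got, 4L)
  # unique region: exactly the self-match
  uprobe <- bs_convert(substr(g[["chr1"]], 1, 80))
  expect_identical(count_mapping_locations(uprobe, g), 1L)
  # a CG-methylated-state probe still finds its unconverted source
  mprobe <- bs_convert(segment, cg_methylated = TRUE)
  expect_gte(count_mapping_locations(mprobe, g), 1L)
})

test_that("candidate filters apply the exact repeat and uniqueness cutoffs", {
  cand <- data.frame(repeat_score = c(10000, 10000.5, 1, 1),
                     uniqueness = c(1L, 1L, 4L, 3L))
  kept <- filter_candidates(cand)
  # removal requires repeat > 10000 and uniqueness > 3
  expect_identical(rownames(kept), c("1", "4"))
  expect_identical(unname(attr(kept, "removed")["total"]), 2L)
  expect_error(filter_candidates(data.frame(x = 1)), "scored")
})

test_that("rank score improves monotonically in each component", {
  base <- data.frame(tm = c(70.5, 70.5), repeat_score = c(1, 1),
                     uniqueness = c(1L, 3L), homopolymer_score = c(3L, 3L))
  sc <- rank_score(base)
  expect_lt(sc$rank_score[1], sc$rank_score[2])
  # identical probes score identically
  same <- rank_score(data.frame(tm = c(70, 70), repeat_score = c(2, 2),
                                uniqueness = c(1L, 1L),
                                homopolymer_score = c(2L, 2L)))
  expect_identical(same$rank_score[1], same$rank_score[2])
  # hand-computed composite under default unit weights: min-max normalized
  # |Tm-70.5| (0,1) + repeats (0,1) + uniqueness (0,1) + homopolymer (0,1)
  pair <- rank_score(data.frame(tm = c(70.5, 72.5), repeat_score = c(1, 5),
                                uniqueness = c(1L, 3L),
                                homopolymer_score = c(2L, 6L)))
  expect_equal(pair$rank_score, c(0, 4))
  expect_error(rank_score(data.frame(tm = 1)), "missing score components")
})

test_that("candidate generation tiles every 5 bp within length bounds", {
  g <- fixture_genome(len = 1500L, control = 0L, seed = 23)
  tg <- data.frame(contig = "chr1", start = 200L, end = 300L)
  cand <- generate_candidates(g, tg)
  expect_setequal(unique(cand$state),
                  c("top_M", "top_U", "bottom_M", "bottom_U"))
  for (st in unique(cand$state)) {
    starts <- sort(cand$start[cand$state == st])
    expect_identical(starts, seq(200L, 250L, by = 5L))
  }
  expect_true(all(cand$length >= 50 & cand$length <= 100))
  expect_true(all(cand$end <= 300L))
  expect_warning(
    none <- generate_candidates(g, data.frame(contig = "chr1", start = 0L,
                                              end = 40L)),
    "shorter than min_len")
  expect_identical(nrow(none), 0L)
})

test_that("candidate sequences re-derive from the genome under their state", {
  g <- fixture_genome(len = 1200L, control = 0L, seed = 24)
  tg <- data.frame(contig = "chr1", start = 100L, end = 260L)
  cand <- generate_candidates(g, tg)
  set.seed(3)
  for (i in sample(nrow(cand), 40)) {
    win <- substr(g[[cand$contig[i]]], cand$start[i] + 1L, cand$end[i])
    want <- if (cand$strand[i] == "top") {
      bs_convert(win, cg_methylated = cand$cg_methylated[i])
    } else {
      bs_convert(paste(rev(strsplit(chartr("ACGT", "TGCA", win), "")[[1]]),
                       collapse = ""), cg_methylated = cand$cg_methylated[i])
    }
    expect_identical(cand$seq[i], want)
  }
})

test_that("probe selection windows hold 3 tiled starts and 20 bp gaps", {
  g <- fixture_genome(len = 3000L, control = 0L, seed = 25)
  tg <- data.frame(contig = "chr1", start = 500L, end = 1500L)
  cand <- generate_candidates(g, tg)
  tab <- build_kmer_table(g)
  cand <- score_candidates(cand, g, tab)
  cand <- rank_score(filter_candidates(cand))
  sel <- suppressWarnings(select_probes(cand, tg))
  # with tile 5 in a 15 bp window, exactly 3 candidate starts are evaluated
  one_state <- cand[cand$state == "top_U", ]
  for (ws in seq(500L, 1400L, by = 35L)) {
    in_win <- one_state$start >= ws & one_state$start < ws + 15L
    expect_identical(sum(in_win), 3L)
  }
  # consecutive windows are spaced 20 bp end-to-start
  ws <- sort(unique(sel$window_start))
  expect_true(all(diff(ws) == 35L))
  # one probe per window per state
  expect_false(any(duplicated(sel[, c("state", "window_start")])))
  # every selected probe passed the filters
  expect_true(all(sel$repeat_score <= 10000))
  expect_true(all(sel$uniqueness <= 3))
})

test_that("windows whose candidates were all filtered emit no probe", {
  cand <- data.frame(contig = "chr1", start = c(35L, 40L), end = c(95L, 100L),
                     strand = "top", cg_methylated = FALSE, state = "top_U",
                     target_id = 1L, seq = "x", length = c(60L, 60L), tm = 70,
                     repeat_score = 1, homopolymer_score = 1, uniqueness = 1L,
                     rank_score = 0)
  tg <- data.frame(contig = "chr1", start = 0L, end = 70L)
  # the first window (0-14) has no candidates, the second (35-49) has two
  expect_warning(sel <- select_probes(cand, tg), "no surviving")
  expect_identical(nrow(sel), 1L)
  expect_identical(nrow(attr(sel, "empty_windows")), 1L)
  # equal rank scores tie-break to the lowest start
  expect_identical(sel$start, 35L)
})
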