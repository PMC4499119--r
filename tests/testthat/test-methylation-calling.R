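# a tiny genome whose chr1 has a lone CG at 0-based position 4
tiny_genome <- c(chr1 = "AATACGATTTAATACGATTA")

test_that("methylation counts are simple C/T tallies at reference cytosines", {
  g <- tiny_genome
  reads <- rbind(
    mk_read("r1", "chr1", 0, "AATACGATTT"),
    mk_read("r2", "chr1", 0, "AATACGATTT"),
    mk_read("r3", "chr1", 0, "AATATGATTT"))   # converted at the CG
  calls <- call_methylation(reads, g, trim = 0)
  site <- calls[calls$pos == 4 & calls$strand == "+", ]
  expect_identical(site$methylated, 2L)
  expect_identical(site$unmethylated, 1L)
  expect_equal(site$level, 2 / 3)
  expect_identical(site$context, "CG")
  # non-C/T bases (error or SNP) are ignored, not counted unmethylated
  reads_g <- mk_read("r4", "chr1", 0, "AATAGGATTT")
  calls_g <- call_methylation(rbind(reads, reads_g), g, trim = 0)
  site_g <- calls_g[calls_g$pos == 4 & calls_g$strand == "+", ]
  expect_identical(site_g$methylated + site_g$unmethylated, 3L)
})

test_that("OB reads inform minus-strand cytosines via G/A", {
  g <- tiny_genome  # minus-strand cytosine at the G of the CG (pos 5)
  reads <- rbind(
    mk_read("r1", "chr1", 0, "AATACGATTT", bs_strand = "OB", orient = "-"),
    mk_read("r2", "chr1", 0, "AATACAATTT", bs_strand = "OB", orient = "-"))
  calls <- call_methylation(reads, g, trim = 0)
  site <- calls[calls$pos == 5 & calls$strand == "-", ]
  expect_identical(site$methylated, 1L)
  expect_identical(site$unmethylated, 1L)
  # OB reads never inform plus-strand cytosines
  expect_false(any(calls$strand == "+"))
})

test_that("the first trimmed bases of each mate are not scored", {
  g <- c(chr1 = "CGTTTTTTTT")
  r <- mk_read("r1", "chr1", 0, "CGTTTTTTTT")
  expect_identical(nrow(call_methylation(r, g, trim = 2)), 0L)
  expect_identical(nrow(call_methylation(r, g, trim = 0)), 1L)
  # '-' oriented reads trim from their 5' end, the right edge
  g2 <- c(chr1 = "TTTTTTTTCG")
  r2 <- mk_read("r2", "chr1", 0, "TTTTTTTTCG", orient = "-")
  expect_identical(nrow(call_methylation(r2, g2, trim = 2)), 0L)
  r3 <- mk_read("r3", "chr1", 0, "TTTTTTTTCG", orient = "+")
  expect_identical(nrow(call_methylation(r3, g2, trim = 2)), 1L)
})

test_that("mate-overlapping positions are counted once", {
  g <- tiny_genome
  pair <- rbind(
    mk_read("p1", "chr1", 0, "AATACGATTT", mate = 1L),
    mk_read("p1", "chr1", 2, "TACGATTTAA", mate = 2L, orient = "-"))
  calls <- call_methylation(pair, g, trim = 0)
  site <- calls[calls$pos == 4, ]
  expect_identical(site$methylated, 1L)
  both <- call_methylation(pair, g, trim = 0, no_overlap = FALSE)
  expect_identical(both[both$pos == 4, ]$methylated, 2L)
})

test_that("reads beyond the contig raise a coordinate error", {
  expect_error(call_methylation(mk_read("r", "chr1", 15, "AATACGATTA"),
                                tiny_genome), "beyond contig")
})

test_that("duplicate marking keys on coordinates and methylation pattern", {
  g <- tiny_genome
  a <- mk_read("a", "chr1", 0, "AATACGATTT")
  b <- mk_read("b", "chr1", 0, "AATACGATTT")   # same coords, same pattern
  c_ <- mk_read("c", "chr1", 0, "AATATGATTT")  # same coords, converted CG
  two_same <- mark_duplicates(rbind(a, b), g)
  expect_identical(sum(two_same$is_duplicate), 1L)
  expect_equal(duplicate_rate(two_same), 0.5)
  two_diff <- mark_duplicates(rbind(a, c_), g)
  expect_identical(sum(two_diff$is_duplicate), 0L)
  # coordinate-only mode flags them regardless of pattern
  coord <- mark_duplicates(rbind(a, c_), use_methylation_pattern = FALSE)
  expect_identical(sum(coord$is_duplicate), 1L)
  single <- mark_duplicates(a, g)
  expect_equal(duplicate_rate(single), 0)
})

test_that("duplicate marking is idempotent and order-independent", {
  g <- fixture_genome(len = 4000L, control = 0L, seed = 61)
  cfg <- sim_config(genome_length = 4000L, control_length = 0L, depth = 8,
                    duplicate_fraction = 0.2, seed = 61)
  meth <- make_methylome(g, seed = 61)
  sim <- simulate_bs_reads(g, meth,
                           data.frame(contig = "chr1", start = 500L,
                                      end = 3500L), cfg)
  m1 <- mark_duplicates(sim$reads, g)
  m2 <- mark_duplicates(m1, g)
  expect_identical(m1$is_duplicate, m2$is_duplicate)
  perm <- sample(nrow(sim$reads))
  m3 <- mark_duplicates(sim$reads[perm, ], g)
  key <- function(d) paste(d$read_id, d$mate)
  expect_identical(m3$is_duplicate[match(key(m1), key(m3))], m1$is_duplicate)
  expect_gt(duplicate_rate(m1), 0.05)
})

test_that("on-target rate uses >= 1 bp overlap with half-open intervals", {
  tg <- data.frame(contig = "chr1", start = 100L, end = 200L)
  over1 <- mk_read("a", "chr1", 91, strrep("A", 10))   # ends at 101: 1 bp in
  abut <- mk_read("b", "chr1", 90, strrep("A", 10))    # ends at 100: 0 bp
  expect_equal(on_target_rate(over1, tg), 1)
  expect_equal(on_target_rate(rbind(over1, abut), tg), 0.5)
  inside <- rbind(mk_read("c", "chr1", 120, strrep("A", 10)),
                  mk_read("d", "chr1", 150, strrep("A", 10)))
  expect_equal(on_target_rate(inside, tg), 1.0)
  expect_error(on_target_rate(over1[0, ], tg), "no aligned reads")
})

test_that("coverage statistics clip mate overlaps and include zero bases", {
  tg <- data.frame(contig = "chr1", start = 0L, end = 100L)
  one <- mk_read("a", "chr1", 0, strrep("A", 100))
  cs <- coverage_stats(one, tg)
  expect_equal(cs$mean, 1.0)
  # mate pair overlapping by 20 bp: overlap bases have depth 1
  pair <- rbind(mk_read("p", "chr1", 0, strrep("A", 60), mate = 1L),
                mk_read("p", "chr1", 40, strrep("A", 60), mate = 2L))
  cs2 <- coverage_stats(pair, tg)
  expect_true(all(cs2$depth == 1L))
  expect_equal(coverage_stats(one[0, ], tg)$mean, 0)
  expect_error(coverage_stats(one, tg[0, ]), "interval|empty")
  # zero-depth bases can be excluded on request
  half <- mk_read("h", "chr1", 0, strrep("A", 50))
  expect_equal(coverage_stats(half, tg)$mean, 0.5)
  expect_equal(coverage_stats(half, tg, include_zero = FALSE)$mean, 1)
})

test_that("fold enrichment follows the base-ratio formula", {
  set.seed(71)
  g <- fixture_genome(len = 10000L, control = 0L, seed = 71)
  tg <- data.frame(contig = "chr1", start = 4950L, end = 5050L)  # 1% of genome
  on <- do.call(rbind, lapply(1:20, function(i)
    mk_read(paste0("r", i), "chr1", 4950L, strrep("A", 100))))
  expect_equal(fold_enrichment(on, tg, g), 100)
  # uniform reads over the genome: enrichment near 1
  starts <- sample(0:(10000 - 100), 400, replace = TRUE)
  unif <- do.call(rbind, lapply(seq_along(starts), function(i)
    mk_read(paste0("u", i), "chr1", starts[i], strrep("A", 100))))
  expect_lt(abs(fold_enrichment(unif, tg, g) - 1), 0.75)
  expect_error(fold_enrichment(on[0, ], tg, g), "no aligned bases")
})

test_that("a 50:50 mixture matches its expected blended histogram", {
  g <- fixture_genome(len = 6000L, control = 0L, seed = 81)
  tg <- data.frame(contig = "chr1", start = 500L, end = 5500L)
  sites <- as.data.frame(cytosine_sites(g))
  # sample A hypomethylated, sample B fully methylated (M.SssI-like)
  low <- sites; low$mc <- 0.02; low$hmc <- 0
  high <- sites; high$mc <- 1; high$hmc <- 0
  cfg_a <- sim_config(genome_length = 6000L, control_length = 0L, depth = 25,
                      seed = 811)
  cfg_b <- sim_config(genome_length = 6000L, control_length = 0L, depth = 25,
                      seed = 812)
  calls_a <- call_methylation(simulate_bs_reads(g, low, tg, cfg_a)$reads, g)
  calls_b <- call_methylation(simulate_bs_reads(g, high, tg, cfg_b)$reads, g)
  # in-silico 50:50 mixture: pool half of each sample's counts
  key <- function(d) paste(d$contig, d$pos, d$strand)
  common <- intersect(key(calls_a), key(calls_b))
  ia <- match(common, key(calls_a)); ib <- match(common, key(calls_b))
  mix <- calls_a[ia, ]
  mix$methylated <- rbinom(length(ia), calls_a$methylated[ia], 0.5) +
    rbinom(length(ia), calls_b$methylated[ib], 0.5)
  mix$unmethylated <- rbinom(length(ia), calls_a$unmethylated[ia], 0.5) +
    rbinom(length(ia), calls_b$unmethylated[ib], 0.5)
  mix$level <- mix$methylated / (mix$methylated + mix$unmethylated)
  res <- methylation_mixture_check(calls_a, calls_b, mix)
  # calibrate "within resampling error" from the generative model itself:
  # parametric-bootstrap mixtures drawn at the same depths, including the
  # estimation noise of the pooled per-site levels
  null_distance <- function(res) {
    p_hat <- rbinom(res$n_sites, res$site_pool_depth, res$site_expected) /
      res$site_pool_depth
    lv <- rbinom(res$n_sites, res$site_depth, p_hat) / res$site_depth
    bins <- length(res$expected)
    cnt <- tabulate(pmin(findInterval(lv, res$breaks, rightmost.closed = TRUE),
                         bins), nbins = bins)
    0.5 * sum(abs(cnt / sum(cnt) - res$expected))
  }
  nulls <- replicate(200, null_distance(res))
  expect_lt(res$distance, max(nulls) + 0.02)
  # mixture equal to sample A alone is far outside resampling error
  res_a <- methylation_mixture_check(calls_a, calls_b, calls_a)
  expect_gt(res_a$distance, max(nulls) + 0.02)
  # independent oracle for the analytic expected histogram: per-site
  # binomial mass accumulated bin by bin in a plain double loop
  want <- numeric(20)
  for (i in seq_along(common)) {
    n <- calls_a$methylated[ia[i]] + calls_a$unmethylated[ia[i]]
    pi_ <- (calls_a$methylated[ia[i]] + calls_b$methylated[ib[i]]) /
      (calls_a$methylated[ia[i]] + calls_a$unmethylated[ia[i]] +
         calls_b$methylated[ib[i]] + calls_b$unmethylated[ib[i]])
    for (k in 0:n) {
      bb <- min(findInterval(k / n, res_a$breaks, rightmost.closed = TRUE), 20)
      want[bb] <- want[bb] + dbinom(k, n, pi_)
    }
  }
  want <- want / sum(want)
  expect_equal(res_a$expected, want, tolerance = 1e-10)
  off <- calls_b; off$contig <- "nowhere"
  expect_error(methylation_mixture_check(calls_a, calls_b, off), "common")
})
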