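# expand reads to one row per (read, reference position, base), applying
# the 5'-end trim; data.table backbone of the calling engine
expand_read_bases <- function(reads, trim = 0L) {
  dt <- data.table::as.data.table(reads)
  widths <- dt$end - dt$start
  if (any(widths != nchar(dt$seq))) {
    stop("read seq length must equal end - start", call. = FALSE)
  }
  n <- nrow(dt)
  idx <- rep.int(seq_len(n), widths)
  offs <- sequence(widths) - 1L
  base <- unlist(strsplit(dt$seq, "", fixed = TRUE), use.names = FALSE)
  out <- data.table::data.table(
    row = idx,
    read_id = dt$read_id[idx],
    mate = dt$mate[idx],
    contig = dt$contig[idx],
    pos = dt$start[idx] + offs,
    bs_strand = dt$bs_strand[idx],
    base = base
  )
  if (trim > 0L) {
    # the first `trim` sequenced bases sit at the left end of '+' oriented
    # reads and at the right end of '-' oriented reads
    orient <- dt$orient[idx]
    w <- widths[idx]
    from5p <- ifelse(orient == "+", offs, w - 1L - offs)
    out <- out[from5p >= trim]
  }
  out
}

#' Call per-cytosine methylation from aligned bisulfite reads
#'
#' At every covered strand-aware reference cytosine (plus-strand C informed
#' by OT reads, minus-strand C -- a reference G -- informed by OB reads), a
#' read base matching the unconverted state (C on OT, G on OB) increments
#' the methylated count and a converted base (T on OT, A on OB) the
#' unmethylated count; any other base (sequencing error or SNP) is ignored.
#' The first `trim` sequenced bases of each mate are skipped, and with
#' `no_overlap = TRUE` positions covered by both mates of a pair are
#' counted once (mate 1 takes precedence). Duplicate-flagged reads are
#' excluded.
#'
#' @param reads Read data.frame (see [read_reads()] for the dialect).
#' @param genome Named character vector of contigs.
#' @param trim Bases ignored at the 5' end of each mate (default 2).
#' @param no_overlap Count mate-overlapping positions once (default `TRUE`).
#' @param exclude_duplicates Drop duplicate-flagged reads (default `TRUE`).
#' @return `data.frame`: `contig`, `pos` (0-based), `strand`, `context`,
#'   `methylated`, `unmethylated`, `level` (`NA` when total is 0).
#' @export
call_methylation <- function(reads, genome, trim = 2L, no_overlap = TRUE,
                             exclude_duplicates = TRUE) {
  genome <- validate_genome(genome)
  reads <- as.data.frame(reads)
  if (exclude_duplicates && !is.null(reads$is_duplicate)) {
    reads <- reads[!isTRUE_vec(reads$is_duplicate), , drop = FALSE]
  }
  for (i in seq_len(nrow(reads))) {
    if (reads$end[i] > nchar(genome[[reads$contig[i]]])) {
      stop("read ", reads$read_id[i], " extends beyond contig ",
           reads$contig[i], call. = FALSE)
    }
  }
  sites <- cytosine_sites(genome, contigs = unique(reads$contig))
  bases <- expand_read_bases(reads, trim = trim)
  if (no_overlap && nrow(bases)) {
    data.table::setorderv(bases, c("read_id", "contig", "pos", "mate"))
    bases <- bases[!duplicated(bases[, c("read_id", "contig", "pos")]), ]
  }
  # site strand informed by the read's bisulfite strand
  bases[, `:=`(strand = ifelse(bs_strand == "OT", "+", "-"))]
  merged <- merge(bases, sites, by = c("contig", "pos", "strand"))
  meth_base <- ifelse(merged$strand == "+", "C", "G")
  unmeth_base <- ifelse(merged$strand == "+", "T", "A")
  merged[, `:=`(m = base == meth_base, u = base == unmeth_base)]
  calls <- merged[, list(methylated = sum(m), unmethylated = sum(u)),
                  by = c("contig", "pos", "strand", "context")]
  calls <- calls[calls$methylated + calls$unmethylated > 0L]
  tot <- calls$methylated + calls$unmethylated
  calls[, `:=`(level = ifelse(tot > 0, methylated / tot, NA_real_))]
  data.table::setorderv(calls, c("contig", "pos", "strand"))
  as.data.frame(calls)
}

# methylation pattern string of a read: the read bases at the strand-aware
# cytosine positions it covers (used as part of duplicate identity)
read_patterns <- function(reads, genome) {
  sites <- cytosine_sites(genome, contigs = unique(reads$contig),
                          drop_incomplete = FALSE)
  bases <- expand_read_bases(reads, trim = 0L)
  bases[, `:=`(strand = ifelse(bs_strand == "OT", "+", "-"))]
  merged <- merge(bases, sites[, c("contig", "pos", "strand")],
                  by = c("contig", "pos", "strand"))
  data.table::setorderv(merged, c("row", "pos"))
  pat <- merged[, list(pattern = paste(base, collapse = "")), by = "row"]
  out <- rep("", nrow(reads))
  out[pat$row] <- pat$pattern
  out
}

#' Mark PCR duplicate reads
#'
#' Reads sharing contig, start, end, mate and bisulfite strand -- and, in
#' pattern mode, the same within-read methylation pattern -- are considered
#' PCR duplicates; one representative (first by read id) stays unflagged.
#' Pattern mode matches the duplicate definition based on identity of both
#' coordinates and DNA methylation patterns within the read; coordinate-only
#' mode (`use_methylation_pattern = FALSE`) reproduces the conventional
#' position-based definition.
#'
#' @param reads Read data.frame, coordinate-sortable.
#' @param genome Needed in pattern mode to locate cytosines.
#' @param use_methylation_pattern Include the methylation pattern in the
#'   duplicate key (default `TRUE`).
#' @return The reads with `is_duplicate` set; the flagged fraction is
#'   attached as attribute `"duplicate_rate"` (also via
#'   [duplicate_rate()]).
#' @export
mark_duplicates <- function(reads, genome = NULL,
                            use_methylation_pattern = TRUE) {
  reads <- as.data.frame(reads)
  if (nrow(reads) == 0L) {
    attr(reads, "duplicate_rate") <- NA_real_
    return(reads)
  }
  key <- paste(reads$contig, reads$start, reads$end, reads$mate,
               reads$bs_strand, sep = "\r")
  if (use_methylation_pattern) {
    if (is.null(genome)) {
      stop("pattern-based duplicate marking needs the genome", call. = FALSE)
    }
    key <- paste(key, read_patterns(reads, validate_genome(genome)),
                 sep = "\r")
  }
  ord <- order(key, reads$read_id, reads$mate)
  dup <- logical(nrow(reads))
  dup[ord] <- duplicated(key[ord])
  reads$is_duplicate <- dup
  attr(reads, "duplicate_rate") <- mean(dup)
  reads
}

#' Duplicate rate of a marked read set
#'
#' @param reads Output of [mark_duplicates()].
#' @return Fraction of reads flagged as duplicates.
#' @export
duplicate_rate <- function(reads) {
  r <- attr(reads, "duplicate_rate")
  if (!is.null(r)) return(r)
  mean(isTRUE_vec(reads$is_duplicate))
}

#' On-target rate of aligned reads
#'
#' Fraction of aligned reads overlapping the target intervals by at least
#' 1 bp; no padding is applied and half-open coordinates mean an abutting
#' read does not count.
#'
#' @param reads Read data.frame.
#' @param targets `GRanges` or BED-like data.frame.
#' @return Fraction in `[0, 1]`.
#' @export
on_target_rate <- function(reads, targets) {
  reads <- as.data.frame(reads)
  if (nrow(reads) == 0L) {
    stop("on-target rate undefined: no aligned reads", call. = FALSE)
  }
  tg <- bed_to_granges(targets)
  gr <- GenomicRanges::GRanges(reads$contig,
                               IRanges::IRanges(reads$start + 1L, reads$end))
  hits <- GenomicRanges::countOverlaps(gr, tg, minoverlap = 1L)
  mean(hits > 0L)
}

# fragment-level intervals: per read_id/contig, mate intervals merged so an
# overlapping pair contributes each base once (clipped overlap)
fragment_ranges <- function(reads) {
  dt <- data.table::as.data.table(reads)
  frag <- dt[, list(start = min(start), end = max(end)),
             by = c("read_id", "contig")]
  # mates of one fragment are collinear here (no gapped alignment), so the
  # union is the single [min start, max end) interval
  GenomicRanges::GRanges(frag$contig,
                         IRanges::IRanges(frag$start + 1L, frag$end))
}

#' Coverage statistics over the target regions
#'
#' Per-base depth over the union of target bases, computed from
#' fragment-level intervals (mate overlaps clipped so each fragment
#' contributes once per base) after excluding duplicates. Zero-depth target
#' bases are included by default.
#'
#' @param reads Read data.frame.
#' @param targets `GRanges` or BED-like data.frame.
#' @param exclude_duplicates Drop duplicate-flagged reads (default `TRUE`).
#' @param include_zero Include zero-depth target bases in the statistics
#'   (default `TRUE`).
#' @return List with `mean`, `median` and the per-base `depth` vector.
#' @export
coverage_stats <- function(reads, targets, exclude_duplicates = TRUE,
                           include_zero = TRUE) {
  tg <- GenomicRanges::reduce(bed_to_granges(targets))
  if (length(tg) == 0L) stop("empty target set", call. = FALSE)
  reads <- as.data.frame(reads)
  if (exclude_duplicates && !is.null(reads$is_duplicate)) {
    reads <- reads[!isTRUE_vec(reads$is_duplicate), , drop = FALSE]
  }
  depth <- integer(0)
  if (nrow(reads) > 0L) {
    fr <- fragment_ranges(reads)
    cov <- GenomicRanges::coverage(fr)
  }
  per_target <- lapply(seq_along(tg), function(i) {
    cn <- as.character(GenomicRanges::seqnames(tg))[i]
    w <- GenomicRanges::width(tg)[i]
    if (nrow(reads) == 0L || !cn %in% names(cov)) return(integer(w))
    v <- cov[[cn]]
    s <- GenomicRanges::start(tg)[i]; e <- GenomicRanges::end(tg)[i]
    len <- length(v)
    inside <- if (s > len) integer(0) else
      as.integer(S4Vectors::window(v, s, min(e, len)))
    c(inside, integer(max(0L, e - max(s - 1L, len))))
  })
  depth <- unlist(per_target)
  if (!include_zero) depth <- depth[depth > 0L]
  list(mean = if (length(depth)) mean(depth) else 0,
       median = if (length(depth)) stats::median(depth) else 0,
       depth = depth)
}

#' Fold enrichment of target coverage
#'
#' Simplified hybrid-selection enrichment: (on-target aligned bases /
#' target size) divided by (total aligned bases / genome size), using
#' fragment-clipped intervals for the aligned bases.
#'
#' @param reads Read data.frame.
#' @param targets `GRanges` or BED-like data.frame.
#' @param genome Named character vector of contigs.
#' @return Enrichment ratio (>= 0).
#' @export
fold_enrichment <- function(reads, targets, genome) {
  genome <- validate_genome(genome)
  reads <- as.data.frame(reads)
  if (!is.null(reads$is_duplicate)) {
    reads <- reads[!isTRUE_vec(reads$is_duplicate), , drop = FALSE]
  }
  if (nrow(reads) == 0L) stop("no aligned bases", call. = FALSE)
  tg <- GenomicRanges::reduce(bed_to_granges(targets))
  fr <- fragment_ranges(reads)
  total_bases <- sum(GenomicRanges::width(fr))
  if (total_bases == 0L) stop("no aligned bases", call. = FALSE)
  hits <- GenomicRanges::findOverlaps(fr, tg)
  ov <- GenomicRanges::pintersect(fr[S4Vectors::queryHits(hits)],
                                  tg[S4Vectors::subjectHits(hits)])
  on_bases <- sum(GenomicRanges::width(ov))
  target_size <- sum(GenomicRanges::width(tg))
  genome_size <- sum(nchar(genome))
  (on_bases / target_size) / (total_bases / genome_size)
}

#' Compare an observed mixture methylome with its expected 50:50 blend
#'
#' For each site common to both pure samples and the mixture, the expected
#' mixture methylation level is the count-pooled level of the two samples.
#' The expected level histogram is then built analytically by propagating
#' each site's pooled level through a binomial at the mixture's observed
#' depth (so expected and observed histograms carry the same resampling
#' spread), and compared with the observed mixture histogram by total
#' variation distance (0 = identical, 1 = disjoint). Mirrors the logic of
#' mixing an untreated and a fully M.SssI-treated sample in equal
#' proportions and checking that the capture does not distort the
#' distribution.
#'
#' @param sample_a_calls,sample_b_calls,mix_calls Call data.frames from
#'   [call_methylation()].
#' @param bins Number of equal-width level bins on `[0, 1]` (default 20).
#' @return List with `distance`, `breaks`, `expected`, `observed`
#'   (proportions per bin), `n_sites`, and the per-site `site_expected`
#'   levels and `site_depth` (for resampling-error calibration).
#' @export
methylation_mixture_check <- function(sample_a_calls, sample_b_calls,
                                      mix_calls, bins = 20L) {
  key <- function(d) paste(d$contig, d$pos, d$strand, sep = ":")
  a <- as.data.frame(sample_a_calls); b <- as.data.frame(sample_b_calls)
  m <- as.data.frame(mix_calls)
  common <- Reduce(intersect, list(key(a), key(b), key(m)))
  if (length(common) == 0L) {
    stop("no common sites between samples and mixture", call. = FALSE)
  }
  ia <- match(common, key(a)); ib <- match(common, key(b))
  im <- match(common, key(m))
  expected_level <- (a$methylated[ia] + b$methylated[ib]) /
    (a$methylated[ia] + a$unmethylated[ia] +
       b$methylated[ib] + b$unmethylated[ib])
  depth <- m$methylated[im] + m$unmethylated[im]
  observed_level <- m$level[im]
  breaks <- seq(0, 1, length.out = bins + 1L)
  bin_of <- function(x) pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                             bins)
  # analytic expected histogram: Binomial(depth_i, p_i) mass per level bin
  p <- numeric(bins)
  for (i in seq_along(common)) {
    n <- depth[i]
    if (n == 0L) next
    k <- 0:n
    w <- stats::dbinom(k, n, expected_level[i])
    bb <- bin_of(k / n)
    p <- p + unname(tapply(w, factor(bb, levels = seq_len(bins)), sum,
                           default = 0))
  }
  p <- as.numeric(p / sum(p))
  cnt <- tabulate(bin_of(observed_level[depth > 0]), nbins = bins)
  q <- cnt / sum(cnt)
  pool_depth <- a$methylated[ia] + a$unmethylated[ia] +
    b$methylated[ib] + b$unmethylated[ib]
  list(distance = 0.5 * sum(abs(p - q)), breaks = breaks,
       expected = p, observed = q, n_sites = length(common),
       site_expected = expected_level, site_depth = depth,
       site_pool_depth = pool_depth)
}

#' Capture QC metrics bundle
#'
#' Convenience wrapper computing duplicate rate, on-target rate, coverage
#' statistics and fold enrichment in one pass.
#'
#' @param reads Read data.frame (will be duplicate-marked if not already).
#' @param targets `GRanges` or BED-like data.frame.
#' @param genome Named character vector of contigs.
#' @param use_methylation_pattern Passed to [mark_duplicates()].
#' @return Named list of metrics.
#' @export
capture_metrics <- function(reads, targets, genome,
                            use_methylation_pattern = TRUE) {
  if (is.null(reads$is_duplicate) || !any(isTRUE_vec(reads$is_duplicate))) {
    reads <- mark_duplicates(reads, genome,
                             use_methylation_pattern = use_methylation_pattern)
  }
  cs <- coverage_stats(reads, targets)
  list(
    duplicate_rate = duplicate_rate(reads),
    on_target_rate = on_target_rate(reads, targets),
    mean_coverage = cs$mean,
    median_coverage = cs$median,
    fold_enrichment = fold_enrichment(reads, targets, genome)
  )
}
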