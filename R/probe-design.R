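#' Melting temperature of an oligonucleotide
#'
#' Default method is the GC-content formula Tm = 64.9 + 41 * (nGC - 16.4) / L
#' (degrees C); `"wallace"` selects the Wallace rule 2(A+T) + 4(G+C),
#' adequate only for short oligos but useful as a cross-check.
#'
#' @param seq Character vector of sequences (no N).
#' @param method `"gc"` (default) or `"wallace"`.
#' @return Numeric vector of melting temperatures in degrees C.
#' @export
melting_temperature <- function(seq, method = c("gc", "wallace")) {
  method <- match.arg(method)
  if (any(nchar(seq) == 0)) stop("empty sequence", call. = FALSE)
  if (any(grepl("[^ACGTacgt]", seq))) {
    stop("melting temperature undefined for sequences containing N",
         call. = FALSE)
  }
  seq <- toupper(seq)
  L <- nchar(seq)
  ngc <- nchar(gsub("[AT]", "", seq))
  switch(method,
    gc = 64.9 + 41 * (ngc - 16.4) / L,
    wallace = 2 * (L - ngc) + 4 * ngc
  )
}

#' Homopolymer score of a sequence
#'
#' The maximum run length of any single base. The full per-base maximum-run
#' vector (A, C, G, T) is attached as attribute `"runs"` for inspection.
#'
#' @param seq A single sequence.
#' @return Integer scalar, the longest single-base run.
#' @export
homopolymer_score <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0) {
    stop("homopolymer score requires one non-empty sequence", call. = FALSE)
  }
  r <- rle(chars(toupper(seq)))
  runs <- vapply(c("A", "C", "G", "T"), function(b) {
    w <- r$lengths[r$values == b]
    if (length(w)) max(w) else 0L
  }, integer(1))
  structure(max(r$lengths), runs = runs)
}

#' Build the k-mer frequency table of a fully converted genome
#'
#' Counts every k-mer (default k = 15) of both strands of the genome after
#' in-silico bisulfite conversion assuming no CG methylation (every C -> T
#' on each strand's own sequence). K-mers containing N are skipped, as are
#' contigs shorter than k (with a warning). Probe repetitiveness is scored
#' against this table.
#'
#' @param genome Named character vector of contigs.
#' @param k K-mer length (default 15).
#' @return Object of class `kmer_table`: list with `k` and `counts`
#'   (named integer vector).
#' @export
build_kmer_table <- function(genome, k = 15L) {
  genome <- validate_genome(genome)
  if (length(genome) == 0) stop("genome is empty", call. = FALSE)
  all_kmers <- character()
  for (cn in names(genome)) {
    s <- genome[[cn]]
    if (nchar(s) < k) {
      warning("contig ", cn, " shorter than k = ", k, "; skipped")
      next
    }
    for (strand_seq in c(bs_convert(s), bs_convert(revcomp(s)))) {
      L <- nchar(strand_seq)
      km <- substring(strand_seq, 1:(L - k + 1L), k:L)
      km <- km[!grepl("N", km, fixed = TRUE)]
      all_kmers <- c(all_kmers, km)
    }
  }
  counts <- if (length(all_kmers)) table(all_kmers) else table(character())
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(k = as.integer(k), counts = counts), class = "kmer_table")
}

#' Look up k-mer counts in a frequency table
#'
#' @param table A `kmer_table`.
#' @param kmers Character vector of k-mers.
#' @return Integer vector of counts (0 for absent k-mers).
#' @export
kmer_lookup <- function(table, kmers) {
  stopifnot(inherits(table, "kmer_table"))
  idx <- match(kmers, names(table$counts))
  out <- table$counts[idx]
  out[is.na(idx)] <- 0L
  unname(out)
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("kmer_table: k =", x$k, "|", length(x$counts), "distinct k-mers |",
      sum(x$counts), "total occurrences\n")
  invisible(x)
}

#' Repeat score of a probe sequence
#'
#' Arithmetic mean of the k-mer table counts over all len - k + 1 k-mers of
#' the (already converted) probe sequence. Probes averaging above the design
#' cutoff (10 000 by default in [filter_candidates()]) are considered
#' repetitive.
#'
#' @param seq Converted probe sequence.
#' @param table A `kmer_table`.
#' @return Mean k-mer frequency.
#' @export
repeat_score <- function(seq, table) {
  stopifnot(inherits(table, "kmer_table"))
  k <- table$k
  L <- nchar(seq)
  if (L < k) stop("probe shorter than k = ", k, call. = FALSE)
  km <- substring(seq, 1:(L - k + 1L), k:L)
  mean(kmer_lookup(table, km))
}

#' Count bisulfite-compatible mapping locations of a probe
#'
#' Searches both orientations of every contig for matches of the converted
#' probe under bisulfite-asymmetric matching: a probe T matches genome C or
#' T on the C-converted orientation (equivalently, probe A matches genome G
#' or A on the opposite orientation); retained probe Cs must match genome C.
#' Implemented by turning probe Ts into the IUPAC wildcard Y and scanning
#' the forward and reverse-complement contig sequences. Exact matching by
#' default; `max_mismatch` allows a mismatch budget.
#'
#' @param seq Converted probe sequence.
#' @param genome Named character vector of contigs.
#' @param max_mismatch Allowed mismatches (default 0).
#' @return Integer count of genomic mapping locations.
#' @export
count_mapping_locations <- function(seq, genome, max_mismatch = 0L) {
  genome <- validate_genome(genome)
  pat <- Biostrings::DNAString(chartr("T", "Y", toupper(seq)))
  n <- 0L
  for (s in genome) {
    subj <- Biostrings::DNAString(s)
    n <- n + Biostrings::countPattern(pat, subj, max.mismatch = max_mismatch,
                                      fixed = "subject")
    n <- n + Biostrings::countPattern(pat, Biostrings::reverseComplement(subj),
                                      max.mismatch = max_mismatch,
                                      fixed = "subject")
  }
  n
}

# probe state labels: strand x CG-methylation assumption
probe_states <- function() {
  data.frame(
    strand = rep(c("top", "bottom"), each = 2),
    cg_methylated = rep(c(TRUE, FALSE), 2),
    state = c("top_M", "top_U", "bottom_M", "bottom_U"),
    stringsAsFactors = FALSE
  )
}

#' Generate tiled variable-length probe candidates
#'
#' Tiles candidate start positions every `tile` bp across each target
#' region, for all four probe states (top/bottom strand x all/no CG
#' methylation). Probe length is variable between `min_len` and `max_len`:
#' starting from `min_len` the probe grows 1 bp at a time until the melting
#' temperature of the converted sequence enters `tm_band`; if the band is
#' unreachable the length whose Tm is closest to the band center is used.
#' Probes are kept inside their target, so targets shorter than `min_len`
#' yield no candidates (with a warning).
#'
#' @param genome Named character vector of contigs.
#' @param targets `GRanges` or BED-like data.frame (`contig`,`start`,`end`,
#'   0-based half-open).
#' @param min_len,max_len Probe length bounds (default 50, 100).
#' @param tile Tiling interval in bp (default 5).
#' @param tm_band Target melting-temperature band in degrees C
#'   (default `c(68, 73)`).
#' @param tm_method Passed to [melting_temperature()].
#' @return `data.frame` of candidates: `contig`, `start`, `end`, `strand`,
#'   `cg_methylated`, `state`, `target_id`, `seq`, `length`, `tm`.
#' @export
generate_candidates <- function(genome, targets, min_len = 50L, max_len = 100L,
                                tile = 5L, tm_band = c(68, 73),
                                tm_method = "gc") {
  genome <- validate_genome(genome)
  tg <- as_bed_df(targets)
  states <- probe_states()
  tm_center <- mean(tm_band)
  res <- vector("list", 0L)
  for (ti in seq_len(nrow(tg))) {
    cn <- tg$contig[ti]; tstart <- tg$start[ti]; tend <- tg$end[ti]
    s <- genome[[cn]]
    if (is.null(s)) stop("target contig not in genome: ", cn, call. = FALSE)
    if (tend > nchar(s)) stop("target exceeds contig bounds: ", cn, call. = FALSE)
    if (tend - tstart < min_len) {
      warning("target ", cn, ":", tstart, "-", tend,
              " shorter than min_len = ", min_len, "; no candidates")
      next
    }
    starts <- seq.int(tstart, tend - min_len, by = tile)
    b <- chars(substr(s, tstart + 1L, tend))
    # cumulative counts over the target window for fast converted-GC tallies
    csG <- cumsum(b == "G")
    csC <- cumsum(b == "C")
    isCG <- b == "C" & c(b[-1L], "") == "G"
    csCG <- cumsum(isCG)
    at0 <- function(cs, i) if (i > 0L) cs[i] else 0L
    for (si in seq_len(nrow(states))) {
      cg_m <- states$cg_methylated[si]
      strand <- states$strand[si]
      pick_len <- integer(length(starts))
      pick_tm <- numeric(length(starts))
      for (st in starts) {
        off <- st - tstart                      # 0-based offset in window
        lens <- seq.int(min_len, min(max_len, tend - st))
        # GC count of the converted probe for each length
        nG <- csG[off + lens] - at0(csG, off)
        nC <- csC[off + lens] - at0(csC, off)
        # CG dinucleotides fully inside the window [off, off+l)
        nCGd <- csCG[off + lens - 1L] - at0(csCG, off)
        gc <- if (strand == "top") {
          if (cg_m) nG + nCGd else nG
        } else {
          if (cg_m) nC + nCGd else nC
        }
        tm <- if (tm_method == "gc") {
          64.9 + 41 * (gc - 16.4) / lens
        } else {
          2 * (lens - gc) + 4 * gc
        }
        in_band <- which(tm >= tm_band[1] & tm <= tm_band[2])
        li <- if (length(in_band)) in_band[1L] else which.min(abs(tm - tm_center))
        pick_len[match(st, starts)] <- lens[li]
        pick_tm[match(st, starts)] <- tm[li]
      }
      window_seq <- substring(s, starts + 1L, starts + pick_len)
      pseq <- if (strand == "top") {
        bs_convert(window_seq, cg_methylated = cg_m)
      } else {
        bs_convert(revcomp(window_seq), cg_methylated = cg_m)
      }
      res[[length(res) + 1L]] <- data.frame(
        contig = cn, start = starts, end = starts + pick_len,
        strand = strand, cg_methylated = cg_m, state = states$state[si],
        target_id = ti, seq = pseq, length = pick_len, tm = pick_tm,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), cg_methylated = logical(),
                      state = character(), target_id = integer(),
                      seq = character(), length = integer(), tm = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Score probe candidates
#'
#' Adds the repeat score (mean 15-mer frequency), homopolymer score (longest
#' single-base run) and uniqueness (bisulfite-compatible genomic mapping
#' locations) to a candidate table.
#'
#' @param candidates Output of [generate_candidates()].
#' @param genome Named character vector of contigs.
#' @param table A `kmer_table` from [build_kmer_table()].
#' @param max_mismatch Mismatch budget for uniqueness counting.
#' @return The candidate table with `repeat_score`, `homopolymer_score` and
#'   `uniqueness` columns.
#' @export
score_candidates <- function(candidates, genome, table, max_mismatch = 0L) {
  genome <- validate_genome(genome)
  candidates$repeat_score <- vapply(candidates$seq, repeat_score, numeric(1),
                                    table = table, USE.NAMES = FALSE)
  candidates$homopolymer_score <- vapply(
    candidates$seq, function(x) as.integer(homopolymer_score(x)), integer(1),
    USE.NAMES = FALSE)
  # identical converted sequences map identically; scan each distinct one once
  uniq_seq <- unique(candidates$seq)
  locs <- vapply(uniq_seq, count_mapping_locations, integer(1),
                 genome = genome, max_mismatch = max_mismatch,
                 USE.NAMES = FALSE)
  candidates$uniqueness <- locs[match(candidates$seq, uniq_seq)]
  candidates
}

#' Filter scored candidates on repetitiveness and uniqueness
#'
#' Retains candidates with mean 15-mer frequency at most `max_repeat`
#' (removal requires strictly greater) and at most `max_locations` genomic
#' mapping locations (more than `max_locations` is discarded). Removal
#' counts per reason are attached as attribute `"removed"`.
#'
#' @param candidates Scored candidate table.
#' @param max_repeat Repeat-score cutoff (default 10000).
#' @param max_locations Mapping-location cutoff (default 3).
#' @return Retained candidates.
#' @export
filter_candidates <- function(candidates, max_repeat = 10000, max_locations = 3L) {
  if (is.null(candidates$repeat_score) || is.null(candidates$uniqueness)) {
    stop("candidates must be scored first (see score_candidates)", call. = FALSE)
  }
  rep_fail <- candidates$repeat_score > max_repeat
  uni_fail <- candidates$uniqueness > max_locations
  keep <- !rep_fail & !uni_fail
  out <- candidates[keep, , drop = FALSE]
  attr(out, "removed") <- c(repeat_score = sum(rep_fail),
                            uniqueness = sum(uni_fail),
                            total = sum(!keep))
  out
}

#' Composite rank score of probe candidates
#'
#' A weighted sum of min-max normalized components, all oriented so that
#' lower is better: distance of Tm from `tm_target`, repeat score,
#' uniqueness and homopolymer score. Normalization is over the supplied
#' candidate set; a component with zero range contributes 0. Lower rank
#' scores identify better probes.
#'
#' @param candidates Scored candidate table.
#' @param tm_target Ideal melting temperature (default 70.5 C, the center
#'   of the default selection band).
#' @param weights Named numeric weights for `tm`, `repeats`, `uniqueness`,
#'   `homopolymer` (default all 1).
#' @return The candidate table with a `rank_score` column.
#' @export
rank_score <- function(candidates,
                       tm_target = 70.5,
                       weights = c(tm = 1, repeats = 1, uniqueness = 1,
                                   homopolymer = 1)) {
  need <- c("tm", "repeat_score", "uniqueness", "homopolymer_score")
  if (!all(need %in% names(candidates))) {
    stop("missing score components: ",
         paste(setdiff(need, names(candidates)), collapse = ", "),
         call. = FALSE)
  }
  norm01 <- function(x) {
    r <- range(x)
    if (r[2] == r[1]) return(rep(0, length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  comp <- cbind(
    tm = norm01(abs(candidates$tm - tm_target)),
    repeats = norm01(candidates$repeat_score),
    uniqueness = norm01(candidates$uniqueness),
    homopolymer = norm01(candidates$homopolymer_score)
  )
  candidates$rank_score <- as.numeric(comp %*% weights[colnames(comp)])
  candidates
}

#' Select the final probe panel by windowed tiling
#'
#' For each target and each of the four probe states, places selection
#' windows of width `window` bp left-to-right from the target start with
#' `gap` bp between the end of one window and the start of the next. Within
#' each window the candidate with the best (lowest) rank score whose start
#' lies in the window is selected; ties break to the lowest start
#' coordinate, then the longest probe. Windows in which every candidate was
#' filtered out are recorded in attribute `"empty_windows"` with a warning.
#'
#' @param candidates Filtered, rank-scored candidate table.
#' @param targets `GRanges` or BED-like data.frame.
#' @param window Selection window width in bp (default 15).
#' @param gap Gap between consecutive windows in bp (default 20).
#' @return Selected probes with `window_id`, `window_start` columns.
#' @export
select_probes <- function(candidates, targets, window = 15L, gap = 20L) {
  if (is.null(candidates$rank_score)) {
    stop("candidates must carry rank_score (see rank_score)", call. = FALSE)
  }
  tg <- as_bed_df(targets)
  sel <- vector("list", 0L)
  empty <- vector("list", 0L)
  for (ti in seq_len(nrow(tg))) {
    cn <- tg$contig[ti]; tstart <- tg$start[ti]; tend <- tg$end[ti]
    wstarts <- seq.int(tstart, max(tstart, tend - 1L), by = window + gap)
    cand_t <- candidates[candidates$contig == cn &
                           candidates$start >= tstart &
                           candidates$start < tend, , drop = FALSE]
    for (st in unique(candidates$state)) {
      cand_s <- cand_t[cand_t$state == st, , drop = FALSE]
      for (wi in seq_along(wstarts)) {
        ws <- wstarts[wi]
        in_win <- cand_s[cand_s$start >= ws & cand_s$start < ws + window, ,
                         drop = FALSE]
        if (nrow(in_win) == 0L) {
          empty[[length(empty) + 1L]] <- data.frame(
            contig = cn, window_start = ws, state = st, target_id = ti,
            stringsAsFactors = FALSE)
          next
        }
        ord <- order(in_win$rank_score, in_win$start, -in_win$length)
        best <- in_win[ord[1L], , drop = FALSE]
        best$window_id <- wi
        best$window_start <- ws
        sel[[length(sel) + 1L]] <- best
      }
    }
  }
  out <- if (length(sel)) do.call(rbind, sel) else
    cbind(candidates[0, , drop = FALSE],
          data.frame(window_id = integer(), window_start = integer()))
  rownames(out) <- NULL
  if (length(empty)) {
    warning(length(empty), " selection window(s) had no surviving candidates")
    attr(out, "empty_windows") <- do.call(rbind, empty)
  }
  out
}

#' Design capture probes end-to-end
#'
#' Convenience wrapper: candidate generation, k-mer table construction,
#' scoring, filtering, ranking and windowed selection, returning the final
#' four-panel probe set.
#'
#' @inheritParams generate_candidates
#' @inheritParams filter_candidates
#' @inheritParams select_probes
#' @param tm_target Passed to [rank_score()].
#' @return Selected probe panel (all four states).
#' @export
design_probes <- function(genome, targets, min_len = 50L, max_len = 100L,
                          tile = 5L, window = 15L, gap = 20L,
                          max_repeat = 10000, max_locations = 3L,
                          tm_band = c(68, 73), tm_target = mean(tm_band),
                          tm_method = "gc") {
  cand <- generate_candidates(genome, targets, min_len = min_len,
                              max_len = max_len, tile = tile,
                              tm_band = tm_band, tm_method = tm_method)
  tab <- build_kmer_table(genome)
  cand <- score_candidates(cand, genome, tab)
  cand <- filter_candidates(cand, max_repeat = max_repeat,
                            max_locations = max_locations)
  cand <- rank_score(cand, tm_target = tm_target)
  select_probes(cand, targets, window = window, gap = gap)
}
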