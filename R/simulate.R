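#' Simulation configuration
#'
#' Bundles the study conditions of the simulator: paired-end 100 bp reads
#' from fragments sheared to 180-220 bp, bisulfite conversion efficiency
#' 0.998, and a mean target depth of 30 by default. All randomness flows
#' from `seed`.
#'
#' @param genome_length Main contig length in bp.
#' @param gc_content Genome GC fraction (default 0.47, plant-like).
#' @param control_length Length of the unmethylated control contig
#'   (chloroplast/lambda analog; 0 disables it).
#' @param snp_rate Per-bp probability that the second parent differs.
#' @param conversion_efficiency Probability an unmethylated C converts
#'   (default 0.998).
#' @param fragment_length_range Sheared fragment sizes in bp (default
#'   `c(180, 220)`).
#' @param read_length Mate length in bp (default 100).
#' @param depth Mean per-base coverage over the targets (default 30).
#' @param off_target_fraction Fraction of fragments placed uniformly over
#'   the whole genome instead of inside targets (default 0).
#' @param duplicate_fraction Fraction of fragments duplicated as literal
#'   PCR copies (default 0).
#' @param error_rate Per-base sequencing substitution rate (default 0).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 50000L, gc_content = 0.47,
                       control_length = 4000L, snp_rate = 0.001,
                       conversion_efficiency = 0.998,
                       fragment_length_range = c(180L, 220L),
                       read_length = 100L, depth = 30,
                       off_target_fraction = 0,
                       duplicate_fraction = 0,
                       error_rate = 0, seed = 1L) {
  stopifnot(gc_content >= 0, gc_content <= 1,
            conversion_efficiency >= 0, conversion_efficiency <= 1,
            fragment_length_range[1] <= fragment_length_range[2],
            read_length <= fragment_length_range[1])
  structure(list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    control_length = as.integer(control_length), snp_rate = snp_rate,
    conversion_efficiency = conversion_efficiency,
    fragment_length_range = as.integer(fragment_length_range),
    read_length = as.integer(read_length), depth = depth,
    off_target_fraction = off_target_fraction,
    duplicate_fraction = duplicate_fraction,
    error_rate = error_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

random_seq <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Generate a random genome with an unmethylated control contig
#'
#' @param config A [sim_config()]; `genome_length`, `gc_content`,
#'   `control_length` and `seed` are used.
#' @param contig_name,control_name Contig names (default `"chr1"`,
#'   `"chrC"`).
#' @return Named character genome; the control contig's name is attached
#'   as attribute `"control_contig"`.
#' @export
make_genome <- function(config = sim_config(), contig_name = "chr1",
                        control_name = "chrC") {
  if (config$genome_length <= 0) stop("genome_length must be > 0", call. = FALSE)
  set.seed(config$seed)
  g <- c(random_seq(config$genome_length, config$gc_content))
  names(g) <- contig_name
  if (config$control_length > 0) {
    g[[control_name]] <- random_seq(config$control_length, config$gc_content)
    attr(g, "control_contig") <- control_name
  }
  g
}

#' Derive two parental genomes differing by SNPs
#'
#' Parent A is the input genome; parent B differs at positions drawn with
#' per-bp probability `snp_rate` (control contigs excluded). A fraction of
#' SNPs (`avoid_cg_fraction`) is constrained to A/T<->T/A substitutions at
#' A/T reference bases so that informative SNPs exist on both bisulfite
#' strands; the remainder substitute a uniformly chosen different base.
#'
#' @param genome Named character genome (parent A).
#' @param snp_rate Per-bp SNP probability.
#' @param avoid_cg_fraction Fraction of SNPs constrained to C/G-free allele
#'   pairs (default 0.5).
#' @param seed Integer seed.
#' @return List with `parent_a`, `parent_b` genomes and `snp_table`
#'   (`contig`, `pos` 0-based, `allele_a`, `allele_b`).
#' @export
make_diploid <- function(genome, snp_rate, avoid_cg_fraction = 0.5,
                         seed = 1L) {
  genome <- validate_genome(genome)
  stopifnot(snp_rate > 0, snp_rate < 1)
  set.seed(seed)
  control <- attr(genome, "control_contig")
  parent_b <- genome
  tabs <- list()
  for (cn in setdiff(names(genome), control)) {
    b <- chars(genome[[cn]])
    L <- length(b)
    at_pos <- runif(L) < snp_rate
    pos <- which(at_pos)
    if (!length(pos)) next
    constrained <- runif(length(pos)) < avoid_cg_fraction
    ref <- b[pos]
    alt <- character(length(pos))
    for (i in seq_along(pos)) {
      if (constrained[i] && ref[i] %in% c("A", "T")) {
        alt[i] <- if (ref[i] == "A") "T" else "A"
      } else {
        alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
      }
    }
    keep <- ref != "N"
    pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
    bb <- b
    bb[pos] <- alt
    parent_b[[cn]] <- paste(bb, collapse = "")
    tabs[[cn]] <- data.frame(contig = cn, pos = pos - 1L, allele_a = ref,
                             allele_b = alt, stringsAsFactors = FALSE)
  }
  snp_table <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(contig = character(), pos = integer(), allele_a = character(),
               allele_b = character(), stringsAsFactors = FALSE)
  rownames(snp_table) <- NULL
  list(parent_a = genome, parent_b = parent_b, snp_table = snp_table)
}

#' Default methylome mixture parameters
#'
#' CG and CHG levels are drawn from two-component high/low Beta mixtures
#' (bimodal, as in plant methylomes), CHH from a single low-mean Beta.
#' `hmc_fraction`/`hmc_level` optionally add 5hmC at CG sites.
#'
#' @return Named list of per-context parameters.
#' @export
methylome_params <- function() {
  list(
    CG = list(w_high = 0.7, high = c(30, 3), low = c(1.5, 30)),
    CHG = list(w_high = 0.6, high = c(15, 5), low = c(1.5, 30)),
    CHH = list(w_high = 0, high = c(1, 1), low = c(2, 18)),
    hmc_fraction = 0, hmc_level = 0.15
  )
}

#' Draw a ground-truth methylome over a genome
#'
#' Assigns every strand-aware cytosine (control contigs excluded; they stay
#' unmethylated) a 5mC level from its context's mixture, and optionally a
#' 5hmC level at CG sites, capped so that 5mC + 5hmC <= 1.
#'
#' @param genome Named character genome.
#' @param params See [methylome_params()].
#' @param seed Integer seed.
#' @return `data.frame`: `contig`, `pos`, `strand`, `context`, `mc`, `hmc`.
#' @export
make_methylome <- function(genome, params = methylome_params(), seed = 1L) {
  genome <- validate_genome(genome)
  set.seed(seed)
  control <- attr(genome, "control_contig")
  sites <- as.data.frame(cytosine_sites(
    genome, contigs = setdiff(names(genome), control)))
  n <- nrow(sites)
  mc <- numeric(n)
  for (ctx in c("CG", "CHG", "CHH")) {
    p <- params[[ctx]]
    idx <- which(sites$context == ctx)
    hi <- runif(length(idx)) < p$w_high
    mc[idx] <- ifelse(hi,
                      rbeta(length(idx), p$high[1], p$high[2]),
                      rbeta(length(idx), p$low[1], p$low[2]))
  }
  hmc <- numeric(n)
  if (params$hmc_fraction > 0) {
    cg <- which(sites$context == "CG")
    sel <- cg[runif(length(cg)) < params$hmc_fraction]
    hmc[sel] <- pmin(params$hmc_level, 1 - mc[sel])
  }
  sites$mc <- mc
  sites$hmc <- hmc
  sites
}

# per-contig cytosine position cache for a parent genome: list by contig
# with +/- strand positions (0-based)
strand_c_positions <- function(genome) {
  lapply(genome, function(s) {
    b <- chars(s)
    list(`+` = which(b == "C") - 1L, `-` = which(b == "G") - 1L)
  })
}

# core paired-end read simulator shared by BS and TAB modes
simulate_reads_engine <- function(parents, methylome, targets, config,
                                  mode = c("bs", "tab"),
                                  protection_rate = 0.98,
                                  mc_conversion_rate = 0.995,
                                  id_prefix = "frag") {
  mode <- match.arg(mode)
  if (is.character(parents)) parents <- list(parent_a = validate_genome(parents))
  parents <- lapply(parents, validate_genome)
  tg <- as_bed_df(targets)
  rl <- config$read_length
  fr <- config$fragment_length_range
  eff <- config$conversion_efficiency
  methylome <- as.data.frame(methylome)
  if (is.null(methylome$hmc)) methylome$hmc <- 0
  mkey <- paste(methylome$contig, methylome$pos, methylome$strand)
  mc_map <- stats::setNames(methylome$mc, mkey)
  hmc_map <- stats::setNames(methylome$hmc, mkey)
  cpos <- lapply(parents, strand_c_positions)
  # fragments needed for the requested mean coverage: each fragment covers
  # min(fragment length, 2 * read length) distinct target bases
  e_bases <- mean(pmin(seq.int(fr[1], fr[2]), 2L * rl))
  n_on <- max(1L, round(config$depth * sum(tg$end - tg$start) / e_bases))
  n_off <- round(n_on * config$off_target_fraction /
                   max(1e-12, 1 - config$off_target_fraction))
  if (config$off_target_fraction >= 1) stop("off_target_fraction must be < 1")
  n_frag <- n_on + n_off
  glen <- vapply(parents[[1L]], nchar, integer(1))
  nr <- n_frag * 2L
  r_id <- character(nr); r_mate <- integer(nr); r_contig <- character(nr)
  r_start <- integer(nr); r_end <- integer(nr); r_bs <- character(nr)
  r_orient <- character(nr); r_seq <- character(nr)
  origins <- character(n_frag)
  f_id <- character(n_frag); f_contig <- character(n_frag)
  f_start <- integer(n_frag); f_end <- integer(n_frag)
  f_bs <- character(n_frag)
  parent_names <- names(parents)
  for (i in seq_len(n_frag)) {
    flen <- sample(seq.int(fr[1], fr[2]), 1L)
    if (i <= n_on) {
      ti <- sample.int(nrow(tg), 1L, prob = tg$end - tg$start)
      cn <- tg$contig[ti]
      lo <- tg$start[ti]; hi <- tg$end[ti]
      if (hi - lo >= flen) {
        fs <- lo + sample.int(hi - lo - flen + 1L, 1L) - 1L
      } else {
        # short target: span it, staying inside the contig
        fs <- min(max(0L, hi - flen),
                  max(0L, min(lo, glen[[cn]] - flen)))
      }
    } else {
      cn <- sample(names(glen), 1L, prob = glen)
      fs <- sample.int(max(1L, glen[[cn]] - flen + 1L), 1L) - 1L
    }
    fe <- min(fs + flen, glen[[cn]])
    pn <- if (length(parents) > 1L) sample(parent_names, 1L) else parent_names
    origins[i] <- pn
    genome_p <- parents[[pn]]
    bs_strand <- sample(c("OT", "OB"), 1L)
    site_strand <- if (bs_strand == "OT") "+" else "-"
    frag <- chars(substr(genome_p[[cn]], fs + 1L, fe))
    allpos <- cpos[[pn]][[cn]][[site_strand]]
    inpos <- allpos[allpos >= fs & allpos < fe]
    if (length(inpos)) {
      keys <- paste(cn, inpos, site_strand)
      m <- mc_map[keys]; m[is.na(m)] <- 0
      h <- hmc_map[keys]; h[is.na(h)] <- 0
      u <- runif(length(inpos))
      is_h <- u < h
      is_m <- !is_h & u < h + m
      unconv_p <- if (mode == "bs") {
        ifelse(is_h | is_m, 1, 1 - eff)
      } else {
        ifelse(is_h, protection_rate,
               ifelse(is_m, 1 - mc_conversion_rate, 1 - eff))
      }
      converted <- runif(length(inpos)) >= unconv_p
      conv_to <- if (site_strand == "+") "T" else "A"
      frag[(inpos - fs + 1L)[converted]] <- conv_to
    }
    if (config$error_rate > 0) {
      hit <- which(runif(length(frag)) < config$error_rate)
      for (k in hit) frag[k] <- sample(setdiff(c("A", "C", "G", "T"), frag[k]), 1L)
    }
    fw <- fe - fs
    m1 <- c(0L, min(rl, fw))                    # leftmost mate interval
    m2 <- c(max(0L, fw - rl), fw)
    seq1 <- paste(frag[(m1[1] + 1L):m1[2]], collapse = "")
    seq2 <- paste(frag[(m2[1] + 1L):m2[2]], collapse = "")
    # OT fragments sequence mate 1 from the left end; OB from the right
    if (bs_strand == "OT") {
      o1 <- "+"; o2 <- "-"
    } else {
      o1 <- "-"; o2 <- "+"
      tmp <- seq1; seq1 <- seq2; seq2 <- tmp
      tmpi <- m1; m1 <- m2; m2 <- tmpi
    }
    id <- paste0(id_prefix, "_", i)
    j1 <- 2L * i - 1L; j2 <- 2L * i
    r_id[c(j1, j2)] <- id
    r_mate[j1] <- 1L; r_mate[j2] <- 2L
    r_contig[c(j1, j2)] <- cn
    r_start[j1] <- fs + m1[1]; r_end[j1] <- fs + m1[2]
    r_start[j2] <- fs + m2[1]; r_end[j2] <- fs + m2[2]
    r_bs[c(j1, j2)] <- bs_strand
    r_orient[j1] <- o1; r_orient[j2] <- o2
    r_seq[j1] <- seq1; r_seq[j2] <- seq2
    f_id[i] <- id; f_contig[i] <- cn; f_start[i] <- fs; f_end[i] <- fe
    f_bs[i] <- bs_strand
  }
  reads <- data.frame(read_id = r_id, mate = r_mate, contig = r_contig,
                      start = r_start, end = r_end, bs_strand = r_bs,
                      orient = r_orient, seq = r_seq, is_duplicate = FALSE,
                      stringsAsFactors = FALSE)
  frag_tab <- data.frame(read_id = f_id, contig = f_contig, start = f_start,
                         end = f_end, bs_strand = f_bs,
                         stringsAsFactors = FALSE)
  if (config$duplicate_fraction > 0) {
    n_dup <- round(config$duplicate_fraction * n_frag)
    if (n_dup > 0) {
      pick <- sample(frag_tab$read_id, n_dup, replace = n_dup > n_frag)
      dup_rows <- lapply(seq_along(pick), function(k) {
        rr <- reads[reads$read_id == pick[k], , drop = FALSE]
        rr$read_id <- paste0(rr$read_id, "_dup", k)
        rr
      })
      dup_reads <- do.call(rbind, dup_rows)
      origins <- c(origins, origins[match(pick, frag_tab$read_id)])
      names(origins) <- c(frag_tab$read_id, dup_reads$read_id[
        !duplicated(dup_reads$read_id)])
      reads <- rbind(reads, dup_reads)
    } else names(origins) <- frag_tab$read_id
  } else names(origins) <- frag_tab$read_id
  rownames(reads) <- NULL
  list(reads = reads,
       truth = list(read_origins = origins, fragments = frag_tab,
                    methylome = methylome))
}

#' Simulate paired-end bisulfite reads with known truth
#'
#' Draws fragments of 180-220 bp (target-weighted placement, optionally
#' with an off-target fraction spread over the whole genome), bisulfite
#' converts each strand-aware cytosine according to its true 5mC/5hmC level
#' and the conversion efficiency (unmethylated Cs fail to convert with
#' probability 1 - efficiency; methylated and hydroxymethylated Cs remain
#' C), and emits both 100 bp mates in reference-forward orientation with
#' true alignment coordinates. Fully deterministic under `config$seed`.
#'
#' @param parents A genome, or the list returned by [make_diploid()] (reads
#'   are drawn 50:50 from the two parents), or any named list of genomes.
#' @param methylome Truth table from [make_methylome()] (reference
#'   coordinates; sites absent from the table are unmethylated).
#' @param targets `GRanges` or BED-like data.frame.
#' @param config A [sim_config()].
#' @return List with `reads` (tabular read format) and `truth`
#'   (`read_origins`, `fragments`, `methylome`).
#' @export
simulate_bs_reads <- function(parents, methylome, targets,
                              config = sim_config()) {
  set.seed(config$seed)
  if (is.list(parents) && !is.null(parents$snp_table)) {
    parents <- parents[c("parent_a", "parent_b")]
  }
  simulate_reads_engine(parents, methylome, targets, config, mode = "bs")
}

#' Simulate TAB-seq reads with spike-in controls
#'
#' As [simulate_bs_reads()] but under TAB-seq chemistry: 5hmC sites stay
#' unconverted with probability `protection_rate`, 5mC sites convert with
#' probability `mc_conversion_rate` (Tet oxidation removes their
#' protection), unmodified Cs convert with the configured efficiency. When
#' `include_spikeins` is set, three control contigs of known state
#' (unmethylated, fully 5mC, fully 5hmC) are appended to the genome and
#' sequenced alongside, for use with [spikein_efficiency()].
#'
#' @inheritParams simulate_bs_reads
#' @param protection_rate 5hmC protection probability (default 0.98).
#' @param mc_conversion_rate 5mC conversion probability under TAB-seq
#'   (default 0.995).
#' @param include_spikeins Append spike-in control contigs (default
#'   `TRUE`).
#' @param spikein_length Control contig length (default 1000).
#' @return List with `reads`, `truth` and `spike_contigs`.
#' @export
simulate_tab_reads <- function(parents, methylome, targets,
                               config = sim_config(),
                               protection_rate = 0.98,
                               mc_conversion_rate = 0.995,
                               include_spikeins = TRUE,
                               spikein_length = 1000L) {
  set.seed(config$seed)
  if (is.list(parents) && !is.null(parents$snp_table)) {
    parents <- parents[c("parent_a", "parent_b")]
  }
  if (is.character(parents)) parents <- list(parent_a = parents)
  parents <- lapply(parents, validate_genome)
  methylome <- as.data.frame(methylome)
  if (is.null(methylome$hmc)) methylome$hmc <- 0
  tg <- as_bed_df(targets)
  spikes <- character(0)
  if (include_spikeins) {
    spikes <- c("spike_C", "spike_mC", "spike_hmC")
    for (sn in spikes) {
      sq <- random_seq(spikein_length, 0.5)
      for (pn in names(parents)) parents[[pn]][[sn]] <- sq
      sites <- as.data.frame(cytosine_sites(stats::setNames(sq, sn)))
      sites$mc <- if (sn == "spike_mC") 1 else 0
      sites$hmc <- if (sn == "spike_hmC") 1 else 0
      methylome <- rbind(methylome,
                         sites[, c("contig", "pos", "strand", "context",
                                   "mc", "hmc")])
      tg <- rbind(tg, data.frame(contig = sn, start = 0L,
                                 end = spikein_length))
    }
  }
  out <- simulate_reads_engine(parents, methylome, tg, config, mode = "tab",
                               protection_rate = protection_rate,
                               mc_conversion_rate = mc_conversion_rate,
                               id_prefix = "tab")
  out$spike_contigs <- spikes
  out$genome <- parents[[1L]]   # parent A with spike contigs appended
  out
}
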