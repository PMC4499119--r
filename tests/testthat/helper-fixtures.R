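# deterministic fixtures shared across the suite

# small genome with a control contig, fixed seed
fixture_genome <- function(len = 6000L, control = 2000L, seed = 42L) {
  make_genome(sim_config(genome_length = len, control_length = control,
                         seed = seed))
}

# one-row region summary in the shape summarize_regions() produces
region_summary <- function(cg, chg, chh, coverage, genotype = "g") {
  data.frame(contig = "chr1", start = 0L, end = 1000L, genotype = genotype,
             level_CG = cg, level_CHG = chg, level_CHH = chh,
             coverage_fraction = coverage, n_sites = 100L,
             stringsAsFactors = FALSE)
}

# hand-built aligned read row(s) in the tabular dialect
mk_read <- function(read_id, contig, start, seq, mate = 1L,
                    bs_strand = "OT", orient = "+") {
  data.frame(read_id = read_id, mate = mate, contig = contig,
             start = start, end = start + nchar(seq), bs_strand = bs_strand,
             orient = orient, seq = seq, is_duplicate = FALSE,
             stringsAsFactors = FALSE)
}

# independent brute-force enumeration of conversion alleles: every subset
# of cytosine positions stays C, the rest become T
oracle_alleles <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  cpos <- which(b == "C")
  n <- length(cpos)
  if (n == 0) return(paste(b, collapse = ""))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  apply(grid, 1, function(keep) {
    bb <- b
    bb[cpos[!unlist(keep)]] <- "T"
    paste(bb, collapse = "")
  })
}

# independent brute-force k-mer count of both fully converted strands
oracle_kmer_counts <- function(genome, k = 15L) {
  revcomp_chr <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  km <- character()
  for (s in genome) {
    for (str in c(s, revcomp_chr(s))) {
      conv <- gsub("C", "T", str, fixed = TRUE)
      L <- nchar(conv)
      if (L < k) next
      kk <- substring(conv, 1:(L - k + 1), k:L)
      km <- c(km, kk[!grepl("N", kk)])
    }
  }
  table(km)
}

# independent sliding-window bisulfite-compatible match count: probe base
# must equal the genome base, except probe T may cover genome C; both
# orientations of every contig are scanned
oracle_mapping_count <- function(probe, genome) {
  revcomp_chr <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  pb <- strsplit(probe, "")[[1]]
  n <- 0L
  for (s in genome) {
    for (subject in c(s, revcomp_chr(s))) {
      sb <- strsplit(subject, "")[[1]]
      L <- length(sb); w <- length(pb)
      for (i in seq_len(max(0L, L - w + 1L))) {
        win <- sb[i:(i + w - 1L)]
        ok <- all(pb == win | (pb == "T" & win == "C"))
        if (ok) n <- n + 1L
      }
    }
  }
  n
}
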