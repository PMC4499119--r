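#' Filter de novo SNP candidates
#'
#' Retains candidates with quality at least `min_quality` and coverage at
#' most `max_coverage`, then removes SNPs lying within `proximity` bp of
#' another retained SNP on the same contig (both members of a close pair
#' are dropped; the distance test is inclusive). Removal counts per reason
#' are attached as attribute `"removed"`.
#'
#' @param candidates SNP data.frame (`contig`, `pos`, `allele_a`,
#'   `allele_b`, `quality`, `coverage`), position-sorted.
#' @param min_quality Minimum phred-like quality (default 20).
#' @param max_coverage Maximum read depth (default 120).
#' @param proximity Minimum distance to the nearest other SNP in bp
#'   (default 20; distance <= proximity removes both).
#' @return Retained SNP records.
#' @export
filter_de_novo_snps <- function(candidates, min_quality = 20,
                                max_coverage = 120, proximity = 20L) {
  candidates <- as.data.frame(candidates)
  qc_pass <- candidates$quality >= min_quality &
    candidates$coverage <= max_coverage
  kept <- candidates[qc_pass, , drop = FALSE]
  kept <- kept[order(kept$contig, kept$pos), , drop = FALSE]
  close <- logical(nrow(kept))
  if (nrow(kept) > 1L) {
    same <- kept$contig[-1L] == kept$contig[-nrow(kept)]
    d <- kept$pos[-1L] - kept$pos[-nrow(kept)]
    near <- same & d <= proximity
    close[-nrow(kept)] <- near                 # first member of a close pair
    close[-1L] <- close[-1L] | near            # second member
  }
  out <- kept[!close, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(quality_coverage = sum(!qc_pass),
                            proximity = sum(close))
  out
}

#' Intersect a catalog SNP list with de novo calls
#'
#' Keeps only positions present in both lists with consistent alleles
#' (order-insensitive pair equality); positions with conflicting alleles
#' are excluded with a warning. The consensus records carry the catalog's
#' allele orientation and `source = "both"`.
#'
#' @param catalog,de_novo SNP data.frames on the same coordinate system.
#' @return Consensus SNP records.
#' @export
intersect_snp_lists <- function(catalog, de_novo) {
  catalog <- as.data.frame(catalog); de_novo <- as.data.frame(de_novo)
  key <- function(d) paste(d$contig, d$pos, sep = ":")
  kc <- key(catalog); kd <- key(de_novo)
  common <- intersect(kc, kd)
  ic <- match(common, kc); id <- match(common, kd)
  pair <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ok <- pair(catalog$allele_a[ic], catalog$allele_b[ic]) ==
    pair(de_novo$allele_a[id], de_novo$allele_b[id])
  if (any(!ok)) {
    warning(sum(!ok), " shared position(s) with conflicting alleles excluded")
  }
  out <- catalog[ic[ok], , drop = FALSE]
  out$quality <- de_novo$quality[id[ok]]
  out$coverage <- de_novo$coverage[id[ok]]
  out$source <- "both"
  rownames(out) <- NULL
  out
}

# converted readout set of an allele on a bisulfite strand, in
# reference-forward coordinates: OT reads show C as C-or-T, OB reads show
# G as G-or-A; all other alleles read as themselves
allele_readouts <- function(allele, bs_strand) {
  if (bs_strand == "OT" && allele == "C") return(c("C", "T"))
  if (bs_strand == "OB" && allele == "G") return(c("G", "A"))
  allele
}

#' Is a SNP informative on a bisulfite strand?
#'
#' A SNP stays informative after bisulfite conversion if its two alleles
#' have disjoint converted readouts on that strand: on OT (C-converted)
#' reads a C/T SNP collapses, on OB (G-converted) reads a G/A SNP
#' collapses; every other allele pair remains distinguishable.
#'
#' @param allele_a,allele_b Allele base vectors.
#' @param bs_strand `"OT"` or `"OB"` (scalar or vector).
#' @return Logical vector.
#' @export
bisulfite_informative <- function(allele_a, allele_b, bs_strand) {
  n <- max(length(allele_a), length(allele_b), length(bs_strand))
  allele_a <- rep_len(toupper(allele_a), n)
  allele_b <- rep_len(toupper(allele_b), n)
  bs_strand <- rep_len(bs_strand, n)
  pair <- paste(pmin(allele_a, allele_b), pmax(allele_a, allele_b))
  !((bs_strand == "OT" & pair == "C T") |
      (bs_strand == "OB" & pair == "A G"))
}

#' Assign reads to a parental origin from the SNPs they carry
#'
#' For each read, the consensus SNPs inside the aligned interval that are
#' informative on the read's bisulfite strand are scored: the read base at
#' the SNP supports parent A if it matches parent A's converted readout and
#' parent B likewise (informative SNPs cannot match both; a base matching
#' neither, e.g. a sequencing error, is excluded). A read with no usable
#' SNPs is `no_info`; with one SNP it takes that parent; with several it is
#' assigned only if strictly more than `threshold` of its SNPs agree,
#' otherwise `ambiguous`.
#'
#' @param reads Read data.frame.
#' @param snps Consensus SNP data.frame (`allele_a` = parent A).
#' @param threshold Support fraction that must be exceeded (default 0.6).
#' @return `data.frame`: `read_id`, `mate`, `verdict`, `n_snps`,
#'   `support_fraction`, `via_mate`.
#' @export
assign_read <- function(reads, snps, threshold = 0.60) {
  reads <- as.data.frame(reads); snps <- as.data.frame(snps)
  n <- nrow(reads)
  verdict <- character(n); n_snps <- integer(n); support <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    in_read <- snps[snps$contig == reads$contig[i] &
                      snps$pos >= reads$start[i] &
                      snps$pos < reads$end[i], , drop = FALSE]
    bsd <- reads$bs_strand[i]
    if (nrow(in_read)) {
      in_read <- in_read[bisulfite_informative(in_read$allele_a,
                                               in_read$allele_b, bsd), ,
                         drop = FALSE]
    }
    a_votes <- 0L; b_votes <- 0L
    for (j in seq_len(nrow(in_read))) {
      base <- substr(reads$seq[i], in_read$pos[j] - reads$start[i] + 1L,
                     in_read$pos[j] - reads$start[i] + 1L)
      in_a <- base %in% allele_readouts(in_read$allele_a[j], bsd)
      in_b <- base %in% allele_readouts(in_read$allele_b[j], bsd)
      if (in_a && !in_b) a_votes <- a_votes + 1L
      if (in_b && !in_a) b_votes <- b_votes + 1L
    }
    tot <- a_votes + b_votes
    n_snps[i] <- tot
    if (tot == 0L) {
      verdict[i] <- "no_info"
    } else if (tot == 1L) {
      verdict[i] <- if (a_votes == 1L) "parent_a" else "parent_b"
      support[i] <- 1
    } else {
      frac <- max(a_votes, b_votes) / tot
      support[i] <- frac
      verdict[i] <- if (frac > threshold) {
        if (a_votes > b_votes) "parent_a" else "parent_b"
      } else "ambiguous"
    }
  }
  data.frame(read_id = reads$read_id, mate = reads$mate, verdict = verdict,
             n_snps = n_snps, support_fraction = support, via_mate = FALSE,
             stringsAsFactors = FALSE)
}

#' Rescue SNP-free reads via their mate's assignment
#'
#' A `no_info` read whose mate carries a parental verdict adopts it (with
#' `via_mate = TRUE`); ambiguous mates do not propagate. Mates with
#' conflicting parental verdicts are both downgraded to `ambiguous`.
#'
#' @param assignments Output of [assign_read()].
#' @return Updated assignment table.
#' @export
rescue_via_mate <- function(assignments) {
  a <- as.data.frame(assignments)
  parental <- c("parent_a", "parent_b")
  for (id in unique(a$read_id[duplicated(a$read_id)])) {
    idx <- which(a$read_id == id)
    v <- a$verdict[idx]
    pv <- unique(v[v %in% parental])
    if (length(pv) > 1L) {
      a$verdict[idx] <- "ambiguous"
      next
    }
    if (length(pv) == 1L) {
      fix <- idx[v == "no_info"]
      a$verdict[fix] <- pv
      a$via_mate[fix] <- TRUE
    }
  }
  a
}

#' Per-parent methylation calling for a hybrid sample
#'
#' Splits reads by resolved parental assignment, calls methylation
#' separately for each parent, and (when targets are supplied) summarizes
#' per-region, per-context levels for both parents with per-region
#' difference columns. Regions where a parent contributed no reads are
#' flagged `insufficient`.
#'
#' @param reads Read data.frame.
#' @param assignments Resolved assignment table (after
#'   [rescue_via_mate()]).
#' @param genome Named character vector of contigs.
#' @param targets Optional `GRanges`/BED-like regions to summarize.
#' @param ... Passed to [call_methylation()].
#' @return List with `parent_a`, `parent_b` call tables and, if targets
#'   were given, a `regions` comparison table.
#' @export
allelic_methylation <- function(reads, assignments, genome, targets = NULL,
                                ...) {
  reads <- as.data.frame(reads)
  key <- paste(reads$read_id, reads$mate)
  akey <- paste(assignments$read_id, assignments$mate)
  verdict <- assignments$verdict[match(key, akey)]
  out <- list()
  calls <- list()
  for (p in c("parent_a", "parent_b")) {
    sub <- reads[!is.na(verdict) & verdict == p, , drop = FALSE]
    calls[[p]] <- if (nrow(sub)) call_methylation(sub, genome, ...) else
      call_methylation(reads[0, , drop = FALSE], genome, ...)
  }
  out$parent_a <- calls$parent_a
  out$parent_b <- calls$parent_b
  if (!is.null(targets)) {
    sa <- summarize_regions(calls$parent_a, targets, genome,
                            genotype = "parent_a")
    sb <- summarize_regions(calls$parent_b, targets, genome,
                            genotype = "parent_b")
    reg <- merge(sa, sb, by = c("contig", "start", "end"),
                 suffixes = c("_a", "_b"))
    for (ctx in c("CG", "CHG", "CHH")) {
      reg[[paste0("diff_", ctx)]] <-
        reg[[paste0("level_", ctx, "_a")]] - reg[[paste0("level_", ctx, "_b")]]
    }
    reg$insufficient <- reg$n_sites_a == 0L | reg$n_sites_b == 0L
    out$regions <- reg
  }
  out
}
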