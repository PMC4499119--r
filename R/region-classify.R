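#' Summarize per-cytosine calls into per-region, per-context levels
#'
#' Region-level methylation is count-weighted: for each region and context,
#' level = sum(methylated) / sum(methylated + unmethylated) over the
#' region's sites. `coverage_fraction` is the fraction of the region's
#' context cytosines (from the reference) observed with at least one read.
#'
#' @param calls Call data.frame from [call_methylation()].
#' @param targets `GRanges` or BED-like data.frame.
#' @param genome Named character vector of contigs (for the denominator of
#'   `coverage_fraction`).
#' @param genotype Label stored in the `genotype` column.
#' @return `data.frame` with one row per region: `contig`, `start`, `end`,
#'   `genotype`, `level_CG`, `level_CHG`, `level_CHH`, `coverage_fraction`,
#'   per-context coverage fractions and `n_sites`.
#' @export
summarize_regions <- function(calls, targets, genome, genotype = "sample") {
  genome <- validate_genome(genome)
  tg <- as_bed_df(targets)
  calls <- as.data.frame(calls)
  sites <- cytosine_sites(genome, contigs = unique(tg$contig))
  out <- vector("list", nrow(tg))
  for (i in seq_len(nrow(tg))) {
    in_reg <- function(d) d$contig == tg$contig[i] & d$pos >= tg$start[i] &
      d$pos < tg$end[i]
    rs <- sites[in_reg(sites), ]
    rc <- calls[in_reg(calls), , drop = FALSE]
    row <- data.frame(contig = tg$contig[i], start = tg$start[i],
                      end = tg$end[i], genotype = genotype,
                      stringsAsFactors = FALSE)
    n_possible <- 0L; n_covered <- 0L
    for (ctx in c("CG", "CHG", "CHH")) {
      tot_sites <- sum(rs$context == ctx)
      cc <- rc[rc$context == ctx, , drop = FALSE]
      m <- sum(cc$methylated); u <- sum(cc$unmethylated)
      row[[paste0("level_", ctx)]] <- if (m + u > 0) m / (m + u) else NA_real_
      row[[paste0("coverage_", ctx)]] <-
        if (tot_sites > 0) nrow(cc) / tot_sites else NA_real_
      n_possible <- n_possible + tot_sites
      n_covered <- n_covered + nrow(cc)
    }
    row$coverage_fraction <- if (n_possible > 0) n_covered / n_possible else
      NA_real_
    row$n_sites <- nrow(rc)
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Default region-classification parameters
#'
#' The thresholds of the two-genotype region taxonomy: `all_high` requires
#' the summed methylation level over three contexts and two genotypes to be
#' at least `sum_high` (4.2 on the 0-6 scale) with coverage at least
#' `cov_high` in both genotypes; `all_low` requires every context level
#' below `low_level` in both genotypes at coverage at least `cov_low`;
#' context-dependent classes require the focal context above its threshold
#' (CG > 0.95, CHG > 0.2, CHH > 0.75) in both genotypes, the other contexts
#' below `cd_other` (0.2), and coverage at least `cov_cd`; DMR typing uses
#' `dmr_min_difference`.
#'
#' @return Named list of parameters.
#' @export
region_class_params <- function() {
  list(
    sum_high = 4.2, cov_high = 0.85,
    low_level = 0.05, cov_low = 0.90,
    cd_thresholds = c(CG = 0.95, CHG = 0.2, CHH = 0.75),
    cd_other = 0.2, cov_cd = 0.80,
    dmr_min_difference = 0.4,
    # numeric slack for inclusive comparisons on floating-point sums
    eps = 1e-9
  )
}

#' Context-wise differential methylation call between two genotypes
#'
#' A region is a DMR in context X when the absolute difference of the two
#' genotypes' levels in X is at least `min_difference`. Several contexts
#' may qualify simultaneously.
#'
#' @param summary_a,summary_b One-row region summaries of the same region.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_difference Minimum absolute level difference (default 0.4).
#' @return Logical scalar.
#' @export
call_dmr <- function(summary_a, summary_b, context,
                     min_difference = 0.4) {
  la <- summary_a[[paste0("level_", context)]]
  lb <- summary_b[[paste0("level_", context)]]
  if (is.na(la) || is.na(lb)) return(FALSE)
  abs(la - lb) >= min_difference
}

#' Classify a target region from two genotypes' methylation summaries
#'
#' Applies the region taxonomy: `all_high` (summed level over CG+CHG+CHH in
#' both genotypes at least 4.2, coverage >= 0.85 in both), `all_low` (every
#' context effectively unmethylated in both, coverage >= 0.90),
#' `context_dependent_{CG,CHG,CHH}` (focal context above its threshold in
#' both genotypes, other contexts < 0.2 in both, coverage >= 0.80), then
#' DMR typing per context (labels may co-occur), else `unclassified`.
#' Inequalities are applied exactly as stated: "at least" thresholds are
#' inclusive, context thresholds strict.
#'
#' @param summary_a,summary_b One-row region summaries (see
#'   [summarize_regions()]) for the same region.
#' @param params Parameter list (see [region_class_params()]).
#' @return List of class `region_class` with `label` (character vector; a
#'   single class label or one or more DMR labels) and `supporting_values`.
#' @export
classify_region <- function(summary_a, summary_b,
                            params = region_class_params()) {
  lv <- function(s, ctx) s[[paste0("level_", ctx)]]
  ctxs <- c("CG", "CHG", "CHH")
  la <- vapply(ctxs, function(c) lv(summary_a, c), numeric(1))
  lb <- vapply(ctxs, function(c) lv(summary_b, c), numeric(1))
  if (anyNA(la) || anyNA(lb)) {
    stop("classification error: missing context level", call. = FALSE)
  }
  cov_a <- summary_a$coverage_fraction; cov_b <- summary_b$coverage_fraction
  total <- sum(la) + sum(lb)
  sup <- list(levels_a = la, levels_b = lb, sum = total,
              coverage_a = cov_a, coverage_b = cov_b)
  res <- function(label) structure(list(label = label,
                                        supporting_values = sup),
                                   class = "region_class")
  eps <- if (is.null(params$eps)) 0 else params$eps
  if (total >= params$sum_high - eps && cov_a >= params$cov_high &&
      cov_b >= params$cov_high) {
    return(res("all_high"))
  }
  if (all(la < params$low_level) && all(lb < params$low_level) &&
      cov_a >= params$cov_low && cov_b >= params$cov_low) {
    return(res("all_low"))
  }
  if (cov_a >= params$cov_cd && cov_b >= params$cov_cd) {
    for (ctx in ctxs) {
      thr <- params$cd_thresholds[[ctx]]
      others <- setdiff(ctxs, ctx)
      if (la[[ctx]] > thr && lb[[ctx]] > thr &&
          all(la[others] < params$cd_other) &&
          all(lb[others] < params$cd_other)) {
        return(res(paste0("context_dependent_", ctx)))
      }
    }
  }
  dmr <- ctxs[vapply(ctxs, function(ctx)
    call_dmr(summary_a, summary_b, ctx,
             min_difference = params$dmr_min_difference), logical(1))]
  if (length(dmr)) return(res(paste0("dmr_", dmr)))
  res("unclassified")
}

#' @export
print.region_class <- function(x, ...) {
  cat("region_class:", paste(x$label, collapse = " + "), "\n")
  invisible(x)
}

#' Classify a table of regions for two genotypes
#'
#' Vectorized wrapper over [classify_region()]; multi-label DMR results are
#' joined with `";"`.
#'
#' @param summaries_a,summaries_b Region summary tables, row-aligned on the
#'   same regions.
#' @param params Parameter list.
#' @return `data.frame` of regions with a `label` column.
#' @export
classify_regions <- function(summaries_a, summaries_b,
                             params = region_class_params()) {
  a <- as.data.frame(summaries_a); b <- as.data.frame(summaries_b)
  stopifnot(nrow(a) == nrow(b))
  lab <- vapply(seq_len(nrow(a)), function(i) {
    paste(classify_region(a[i, , drop = FALSE], b[i, , drop = FALSE],
                          params)$label, collapse = ";")
  }, character(1))
  out <- a[, intersect(c("contig", "start", "end"), names(a)), drop = FALSE]
  for (ctx in c("CG", "CHG", "CHH")) {
    out[[paste0("level_", ctx, "_a")]] <- a[[paste0("level_", ctx)]]
    out[[paste0("level_", ctx, "_b")]] <- b[[paste0("level_", ctx)]]
  }
  out$coverage_a <- a$coverage_fraction
  out$coverage_b <- b$coverage_fraction
  out$label <- lab
  out
}

#' Concordance of methylation differences between two platforms
#'
#' Pairs the per-region methylation differences measured by two platforms
#' (e.g. whole-genome and capture bisulfite sequencing) over a DMR list and
#' reports their Pearson correlation and mean absolute deviation.
#'
#' @param wgbs_differences,capture_differences Named numeric vectors (names
#'   are region identifiers) or data.frames with `region` and `difference`.
#' @param dmr_list Optional character vector of region identifiers to
#'   restrict to.
#' @return List with `correlation`, `mean_abs_dev`, `n` and the paired
#'   table.
#' @export
compare_platforms <- function(wgbs_differences, capture_differences,
                              dmr_list = NULL) {
  vecify <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$difference, x$region) else x
  }
  w <- vecify(wgbs_differences); cp <- vecify(capture_differences)
  common <- intersect(names(w), names(cp))
  if (!is.null(dmr_list)) common <- intersect(common, dmr_list)
  if (length(common) == 0L) {
    stop("no common regions between the two platforms", call. = FALSE)
  }
  pw <- w[common]; pc <- cp[common]
  list(
    correlation = stats::cor(pw, pc),
    mean_abs_dev = mean(abs(pw - pc)),
    n = length(common),
    pairs = data.frame(region = common, wgbs = unname(pw),
                       capture = unname(pc), stringsAsFactors = FALSE)
  )
}
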