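#' Quantify 5hmC and 5mC from paired TAB-seq and bisulfite calls
#'
#' TAB-seq protects 5hmC while removing the 5mC signal, so the unconverted
#' fraction of a TAB-seq library estimates the 5hmC level directly, and the
#' 5mC level follows by subtracting it from the (5mC + 5hmC) unconverted
#' fraction of standard bisulfite sequencing. Only sites inside the capture
#' targets with TAB coverage of at least `min_coverage` are reported;
#' negative 5mC estimates (sampling noise) are clamped to 0 and flagged. A
#' site covered in TAB-seq but absent (or under-covered) in the bisulfite
#' data keeps its 5hmC estimate with an undefined (`NA`) 5mC.
#'
#' @param tab_calls,bs_calls Call tables with `contig`, `pos`, `strand`,
#'   `methylated` (unconverted count) and `unmethylated` (converted count),
#'   as produced by [call_methylation()].
#' @param targets `GRanges` or BED-like data.frame.
#' @param min_coverage Minimum TAB-seq depth per reported site (default 10).
#' @param min_coverage_bs Minimum bisulfite depth for the 5mC estimate
#'   (default: same as `min_coverage`).
#' @param contexts Contexts analyzed (default `"CG"`).
#' @return `data.frame`: site columns plus `tab_unconverted`,
#'   `bs_unconverted`, `hmc_level`, `mc_level`, `coverage_tab`,
#'   `coverage_bs`, `clamped`.
#' @export
hmc_quantify <- function(tab_calls, bs_calls, targets, min_coverage = 10L,
                         min_coverage_bs = min_coverage,
                         contexts = "CG") {
  tab <- as.data.frame(tab_calls); bs <- as.data.frame(bs_calls)
  if (!is.null(contexts) && "context" %in% names(tab)) {
    tab <- tab[tab$context %in% contexts, , drop = FALSE]
  }
  tg <- as_bed_df(targets)
  in_targets <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(tg))) {
    in_targets <- in_targets | (tab$contig == tg$contig[i] &
                                  tab$pos >= tg$start[i] &
                                  tab$pos < tg$end[i])
  }
  tab <- tab[in_targets, , drop = FALSE]
  cov_tab <- tab$methylated + tab$unmethylated
  keep <- cov_tab >= min_coverage
  tab <- tab[keep, , drop = FALSE]
  cov_tab <- cov_tab[keep]
  key <- function(d) paste(d$contig, d$pos, d$strand, sep = ":")
  ib <- match(key(tab), key(bs))
  cov_bs <- ifelse(is.na(ib), 0L, bs$methylated[ib] + bs$unmethylated[ib])
  bs_frac <- ifelse(!is.na(ib) & cov_bs >= min_coverage_bs,
                    bs$methylated[ib] / cov_bs, NA_real_)
  tab_frac <- tab$methylated / cov_tab
  mc_raw <- bs_frac - tab_frac
  out <- data.frame(
    contig = tab$contig, pos = tab$pos, strand = tab$strand,
    context = if ("context" %in% names(tab)) tab$context else NA_character_,
    tab_unconverted = tab_frac, bs_unconverted = bs_frac,
    hmc_level = tab_frac,
    mc_level = pmax(mc_raw, 0),
    coverage_tab = cov_tab, coverage_bs = cov_bs,
    clamped = !is.na(mc_raw) & mc_raw < 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Conversion and protection efficiencies from spike-in controls
#'
#' From TAB-seq (or bisulfite) calls on the three spike-in control contigs:
#' the unmethylated control yields the conversion rate, the 5mC control the
#' combined oxidation-plus-conversion rate, and the 5hmC control the
#' protection rate (fraction remaining unconverted).
#'
#' @param calls Call table covering the control contigs.
#' @param controls Named character vector mapping control class to contig
#'   name; names must include `unmethylated`, `mC`, `hmC`.
#' @return Named list: `conversion_rate`, `mC_conversion_rate`,
#'   `hmC_protection_rate`, all in `[0, 1]`.
#' @export
spikein_efficiency <- function(calls,
                               controls = c(unmethylated = "spike_C",
                                            mC = "spike_mC",
                                            hmC = "spike_hmC")) {
  calls <- as.data.frame(calls)
  need <- c("unmethylated", "mC", "hmC")
  if (!all(need %in% names(controls))) {
    stop("controls must name the unmethylated, mC and hmC contigs",
         call. = FALSE)
  }
  rate <- function(contig, converted_of) {
    sub <- calls[calls$contig == contig, , drop = FALSE]
    tot <- sum(sub$methylated) + sum(sub$unmethylated)
    if (nrow(sub) == 0L || tot == 0L) {
      stop("control contig ", contig, " missing or uncovered", call. = FALSE)
    }
    sum(sub[[converted_of]]) / tot
  }
  list(
    conversion_rate = rate(controls[["unmethylated"]], "unmethylated"),
    mC_conversion_rate = rate(controls[["mC"]], "unmethylated"),
    hmC_protection_rate = rate(controls[["hmC"]], "methylated")
  )
}
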