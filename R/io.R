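# single conversion layer between file conventions and internal coordinates:
# BED and the internal representation are 0-based half-open; VCF-like SNP
# tables are 1-based on disk and converted here, nowhere else.

# normalize targets to a BED-like data.frame (contig, start, end; 0-based
# half-open); accepts GRanges or data.frame
as_bed_df <- function(x) {
  if (methods::is(x, "GRanges")) {
    return(data.frame(
      contig = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x) - 1L,
      end = GenomicRanges::end(x),
      stringsAsFactors = FALSE
    ))
  }
  x <- as.data.frame(x)
  if (!all(c("contig", "start", "end") %in% names(x))) {
    stop("targets need contig/start/end columns or a GRanges", call. = FALSE)
  }
  if (any(x$start >= x$end)) stop("empty or inverted interval", call. = FALSE)
  x[, c("contig", "start", "end"), drop = FALSE]
}

# BED df -> GRanges (1-based closed internally to GRanges)
bed_to_granges <- function(bed) {
  bed <- as_bed_df(bed)
  GenomicRanges::GRanges(bed$contig,
                         IRanges::IRanges(bed$start + 1L, bed$end))
}

#' Read a BED file of intervals
#'
#' Parses a 3+ column BED file (0-based half-open) with validation; a
#' malformed line raises an error naming the line number.
#'
#' @param path BED file path.
#' @return `data.frame` with `contig`, `start`, `end` (plus `name` if a
#'   4th column is present), 0-based half-open.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lnum <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop("BED parse error at line ", lnum[i], ": fewer than 3 columns",
           call. = FALSE)
    }
    st <- suppressWarnings(as.integer(f[2])); en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en)) {
      stop("BED parse error at line ", lnum[i], ": non-integer coordinates",
           call. = FALSE)
    }
    if (st >= en) {
      stop("BED parse error at line ", lnum[i], ": empty interval (start >= end)",
           call. = FALSE)
    }
    data.frame(contig = f[1], start = st, end = en,
               name = if (length(f) >= 4L) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE)
  }
  if (all(is.na(out$name))) out$name <- NULL
  out
}

#' Write intervals to a BED file
#'
#' @param intervals BED-like data.frame or `GRanges`; optional `name` and
#'   `score` columns become BED columns 4-5.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  df <- as.data.frame(intervals)
  if (methods::is(intervals, "GRanges")) df <- as_bed_df(intervals)
  cols <- list(df$contig, df$start, df$end)
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
    if (!is.null(df$score)) cols <- c(cols, list(df$score))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF-like SNP table
#'
#' Tab-separated columns CHROM, POS (1-based), REF, ALT, QUAL, DP with a
#' header line. Positions are converted to the internal 0-based convention;
#' REF maps to `allele_a` (reference parent) and ALT to `allele_b`.
#'
#' @param path File path.
#' @param source Source label stored on each record (default `"de_novo"`).
#' @return `data.frame`: `contig`, `pos` (0-based), `allele_a`, `allele_b`,
#'   `quality`, `coverage`, `source`.
#' @export
read_snp_table <- function(path, source = "de_novo") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("CHROM", "POS", "REF", "ALT", "QUAL", "DP")
  if (!all(need %in% names(df))) {
    stop("SNP table schema error: expected columns ",
         paste(need, collapse = " "), call. = FALSE)
  }
  data.frame(contig = as.character(df$CHROM), pos = as.integer(df$POS) - 1L,
             allele_a = toupper(df$REF), allele_b = toupper(df$ALT),
             quality = as.numeric(df$QUAL), coverage = as.integer(df$DP),
             source = source, stringsAsFactors = FALSE)
}

#' Write a SNP table in the VCF-like dialect
#'
#' @param snps Internal SNP data.frame (0-based `pos`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_table <- function(snps, path) {
  out <- data.frame(CHROM = snps$contig, POS = snps$pos + 1L,
                    REF = snps$allele_a, ALT = snps$allele_b,
                    QUAL = snps$quality, DP = snps$coverage)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned bisulfite reads from the tabular read format
#'
#' The SAM-like dialect used throughout the package: tab-separated with a
#' header, columns `read_id`, `mate` (1/2), `contig`, `start` (0-based),
#' `end` (half-open), `bs_strand` (OT/OB), `orient` (+/-; where the read's
#' 5' end sits in reference coordinates), `seq` (reference-forward
#' orientation), `is_duplicate` (0/1).
#'
#' @param path File path.
#' @return `data.frame` of reads.
#' @export
read_reads <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("read_id", "mate", "contig", "start", "end", "bs_strand",
            "orient", "seq")
  if (!all(need %in% names(df))) {
    stop("read table schema error: expected columns ",
         paste(need, collapse = " "), call. = FALSE)
  }
  if (is.null(df$is_duplicate)) df$is_duplicate <- 0L
  df$is_duplicate <- as.logical(df$is_duplicate)
  df
}

#' Write aligned reads in the tabular read format
#'
#' @param reads Read data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reads <- function(reads, path) {
  reads$is_duplicate <- as.integer(isTRUE_vec(reads$is_duplicate))
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & as.logical(x)

#' Read a per-cytosine methylation call table
#'
#' Tab-separated with header: `contig`, `pos` (0-based), `strand`,
#' `context`, `methylated`, `unmethylated`. The `level` column is recomputed
#' on read; sites with zero total coverage get `NA` (missing), never 0.
#'
#' @param path File path.
#' @return `data.frame` of calls with a `level` column.
#' @export
read_call_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("contig", "pos", "strand", "context", "methylated", "unmethylated")
  if (!all(need %in% names(df))) {
    stop("call table schema error: expected columns ",
         paste(need, collapse = " "), call. = FALSE)
  }
  tot <- df$methylated + df$unmethylated
  df$level <- ifelse(tot > 0, df$methylated / tot, NA_real_)
  df
}

#' Write a methylation call table
#'
#' @param calls Call data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_call_table <- function(calls, path) {
  cols <- c("contig", "pos", "strand", "context", "methylated", "unmethylated",
            "level")
  utils::write.table(as.data.frame(calls)[, intersect(cols, names(calls))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write methylation levels as bedGraph tracks
#'
#' One bedGraph file per requested context; sites without coverage are
#' omitted (a missing level is never written as 0).
#'
#' @param calls Call data.frame with `level`.
#' @param path Output path; when several contexts are written, the context
#'   is inserted before the file extension.
#' @param contexts Contexts to write (default: those present).
#' @return Invisibly, the written paths.
#' @export
write_bedgraph <- function(calls, path, contexts = NULL) {
  calls <- as.data.frame(calls)
  if (is.null(contexts)) contexts <- unique(calls$context)
  paths <- character()
  for (ctx in contexts) {
    sub <- calls[calls$context == ctx & !is.na(calls$level), , drop = FALSE]
    p <- if (length(contexts) == 1L) path else
      sub("(\\.[^.]+)?$", paste0(".", ctx, "\\1"), path)
    lines <- sprintf("%s\t%d\t%d\t%.6g", sub$contig, sub$pos, sub$pos + 1L,
                     sub$level)
    writeLines(c(sprintf("track type=bedGraph name=%s", ctx), lines), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a key-value metrics report
#'
#' Deterministic two-column TSV (metric, value); identical inputs produce
#' identical bytes.
#'
#' @param metrics Named list or vector of scalar metrics.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(metrics, path) {
  m <- unlist(metrics)
  lines <- sprintf("%s\t%s", names(m),
                   vapply(m, function(v) format(v, digits = 10), character(1)))
  writeLines(c("metric\tvalue", lines), path)
  invisible(path)
}
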