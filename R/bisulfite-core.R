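#' In-silico bisulfite conversion of a sequence
#'
#' Applies the deterministic bisulfite conversion rule to a nucleotide
#' sequence read 5'->3' on its own strand: every cytosine deaminates to
#' thymine, except that under `cg_methylated = TRUE` cytosines immediately
#' followed by guanine (CG dinucleotides) are assumed methylated and remain
#' cytosine. Non-cytosine bases are untouched and length is preserved.
#'
#' For a bottom-strand window, pass the reverse complement of the top-strand
#' sequence; CG dinucleotides are strand-symmetric so the same rule applies.
#'
#' @param seq Character vector of sequences over A/C/G/T/N.
#' @param cg_methylated If `TRUE`, CG-context cytosines are preserved
#'   (the "all CGs methylated" probe state); if `FALSE` every C converts.
#' @return Character vector of converted sequences.
#' @examples
#' bs_convert("ACGT")                        # "ATGT"
#' bs_convert("ACGT", cg_methylated = TRUE)  # "ACGT"
#' @export
bs_convert <- function(seq, cg_methylated = FALSE) {
  if (any(grepl("[^ACGTNacgtn]", seq))) {
    stop("sequence contains characters outside the A/C/G/T/N alphabet",
         call. = FALSE)
  }
  seq <- toupper(seq)
  if (!cg_methylated) {
    return(gsub("C", "T", seq, fixed = TRUE))
  }
  # protect CG cytosines, convert the rest; perl lookahead keeps the G intact
  gsub("C(?!G)", "T", seq, perl = TRUE)
}

# converted bottom strand of a forward-coordinates window, returned in
# forward coordinates (G -> A where the bottom-strand C converted)
bs_convert_forward_bottom <- function(seq, cg_methylated = FALSE) {
  revcomp(bs_convert(revcomp(seq), cg_methylated = cg_methylated))
}

#' Classify the sequence context of a cytosine
#'
#' Determines the CG / CHG / CHH context (H = A, T or C) of a strand-aware
#' cytosine from the reference sequence alone. On the minus strand the
#' reference base is G and the context is read on the reverse complement.
#' Sites whose context window runs off the contig end are labelled `"edge"`;
#' windows containing N yield `NA` (no call).
#'
#' @param genome Named character vector of contigs.
#' @param contig Contig name (scalar or vector recycled against `pos`).
#' @param pos 0-based position(s) of the cytosine.
#' @param strand `"+"` or `"-"` per position.
#' @return Character vector with values `"CG"`, `"CHG"`, `"CHH"`, `"edge"`
#'   or `NA`.
#' @export
classify_context <- function(genome, contig, pos, strand = "+") {
  genome <- validate_genome(genome)
  n <- max(length(contig), length(pos), length(strand))
  contig <- rep_len(contig, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- genome[[contig[i]]]
    if (is.null(s)) stop("unknown contig: ", contig[i], call. = FALSE)
    out[i] <- context_at(s, pos[i], strand[i])
  }
  out
}

# scalar context classification on one contig string; pos is 0-based
context_at <- function(seq, pos, strand) {
  L <- nchar(seq)
  if (pos < 0L || pos >= L) stop("position out of contig bounds", call. = FALSE)
  base <- substr(seq, pos + 1L, pos + 1L)
  if (strand == "+") {
    if (base != "C") stop("reference base at position is not a + strand cytosine",
                          call. = FALSE)
    b1 <- if (pos + 2L <= L) substr(seq, pos + 2L, pos + 2L) else ""
    b2 <- if (pos + 3L <= L) substr(seq, pos + 3L, pos + 3L) else ""
  } else {
    if (base != "G") stop("reference base at position is not a - strand cytosine",
                          call. = FALSE)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    b1 <- if (pos >= 1L) comp[[substr(seq, pos, pos)]] else ""
    b2 <- if (pos >= 2L) comp[[substr(seq, pos - 1L, pos - 1L)]] else ""
  }
  if (b1 == "") return("edge")
  if (b1 == "N") return(NA_character_)
  if (b1 == "G") return("CG")
  if (b2 == "") return("edge")
  if (b2 == "N") return(NA_character_)
  if (b2 == "G") return("CHG") else return("CHH")
}

#' Tabulate all strand-aware cytosine sites of a genome
#'
#' Enumerates every + strand C and - strand G with its CG/CHG/CHH context.
#' Edge-truncated sites are flagged in the `context` column as `"edge"` and
#' sites with N in the context window as `NA`; both are excluded when
#' `drop_incomplete = TRUE` (the default, matching how summaries treat them).
#'
#' @param genome Named character vector of contigs.
#' @param contigs Optional subset of contig names.
#' @param drop_incomplete Drop edge/N sites (default `TRUE`).
#' @return `data.table` with columns `contig`, `pos` (0-based), `strand`,
#'   `context`.
#' @export
cytosine_sites <- function(genome, contigs = NULL, drop_incomplete = TRUE) {
  genome <- validate_genome(genome)
  if (is.null(contigs)) contigs <- names(genome)
  res <- lapply(contigs, function(cn) {
    s <- genome[[cn]]
    b <- chars(s)
    L <- length(b)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    make_ctx <- function(b1, b2) {
      ctx <- rep(NA_character_, length(b1))
      ctx[b1 == "G"] <- "CG"
      h1 <- b1 %in% c("A", "T", "C")
      ctx[h1 & b2 == "G"] <- "CHG"
      ctx[h1 & b2 %in% c("A", "T", "C")] <- "CHH"
      # edge flags: missing downstream bases (encoded "")
      ctx[b1 == ""] <- "edge"
      ctx[h1 & b2 == ""] <- "edge"
      ctx
    }
    at <- function(i) ifelse(i >= 1L & i <= L, b[pmax(pmin(i, L), 1L)], "")
    plus <- which(b == "C")
    minus <- which(b == "G")
    ctx_p <- if (length(plus)) make_ctx(at(plus + 1L), at(plus + 2L)) else character()
    b1m <- at(minus - 1L); b2m <- at(minus - 2L)
    b1m[b1m != ""] <- comp[b1m[b1m != ""]]
    b2m[b2m != ""] <- comp[b2m[b2m != ""]]
    ctx_m <- if (length(minus)) make_ctx(b1m, b2m) else character()
    data.table::data.table(
      contig = cn,
      pos = c(plus, minus) - 1L,
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      context = c(ctx_p, ctx_m)
    )
  })
  out <- data.table::rbindlist(res)
  if (drop_incomplete && nrow(out)) {
    out <- out[!is.na(out$context) & out$context != "edge", ]
  }
  data.table::setkeyv(out, c("contig", "pos", "strand"))
  out[]
}

#' Enumerate bisulfite conversion alleles of a fragment
#'
#' Each potentially methylated cytosine of a single-stranded fragment may
#' independently survive conversion (methylated, reads C) or convert
#' (unmethylated, reads T), so a fragment with n such cytosines has 2^n
#' distinguishable converted alleles. By default every strand cytosine
#' counts as potentially methylated (non-CG methylation is prevalent in
#' plant genomes); `cg_only = TRUE` restricts n to CG-context cytosines.
#'
#' @param seq Fragment sequence, 5'->3' on its own strand.
#' @param cg_only Count only CG-context cytosines.
#' @param materialize Also return the allele sequences (requires n <= 20).
#' @return List with `n_cytosines`, `allele_count`, and (if materialized)
#'   `alleles`, a character vector of the 2^n conversion patterns.
#' @export
enumerate_alleles <- function(seq, cg_only = FALSE, materialize = FALSE) {
  if (grepl("[^ACGTNacgtn]", seq)) {
    stop("sequence contains characters outside the A/C/G/T/N alphabet",
         call. = FALSE)
  }
  seq <- toupper(seq)
  b <- chars(seq)
  cpos <- which(b == "C")
  if (cg_only && length(cpos)) {
    nxt <- c(b[-1L], "")
    cpos <- cpos[nxt[cpos] == "G"]
  }
  n <- length(cpos)
  out <- list(n_cytosines = n, allele_count = 2^n)
  if (materialize) {
    if (n > 20L) stop("refusing to materialize more than 2^20 alleles",
                      call. = FALSE)
    alle <- character(2^n)
    for (m in seq_len(2^n) - 1L) {
      bb <- b
      conv <- cpos[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) == 0L]
      bb[conv] <- "T"
      alle[m + 1L] <- paste(bb, collapse = "")
    }
    out$alleles <- alle
  }
  out
}

#' Estimate the bisulfite conversion rate from an unmethylated control
#'
#' Pools per-site (converted, total) counts from a control contig known to
#' be unmethylated (a chloroplast or lambda analog) and reports the overall
#' conversion rate sum(converted)/sum(total).
#'
#' @param converted Integer vector of converted (read T) counts, or a
#'   two-column data.frame/list with `converted` and `total`.
#' @param total Integer vector of total counts.
#' @return Conversion rate in `[0, 1]`.
#' @export
conversion_rate <- function(converted, total = NULL) {
  if (is.null(total)) {
    total <- converted$total
    converted <- converted$converted
  }
  if (any(total < 0) || any(converted < 0) || any(converted > total)) {
    stop("counts must satisfy 0 <= converted <= total", call. = FALSE)
  }
  tot <- sum(total)
  if (tot == 0) {
    stop("conversion rate undefined: no control cytosines observed",
         call. = FALSE)
  }
  sum(converted) / tot
}
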