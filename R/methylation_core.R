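#' Parameters for methylcytosine calling
#'
#' @param error_rate combined bisulfite non-conversion / sequencing error
#'   rate epsilon in `[0, 1)`; the null methylation probability of an
#'   unmethylated cytosine. Default 0.005 (conversion rate > 99%).
#' @param alpha FDR threshold for the Benjamini-Hochberg-corrected
#'   binomial test, in (0, 1).
#' @param min_coverage minimum read coverage to call a methylation status
#'   for a base (default 4); shallower cytosines stay "uncalled".
#' @return a list of validated parameters.
#' @export
methylation_call_params <- function(error_rate = 0.005, alpha = 0.05,
                                    min_coverage = 4L) {
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1)
    stop("error_rate must lie in [0, 1)")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(min_coverage) || min_coverage < 1)
    stop("min_coverage must be >= 1")
  list(error_rate = error_rate, alpha = alpha,
       min_coverage = as.integer(min_coverage))
}

# character vector of one chromosome sequence, uppercased
.seq_chars <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet"))
    x <- as.character(x)
  if (length(x) != 1L) stop("expected a single sequence")
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

# context of cytosines at 0-based positions pos0 on the given strand of a
# character vector v; NA where the needed downstream bases run off the end
# or are not A/C/G/T. Errors unless the base at pos0 is C on that strand.
.context_from_chars <- function(v, pos0, strand) {
  n <- length(v)
  i <- pos0 + 1L                      # 1-based index
  if (any(i < 1L | i > n)) stop("position outside sequence")
  plus <- strand == "+"
  base <- v[i]
  ok <- ifelse(plus, base == "C", base == "G")
  if (!all(ok))
    stop("base at position ", pos0[which(!ok)[1]], " is not a cytosine on the ",
         strand[which(!ok)[1]], " strand")
  at <- function(j) ifelse(j >= 1L & j <= n, v[pmax(pmin(j, n), 1L)], NA_character_)
  nxt <- ifelse(plus, at(i + 1L), chartr("ACGT", "TGCA", at(i - 1L)))
  nx2 <- ifelse(plus, at(i + 2L), chartr("ACGT", "TGCA", at(i - 2L)))
  valid <- function(b) !is.na(b) & b %in% c("A", "C", "G", "T")
  out <- rep(NA_character_, length(i))
  out[valid(nxt) & nxt == "G"] <- "CG"
  rest <- is.na(out) & valid(nxt)
  out[rest & valid(nx2) & nx2 == "G"] <- "CHG"
  out[rest & valid(nx2) & nx2 != "G"] <- "CHH"
  out
}

#' Assign the sequence context of a cytosine
#'
#' Determines CG / CHG / CHH (H = A, T or C) for the cytosine at `pos` on
#' `strand` of `seq`, reading 5' to 3' on that strand (the reverse
#' complement is consulted for minus-strand cytosines). Returns `NA` when
#' the needed downstream bases fall off the sequence end or are `N`.
#'
#' @param seq one sequence: character scalar or `Biostrings::DNAString`.
#' @param pos 0-based position(s) of the cytosine on the forward axis.
#' @param strand "+" or "-", recycled along `pos`.
#' @return character vector of contexts ("CG", "CHG", "CHH" or `NA`).
#' @export
assign_context <- function(seq, pos, strand = "+") {
  v <- .seq_chars(seq)
  strand <- rep_len(strand, length(pos))
  if (any(!strand %in% c("+", "-"))) stop("strand must be + or -")
  .context_from_chars(v, as.integer(pos), strand)
}

#' Enumerate all cytosine sites of a genome with their contexts
#'
#' Scans every chromosome on both strands and returns one row per
#' reference cytosine (C on plus, G on minus). Sites whose context cannot
#' be determined (sequence end, N in the trinucleotide) get `NA` context;
#' eligible sites are partitioned exactly into CG/CHG/CHH.
#'
#' @param genome named character vector or `Biostrings::DNAStringSet`.
#' @return `data.table` with chrom, pos (0-based), strand, context.
#' @export
cytosine_sites <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  out <- lapply(names(genome), function(ch) {
    v <- .seq_chars(genome[[ch]])
    ip <- which(v == "C"); im <- which(v == "G")
    dt <- data.table(
      chrom = ch,
      pos = c(ip, im) - 1L,
      strand = rep(c("+", "-"), c(length(ip), length(im))))
    dt[, context := .context_from_chars(v, pos, strand)]
    setorder(dt, pos, strand)
    dt
  })
  rbindlist(out)
}

#' Call methylated cytosines
#'
#' For every record with coverage at or above `min_coverage`, tests the
#' methylated read count against the error rate with a one-sided binomial
#' test (P(X >= n_meth | n_total, epsilon)) and applies Benjamini-Hochberg
#' correction separately within each sequence context (the CHH base rate
#' differs from CG by an order of magnitude, so a shared FDR pool would
#' distort both). Records with q <= alpha are called "yes", tested records
#' above alpha "no", and records below the coverage floor "uncalled".
#'
#' @param records cytosine record table.
#' @param params list from [methylation_call_params()].
#' @return copy of `records` with columns p_meth, q_meth and
#'   is_methylated ("yes"/"no"/"uncalled") appended.
#' @export
call_methylated <- function(records, params = methylation_call_params()) {
  records <- validate_cytosines(records)
  if (is.null(params$error_rate) || is.null(params$alpha) ||
      is.null(params$min_coverage))
    stop("params must come from methylation_call_params()")
  out <- copy(records)
  out[, `:=`(p_meth = NA_real_, q_meth = NA_real_, is_methylated = "uncalled")]
  tested <- out$n_total >= params$min_coverage
  if (any(tested)) {
    out[tested, p_meth := pbinom(n_meth - 1L, n_total, params$error_rate,
                                 lower.tail = FALSE)]
    out[tested, q_meth := p.adjust(p_meth, method = "BH"), by = context]
    out[tested, is_methylated := ifelse(q_meth <= params$alpha, "yes", "no")]
  }
  out[]
}

#' Weighted methylation level of a region
#'
#' The ratio of methylated read counts to total read counts pooled over
#' the covered cytosines of a context and region:
#' `sum(n_meth) / sum(n_total)`. Read-weighted, not site-averaged. Returns
#' `NA` (undefined, distinct from 0) when no reads cover the selection.
#'
#' @param records cytosine record table.
#' @param context optional context filter ("CG", "CHG", "CHH").
#' @param region optional data.frame of half-open intervals with columns
#'   chrom, start, end; cytosines outside all intervals are excluded.
#' @return numeric scalar in `[0, 1]`, or `NA_real_`.
#' @export
weighted_level <- function(records, context = NULL, region = NULL) {
  records <- validate_cytosines(records)
  if (!is.null(context)) {
    if (!context %in% CONTEXTS) stop("unknown context: ", context)
    keep_ctx <- records$context == context
    records <- records[keep_ctx]
  }
  if (!is.null(region) && nrow(records)) {
    region <- as.data.table(region)
    keep <- rep(FALSE, nrow(records))
    for (i in seq_len(nrow(region))) {
      keep <- keep | (records$chrom == region$chrom[i] &
                        records$pos >= region$start[i] &
                        records$pos < region$end[i])
    }
    records <- records[keep]
  }
  tot <- sum(as.numeric(records$n_total))
  if (tot == 0) return(NA_real_)
  sum(as.numeric(records$n_meth)) / tot
}

#' Pairwise replicate correlation of windowed methylation levels
#'
#' Computes the weighted methylation level in fixed non-overlapping
#' windows for each replicate and returns the pairwise Pearson
#' correlation matrix over windows covered in every replicate.
#'
#' @param replicates named list of cytosine record tables.
#' @param window window width in bp (default 10000).
#' @param context optional context filter.
#' @return Pearson correlation matrix with one row/column per replicate;
#'   attribute `n_windows` gives the number of windows used.
#' @export
replicate_correlation <- function(replicates, window = 10000L, context = NULL) {
  if (!is.list(replicates) || length(replicates) < 2L)
    stop("need at least 2 replicates")
  if (is.null(names(replicates)))
    names(replicates) <- paste0("rep", seq_along(replicates))
  levs <- lapply(names(replicates), function(nm) {
    r <- validate_cytosines(replicates[[nm]], nm)
    if (!is.null(context)) {
      keep_ctx <- r$context == context
      r <- r[keep_ctx]
    }
    r <- r[n_total > 0L]
    r[, .(level = sum(as.numeric(n_meth)) / sum(as.numeric(n_total))),
      by = .(chrom, win = pos %/% as.integer(window))]
  })
  merged <- Reduce(function(a, b) merge(a, b, by = c("chrom", "win")), levs)
  if (nrow(merged) < 2L) stop("fewer than 2 windows covered in all replicates")
  m <- as.matrix(merged[, -(1:2)])
  colnames(m) <- names(replicates)
  out <- cor(m, method = "pearson")
  attr(out, "n_windows") <- nrow(merged)
  out
}
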