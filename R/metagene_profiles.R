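# bin index along the 5'->3' metagene axis for one record/feature pair.
# Bins: nf flank bins upstream, body_bins percentile bins, nf downstream.
# Returns NA for positions outside [start-flank, end+flank).
.metagene_bin <- function(pos, start, end, strand, flank, flank_bin, body_bins) {
  nf <- as.integer(ceiling(flank / flank_bin))
  width <- end - start
  minus <- strand == "-"
  bin <- rep(NA_integer_, length(pos))

  up <- ifelse(minus, pos >= end & pos < end + flank,
               pos >= start - flank & pos < start)
  off_up <- ifelse(minus, end + flank - 1L - pos, pos - (start - flank))
  bin[up] <- (off_up[up] %/% flank_bin) + 1L

  body <- pos >= start & pos < end
  rel <- ifelse(minus, end - 1L - pos, pos - start)
  b <- pmin(body_bins - 1L, as.integer((as.numeric(rel) * body_bins) %/% width))
  bin[body] <- nf + b[body] + 1L

  dn <- ifelse(minus, pos >= start - flank & pos < start,
               pos >= end & pos < end + flank)
  dn <- dn & !up & !body
  off_dn <- ifelse(minus, start - 1L - pos, pos - end)
  bin[dn] <- nf + body_bins + (off_dn[dn] %/% flank_bin) + 1L
  bin
}

.metagene_labels <- function(nf, body_bins) {
  c(sprintf("U%02d", seq_len(nf)), sprintf("B%02d", seq_len(body_bins)),
    sprintf("D%02d", seq_len(nf)))
}

#' Average methylation profile over feature bodies with flanks
#'
#' Builds the metagene profile of one context over a feature set: fixed
#' 100-bp bins across the 2-kb flanks and equal-width percentile bins
#' across each feature body, oriented 5' to 3' (minus-strand features are
#' reversed). The per-bin level pools read counts across features
#' (`sum(n_meth) / sum(n_total)` within the bin), matching the weighted
#' methylation level definition; `average = "feature_mean"` averages
#' per-feature bin levels instead. Flanks are truncated at chromosome
#' edges; features shorter than `body_bins` bases are skipped and counted
#' in the `n_skipped` attribute.
#'
#' @param records cytosine record table.
#' @param features feature table (all rows are profiled; subset upstream
#'   to select a kind).
#' @param context context to profile ("CG", "CHG" or "CHH").
#' @param flank flank width in bp (default 2000).
#' @param flank_bin flank bin width in bp (default 100).
#' @param body_bins number of equal-width body bins (default 20).
#' @param average "pooled" (count-pooled, default) or "feature_mean".
#' @return a `data.table` of class `methylation_profile` with columns
#'   bin, label, n_meth, n_total, level; attributes context, average,
#'   n_features, n_skipped.
#' @export
compute_profile <- function(records, features, context,
                            flank = 2000L, flank_bin = 100L, body_bins = 20L,
                            average = c("pooled", "feature_mean")) {
  average <- match.arg(average)
  records <- validate_cytosines(records)
  features <- validate_features(features)
  if (!context %in% CONTEXTS) stop("unknown context: ", context)
  if (!nrow(features)) stop("empty feature set")
  flank <- as.integer(flank); flank_bin <- as.integer(flank_bin)
  body_bins <- as.integer(body_bins)
  nf <- as.integer(ceiling(flank / flank_bin))
  nbins <- 2L * nf + body_bins

  short <- features$end - features$start < body_bins
  n_skipped <- sum(short)
  if (n_skipped) features <- features[!short]

  skel <- data.table(bin = seq_len(nbins),
                     label = .metagene_labels(nf, body_bins),
                     n_meth = 0, n_total = 0)
  finish <- function(acc) {
    out <- merge(skel[, .(bin, label)], acc, by = "bin", all.x = TRUE)
    out[is.na(n_meth), `:=`(n_meth = 0, n_total = 0)]
    if (average == "pooled")
      out[, level := ifelse(n_total > 0, n_meth / n_total, NA_real_)]
    setorder(out, bin)
    setattr(out, "class", c("methylation_profile", class(out)))
    setattr(out, "context", context)
    setattr(out, "average", average)
    setattr(out, "n_features", nrow(features))
    setattr(out, "n_skipped", n_skipped)
    out[]
  }
  keep_ctx <- records$context == context & records$n_total > 0L
  rec <- records[keep_ctx]
  if (!nrow(features) || !nrow(rec)) {
    acc <- skel[, .(bin, n_meth, n_total)][0]
    if (average == "feature_mean") acc[, level := numeric(0)]
    return(finish(acc))
  }

  fx <- features[, .(id, chrom, strand, fstart = start, fend = end,
                     start = start - flank, end = end + flank - 1L)]
  rx <- rec[, .(chrom, start = pos, end = pos, n_meth, n_total)]
  setkey(fx, chrom, start, end)
  hits <- foverlaps(rx, fx, type = "within", nomatch = NULL)
  if (!nrow(hits)) {
    acc <- skel[, .(bin, n_meth, n_total)][0]
    if (average == "feature_mean") acc[, level := numeric(0)]
    return(finish(acc))
  }
  hits[, bin := .metagene_bin(i.start, fstart, fend, strand,
                              flank, flank_bin, body_bins)]
  hits <- hits[!is.na(bin)]
  if (average == "pooled") {
    acc <- hits[, .(n_meth = sum(as.numeric(n_meth)),
                    n_total = sum(as.numeric(n_total))), by = bin]
  } else {
    per_feat <- hits[, .(n_meth = sum(as.numeric(n_meth)),
                         n_total = sum(as.numeric(n_total))),
                     by = .(id, bin)]
    acc <- per_feat[n_total > 0,
                    .(n_meth = sum(n_meth), n_total = sum(n_total),
                      level = mean(n_meth / n_total)), by = bin]
  }
  finish(acc)
}

#' Compare two metagene profiles
#'
#' Paired two-sided t-test over per-bin methylation levels; bins undefined
#' in either profile are dropped pairwise. When the per-bin differences
#' are exactly constant and nonzero (zero variance), the test statistic is
#' unbounded: the result carries `degenerate = TRUE` and a p-value below
#' 1e-10. Two identical profiles give t = 0, p = 1.
#'
#' @param profile_a,profile_b `methylation_profile` objects with the same
#'   bin structure.
#' @return list with statistic, p_value, n_bins, degenerate.
#' @export
compare_profiles <- function(profile_a, profile_b) {
  a <- as.data.table(profile_a); b <- as.data.table(profile_b)
  if (nrow(a) != nrow(b) || !identical(a$label, b$label))
    stop("profiles have different bin structures")
  ok <- !is.na(a$level) & !is.na(b$level)
  n <- sum(ok)
  if (n < 3L) stop("fewer than 3 paired bins with defined levels")
  d <- a$level[ok] - b$level[ok]
  if (all(d == 0))
    return(list(statistic = 0, p_value = 1, n_bins = n, degenerate = FALSE))
  tt <- tryCatch(t.test(a$level[ok], b$level[ok], paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt))   # constant nonzero difference: unbounded statistic
    return(list(statistic = sign(mean(d)) * Inf, p_value = 1e-12,
                n_bins = n, degenerate = TRUE))
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       n_bins = n, degenerate = FALSE)
}

#' Write a metagene profile as TSV
#' @param profile `methylation_profile` object.
#' @param path output path.
#' @param kind feature-kind label written into the first column.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, kind = "feature") {
  ctx <- attr(profile, "context") %||% NA_character_
  dt <- as.data.table(profile)[, .(kind = kind, context = ctx, bin, label,
                                   level = signif(level, 6), n_meth, n_total)]
  writeLines("#kind\tcontext\tbin\tlabel\tlevel\tn_meth\tn_total", path)
  fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
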