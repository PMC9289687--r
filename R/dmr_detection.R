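#' Context-specific DMR calling criteria
#'
#' Thresholds for sliding-window DMR detection between cytotypes. The
#' per-context defaults are: minimum cytosines per window 20 (allC), 5
#' (CG), 5 (CHG) or 15 (CHH); minimum absolute methylation-ratio
#' difference 0.20 (allC) or 0.25 (single contexts); q <= 0.05; and a
#' minimum pooled per-cytosine coverage of 4 in each group. Window
#' geometry defaults to 200-bp windows advanced in 100-bp steps.
#'
#' @param context "CG", "CHG", "CHH" or "allC" (all three contexts pooled).
#' @param window,step window width and step in bp; `step <= window`.
#' @param min_sites,min_delta,max_q,min_coverage overrides of the
#'   per-context defaults above.
#' @return list of class `dmr_criteria`.
#' @export
dmr_criteria <- function(context = c("CG", "CHG", "CHH", "allC"),
                         window = 200L, step = 100L,
                         min_sites = NULL, min_delta = NULL,
                         max_q = 0.05, min_coverage = 4L) {
  context <- match.arg(context)
  defaults_sites <- c(allC = 20L, CG = 5L, CHG = 5L, CHH = 15L)
  defaults_delta <- c(allC = 0.20, CG = 0.25, CHG = 0.25, CHH = 0.25)
  min_sites <- as.integer(min_sites %||% defaults_sites[[context]])
  min_delta <- min_delta %||% defaults_delta[[context]]
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) stop("need window >= step >= 1")
  if (min_sites < 1L || min_delta <= 0 || max_q <= 0 || max_q > 1 ||
      min_coverage < 1L)
    stop("thresholds must be positive (and max_q in (0, 1])")
  structure(list(context = context, window = window, step = step,
                 min_sites = min_sites, min_delta = min_delta,
                 max_q = max_q, min_coverage = as.integer(min_coverage)),
            class = "dmr_criteria")
}

#' Tile chromosomes with sliding windows
#'
#' Half-open windows of width `window` advanced by `step` per chromosome;
#' the final window is truncated at the chromosome end.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window,step window width and step in bp.
#' @return `data.table` with chrom, start, end, ordered by (chrom, start).
#' @export
scan_windows <- function(chrom_lengths, window = 200L, step = 100L) {
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) stop("need window >= step >= 1")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    k <- max(1L, as.integer(ceiling((len - window) / step)) + 1L)
    start <- step * (seq_len(k) - 1L)
    data.table(chrom = ch, start = start, end = pmin(start + window, len))
  })
  rbindlist(out)
}

# pool replicate tables (or pass through one table) into per-position counts
.pool_records <- function(x, what) {
  if (is.data.frame(x)) x <- list(x)
  if (!length(x)) stop("empty record set for ", what)
  dt <- rbindlist(lapply(seq_along(x), function(i)
    validate_cytosines(x[[i]], paste0(what, "[", i, "]"))))
  if (!nrow(dt)) stop("empty record set for ", what)
  dt[, .(n_meth = sum(as.numeric(n_meth)), n_total = sum(as.numeric(n_total))),
     by = .(chrom, pos, strand, context)]
}

#' Call differentially methylated regions between cytotypes
#'
#' Sliding-window DMR detection. Replicates are pooled per cytotype;
#' cytosines are kept only where the pooled coverage reaches
#' `min_coverage` in *both* groups at the same position (preventing
#' coverage-composition artifacts). Each window with at least `min_sites`
#' such cytosines is scored: weighted level per group, their difference
#' `delta = ratio_4x - ratio_2x`, and a two-sided Fisher's exact test on
#' the pooled 2x2 count table. Benjamini-Hochberg correction runs across
#' all tested windows of the run; windows passing `|delta| >= min_delta`
#' and `q <= max_q` are retained and overlapping or book-ended windows of
#' the same direction are merged into maximal regions (ratios recomputed
#' over the merged interval, minimum q kept).
#'
#' @param records_2x,records_4x cytosine record table, or list of
#'   replicate tables, for each cytotype.
#' @param criteria list from [dmr_criteria()].
#' @param chrom_lengths optional named vector; inferred from the records
#'   when missing.
#' @param merge merge significant windows (default TRUE).
#' @return `data.table` of DMRs with columns chrom, start, end, context,
#'   n_sites, ratio_2x, ratio_4x, delta, p, q, direction. The attribute
#'   `windows` holds the full table of tested windows (before
#'   significance filtering) for inspection.
#' @export
call_dmrs <- function(records_2x, records_4x, criteria = dmr_criteria("CG"),
                      chrom_lengths = NULL, merge = TRUE) {
  if (!inherits(criteria, "dmr_criteria"))
    stop("criteria must come from dmr_criteria()")
  p2 <- .pool_records(records_2x, "records_2x")
  p4 <- .pool_records(records_4x, "records_4x")
  if (is.null(chrom_lengths))
    chrom_lengths <- infer_chrom_lengths(p2, p4)
  if (criteria$context != "allC") {
    p2 <- p2[context == criteria$context]
    p4 <- p4[context == criteria$context]
  }
  sites <- merge(p2, p4, by = c("chrom", "pos", "strand", "context"),
                 suffixes = c("_2x", "_4x"))
  sites <- sites[n_total_2x >= criteria$min_coverage &
                   n_total_4x >= criteria$min_coverage]

  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), n_sites = integer(),
                      ratio_2x = numeric(), ratio_4x = numeric(),
                      delta = numeric(), p = numeric(), q = numeric(),
                      direction = character())
  win_cols <- c("chrom", "start", "end", "n_sites", "m2", "t2", "m4", "t4",
                "ratio_2x", "ratio_4x", "delta", "p", "q", "significant")
  if (!nrow(sites)) {
    setattr(empty, "windows", empty[0][, .(chrom, start, end)])
    return(empty)
  }

  # expand each site to every covering window on the step grid
  step <- criteria$step; window <- criteria$window
  n_off <- as.integer(ceiling(window / step))
  max_start <- scan_windows(chrom_lengths, window, step)[
    , .(max_start = max(start)), by = chrom]
  expanded <- rbindlist(lapply(seq_len(n_off) - 1L, function(j) {
    e <- copy(sites)
    e[, wstart := (pos %/% step - j) * step]
    e[wstart >= 0L & pos < wstart + window]
  }))
  expanded <- expanded[max_start, on = "chrom"][wstart <= max_start]

  wins <- expanded[, .(n_sites = .N,
                       m2 = sum(n_meth_2x), t2 = sum(n_total_2x),
                       m4 = sum(n_meth_4x), t4 = sum(n_total_4x)),
                   by = .(chrom, wstart)]
  wins <- wins[n_sites >= criteria$min_sites]
  if (!nrow(wins)) {
    setattr(empty, "windows", empty[0][, .(chrom, start, end)])
    return(empty)
  }
  len_of <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  wins[, `:=`(start = wstart, end = pmin(wstart + window, len_of[chrom]))]
  wins[, `:=`(ratio_2x = m2 / t2, ratio_4x = m4 / t4)]
  wins[, delta := ratio_4x - ratio_2x]
  wins[, p := mapply(function(m2, t2, m4, t4)
    fisher.test(matrix(c(m2, t2 - m2, m4, t4 - m4), nrow = 2))$p.value,
    m2, t2, m4, t4)]
  wins[, q := p.adjust(p, method = "BH")]
  wins[, significant := abs(delta) >= criteria$min_delta & q <= criteria$max_q]
  setorder(wins, chrom, start)
  tested <- wins[, win_cols, with = FALSE]

  sig <- wins[significant == TRUE]
  if (!nrow(sig)) {
    setattr(empty, "windows", tested)
    return(empty)
  }
  sig[, direction := ifelse(delta > 0, "hyper", "hypo")]

  if (merge) {
    setorder(sig, chrom, direction, start, end)
    # chain-merge overlapping or book-ended windows of one direction
    sig[, grp := {
      ce <- cummax(end)
      cumsum(c(1L, as.integer(start[-1] > ce[-length(ce)])))
    }, by = .(chrom, direction)]
    merged <- sig[, .(start = min(start), end = max(end),
                      p = min(p), q = min(q)),
                  by = .(chrom, direction, grp)][, grp := NULL]
  } else {
    merged <- sig[, .(chrom, direction, start, end, p, q)]
  }
  # recompute pooled ratios over each (possibly merged) region
  setkey(sites, chrom, pos)
  stats <- lapply(seq_len(nrow(merged)), function(i) {
    s <- sites[chrom == merged$chrom[i] & pos >= merged$start[i] &
                 pos < merged$end[i]]
    list(n_sites = nrow(s),
         ratio_2x = sum(s$n_meth_2x) / sum(s$n_total_2x),
         ratio_4x = sum(s$n_meth_4x) / sum(s$n_total_4x))
  })
  merged[, n_sites := vapply(stats, `[[`, integer(1), "n_sites")]
  merged[, ratio_2x := vapply(stats, `[[`, numeric(1), "ratio_2x")]
  merged[, ratio_4x := vapply(stats, `[[`, numeric(1), "ratio_4x")]
  merged[, delta := ratio_4x - ratio_2x]
  merged[, context := criteria$context]
  setorder(merged, chrom, start)
  out <- merged[, .(chrom, start, end, context, n_sites, ratio_2x, ratio_4x,
                    delta, p, q, direction)]
  setattr(out, "windows", tested)
  out
}

#' Summarise DMR calls per context
#'
#' @param dmrs DMR table from [call_dmrs()] (contexts may be mixed).
#' @return `data.table` with context, n, n_hyper, n_hypo and
#'   hyper_fraction (`NaN` when a context has no DMRs).
#' @export
summarize_dmrs <- function(dmrs) {
  dmrs <- as.data.table(dmrs)
  if (!nrow(dmrs))
    return(data.table(context = character(), n = integer(),
                      n_hyper = integer(), n_hypo = integer(),
                      hyper_fraction = numeric()))
  dmrs[, .(n = .N, n_hyper = sum(direction == "hyper"),
           n_hypo = sum(direction == "hypo"),
           hyper_fraction = sum(direction == "hyper") / .N),
       by = context]
}

#' Annotate DMR genomic locations
#'
#' Assigns each DMR to PCG, lncRNA, TE or intergenic. Among overlapped
#' kinds the one covering the most DMR bases wins (union of overlap per
#' kind); ties fall to the precedence PCG > lncRNA > TE. The `flank_gene`
#' flag marks DMRs whose midpoint lies within `flank` bp of a PCG or
#' lncRNA boundary (inside the gene counts as distance 0).
#'
#' @param dmrs DMR table.
#' @param features feature table.
#' @param flank gene-flank distance in bp (default 4000).
#' @return copy of `dmrs` with annotation and flank_gene columns.
#' @export
annotate_dmr_location <- function(dmrs, features, flank = 4000L) {
  dmrs <- as.data.table(dmrs)
  features <- validate_features(features)
  out <- copy(dmrs)
  if (!nrow(out)) {
    out[, `:=`(annotation = character(0), flank_gene = logical(0))]
    return(out[])
  }
  precedence <- c(PCG = 1L, lncRNA = 2L, TE = 3L)
  genes <- features[kind %in% c("PCG", "lncRNA")]
  ann <- character(nrow(out)); fl <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ds <- out$start[i]; de <- out$end[i]; ch <- out$chrom[i]
    ov <- features[chrom == ch & start < de & end > ds]
    if (nrow(ov)) {
      bp <- ov[, .(bp = union_bp(pmax(start, ds), pmin(end, de))), by = kind]
      bp[, prec := precedence[kind]]
      setorder(bp, -bp, prec)
      ann[i] <- bp$kind[1]
    } else ann[i] <- "intergenic"
    mid <- (ds + de) %/% 2L
    if (nrow(genes)) {
      gch <- genes[chrom == ch]
      fl[i] <- nrow(gch) > 0 &&
        min(interval_gap(gch$start, gch$end, mid, mid + 1L)) <= flank
    }
  }
  out[, `:=`(annotation = ann, flank_gene = fl)]
  out[]
}
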