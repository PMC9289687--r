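# Nearest-subject interval per query, by gap distance between half-open
# intervals (0 on intersection or book-ending). Ties resolved by lower
# subject start, then subject id. Queries on chromosomes with no subject
# get NA distance and no_subject = TRUE.
.nearest_interval <- function(query, subject) {
  out <- data.table(idx = seq_len(nrow(query)),
                    nearest = NA_character_, distance = NA_integer_,
                    no_subject = TRUE)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sub <- subject[subject$chrom == ch]
    if (!nrow(sub)) next
    setorder(sub, start, id)
    ir_q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    ir_s <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    hits <- IRanges::distanceToNearest(ir_q, ir_s, select = "all")
    hdt <- data.table(q = S4Vectors::queryHits(hits),
                      s = S4Vectors::subjectHits(hits),
                      d = S4Vectors::mcols(hits)$distance)
    setorder(hdt, q, s)            # subjects pre-sorted by (start, id)
    hdt <- hdt[!duplicated(q)]
    out[qi[hdt$q], `:=`(nearest = sub$id[hdt$s],
                        distance = as.integer(hdt$d),
                        no_subject = FALSE)]
  }
  out
}

#' Nearest transposable element per feature
#'
#' Distance is the gap between the half-open intervals: 0 when the
#' feature and TE intersect (body overlap) and also for book-ended
#' intervals; otherwise the number of bases separating them. Ties are
#' broken by lower TE start, then TE id. Features on chromosomes without
#' any TE get `NA` distance and `no_te = TRUE`.
#'
#' @param features feature table (any kinds).
#' @param tes feature table of TEs (rows with kind != "TE" are dropped).
#' @return `data.table` with id, kind, chrom, nearest_te, distance,
#'   overlaps_te_body, no_te.
#' @export
nearest_te <- function(features, tes) {
  features <- validate_features(features)
  tes <- validate_features(tes)[kind == "TE"]
  if (!nrow(features) || !nrow(tes)) stop("need non-empty features and TEs")
  nn <- .nearest_interval(features, tes)
  out <- features[, .(id, kind, chrom, start, end)]
  out[, `:=`(nearest_te = nn$nearest, distance = nn$distance,
             no_te = nn$no_subject)]
  # body overlap: distance 0 with true intersection (book-ends excluded)
  tkey <- tes[, .(id, tstart = start, tend = end)]
  out <- merge(out, tkey, by.x = "nearest_te", by.y = "id",
               all.x = TRUE, sort = FALSE)
  out[, overlaps_te_body := !is.na(distance) & distance == 0L &
        tstart < end & tend > start]
  setorder(out, chrom, start)
  out[, .(id, kind, chrom, nearest_te, distance, overlaps_te_body, no_te)]
}

#' Count TEs in the flanking regions of features
#'
#' Counts TEs intersecting the union of the two flanks
#' `[start - flank, start)` and `[end, end + flank)`. A TE spanning both
#' flanks is counted once; TEs confined to the feature body intersect
#' neither flank and are excluded.
#'
#' @param features feature table.
#' @param tes TE feature table.
#' @param flank flank width in bp (default 4000).
#' @return `data.table` with id and te_count_flank.
#' @export
count_flank_tes <- function(features, tes, flank = 4000L) {
  features <- validate_features(features)
  tes <- validate_features(tes)[kind == "TE"]
  flank <- as.integer(flank)
  counts <- integer(nrow(features))
  for (ch in unique(features$chrom)) {
    qi <- which(features$chrom == ch)
    sub <- tes[chrom == ch]
    if (!nrow(sub)) next
    for (i in qi) {
      s <- features$start[i]; e <- features$end[i]
      left <- sub$start < s & sub$end > max(0L, s - flank)
      right <- sub$start < e + flank & sub$end > e
      counts[i] <- sum(left | right)
    }
  }
  data.table(id = features$id, te_count_flank = counts)
}

#' Fraction of features overlapped by TEs at body and flank windows
#'
#' For each window size w (0 = body only), computes the fraction of
#' features with at least one TE intersecting `[start - w, end + w)`:
#' overall, per TE class and per TE order. Fractions are non-decreasing
#' with window size.
#'
#' @param features feature table (typically lncRNAs).
#' @param tes TE feature table.
#' @param windows flank window sizes in bp; 0 means the feature body.
#' @return `data.table` with window, category ("any", "class_I",
#'   "class_II", "order_<order>"), n_overlapped and fraction.
#' @export
overlap_classification <- function(features, tes,
                                   windows = c(0L, 2000L, 4000L, 8000L)) {
  features <- validate_features(features)
  tes <- validate_features(tes)[kind == "TE"]
  n <- nrow(features)
  if (!n) stop("empty feature set")
  cats <- list(any = rep(TRUE, nrow(tes)))
  for (cl in c("I", "II"))
    cats[[paste0("class_", cl)]] <- !is.na(tes$te_class) & tes$te_class == cl
  for (o in intersect(TE_ORDERS, unique(tes$te_order)))
    cats[[paste0("order_", o)]] <- !is.na(tes$te_order) & tes$te_order == o
  out <- list()
  for (w in sort(as.integer(windows))) {
    hit_any <- matrix(FALSE, nrow = n, ncol = length(cats),
                      dimnames = list(NULL, names(cats)))
    for (ch in unique(features$chrom)) {
      qi <- which(features$chrom == ch)
      si <- which(tes$chrom == ch)
      if (!length(si)) next
      for (i in qi) {
        s <- features$start[i] - w; e <- features$end[i] + w
        ov <- si[tes$start[si] < e & tes$end[si] > s]
        if (length(ov))
          for (cn in names(cats)) hit_any[i, cn] <- any(cats[[cn]][ov])
      }
    }
    out[[as.character(w)]] <- data.table(
      window = w, category = names(cats),
      n_overlapped = colSums(hit_any),
      fraction = colSums(hit_any) / n)
  }
  rbindlist(out)
}

#' Partition features into expression groups
#'
#' Features whose mean FPKM (for one cytotype) falls below
#' `none_threshold` form the "none" group; the remaining expressed
#' features are ranked and split into equal-size tertiles labelled low /
#' middle / high, with remainders assigned to the lower groups.
#'
#' @param expr long-format expression table (id, cytotype, replicate, fpkm).
#' @param cytotype which cytotype's means to use ("2x" or "4x").
#' @param none_threshold FPKM below which a feature is "none" (default 0.1).
#' @return `data.table` with id, mean_fpkm, group (factor none < low <
#'   middle < high).
#' @export
expression_groups <- function(expr, cytotype = "2x", none_threshold = 0.1) {
  expr <- as.data.table(expr)
  need <- c("id", "cytotype", "replicate", "fpkm")
  miss <- setdiff(need, names(expr))
  if (length(miss)) stop("expression table lacks: ", paste(miss, collapse = ", "))
  ct <- cytotype
  m <- expr[expr$cytotype == ct][, .(mean_fpkm = mean(fpkm)), by = id]
  if (!nrow(m)) stop("no samples for cytotype ", cytotype)
  m[, group := "none"]
  ex <- which(m$mean_fpkm >= none_threshold)
  if (!length(ex)) {
    warning("all features fall below the expression threshold")
  } else {
    o <- ex[order(m$mean_fpkm[ex], m$id[ex])]
    ne <- length(o)
    base <- ne %/% 3L; rem <- ne %% 3L
    sizes <- c(low = base + (rem >= 1L), middle = base + (rem >= 2L),
               high = base)
    m$group[o] <- rep(c("low", "middle", "high"), times = sizes)
  }
  m[, group := factor(group, levels = c("none", "low", "middle", "high"))]
  m[]
}

#' Metagene profiles stratified by expression group
#'
#' Delegates to [compute_profile()] for each expression-group subset of
#' the features; empty groups are omitted with a warning.
#'
#' @param records cytosine record table.
#' @param features feature table.
#' @param labels output of [expression_groups()] (id, group).
#' @param context context to profile.
#' @param ... passed to [compute_profile()].
#' @return named list of `methylation_profile` objects, one per
#'   non-empty group.
#' @export
profile_by_group <- function(records, features, labels, context, ...) {
  features <- validate_features(features)
  labels <- as.data.table(labels)
  out <- list()
  for (g in levels(labels$group)) {
    ids <- labels[group == g, id]
    sub <- features[id %in% ids]
    if (!nrow(sub)) {
      warning("expression group '", g, "' has no features; omitted")
      next
    }
    out[[g]] <- compute_profile(records, sub, context, ...)
  }
  out
}

#' TE methylation level binned by distance to the nearest anchor feature
#'
#' Each TE (optionally filtered by class and/or order) is assigned the
#' gap distance to its nearest anchor (PCG, lncRNA or lincRNA set;
#' 0 = overlapping the anchor body), TEs are grouped into `bin`-bp
#' distance bins up to `max_distance`, and the weighted methylation level
#' of the cytosines inside the TE bodies of each bin is computed.
#'
#' @param tes TE feature table.
#' @param anchors anchor feature table (e.g. PCGs or lncRNAs).
#' @param records cytosine record table.
#' @param context context to analyse.
#' @param bin distance bin width in bp (default 500).
#' @param max_distance largest distance retained (default 8000).
#' @param te_class,te_order optional TE filters.
#' @return `data.table` with bin_start, bin_end, n_tes, n_meth, n_total,
#'   level (`NA` level for empty bins).
#' @export
methylation_by_distance <- function(tes, anchors, records, context,
                                    bin = 500L, max_distance = 8000L,
                                    te_class = NULL, te_order = NULL) {
  tes <- validate_features(tes)[kind == "TE"]
  anchors <- validate_features(anchors)
  records <- validate_cytosines(records)
  if (!context %in% CONTEXTS) stop("unknown context: ", context)
  want_class <- te_class; want_order <- te_order
  if (!is.null(want_class)) tes <- tes[!is.na(te_class) & te_class == want_class]
  if (!is.null(want_order)) tes <- tes[!is.na(te_order) & te_order == want_order]
  if (!nrow(tes) || !nrow(anchors)) stop("need non-empty TEs and anchors")
  bin <- as.integer(bin); max_distance <- as.integer(max_distance)
  nn <- .nearest_interval(tes, anchors)
  tes <- copy(tes)[, distance := nn$distance]
  tes <- tes[!is.na(distance) & distance < max_distance]
  skel <- data.table(bin_start = seq(0L, max_distance - bin, by = bin))
  skel[, bin_end := bin_start + bin]
  if (!nrow(tes)) {
    skel[, `:=`(n_tes = 0L, n_meth = 0, n_total = 0, level = NA_real_)]
    return(skel[])
  }
  tes[, bin_start := (distance %/% bin) * bin]
  keep_ctx <- records$context == context & records$n_total > 0L
  rec <- records[keep_ctx]
  body <- tes[, .(chrom, start, end = end - 1L, bin_start)]  # closed for foverlaps
  rx <- rec[, .(chrom, start = pos, end = pos, n_meth, n_total)]
  setkey(body, chrom, start, end)
  hits <- if (nrow(rx)) foverlaps(rx, body, type = "within", nomatch = NULL)
          else body[0][, `:=`(n_meth = integer(0), n_total = integer(0))]
  agg <- hits[, .(n_meth = sum(as.numeric(n_meth)),
                  n_total = sum(as.numeric(n_total))), by = bin_start]
  ntes <- tes[, .(n_tes = .N), by = bin_start]
  out <- merge(skel, ntes, by = "bin_start", all.x = TRUE)
  out <- merge(out, agg, by = "bin_start", all.x = TRUE)
  out[is.na(n_tes), n_tes := 0L]
  out[is.na(n_meth), `:=`(n_meth = 0, n_total = 0)]
  out[, level := ifelse(n_total > 0, n_meth / n_total, NA_real_)]
  setorder(out, bin_start)
  out[]
}

#' Two-group location tests
#'
#' Two-sided Welch t-test or Wilcoxon rank-sum test between two numeric
#' samples. The Wilcoxon test is exact for small untied samples and uses
#' the tie-corrected normal approximation otherwise. A Welch test on two
#' zero-variance samples is degenerate: the result carries
#' `degenerate = TRUE` with `NA` statistic and p-value.
#'
#' @param values_a,values_b numeric vectors.
#' @param test "t" or "wilcoxon".
#' @return list with statistic, p_value, n_a, n_b, degenerate.
#' @export
group_tests <- function(values_a, values_b, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (test == "t") {
    if (length(values_a) < 2L || length(values_b) < 2L)
      stop("Welch t-test needs n >= 2 per group")
    res <- tryCatch(t.test(values_a, values_b), error = function(e) NULL)
    if (is.null(res))
      return(list(statistic = NA_real_, p_value = NA_real_,
                  n_a = length(values_a), n_b = length(values_b),
                  degenerate = TRUE))
    return(list(statistic = unname(res$statistic), p_value = res$p.value,
                n_a = length(values_a), n_b = length(values_b),
                degenerate = FALSE))
  }
  if (!length(values_a) || !length(values_b))
    stop("Wilcoxon test needs n >= 1 per group")
  exact <- length(values_a) + length(values_b) <= 20L
  res <- suppressWarnings(wilcox.test(values_a, values_b, exact = exact,
                                      correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_a = length(values_a), n_b = length(values_b), degenerate = FALSE)
}
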