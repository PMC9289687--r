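`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed derived from a base seed and a string label.
# Keeps reproducibility independent of iteration order: every (sample,
# chromosome) pair gets its own stream. Result stays inside 32-bit range.
substream_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 48271 + h) %% 2147480009 + 1)
}

# column contract for per-cytosine count tables
CYTO_COLS <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")

empty_cytosine_table <- function() {
  data.table(chrom = character(), pos = integer(), strand = character(),
             context = character(), n_meth = integer(), n_total = integer())
}

validate_cytosines <- function(x, what = "records") {
  if (!is.data.frame(x)) stop(what, " must be a data.frame/data.table")
  miss <- setdiff(CYTO_COLS, names(x))
  if (length(miss)) stop(what, " lacks column(s): ", paste(miss, collapse = ", "))
  x <- as.data.table(x)
  if (nrow(x)) {
    if (any(x$n_meth < 0 | x$n_total < 0 | x$n_meth > x$n_total))
      stop(what, ": need 0 <= n_meth <= n_total")
    bad <- !x$context %in% CONTEXTS
    if (any(bad))
      stop(what, ": unknown context token(s): ",
           paste(unique(x$context[bad]), collapse = ", "))
  }
  x
}

FEATURE_COLS <- c("id", "chrom", "start", "end", "strand", "kind",
                  "subkind", "te_class", "te_order")

empty_feature_table <- function() {
  data.table(id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), kind = character(),
             subkind = character(), te_class = character(),
             te_order = character())
}

validate_features <- function(x, what = "features") {
  if (!is.data.frame(x)) stop(what, " must be a data.frame/data.table")
  miss <- setdiff(FEATURE_COLS, names(x))
  if (length(miss)) stop(what, " lacks column(s): ", paste(miss, collapse = ", "))
  x <- as.data.table(x)
  if (nrow(x)) {
    if (any(x$end <= x$start)) stop(what, ": intervals must satisfy start < end")
    if (anyDuplicated(x$id)) stop(what, ": duplicate feature id(s): ",
                                  paste(head(unique(x$id[duplicated(x$id)]), 5), collapse = ", "))
    if (any(!x$kind %in% FEATURE_KINDS))
      stop(what, ": kind must be one of ", paste(FEATURE_KINDS, collapse = ", "))
  }
  x
}

# Gap distance between half-open intervals [s1,e1) and [s2,e2): 0 when they
# intersect or are book-ended, otherwise the number of bases between them.
interval_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s1 - e2, s2 - e1))

# chromosome lengths inferred from record tables when no genome is attached
infer_chrom_lengths <- function(...) {
  tabs <- list(...)
  dt <- rbindlist(lapply(tabs, function(x) as.data.table(x)[, .(chrom, pos)]))
  if (!nrow(dt)) stop("cannot infer chromosome lengths from empty records")
  out <- dt[, .(len = max(pos) + 1L), by = chrom]
  setNames(out$len, out$chrom)
}

# union of bp covered by a set of half-open intervals (numeric vectors)
union_bp <- function(start, end) {
  if (!length(start)) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce) ce <- max(ce, end[i])
    else { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
  }
  tot + (ce - cs)
}
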