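library(data.table)

# quick cytosine record constructor
rec <- function(chrom, pos, strand = "+", context = "CG", n_meth, n_total) {
  data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, n_meth = as.integer(n_meth),
             n_total = as.integer(n_total))
}

# quick feature constructor
feat <- function(id, chrom, start, end, strand = "+", kind = "PCG",
                 subkind = NA_character_, te_class = NA_character_,
                 te_order = NA_character_) {
  data.table(id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, kind = kind,
             subkind = subkind, te_class = te_class, te_order = te_order)
}

# random interval layout on a few chromosomes (0-based half-open)
random_layout <- function(n, chroms = c("c1", "c2"), len = 50000L,
                          max_width = 3000L) {
  start <- sample.int(len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.table(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width)
}

# quadratic brute-force nearest gap distance (NA when no subject on chrom)
oracle_nearest_distance <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    s <- subject[subject$chrom == query$chrom[i], ]
    if (!nrow(s)) return(NA_integer_)
    as.integer(min(pmax(0L, pmax(query$start[i] - s$end, s$start - query$end[i]))))
  }, integer(1))
}

# quadratic brute-force flank TE count
oracle_flank_count <- function(features, tes, flank = 4000L) {
  vapply(seq_len(nrow(features)), function(i) {
    s <- tes[tes$chrom == features$chrom[i], ]
    if (!nrow(s)) return(0L)
    fs <- features$start[i]; fe <- features$end[i]
    left <- s$end > max(0L, fs - flank) & s$start < fs
    right <- s$end > fe & s$start < fe + flank
    sum(left | right)
  }, integer(1))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(m2, u2, m4, u4) {
  k <- m2 + m4          # total methylated reads
  n2 <- m2 + u2; n4 <- m4 + u4
  lo <- max(0, k - n4); hi <- min(k, n2)
  probs <- stats::dhyper(lo:hi, n2, n4, k)
  p_obs <- stats::dhyper(m2, n2, n4, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent per-bin pooled metagene oracle: explicit bin intervals per
# feature, membership by position comparison
oracle_profile_counts <- function(records, features, context, flank = 2000L,
                                  flank_bin = 100L, body_bins = 20L) {
  nf <- ceiling(flank / flank_bin)
  nb <- 2L * nf + body_bins
  n_meth <- numeric(nb); n_total <- numeric(nb)
  keep <- records$context == context & records$n_total > 0L
  r <- as.data.frame(records)[keep, ]
  for (fi in seq_len(nrow(features))) {
    f <- features[fi, ]
    if (f$end - f$start < body_bins) next
    bins <- vector("list", nb)
    if (f$strand == "-") {
      for (b in seq_len(nf))                      # 5' flank, high coords
        bins[[b]] <- c(f$end + flank - b * flank_bin,
                       f$end + flank - (b - 1L) * flank_bin)
      edges <- f$end - ceiling((f$end - f$start) * (0:body_bins) / body_bins)
      for (b in seq_len(body_bins))
        bins[[nf + b]] <- c(edges[b + 1L], edges[b])
      for (b in seq_len(nf))
        bins[[nf + body_bins + b]] <- c(f$start - b * flank_bin,
                                        f$start - (b - 1L) * flank_bin)
    } else {
      for (b in seq_len(nf))
        bins[[b]] <- c(f$start - flank + (b - 1L) * flank_bin,
                       f$start - flank + b * flank_bin)
      edges <- f$start + ceiling((f$end - f$start) * (0:body_bins) / body_bins)
      for (b in seq_len(body_bins))
        bins[[nf + b]] <- c(edges[b], edges[b + 1L])
      for (b in seq_len(nf))
        bins[[nf + body_bins + b]] <- c(f$end + (b - 1L) * flank_bin,
                                        f$end + b * flank_bin)
    }
    rc <- r[r$chrom == f$chrom, ]
    for (b in seq_len(nb)) {
      inb <- rc$pos >= bins[[b]][1] & rc$pos < bins[[b]][2]
      n_meth[b] <- n_meth[b] + sum(rc$n_meth[inb])
      n_total[b] <- n_total[b] + sum(rc$n_total[inb])
    }
  }
  data.table(bin = seq_len(nb), n_meth = n_meth, n_total = n_total)
}

# deterministic toy site table spanning ~50 windows on one chromosome;
# a block of sites gets a large group difference
toy_dmr_sites <- function(seed = 13, n = 260, len = 5200L) {
  set.seed(seed)
  pos <- sort(sample.int(len, n) - 1L)
  base <- runif(n, 0.2, 0.5)
  t2 <- sample(4:30, n, TRUE); t4 <- sample(4:30, n, TRUE)
  p4 <- base
  p4[pos >= 2000 & pos < 2600] <- base[pos >= 2000 & pos < 2600] + 0.45
  r2 <- rec("c1", pos, context = "CG",
            n_meth = rbinom(n, t2, base), n_total = t2)
  r4 <- rec("c1", pos, context = "CG",
            n_meth = rbinom(n, t4, pmin(1, p4)), n_total = t4)
  list(r2 = r2, r4 = r4, len = len)
}

# small simulated experiment shared across tests (cached per session)
small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_chroms = 1L, chrom_length = 3e5,
                               planted_dmr_n = 5L, replicates = 2L)
      cache <<- list(cfg = cfg, x = simulate_experiment(cfg, seed = 42L))
    }
    cache
  }
})
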