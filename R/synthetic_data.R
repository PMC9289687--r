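#' Configuration of the synthetic WGBS experiment
#'
#' Defines the study conditions emulated by the generator: a small plant
#' genome whose TE complement covers ~60% of the sequence, gene and
#' lncRNA densities scaled from a ~580-Mb genome carrying ~33k PCGs and
#' ~13.5k lncRNAs, per-stratum methylation baselines calibrated so that
#' the genome-wide weighted levels land near mCG 0.67 / mCHG 0.49 /
#' mCHH 0.06, metagene body shapes (CG body peak, CHG/CHH body dip for
#' genes), negative-binomial sequencing depth around 30x, a symmetric
#' conversion/sequencing error rate of 0.005, three replicates per
#' cytotype, planted CG DMRs (delta 0.4) and expression coupled to TE
#' proximity (suppression for PCGs, activation for lncRNAs).
#'
#' @param ... overrides of any default listed below.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_chroms = 2L,
    chrom_length = 1e6,
    gc = 0.36,
    # feature densities per Mb and log-normal length models (bp)
    pcg_per_mb = 57, pcg_len_meanlog = log(3000), pcg_len_sdlog = 0.45,
    lncrna_per_mb = 23, lnc_len_meanlog = log(900), lnc_len_sdlog = 0.5,
    linc_fraction = 0.42,
    te_bp_fraction = 0.60, te_len_meanlog = log(3000), te_len_sdlog = 0.7,
    te_order_weights = c(Gypsy = 0.35, Copia = 0.15, LINE = 0.05,
                         LTR_other = 0.08, SINE = 0.01, MITE = 0.12,
                         Helitron = 0.08, hAT = 0.07, Stowaway = 0.03,
                         Harbinger = 0.02, other = 0.04),
    # fraction of gene bodies kept free of TE insertions
    te_free_gene_fraction = 0.40,
    # baseline methylation probability per stratum and context
    pi_intergenic = c(CG = 0.34, CHG = 0.35, CHH = 0.043),
    pi_pcg_body = c(CG = 0.60, CHG = 0.10, CHH = 0.02),
    pi_lncrna_body = c(CG = 0.65, CHG = 0.40, CHH = 0.06),
    pi_te_body = c(CG = 0.79, CHG = 0.63, CHH = 0.070),
    pi_te_order = list(Gypsy = c(CG = 0.85, CHG = 0.68, CHH = 0.08),
                       Copia = c(CG = 0.82, CHG = 0.65, CHH = 0.08),
                       MITE = c(CG = 0.70, CHG = 0.52, CHH = 0.10)),
    # multiplicative metagene body shapes (CG peak, CHG/CHH dip)
    body_shape = list(PCG = c(CG = 1.15, CHG = 0.5, CHH = 0.5),
                      lncRNA = c(CG = 1.05, CHG = 0.8, CHH = 0.8)),
    shape_ramp = 0.1,
    # planted DMRs: NULL means auto-plant with the settings below
    planted_dmrs = NULL,
    planted_dmr_n = 20L, planted_dmr_context = "CG",
    planted_dmr_delta = 0.4, planted_dmr_width = 400L,
    planted_dmr_min_sites = 10L, planted_dmr_direction = "hyper",
    # sequencing model
    depth_mean = 30, depth_dispersion = 5, error_rate = 0.005,
    replicates = 3L,
    # expression model: log FPKM = intercept + dist_slope * log10(1 + d)
    #                   + count_slope * flank TE count + N(0, sigma)
    expr_intercept = c(PCG = 1.0, lncRNA = 0.2),
    expr_dist_slope = c(PCG = 0.5, lncRNA = -0.5),
    expr_count_slope = c(PCG = -0.10, lncRNA = 0.10),
    expr_sigma = c(PCG = 0.9, lncRNA = 0.9),
    expr_none_fraction = c(PCG = 0.25, lncRNA = 0.35),
    expr_flank = 4000L, expr_max_distance = 10000L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown simulation_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  probs <- c(cfg$pi_intergenic, cfg$pi_pcg_body, cfg$pi_lncrna_body,
             cfg$pi_te_body, unlist(cfg$pi_te_order), cfg$error_rate, cfg$gc)
  if (any(probs < 0 | probs > 1))
    stop("all baseline probabilities, gc and error_rate must lie in [0, 1]")
  if (cfg$depth_mean < 1) stop("depth_mean must be >= 1")
  if (cfg$n_chroms < 1 || cfg$chrom_length < 1000)
    stop("need n_chroms >= 1 and chrom_length >= 1000")
  if (cfg$te_bp_fraction < 0 || cfg$te_bp_fraction >= 1)
    stop("te_bp_fraction must lie in [0, 1)")
  if (!is.null(cfg$planted_dmrs)) {
    pd <- as.data.table(cfg$planted_dmrs)
    need <- c("chrom", "start", "end", "context", "delta")
    if (length(setdiff(need, names(pd))))
      stop("planted_dmrs needs columns ", paste(need, collapse = ", "))
  }
  invisible(cfg)
}

# non-overlapping intervals laid down by an alternating gap/length walk
.walk_place <- function(len, n_target, meanlog, sdlog, min_len = 200) {
  if (n_target < 1) return(data.table(start = integer(), end = integer()))
  mean_len <- exp(meanlog + sdlog^2 / 2)
  mean_gap <- max(50, len / n_target - mean_len)
  starts <- integer(); ends <- integer()
  cur <- rexp(1, 1 / mean_gap)
  while (cur < len - min_len) {
    l <- min(50000, max(min_len, round(rlnorm(1, meanlog, sdlog))))
    e <- min(len, cur + l)
    starts <- c(starts, as.integer(round(cur))); ends <- c(ends, as.integer(e))
    cur <- e + rexp(1, 1 / mean_gap) + 1
  }
  data.table(start = starts, end = ends)
}

#' Simulate a genome with gene, lncRNA and TE annotations
#'
#' Generates random chromosome sequences at the configured GC fraction
#' and places features: non-overlapping PCG bodies, lncRNAs (the
#' configured lincRNA fraction placed strictly intergenic), and TEs drawn
#' until their union covers the target fraction of the genome. A
#' configured fraction of gene bodies is protected from TE insertion so
#' that TE-free genes exist for proximity analyses. Reproducible for a
#' given seed.
#'
#' @param config [simulation_config()] object.
#' @param seed integer seed.
#' @return list with `genome` (named character vector) and `features`
#'   (feature table).
#' @export
simulate_genome <- function(config = simulation_config(), seed = 1L) {
  .validate_sim_config(config)
  set.seed(substream_seed(seed, "genome"))
  L <- as.integer(config$chrom_length)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  base_p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
              G = config$gc / 2, T = (1 - config$gc) / 2)
  genome <- vapply(chroms, function(ch)
    paste(sample(names(base_p), L, replace = TRUE, prob = base_p),
          collapse = ""), character(1))

  feats <- list()
  for (ch in chroms) {
    n_pcg_target <- config$pcg_per_mb * L / 1e6
    pcg <- NULL
    for (try in seq_len(20L)) {   # bounded retries for short chromosomes
      cand <- .walk_place(L, n_pcg_target,
                          config$pcg_len_meanlog, config$pcg_len_sdlog)
      if (nrow(cand) >= floor(0.5 * n_pcg_target)) { pcg <- cand; break }
    }
    if (is.null(pcg))
      stop("could not place the requested PCG density on ", ch)
    pcg[, `:=`(chrom = ch, kind = "PCG",
               strand = sample(c("+", "-"), .N, replace = TRUE),
               subkind = NA_character_,
               te_class = NA_character_, te_order = NA_character_)]

    empty_rows <- data.table(start = integer(), end = integer(),
                             chrom = character(), kind = character(),
                             strand = character(), subkind = character(),
                             te_class = character(), te_order = character())
    n_lnc <- round(config$lncrna_per_mb * L / 1e6)
    lnc_rows <- list(); attempts <- 0L
    while (length(lnc_rows) < n_lnc && attempts < 50L * n_lnc) {
      attempts <- attempts + 1L
      l <- min(20000, max(200, round(rlnorm(1, config$lnc_len_meanlog,
                                            config$lnc_len_sdlog))))
      s <- sample.int(L - l, 1L) - 1L
      linc <- runif(1) < config$linc_fraction
      if (linc && any(pcg$start < s + l & pcg$end > s)) next
      lnc_rows[[length(lnc_rows) + 1L]] <-
        data.table(start = s, end = s + l, chrom = ch, kind = "lncRNA",
                   strand = sample(c("+", "-"), 1L),
                   subkind = if (linc) "lincRNA" else "other",
                   te_class = NA_character_, te_order = NA_character_)
    }
    if (length(lnc_rows) < n_lnc)
      stop("could not place the requested lncRNA density on ", ch)
    lnc <- if (length(lnc_rows)) rbindlist(lnc_rows) else copy(empty_rows)

    # protect a fraction of gene bodies from TE insertion
    genes <- rbind(pcg, lnc)
    prot_i <- which(runif(nrow(genes)) < config$te_free_gene_fraction)
    prot <- genes[prot_i, .(start, end)]

    target <- config$te_bp_fraction * L
    te <- copy(empty_rows)
    if (target > 0) {
      te_rows <- list(); attempts <- 0L; covered <- 0
      max_attempts <- 50L * ceiling(target / exp(config$te_len_meanlog))
      while (covered < target && attempts < max_attempts) {
        attempts <- attempts + 1L
        l <- min(30000, max(100, round(rlnorm(1, config$te_len_meanlog,
                                              config$te_len_sdlog))))
        s <- sample.int(max(1L, L - l), 1L) - 1L
        if (nrow(prot) && any(prot$start < s + l & prot$end > s)) next
        te_rows[[length(te_rows) + 1L]] <- c(s, s + l)
        if (length(te_rows) %% 10L == 0L) {
          m <- do.call(rbind, te_rows)
          covered <- union_bp(m[, 1], m[, 2])
        }
      }
      if (!length(te_rows))
        stop("could not place any TE on ", ch)
      m <- do.call(rbind, te_rows)
      covered <- union_bp(m[, 1], m[, 2])
      if (covered < (config$te_bp_fraction - 0.05) * L)
        stop("could not reach the target TE fraction on ", ch,
             " (realised ", round(covered / L, 3), ")")
      ord <- sample(names(config$te_order_weights), nrow(m), replace = TRUE,
                    prob = config$te_order_weights)
      te <- data.table(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                       chrom = ch, kind = "TE", strand = ".",
                       subkind = NA_character_,
                       te_class = unname(TE_CLASS_OF[ord]), te_order = ord)
    }
    feats[[ch]] <- rbind(pcg, lnc, te, fill = TRUE)
  }
  features <- rbindlist(feats)
  setorder(features, chrom, start, end)
  features[, id := sprintf("%s_%05d", c(PCG = "PCG", lncRNA = "LNC",
                                        TE = "TE")[kind],
                           seq_len(.N)), by = kind]
  setcolorder(features, FEATURE_COLS)
  list(genome = genome, features = validate_features(features))
}

# relative body position (0..1) -> trapezoidal ramp multiplier weight
.shape_weight <- function(x, ramp) pmin(1, pmin(x, 1 - x) / ramp)

#' True per-cytosine methylation probabilities of a simulated genome
#'
#' Deterministic stratum model: every cytosine site takes the baseline of
#' its stratum (TE body by order, else PCG body, else lncRNA body, else
#' intergenic), gene-body sites are modulated by the metagene shape
#' multiplier (ramped CG peak, CHG/CHH dip), and sites inside planted
#' DMRs of the matching context are shifted by the planted delta for the
#' 4x cytotype. Probabilities are clipped to `[0, 1]`.
#'
#' @param sites site table from [cytosine_sites()] (rows with `NA`
#'   context are dropped).
#' @param features feature table.
#' @param config [simulation_config()] object.
#' @param cytotype "2x" or "4x".
#' @param planted_dmrs optional DMR truth table overriding
#'   `config$planted_dmrs`.
#' @return numeric vector of probabilities aligned with the (filtered)
#'   site table; the filtered table is attached as attribute `sites`.
#' @export
true_methylation_prob <- function(sites, features, config, cytotype = "2x",
                                  planted_dmrs = NULL) {
  if (!cytotype %in% c("2x", "4x")) stop("cytotype must be 2x or 4x")
  sites <- as.data.table(sites)[!is.na(context)]
  features <- validate_features(features)
  p <- unname(unlist(config$pi_intergenic)[sites$context])

  overlay <- function(kind_name, base_pi, shaped) {
    fs <- features[kind == kind_name]
    if (!nrow(fs)) return()
    fx <- fs[, .(id, chrom, strand, fstart = start, fend = end,
                 start, end = end - 1L)]
    rx <- sites[, .(chrom, start = pos, end = pos, row = .I,
                    context, strand)]
    setkey(fx, chrom, start, end)
    hits <- foverlaps(rx, fx, type = "within", nomatch = NULL)
    hits <- hits[!duplicated(row)]
    if (!nrow(hits)) return()
    newp <- unname(base_pi[hits$context])
    if (shaped) {
      rel <- ifelse(hits$strand == "-",
                    (hits$fend - 1L - hits$i.start) / (hits$fend - hits$fstart),
                    (hits$i.start - hits$fstart) / (hits$fend - hits$fstart))
      amp <- unname(unlist(config$body_shape[[kind_name]])[hits$context])
      mult <- 1 + (amp - 1) * .shape_weight(rel, config$shape_ramp)
      newp <- newp * mult
    }
    p[hits$row] <<- newp
  }
  overlay("lncRNA", unlist(config$pi_lncrna_body), shaped = TRUE)
  overlay("PCG", unlist(config$pi_pcg_body), shaped = TRUE)

  te <- features[kind == "TE"]
  if (nrow(te)) {
    fx <- te[, .(te_order, chrom, start, end = end - 1L)]
    rx <- sites[, .(chrom, start = pos, end = pos, row = .I, context)]
    setkey(fx, chrom, start, end)
    hits <- foverlaps(rx, fx, type = "within", nomatch = NULL)
    hits <- hits[!duplicated(row)]
    if (nrow(hits)) {
      base <- unname(unlist(config$pi_te_body)[hits$context])
      for (o in names(config$pi_te_order)) {
        sel <- hits$te_order == o
        if (any(sel))
          base[sel] <- unname(unlist(config$pi_te_order[[o]])[hits$context[sel]])
      }
      p[hits$row] <- base
    }
  }

  pd <- planted_dmrs %||% config$planted_dmrs
  if (!is.null(pd) && cytotype == "4x") {
    pd <- as.data.table(pd)
    for (i in seq_len(nrow(pd))) {
      sel <- sites$chrom == pd$chrom[i] & sites$pos >= pd$start[i] &
        sites$pos < pd$end[i]
      if (pd$context[i] != "allC") sel <- sel & sites$context == pd$context[i]
      p[sel] <- p[sel] + pd$delta[i]
    }
  }
  p <- pmin(1, pmax(0, p))
  attr(p, "sites") <- sites
  p
}

#' Simulate one bisulfite methylome sample
#'
#' For every reference cytosine with a defined context: sequencing depth
#' is drawn from a negative binomial (so uncovered cytosines occur and
#' the coverage filter downstream is exercised), and the methylated read
#' count from `Binomial(depth, p(1 - eps) + (1 - p) eps)` where `p` is
#' the site's true methylation probability and `eps` the symmetric
#' conversion/sequencing error rate. Randomness is drawn from a
#' per-(cytotype, replicate, chromosome) substream of the seed so
#' results do not depend on iteration order.
#'
#' @param genome named character vector (from [simulate_genome()]).
#' @param features feature table.
#' @param config [simulation_config()] object.
#' @param cytotype "2x" or "4x".
#' @param replicate replicate index (1-based).
#' @param seed integer base seed of the experiment.
#' @param sites optional precomputed [cytosine_sites()] table.
#' @param planted_dmrs optional DMR truth table.
#' @return cytosine record table (chrom, pos, strand, context, n_meth,
#'   n_total), including uncovered rows with `n_total = 0`.
#' @export
simulate_methylome <- function(genome, features, config = simulation_config(),
                               cytotype = "2x", replicate = 1L, seed = 1L,
                               sites = NULL, planted_dmrs = NULL) {
  if (!cytotype %in% c("2x", "4x")) stop("cytotype must be 2x or 4x")
  if (is.null(sites)) sites <- cytosine_sites(genome)
  p <- true_methylation_prob(sites, features, config, cytotype, planted_dmrs)
  st <- attr(p, "sites")
  eps <- config$error_rate
  out <- vector("list", length(unique(st$chrom)))
  names(out) <- unique(st$chrom)
  for (ch in names(out)) {
    idx <- which(st$chrom == ch)
    set.seed(substream_seed(seed, "methylome", cytotype, replicate, ch))
    depth <- rnbinom(length(idx), mu = config$depth_mean,
                     size = config$depth_dispersion)
    pm <- p[idx] * (1 - eps) + (1 - p[idx]) * eps
    nm <- rbinom(length(idx), depth, pm)
    out[[ch]] <- st[idx][, .(chrom, pos, strand, context,
                             n_meth = nm, n_total = depth)]
  }
  rbindlist(out)
}

#' Choose intergenic regions suitable for planting DMRs
#'
#' Samples non-overlapping intergenic windows that contain at least
#' `min_sites` cytosines of the requested context, so every planted DMR
#' is detectable in principle, and checks that the shifted group mean
#' stays inside `[0, 1]`.
#'
#' @param genome named character vector.
#' @param features feature table.
#' @param config [simulation_config()] object.
#' @param n number of regions.
#' @param context DMR context.
#' @param width region width in bp.
#' @param delta planted difference (positive).
#' @param direction "hyper" (4x above 2x) or "hypo".
#' @param min_sites minimum context sites per region.
#' @param seed integer seed.
#' @param sites optional precomputed site table.
#' @return truth `data.table` with chrom, start, end, context, delta
#'   (signed), direction, n_sites.
#' @export
select_dmr_regions <- function(genome, features, config = simulation_config(),
                               n = 20L, context = "CG", width = 400L,
                               delta = 0.4, direction = "hyper",
                               min_sites = 10L, seed = 1L, sites = NULL) {
  if (!context %in% c(CONTEXTS, "allC")) stop("unknown context: ", context)
  if (is.null(sites)) sites <- cytosine_sites(genome)
  sites <- as.data.table(sites)[!is.na(context)]
  signed <- if (direction == "hyper") abs(delta) else -abs(delta)
  base <- unlist(config$pi_intergenic)
  shifted <- base[if (context == "allC") CONTEXTS else context] + signed
  if (any(shifted < 0 | shifted > 1))
    stop("planted delta pushes the intergenic baseline outside [0, 1]")
  set.seed(substream_seed(seed, "dmr_regions"))
  lens <- vapply(genome, nchar, integer(1))
  cand <- scan_windows(lens, window = as.integer(width),
                       step = as.integer(width))
  # intergenic only: baseline known and uniform inside the region
  for (k in FEATURE_KINDS) {
    fs <- features[kind == k]
    if (!nrow(fs)) next
    keep <- rep(TRUE, nrow(cand))
    for (ch in unique(cand$chrom)) {
      ci <- which(cand$chrom == ch)
      fch <- fs[chrom == ch]
      if (!nrow(fch)) next
      keep[ci] <- !vapply(ci, function(i)
        any(fch$start < cand$end[i] & fch$end > cand$start[i]), logical(1))
    }
    cand <- cand[keep]
  }
  if (!nrow(cand)) stop("no intergenic candidate regions available")
  keep_ctx <- context == "allC" | sites$context == context
  ctx_sites <- sites[keep_ctx]
  sx <- ctx_sites[, .(chrom, start = pos, end = pos)]
  cx <- copy(cand)[, `:=`(wstart = start, end2 = end - 1L)]
  setkey(cx, chrom, wstart, end2)
  counts <- foverlaps(sx, cx, by.x = c("chrom", "start", "end"),
                      by.y = c("chrom", "wstart", "end2"),
                      type = "within", nomatch = NULL)[
    , .N, by = .(chrom, wstart)]
  cand <- merge(cand, counts, by.x = c("chrom", "start"),
                by.y = c("chrom", "wstart"), all.x = TRUE)
  cand[is.na(N), N := 0L]
  cand <- cand[N >= min_sites]
  if (nrow(cand) < n)
    stop("only ", nrow(cand), " candidate regions with >= ", min_sites,
         " ", context, " sites; requested ", n)
  pick <- cand[sample.int(nrow(cand), n)]
  setorder(pick, chrom, start)
  pick[, .(chrom, start, end, context = ..context, delta = signed,
           direction = ..direction, n_sites = N)]
}

#' Simulate expression coupled to TE proximity
#'
#' Draws FPKM values for PCGs and lncRNAs under the model
#' `log FPKM = intercept_kind + dist_slope_kind * log10(1 + d) +
#' count_slope_kind * n_TE_flank + N(0, sigma)`, where `d` is the gap
#' distance to the nearest TE (capped at `expr_max_distance`) and
#' `n_TE_flank` the TE count within the 4-kb flanks. With the default
#' signs, TE proximity and abundance suppress PCG expression and activate
#' lncRNA expression. The configured fraction of features per kind with
#' the lowest model mean is silenced (FPKM 0 in every sample, the "none"
#' class), so silencing follows TE burden as expression does. Both
#' cytotypes share the
#' same expression model (dosage-neutral truth); replicates differ only
#' by noise.
#'
#' @param features feature table containing PCGs and/or lncRNAs.
#' @param tes TE feature table (required when any slope is nonzero).
#' @param config [simulation_config()] object.
#' @param seed integer seed.
#' @return list with `expression` (long table: id, cytotype, replicate,
#'   fpkm) and `coefficients` (the truth model per kind, including the
#'   per-feature distances/counts used).
#' @export
simulate_expression <- function(features, tes = NULL,
                                config = simulation_config(), seed = 1L) {
  features <- validate_features(features)
  genes <- features[kind %in% c("PCG", "lncRNA")]
  if (!nrow(genes)) stop("no PCG/lncRNA features to express")
  slopes_used <- any(unlist(config$expr_dist_slope) != 0) ||
    any(unlist(config$expr_count_slope) != 0)
  if (is.null(tes)) tes <- features[kind == "TE"]
  if (slopes_used && !nrow(tes))
    stop("TE index required: expression slopes are nonzero but no TEs given")
  set.seed(substream_seed(seed, "expression"))
  if (nrow(tes)) {
    prox <- nearest_te(genes, tes)
    cnts <- count_flank_tes(genes, tes, flank = config$expr_flank)
    genes <- merge(genes, prox[, .(id, distance)], by = "id")
    genes <- merge(genes, cnts, by = "id")
    genes[is.na(distance), distance := config$expr_max_distance]
    genes[, distance := pmin(distance, config$expr_max_distance)]
  } else {
    genes[, `:=`(distance = config$expr_max_distance, te_count_flank = 0L)]
  }
  genes[, mu := unname(unlist(config$expr_intercept)[kind]) +
          unname(unlist(config$expr_dist_slope)[kind]) * log10(1 + distance) +
          unname(unlist(config$expr_count_slope)[kind]) * te_count_flank]
  # the silenced class: the configured fraction with the lowest model mean
  # per kind, so silencing is coupled to TE burden like expression itself
  genes[, none := FALSE]
  for (kd in unique(genes$kind)) {
    idx <- which(genes$kind == kd)
    k <- round(unname(unlist(config$expr_none_fraction)[kd]) * length(idx))
    if (k > 0) {
      o <- idx[order(genes$mu[idx], genes$id[idx])]
      genes$none[o[seq_len(k)]] <- TRUE
    }
  }
  rows <- CJ(id = genes$id, cytotype = c("2x", "4x"),
             replicate = seq_len(config$replicates))
  rows <- merge(rows, genes[, .(id, kind, mu, none)], by = "id")
  rows[, fpkm := ifelse(none, 0,
                        exp(rnorm(.N, mean = mu,
                                  sd = unname(unlist(config$expr_sigma)[kind]))))]
  setorder(rows, id, cytotype, replicate)
  list(expression = rows[, .(id, cytotype, replicate, fpkm)],
       coefficients = list(
         intercept = config$expr_intercept,
         dist_slope = config$expr_dist_slope,
         count_slope = config$expr_count_slope,
         sigma = config$expr_sigma,
         none_fraction = config$expr_none_fraction,
         per_feature = genes[, .(id, kind, distance, te_count_flank, mu, none)]))
}

#' Run the full synthetic experiment
#'
#' Chains [simulate_genome()], DMR planting ([select_dmr_regions()] when
#' `config$planted_dmrs` is `NULL` and `planted_dmr_n > 0`),
#' [simulate_methylome()] for every (cytotype, replicate), and
#' [simulate_expression()], and assembles the truth record needed to
#' score downstream calls. When `outdir` is given, all on-disk dialects
#' are written (FASTA, GFF3, TE-TSV, per-sample cytosine TSVs,
#' expression TSV, truth JSON).
#'
#' @param config [simulation_config()] object.
#' @param seed integer seed for every stream.
#' @param outdir optional output directory.
#' @return list with genome, features, records (nested list
#'   `records[[cytotype]][[replicate]]`), expression, truth (planted
#'   DMRs, expression coefficients, per-site true probabilities for both
#'   cytotypes) and, when written, `paths`.
#' @export
simulate_experiment <- function(config = simulation_config(), seed = 1L,
                                outdir = NULL) {
  g <- simulate_genome(config, seed)
  sites <- cytosine_sites(g$genome)
  planted <- config$planted_dmrs
  if (is.null(planted) && config$planted_dmr_n > 0) {
    planted <- select_dmr_regions(
      g$genome, g$features, config, n = config$planted_dmr_n,
      context = config$planted_dmr_context, width = config$planted_dmr_width,
      delta = config$planted_dmr_delta,
      direction = config$planted_dmr_direction,
      min_sites = config$planted_dmr_min_sites, seed = seed, sites = sites)
  } else if (!is.null(planted)) {
    planted <- as.data.table(planted)
    if (!"direction" %in% names(planted))
      planted[, direction := ifelse(delta >= 0, "hyper", "hypo")]
  }
  records <- list()
  for (ct in c("2x", "4x")) {
    records[[ct]] <- lapply(seq_len(config$replicates), function(r)
      simulate_methylome(g$genome, g$features, config, ct, r, seed,
                         sites = sites, planted_dmrs = planted))
    names(records[[ct]]) <- paste0("rep", seq_len(config$replicates))
  }
  ex <- simulate_expression(g$features, config = config, seed = seed)
  p2 <- true_methylation_prob(sites, g$features, config, "2x", planted)
  p4 <- true_methylation_prob(sites, g$features, config, "4x", planted)
  site_truth <- copy(attr(p2, "sites"))[, `:=`(p_2x = as.numeric(p2),
                                               p_4x = as.numeric(p4))]
  truth <- list(planted_dmrs = planted, expression = ex$coefficients,
                site_truth = site_truth)
  out <- list(genome = g$genome, features = g$features, records = records,
              expression = ex$expression, truth = truth)
  if (!is.null(outdir)) out$paths <- .write_experiment(out, config, outdir)
  out
}

.write_experiment <- function(x, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$genome <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(x$genome), paths$genome)
  paths$features <- file.path(outdir, "features.gff3")
  write_features(x$features[kind != "TE"], paths$features, "GFF3")
  paths$tes <- file.path(outdir, "tes.tsv")
  write_features(x$features, paths$tes, "TE-TSV")
  for (ct in names(x$records)) for (rp in names(x$records[[ct]])) {
    key <- paste0("cytosines_", ct, "_", rp)
    paths[[key]] <- file.path(outdir, paste0(key, ".tsv"))
    write_cytosine_table(x$records[[ct]][[rp]], paths[[key]])
  }
  paths$expression <- file.path(outdir, "expression.tsv")
  write_expression_table(x$expression, paths$expression)
  paths$truth <- file.path(outdir, "truth.json")
  truth_json <- list(
    planted_dmrs = x$truth$planted_dmrs,
    expression_coefficients = x$truth$expression[
      setdiff(names(x$truth$expression), "per_feature")])
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths
}

#' Score DMR calls against the planted truth
#'
#' A planted region counts as recovered when at least one called DMR of
#' the same context overlaps it; a called DMR not overlapping any
#' planted region of its context is a false positive.
#'
#' @param dmrs called DMR table.
#' @param truth_dmrs planted truth table (chrom, start, end, context).
#' @return list with sensitivity, fdr, n_called, n_truth, n_recovered,
#'   n_false.
#' @export
score_dmr_calls <- function(dmrs, truth_dmrs) {
  dmrs <- as.data.table(dmrs)
  truth_dmrs <- as.data.table(truth_dmrs)
  if (!nrow(truth_dmrs)) stop("empty truth table")
  hit <- function(a, b)   # does any row of b overlap interval a?
    any(b$chrom == a$chrom & b$start < a$end & b$end > a$start &
          (b$context == a$context | b$context == "allC" | a$context == "allC"))
  recovered <- vapply(seq_len(nrow(truth_dmrs)), function(i)
    nrow(dmrs) > 0 && hit(truth_dmrs[i], dmrs), logical(1))
  false <- if (nrow(dmrs)) vapply(seq_len(nrow(dmrs)), function(i)
    !hit(dmrs[i], truth_dmrs), logical(1)) else logical(0)
  list(sensitivity = mean(recovered),
       fdr = if (nrow(dmrs)) mean(false) else 0,
       n_called = nrow(dmrs), n_truth = nrow(truth_dmrs),
       n_recovered = sum(recovered), n_false = sum(false))
}
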