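#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Top-level fields:
#' * `mode`: "synthetic" (default; inputs come from the simulator) or
#'   "real" (paths below must exist).
#' * `outdir`: output directory (required).
#' * `seed`: integer seed used by every stochastic stage.
#' * `paths` (real mode): `genome` (FASTA), `features` (GFF3), `tes`
#'   (TE-TSV), `cytosines` (named list sample -> TSV; sample names must
#'   look like `2x_rep1`), `expression` (TSV), and optional
#'   `cytosines_one_based` flag.
#' * `sim`: overrides passed to [simulation_config()].
#' * `call`: overrides for [methylation_call_params()].
#' * `dmr`: `contexts` (default CG, CHG, CHH), `window`, `step`.
#' * `profile`: `flank`, `flank_bin`, `body_bins`.
#' * `associate`: `flank`, `none_threshold`, `distance_bin`,
#'   `max_distance`.
#' * `log_level`: "info" (default) or "quiet".
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- list(mode = "synthetic", outdir = NULL, seed = 1L, paths = list(),
              sim = list(), call = list(), dmr = list(), profile = list(),
              associate = list(), log_level = "info")
  cfg[names(config)] <- config
  if (!cfg$mode %in% c("synthetic", "real"))
    stop("config field 'mode' must be 'synthetic' or 'real'")
  if (is.null(cfg$outdir)) stop("config field 'outdir' is required")
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$mode == "real") {
    need <- c("genome", "features", "tes", "cytosines", "expression")
    for (f in need)
      if (is.null(cfg$paths[[f]]))
        stop("config field 'paths.", f, "' is required in real mode")
    flat <- c(cfg$paths$genome, cfg$paths$features, cfg$paths$tes,
              unlist(cfg$paths$cytosines), cfg$paths$expression)
    missing <- flat[!file.exists(flat)]
    if (length(missing))
      stop("config paths do not exist: ", paste(missing, collapse = ", "))
    if (is.null(names(cfg$paths$cytosines)) ||
        !all(grepl("^[24]x_rep[0-9]+$", names(cfg$paths$cytosines))))
      stop("config field 'paths.cytosines' must be a named list with names ",
           "like 2x_rep1, 4x_rep2")
  }
  cfg$sim_config <- do.call(simulation_config, cfg$sim)
  cfg$call_params <- do.call(methylation_call_params, cfg$call)
  cfg$dmr$contexts <- cfg$dmr$contexts %||% c("CG", "CHG", "CHH")
  cfg$dmr$window <- as.integer(cfg$dmr$window %||% 200L)
  cfg$dmr$step <- as.integer(cfg$dmr$step %||% 100L)
  cfg$profile$flank <- as.integer(cfg$profile$flank %||% 2000L)
  cfg$profile$flank_bin <- as.integer(cfg$profile$flank_bin %||% 100L)
  cfg$profile$body_bins <- as.integer(cfg$profile$body_bins %||% 20L)
  cfg$associate$flank <- as.integer(cfg$associate$flank %||% 4000L)
  cfg$associate$none_threshold <- cfg$associate$none_threshold %||% 0.1
  cfg$associate$distance_bin <- as.integer(cfg$associate$distance_bin %||% 500L)
  cfg$associate$max_distance <- as.integer(cfg$associate$max_distance %||% 8000L)
  structure(cfg, class = "pipeline_config")
}

.pl_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  msg <- paste0("[", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "] ", ...)
  message(msg)
  logfile <- file.path(cfg$outdir, "run.log")
  if (dir.exists(cfg$outdir)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible()
}

# load inputs: either the synthetic experiment or the configured files
.pipeline_inputs <- function(cfg) {
  if (cfg$mode == "synthetic") {
    sim_dir <- file.path(cfg$outdir, "sim")
    x <- simulate_experiment(cfg$sim_config, seed = cfg$seed, outdir = sim_dir)
    samples <- list()
    for (ct in names(x$records)) for (rp in names(x$records[[ct]]))
      samples[[paste0(ct, "_", rp)]] <- x$records[[ct]][[rp]]
    list(genome = x$genome, features = x$features, samples = samples,
         expression = x$expression, truth = x$truth)
  } else {
    genome <- as.character(Biostrings::readDNAStringSet(cfg$paths$genome))
    names(genome) <- sub("\\s.*$", "", names(genome))
    features <- rbind(read_features(cfg$paths$features, "GFF3"),
                      read_features(cfg$paths$tes, "TE-TSV"))
    features <- validate_features(features)
    one_based <- isTRUE(cfg$paths$cytosines_one_based)
    samples <- lapply(cfg$paths$cytosines, read_cytosine_table,
                      one_based_input = one_based)
    list(genome = genome, features = features, samples = samples,
         expression = read_expression_table(cfg$paths$expression),
         truth = NULL)
  }
}

.split_cytotype <- function(samples) {
  ct <- sub("_rep.*$", "", names(samples))
  list(`2x` = samples[ct == "2x"], `4x` = samples[ct == "4x"])
}

#' Run the analysis pipeline
#'
#' Subcommands: `simulate` (write the synthetic experiment), `callmc`
#' (methylcytosine calls per sample), `level` (genome-wide, per-chromosome
#' and per-feature-kind weighted levels plus replicate correlations),
#' `profile` (metagene profiles per kind, context and cytotype), `dmr`
#' (DMR calling, annotation, summary), `associate` (TE proximity,
#' overlap classification, expression groups, distance-binned TE
#' methylation, TE-presence expression tests), and `all` (everything in
#' order; `simulate` is skipped in real mode). Outputs are TSV/BED/JSON
#' files under `outdir`; a run manifest with the config hash and seed is
#' written on every invocation. Outputs are deterministic for a fixed
#' config and seed.
#'
#' @param subcommand one of simulate, callmc, level, profile, dmr,
#'   associate, all.
#' @param config [pipeline_config()] input (list or YAML path).
#' @param seed optional seed override.
#' @param outdir optional output-directory override.
#' @return invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "callmc", "level",
                                        "profile", "dmr", "associate"),
                         config = list(), seed = NULL, outdir = NULL) {
  subcommand <- match.arg(subcommand)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(outdir)) config$outdir <- outdir
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "methploid", version = as.character(packageVersion("methploid")),
    r_version = R.version.string, seed = config$seed, mode = config$mode,
    subcommand = subcommand,
    config_hash = .config_hash(config), timestamp = format(Sys.time()))
  jsonlite::write_json(manifest, file.path(config$outdir, "run_manifest.json"),
                       auto_unbox = TRUE)

  .pl_log(config, "loading inputs (mode=", config$mode, ")")
  inputs <- .pipeline_inputs(config)
  paths <- list()
  if (config$mode == "synthetic" && subcommand %in% c("simulate", "all")) {
    paths$sim <- file.path(config$outdir, "sim")
    .pl_log(config, "synthetic experiment written under ", paths$sim)
    if (subcommand == "simulate") return(invisible(paths))
  }
  stages <- if (subcommand == "all")
    c("callmc", "level", "profile", "dmr", "associate") else subcommand
  for (st in stages) {
    .pl_log(config, "stage ", st)
    paths <- c(paths, switch(st,
      callmc = .stage_callmc(config, inputs),
      level = .stage_level(config, inputs),
      profile = .stage_profile(config, inputs),
      dmr = .stage_dmr(config, inputs),
      associate = .stage_associate(config, inputs)))
  }
  invisible(paths)
}

.config_hash <- function(cfg) {
  core <- cfg[setdiff(names(cfg), c("sim_config", "call_params"))]
  raw <- serialize(core, NULL, version = 2)
  # small rolling hash; stable across sessions for identical configs
  h <- 0
  for (b in as.integer(raw)) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.stage_callmc <- function(cfg, inputs) {
  out <- list()
  summ <- list()
  for (nm in names(inputs$samples)) {
    called <- call_methylated(inputs$samples[[nm]], cfg$call_params)
    p <- file.path(cfg$outdir, paste0("calls_", nm, ".tsv"))
    writeLines("#chrom\tpos\tstrand\tcontext\tn_meth\tn_total\tp_meth\tq_meth\tis_methylated", p)
    fwrite(called[, .(chrom, pos, strand, context, n_meth, n_total,
                      p_meth = signif(p_meth, 4), q_meth = signif(q_meth, 4),
                      is_methylated)],
           p, sep = "\t", col.names = FALSE, append = TRUE)
    out[[paste0("calls_", nm)]] <- p
    summ[[nm]] <- called[is_methylated != "uncalled",
                         .(sample = nm, n_called = .N,
                           frac_methylated = mean(is_methylated == "yes")),
                         by = context]
  }
  p <- file.path(cfg$outdir, "call_summary.tsv")
  writeLines("#sample\tcontext\tn_called\tfrac_methylated", p)
  fwrite(rbindlist(summ)[, .(sample, context, n_called,
                             frac_methylated = signif(frac_methylated, 6))],
         p, sep = "\t", col.names = FALSE, append = TRUE)
  out$call_summary <- p
  out
}

.stage_level <- function(cfg, inputs) {
  rows <- list()
  kinds <- split(inputs$features, inputs$features$kind)
  for (nm in names(inputs$samples)) {
    rec <- inputs$samples[[nm]]
    for (ctx in CONTEXTS) {
      rows[[length(rows) + 1L]] <- data.table(
        sample = nm, region = "genome", context = ctx,
        level = weighted_level(rec, ctx))
      for (kd in names(kinds)) {
        reg <- kinds[[kd]][, .(chrom, start, end)]
        rows[[length(rows) + 1L]] <- data.table(
          sample = nm, region = paste0(kd, "_body"), context = ctx,
          level = weighted_level(rec, ctx, region = reg))
      }
    }
  }
  levels <- rbindlist(rows)
  p <- file.path(cfg$outdir, "levels.tsv")
  writeLines("#sample\tregion\tcontext\tlevel", p)
  fwrite(levels[, .(sample, region, context, level = signif(level, 6))],
         p, sep = "\t", col.names = FALSE, append = TRUE)
  out <- list(levels = p)

  by_ct <- .split_cytotype(inputs$samples)
  cors <- list()
  for (ct in names(by_ct)) {
    if (length(by_ct[[ct]]) >= 2L) {
      cm <- replicate_correlation(by_ct[[ct]], window = 10000L)
      cd <- as.data.table(as.table(cm))
      setnames(cd, c("rep_a", "rep_b", "pearson_r"))
      cd[, cytotype := ct]
      cors[[ct]] <- cd
    }
  }
  if (length(cors)) {
    p <- file.path(cfg$outdir, "replicate_correlation.tsv")
    writeLines("#cytotype\trep_a\trep_b\tpearson_r", p)
    fwrite(rbindlist(cors)[, .(cytotype, rep_a, rep_b,
                               pearson_r = signif(pearson_r, 6))],
           p, sep = "\t", col.names = FALSE, append = TRUE)
    out$replicate_correlation <- p
  }
  out
}

.pool_samples <- function(samples) {
  dt <- rbindlist(samples)
  dt[, .(n_meth = sum(as.numeric(n_meth)), n_total = sum(as.numeric(n_total))),
     by = .(chrom, pos, strand, context)]
}

.stage_profile <- function(cfg, inputs) {
  by_ct <- .split_cytotype(inputs$samples)
  rows <- list()
  for (ct in names(by_ct)) {
    if (!length(by_ct[[ct]])) next
    pooled <- .pool_samples(by_ct[[ct]])
    for (kd in FEATURE_KINDS) {
      fs <- inputs$features[kind == kd]
      if (!nrow(fs)) next
      for (ctx in CONTEXTS) {
        pr <- compute_profile(pooled, fs, ctx, flank = cfg$profile$flank,
                              flank_bin = cfg$profile$flank_bin,
                              body_bins = cfg$profile$body_bins)
        rows[[length(rows) + 1L]] <-
          as.data.table(pr)[, .(cytotype = ct, kind = kd, context = ctx,
                                bin, label, level = signif(level, 6),
                                n_meth, n_total)]
      }
    }
  }
  p <- file.path(cfg$outdir, "profiles.tsv")
  writeLines("#cytotype\tkind\tcontext\tbin\tlabel\tlevel\tn_meth\tn_total", p)
  fwrite(rbindlist(rows), p, sep = "\t", col.names = FALSE, append = TRUE)
  list(profiles = p)
}

.stage_dmr <- function(cfg, inputs) {
  by_ct <- .split_cytotype(inputs$samples)
  if (!length(by_ct$`2x`) || !length(by_ct$`4x`))
    stop("DMR calling needs samples for both cytotypes")
  all_dmrs <- list()
  for (ctx in cfg$dmr$contexts) {
    crit <- dmr_criteria(ctx, window = cfg$dmr$window, step = cfg$dmr$step)
    dm <- call_dmrs(by_ct$`2x`, by_ct$`4x`, crit)
    all_dmrs[[ctx]] <- dm
  }
  dmrs <- rbindlist(all_dmrs)
  dmrs <- annotate_dmr_location(dmrs, inputs$features,
                                flank = cfg$associate$flank)
  prefix <- file.path(cfg$outdir, "dmrs")
  write_dmr_output(dmrs, prefix)
  summ <- summarize_dmrs(dmrs)
  p <- file.path(cfg$outdir, "dmr_summary.tsv")
  writeLines("#context\tn\tn_hyper\tn_hypo\thyper_fraction", p)
  if (nrow(summ))
    fwrite(summ[, .(context, n, n_hyper, n_hypo,
                    hyper_fraction = signif(hyper_fraction, 6))],
           p, sep = "\t", col.names = FALSE, append = TRUE)
  list(dmrs_bed = paste0(prefix, ".bed"), dmrs_tsv = paste0(prefix, ".tsv"),
       dmr_summary = p)
}

.stage_associate <- function(cfg, inputs) {
  out <- list()
  tes <- inputs$features[kind == "TE"]
  genes <- inputs$features[kind %in% c("PCG", "lncRNA")]
  if (!nrow(tes) || !nrow(genes))
    stop("association stage needs both genes and TEs")
  prox <- nearest_te(genes, tes)
  cnts <- count_flank_tes(genes, tes, flank = cfg$associate$flank)
  prox <- merge(prox, cnts, by = "id")
  p <- file.path(cfg$outdir, "proximity.tsv")
  writeLines("#id\tkind\tchrom\tnearest_te\tdistance\toverlaps_te_body\tte_count_flank", p)
  fwrite(prox[, .(id, kind, chrom, nearest_te, distance, overlaps_te_body,
                  te_count_flank)],
         p, sep = "\t", col.names = FALSE, append = TRUE)
  out$proximity <- p

  lnc <- inputs$features[kind == "lncRNA"]
  if (nrow(lnc)) {
    oc <- overlap_classification(lnc, tes)
    p <- file.path(cfg$outdir, "lncrna_te_overlap.tsv")
    writeLines("#window\tcategory\tn_overlapped\tfraction", p)
    fwrite(oc[, .(window, category, n_overlapped,
                  fraction = signif(fraction, 6))],
           p, sep = "\t", col.names = FALSE, append = TRUE)
    out$lncrna_te_overlap <- p
  }

  groups <- list()
  tests <- list()
  for (ct in c("2x", "4x")) {
    if (!any(inputs$expression$cytotype == ct)) next
    for (kd in c("PCG", "lncRNA")) {
      ids <- inputs$features[kind == kd, id]
      ex <- inputs$expression[id %in% ids]
      if (!nrow(ex)) next
      gl <- expression_groups(ex, cytotype = ct,
                              none_threshold = cfg$associate$none_threshold)
      gl[, `:=`(cytotype = ct, kind = kd)]
      groups[[paste(ct, kd)]] <- gl
      # TE-presence effect on expression (body overlap)
      px <- merge(gl, prox[, .(id, overlaps_te_body)], by = "id")
      with_te <- px[overlaps_te_body == TRUE, mean_fpkm]
      without <- px[overlaps_te_body == FALSE, mean_fpkm]
      if (length(with_te) >= 2 && length(without) >= 2) {
        gt <- group_tests(log2(1 + without), log2(1 + with_te), "t")
        tests[[paste(ct, kd)]] <- data.table(
          cytotype = ct, kind = kd, comparison = "te_free_vs_te_body",
          mean_fpkm_te_free = mean(without), mean_fpkm_te_body = mean(with_te),
          statistic = gt$statistic, p_value = gt$p_value)
      }
    }
  }
  if (length(groups)) {
    p <- file.path(cfg$outdir, "expression_groups.tsv")
    writeLines("#id\tcytotype\tkind\tmean_fpkm\tgroup", p)
    fwrite(rbindlist(groups)[, .(id, cytotype, kind,
                                 mean_fpkm = signif(mean_fpkm, 6), group)],
           p, sep = "\t", col.names = FALSE, append = TRUE)
    out$expression_groups <- p
  }
  if (length(tests)) {
    p <- file.path(cfg$outdir, "te_expression_tests.tsv")
    writeLines("#cytotype\tkind\tcomparison\tmean_fpkm_te_free\tmean_fpkm_te_body\tstatistic\tp_value", p)
    fwrite(rbindlist(tests)[, .(cytotype, kind, comparison,
                                mean_fpkm_te_free = signif(mean_fpkm_te_free, 6),
                                mean_fpkm_te_body = signif(mean_fpkm_te_body, 6),
                                statistic = signif(statistic, 6),
                                p_value = signif(p_value, 6))],
           p, sep = "\t", col.names = FALSE, append = TRUE)
    out$te_expression_tests <- p
  }

  pooled <- .pool_samples(inputs$samples)
  md <- list()
  for (anchor_kind in c("PCG", "lncRNA")) {
    anchors <- inputs$features[kind == anchor_kind]
    if (!nrow(anchors)) next
    for (ctx in CONTEXTS) {
      m <- methylation_by_distance(tes, anchors, pooled, ctx,
                                   bin = cfg$associate$distance_bin,
                                   max_distance = cfg$associate$max_distance)
      m[, `:=`(anchor = anchor_kind, context = ctx)]
      md[[paste(anchor_kind, ctx)]] <- m
    }
  }
  if (length(md)) {
    p <- file.path(cfg$outdir, "te_methylation_by_distance.tsv")
    writeLines("#anchor\tcontext\tbin_start\tbin_end\tn_tes\tlevel\tn_meth\tn_total", p)
    fwrite(rbindlist(md)[, .(anchor, context, bin_start, bin_end, n_tes,
                             level = signif(level, 6), n_meth, n_total)],
           p, sep = "\t", col.names = FALSE, append = TRUE)
    out$te_methylation_by_distance <- p
  }
  out
}
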