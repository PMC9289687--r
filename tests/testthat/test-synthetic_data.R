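test_that("genome simulation is reproducible and honours zero densities", {
  cfg <- simulation_config(n_chroms = 1L, chrom_length = 1e5,
                           te_bp_fraction = 0, planted_dmr_n = 0L)
  g1 <- simulate_genome(cfg, seed = 5)
  g2 <- simulate_genome(cfg, seed = 5)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$features, g2$features)
  expect_equal(nrow(g1$features[kind == "TE"]), 0L)   # zero TE density
  g3 <- simulate_genome(cfg, seed = 6)
  expect_false(identical(g1$genome, g3$genome))
})

test_that("the realised TE bp fraction lands near its target", {
  cfg <- simulation_config(n_chroms = 1L, chrom_length = 1e6)
  g <- simulate_genome(cfg, seed = 8)
  te <- g$features[kind == "TE"]
  frac <- union_bp(te$start, te$end) / 1e6
  expect_lt(abs(frac - 0.60), 0.05)
  # PCG bodies never overlap each other
  pcg <- g$features[kind == "PCG"][order(start)]
  expect_true(all(pcg$start[-1] >= head(pcg$end, -1)))
  # lincRNAs are intergenic
  linc <- g$features[subkind == "lincRNA"]
  for (i in seq_len(nrow(linc)))
    expect_false(any(pcg$start < linc$end[i] & pcg$end > linc$start[i]))
})

test_that("methylome counts follow the configured probabilities at the edges", {
  cfg0 <- simulation_config(
    n_chroms = 1L, chrom_length = 5e4, te_bp_fraction = 0,
    pcg_per_mb = 0, lncrna_per_mb = 0, planted_dmr_n = 0L,
    pi_intergenic = c(CG = 0, CHG = 0, CHH = 0), error_rate = 0)
  g <- simulate_genome(cfg0, seed = 2)
  r <- simulate_methylome(g$genome, g$features, cfg0, "2x", 1, seed = 2)
  expect_true(all(r$n_meth == 0))                     # p = 0, eps = 0
  cfg1 <- simulation_config(
    n_chroms = 1L, chrom_length = 5e4, te_bp_fraction = 0,
    pcg_per_mb = 0, lncrna_per_mb = 0, planted_dmr_n = 0L,
    pi_intergenic = c(CG = 1, CHG = 1, CHH = 1), error_rate = 0)
  r1 <- simulate_methylome(g$genome, g$features, cfg1, "2x", 1, seed = 2)
  expect_true(all(r1$n_meth == r1$n_total))           # saturation
  expect_error(simulate_methylome(g$genome, g$features, cfg1, "6x", 1, 2),
               "cytotype")
})

test_that("the weighted level estimator recovers the configured baseline", {
  cfg <- simulation_config(
    n_chroms = 1L, chrom_length = 4e5, te_bp_fraction = 0,
    pcg_per_mb = 0, lncrna_per_mb = 0, planted_dmr_n = 0L,
    pi_intergenic = c(CG = 0.67, CHG = 0.49, CHH = 0.06), error_rate = 0)
  g <- simulate_genome(cfg, seed = 3)
  r <- simulate_methylome(g$genome, g$features, cfg, "2x", 1, seed = 3)
  cg <- r[context == "CG"]
  se <- sqrt(0.67 * 0.33 / sum(cg$n_total))
  expect_lt(abs(weighted_level(r, "CG") - 0.67), 3 * se)
})

test_that("per-sample substreams are deterministic and distinct", {
  sx <- small_experiment()
  cfg <- sx$cfg
  g <- list(genome = sx$x$genome, features = sx$x$features)
  again <- simulate_methylome(g$genome, g$features, cfg, "2x", 1, seed = 42L,
                              planted_dmrs = sx$x$truth$planted_dmrs)
  expect_identical(again, sx$x$records[["2x"]][["rep1"]])
  expect_false(identical(sx$x$records[["2x"]][["rep1"]]$n_meth,
                         sx$x$records[["2x"]][["rep2"]]$n_meth))
  expect_false(identical(sx$x$records[["2x"]][["rep1"]]$n_meth,
                         sx$x$records[["4x"]][["rep1"]]$n_meth))
})

test_that("expression responds to TE proximity with the configured signs", {
  set.seed(14)
  n <- 500
  # genes spread along one long chromosome, one TE at the origin of each
  # 20-kb cell so nearest-TE distance varies deterministically
  starts <- seq(0L, by = 20000L, length.out = n) +
    sample(500:9500, n, replace = TRUE)
  genes <- feat(sprintf("g%03d", seq_len(n)), "c1", starts, starts + 1000L,
                kind = "PCG")
  tes <- feat(sprintf("t%03d", seq_len(n)), "c1",
              seq(0L, by = 20000L, length.out = n),
              seq(0L, by = 20000L, length.out = n) + 200L, ".", "TE",
              te_class = "I", te_order = "Gypsy")
  cfg <- simulation_config(expr_none_fraction = c(PCG = 0, lncRNA = 0),
                           replicates = 1L)
  ex <- simulate_expression(rbind(genes, tes), config = cfg, seed = 9)
  m <- merge(ex$expression[cytotype == "2x"],
             ex$coefficients$per_feature[, .(id, distance)], by = "id")
  rho <- stats::cor(m$fpkm, m$distance, method = "spearman")
  expect_gt(rho, 0)      # farther from TEs -> higher PCG expression
  # same seed twice: identical table
  ex2 <- simulate_expression(rbind(genes, tes), config = cfg, seed = 9)
  expect_identical(ex$expression, ex2$expression)
  # degenerate model: no slopes, no noise, no zero class
  cfg0 <- simulation_config(expr_dist_slope = c(PCG = 0, lncRNA = 0),
                            expr_count_slope = c(PCG = 0, lncRNA = 0),
                            expr_sigma = c(PCG = 0, lncRNA = 0),
                            expr_none_fraction = c(PCG = 0, lncRNA = 0))
  ex0 <- simulate_expression(rbind(genes, tes), config = cfg0, seed = 9)
  expect_equal(length(unique(ex0$expression$fpkm)), 1L)
  # lncRNA slope is positive for proximity: nearer TEs -> higher expression
  lnc <- copy(genes)[, `:=`(kind = "lncRNA", id = sub("^g", "l", id))]
  exl <- simulate_expression(rbind(lnc, tes), config = cfg, seed = 9)
  ml <- merge(exl$expression[cytotype == "2x"],
              exl$coefficients$per_feature[, .(id, distance)], by = "id")
  expect_lt(stats::cor(ml$fpkm, ml$distance, method = "spearman"), 0)
})

test_that("planted DMR regions are detectable by construction", {
  sx <- small_experiment()
  tr <- sx$x$truth$planted_dmrs
  expect_true(all(tr$n_sites >= sx$cfg$planted_dmr_min_sites))
  # regions are intergenic: no overlap with any feature
  for (i in seq_len(nrow(tr))) {
    f <- sx$x$features[chrom == tr$chrom[i] & start < tr$end[i] &
                         end > tr$start[i]]
    expect_equal(nrow(f), 0L)
  }
  # the truth table alone scores calls (no config needed)
  fake <- data.table(chrom = tr$chrom[1], start = tr$start[1],
                     end = tr$end[1], context = tr$context[1])
  sc <- score_dmr_calls(fake, tr)
  expect_equal(sc$n_recovered, 1L)
  expect_equal(sc$fdr, 0)
})

test_that("experiment files land on disk in the documented dialects", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_chroms = 1L, chrom_length = 1e5,
                           planted_dmr_n = 2L, planted_dmr_min_sites = 5L,
                           planted_dmr_width = 200L, replicates = 1L)
  x <- simulate_experiment(cfg, seed = 3, outdir = dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(fa[["chr1"]]), x$genome[["chr1"]])
  back <- read_features(file.path(dir, "tes.tsv"), "TE-TSV")
  expect_equal(nrow(back), nrow(x$features[kind == "TE"]))
  r <- read_cytosine_table(file.path(dir, "cytosines_2x_rep1.tsv"))
  expect_equal(r, x$records[["2x"]][["rep1"]])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$planted_dmrs), 2L)
})
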