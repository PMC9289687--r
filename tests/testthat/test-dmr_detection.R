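test_that("scan_windows tiles chromosomes with truncation", {
  w <- scan_windows(c(c1 = 500L), 200L, 100L)
  expect_equal(w$start, c(0L, 100L, 200L, 300L))
  expect_equal(w$end, c(200L, 300L, 400L, 500L))
  expect_equal(scan_windows(c(c1 = 150L), 200L, 100L),
               data.table(chrom = "c1", start = 0L, end = 150L))
  # step = window: disjoint tiling covering the chromosome
  w2 <- scan_windows(c(c1 = 950L), 200L, 200L)
  expect_equal(w2$start, w2$end - c(rep(200L, 4), 150L))
  expect_equal(sum(w2$end - w2$start), 950L)
  expect_error(scan_windows(c(c1 = 100L), 100L, 200L), "window >= step")
})

test_that("window statistics match a brute-force Fisher + BH oracle exactly", {
  toy <- toy_dmr_sites()
  crit <- dmr_criteria("CG")
  dm <- call_dmrs(toy$r2, toy$r4, crit, chrom_lengths = c(c1 = toy$len))
  wins <- attr(dm, "windows")
  expect_gt(nrow(wins), 20)

  # independent oracle: loop over all windows, shared covered sites,
  # hypergeometric-enumeration Fisher p, BH across tested windows
  grid <- scan_windows(c(c1 = toy$len), crit$window, crit$step)
  m <- merge(toy$r2, toy$r4, by = c("chrom", "pos", "strand", "context"),
             suffixes = c("_2", "_4"))
  m <- m[n_total_2 >= 4 & n_total_4 >= 4]
  oracle <- list()
  for (i in seq_len(nrow(grid))) {
    s <- m[pos >= grid$start[i] & pos < grid$end[i]]
    if (nrow(s) < crit$min_sites) next
    m2 <- sum(s$n_meth_2); t2 <- sum(s$n_total_2)
    m4 <- sum(s$n_meth_4); t4 <- sum(s$n_total_4)
    oracle[[length(oracle) + 1L]] <- data.table(
      start = grid$start[i], end = grid$end[i], n_sites = nrow(s),
      delta = m4 / t4 - m2 / t2,
      p = oracle_fisher_p(m2, t2 - m2, m4, t4 - m4))
  }
  oracle <- rbindlist(oracle)
  oracle[, q := p.adjust(p, "BH")]
  expect_equal(nrow(wins), nrow(oracle))
  expect_equal(wins$start, oracle$start)
  expect_equal(wins$n_sites, oracle$n_sites)
  expect_equal(wins$delta, oracle$delta, tolerance = 1e-12)
  expect_equal(wins$p, oracle$p, tolerance = 1e-9)
  expect_equal(wins$q, oracle$q, tolerance = 1e-9)

  # the planted block is recovered as one merged hyper DMR covering it
  expect_gte(nrow(dm), 1)
  expect_true(all(dm$direction == "hyper"))
  expect_true(any(dm$start <= 2000 & dm$end >= 2600))
})

test_that("effect-size, site-count and coverage thresholds are enforced", {
  # |delta| = 0.10 windows are never emitted however significant
  n <- 30; pos <- seq(0, by = 6, length.out = n)
  r2 <- rec("c1", pos, context = "CG", n_meth = rep(100L, n),
            n_total = rep(250L, n))
  r4 <- rec("c1", pos, context = "CG", n_meth = rep(125L, n),
            n_total = rep(250L, n))
  dm <- call_dmrs(r2, r4, dmr_criteria("CG"), chrom_lengths = c(c1 = 400L))
  wins <- attr(dm, "windows")
  expect_true(all(abs(wins$delta - 0.1) < 1e-9))
  expect_true(all(wins$q < 0.05))        # significant, but below min_delta
  expect_equal(nrow(dm), 0L)

  # 4 CG sites in the window: never tested
  r2 <- rec("c1", c(10, 20, 30, 40), context = "CG",
            n_meth = 0L, n_total = 20L)
  r4 <- rec("c1", c(10, 20, 30, 40), context = "CG",
            n_meth = 20L, n_total = 20L)
  dm <- call_dmrs(r2, r4, dmr_criteria("CG"), chrom_lengths = c(c1 = 200L))
  expect_equal(nrow(attr(dm, "windows")), 0L)

  # a 5th site with pooled coverage 3 in one group does not rescue it
  r2b <- rbind(r2, rec("c1", 50, context = "CG", n_meth = 0L, n_total = 3L))
  r4b <- rbind(r4, rec("c1", 50, context = "CG", n_meth = 20L, n_total = 20L))
  dm <- call_dmrs(r2b, r4b, dmr_criteria("CG"), chrom_lengths = c(c1 = 200L))
  expect_equal(nrow(attr(dm, "windows")), 0L)
})

test_that("raising the effect threshold never increases the DMR count", {
  toy <- toy_dmr_sites(seed = 31)
  counts <- vapply(c(0.1, 0.2, 0.25, 0.3, 0.4, 0.6), function(d) {
    crit <- dmr_criteria("CG", min_delta = d)
    nrow(call_dmrs(toy$r2, toy$r4, crit, chrom_lengths = c(c1 = toy$len)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("merged DMRs of one context never overlap each other", {
  toy <- toy_dmr_sites(seed = 57)
  dm <- call_dmrs(toy$r2, toy$r4, dmr_criteria("CG"),
                  chrom_lengths = c(c1 = toy$len))
  if (nrow(dm) > 1) {
    setorder(dm, chrom, start)
    same_dir <- dm[, .N, by = .(chrom, direction)]
    for (g in seq_len(nrow(same_dir))) {
      sub <- dm[chrom == same_dir$chrom[g] & direction == same_dir$direction[g]]
      if (nrow(sub) > 1) expect_true(all(sub$start[-1] >= head(sub$end, -1)))
    }
  }
  expect_error(call_dmrs(list(), toy$r4, dmr_criteria("CG")), "empty record")
})

test_that("replicate pooling accepts lists of tables", {
  toy <- toy_dmr_sites(seed = 77)
  halves2 <- list(copy(toy$r2)[, n_meth := pmin(n_meth, n_total)], toy$r2)
  dm_pooled <- call_dmrs(halves2, toy$r4, dmr_criteria("CG"),
                         chrom_lengths = c(c1 = toy$len))
  manual <- toy$r2[halves2[[1]], on = c("chrom", "pos", "strand", "context")
                   ][, .(chrom, pos, strand, context,
                         n_meth = n_meth + i.n_meth,
                         n_total = n_total + i.n_total)]
  dm_manual <- call_dmrs(manual, toy$r4, dmr_criteria("CG"),
                         chrom_lengths = c(c1 = toy$len))
  expect_equal(dm_pooled, dm_manual, ignore_attr = TRUE)
})

test_that("DMR location annotation uses bp-majority with precedence", {
  fts <- rbind(feat("g1", "c1", 1000, 2000, "+", "PCG"),
               feat("t1", "c1", 1800, 3000, ".", "TE", te_class = "I",
                    te_order = "Gypsy"),
               feat("l1", "c1", 8000, 9000, "+", "lncRNA"))
  dmrs <- data.table(chrom = "c1",
                     start = c(2100L, 1500L, 20000L, 2400L),
                     end = c(2400L, 2000L, 20200L, 2900L),
                     context = "CG", ratio_2x = 0.1, ratio_4x = 0.5,
                     delta = 0.4, p = 1e-8, q = 1e-5, direction = "hyper")
  ann <- annotate_dmr_location(dmrs, fts, flank = 4000L)
  expect_equal(ann$annotation, c("TE", "PCG", "intergenic", "TE"))
  # DMR inside a TE 100 bp from the PCG: flanking flag set
  expect_true(ann$flank_gene[1])
  expect_false(ann$flank_gene[3])
  # bp-majority: 60% PCG / 40% TE -> PCG
  d2 <- data.table(chrom = "c1", start = 1400L, end = 1900L, context = "CG",
                   ratio_2x = 0.1, ratio_4x = 0.5, delta = 0.4, p = 1e-8,
                   q = 1e-5, direction = "hyper")
  expect_equal(annotate_dmr_location(d2, fts)$annotation, "PCG")
})

test_that("summaries count contexts and directions", {
  dm <- data.table(context = c("CG", "CG", "CG", "CG", "CHH"),
                   direction = c("hyper", "hyper", "hypo", "hypo", "hypo"))
  s <- summarize_dmrs(dm)
  expect_equal(s[context == "CG", hyper_fraction], 0.5)
  expect_equal(s[context == "CHH", n_hyper], 0L)
  expect_equal(nrow(summarize_dmrs(dm[0])), 0L)
})

test_that("only planted hyper DMRs are called on simulator output", {
  sx <- small_experiment()
  dm <- call_dmrs(sx$x$records[["2x"]], sx$x$records[["4x"]],
                  dmr_criteria("CG"))
  expect_true(all(dm$direction == "hyper"))
  sc <- score_dmr_calls(dm, sx$x$truth$planted_dmrs)
  expect_gte(sc$sensitivity, 0.8)
  expect_lte(sc$fdr, 0.2)
  # every planted DMR's realized pooled difference has the planted sign
  p2 <- rbindlist(sx$x$records[["2x"]])
  p4 <- rbindlist(sx$x$records[["4x"]])
  for (i in seq_len(nrow(sx$x$truth$planted_dmrs))) {
    tr <- sx$x$truth$planted_dmrs[i]
    reg <- data.table(chrom = tr$chrom, start = tr$start, end = tr$end)
    d <- weighted_level(p4, tr$context, reg) - weighted_level(p2, tr$context, reg)
    expect_gt(d * sign(tr$delta), 0)
  }
})
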