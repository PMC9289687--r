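test_that("nearest TE distances follow the half-open gap convention", {
  tes <- feat("t1", "c1", 100, 200, ".", "TE", te_class = "I",
              te_order = "Gypsy")
  g <- function(s, e) feat("g1", "c1", s, e, "+", "PCG")
  expect_equal(nearest_te(g(300, 400), tes)$distance, 100L)
  ov <- nearest_te(g(150, 400), tes)
  expect_equal(ov$distance, 0L)
  expect_true(ov$overlaps_te_body)
  # book-ended: distance 0 but no body intersection
  be <- nearest_te(g(200, 400), tes)
  expect_equal(be$distance, 0L)
  expect_false(be$overlaps_te_body)
  # chromosome without TEs is flagged, not an error
  mix <- rbind(g(300, 400), feat("g2", "c9", 0, 100, "+", "PCG"))
  nn <- nearest_te(mix, tes)
  expect_true(nn[id == "g2", no_te])
  expect_true(is.na(nn[id == "g2", distance]))
  # ties break to the lower TE start
  ties <- rbind(feat("tb", "c1", 500, 600, ".", "TE", te_class = "I",
                     te_order = "Copia"),
                feat("ta", "c1", 100, 200, ".", "TE", te_class = "I",
                     te_order = "Gypsy"))
  expect_equal(nearest_te(g(300, 400), ties)$nearest_te, "ta")
})

test_that("nearest and flank counts match quadratic oracles on random layouts", {
  set.seed(77)
  for (k in 1:25) {
    fts <- random_layout(30)[, .(id = sprintf("f%02d", .I), chrom, start, end,
                                 strand = "+", kind = "PCG",
                                 subkind = NA_character_,
                                 te_class = NA_character_,
                                 te_order = NA_character_)]
    tes <- random_layout(40)[, .(id = sprintf("t%02d", .I), chrom, start, end,
                                 strand = ".", kind = "TE",
                                 subkind = NA_character_, te_class = "I",
                                 te_order = "Gypsy")]
    nn <- nearest_te(fts, tes)
    nn <- nn[match(fts$id, id)]
    expect_equal(nn$distance, oracle_nearest_distance(fts, tes))
    fc <- count_flank_tes(fts, tes, flank = 4000L)
    expect_equal(fc$te_count_flank, oracle_flank_count(fts, tes, 4000L))
  }
})

test_that("flank TE counting deduplicates and excludes body-only TEs", {
  f <- feat("g1", "c1", 10000, 10100, "+", "PCG")
  # spans upstream flank, body and downstream flank: counted once
  spanning <- feat("t1", "c1", 5000, 16000, ".", "TE", te_class = "I",
                   te_order = "Gypsy")
  expect_equal(count_flank_tes(f, spanning)$te_count_flank, 1L)
  # body-only TE: zero
  inside <- feat("t2", "c1", 10010, 10090, ".", "TE", te_class = "I",
                 te_order = "Gypsy")
  expect_equal(count_flank_tes(f, inside)$te_count_flank, 0L)
  expect_equal(count_flank_tes(f, inside[0])$te_count_flank, 0L)
})

test_that("overlap classification is monotone in window size", {
  lnc <- feat("l1", "c1", 1000, 2000, "+", "lncRNA")
  gy <- feat("t1", "c1", 1200, 1500, ".", "TE", te_class = "I",
             te_order = "Gypsy")
  oc <- overlap_classification(lnc, gy)
  expect_equal(oc[window == 0 & category == "any", fraction], 1)
  expect_equal(oc[window == 0 & category == "class_I", fraction], 1)
  expect_equal(oc[window == 0 & category == "order_Gypsy", fraction], 1)
  # no TEs at all: fractions 0
  oc0 <- overlap_classification(lnc, gy[0])
  expect_true(all(oc0$fraction == 0))
  # random layouts: fraction(2 kb) <= fraction(8 kb) in every category
  set.seed(5)
  for (k in 1:10) {
    fts <- random_layout(20)[, .(id = sprintf("f%02d", .I), chrom, start, end,
                                 strand = "+", kind = "lncRNA",
                                 subkind = NA_character_,
                                 te_class = NA_character_,
                                 te_order = NA_character_)]
    tes <- random_layout(15)[, .(id = sprintf("t%02d", .I), chrom, start, end,
                                 strand = ".", kind = "TE",
                                 subkind = NA_character_,
                                 te_class = sample(c("I", "II"), 15, TRUE),
                                 te_order = sample(c("Gypsy", "MITE"), 15,
                                                   TRUE))]
    oc <- overlap_classification(fts, tes, windows = c(2000L, 8000L))
    wide <- dcast(oc, category ~ window, value.var = "fraction")
    expect_true(all(wide$`2000` <= wide$`8000`))
  }
})

test_that("expression groups split a none class plus tertiles", {
  mk <- function(fpkm) data.table(id = sprintf("g%04d", seq_along(fpkm)),
                                  cytotype = "2x", replicate = 1L,
                                  fpkm = fpkm)
  g <- expression_groups(mk(c(0, 1, 10, 100)))
  expect_equal(as.character(g[order(id)]$group),
               c("none", "low", "middle", "high"))
  # remainder rule: 3001 expressed -> 1001/1000/1000
  g2 <- expression_groups(mk(seq(0.2, 300.2, length.out = 3001)))
  expect_equal(as.vector(table(g2$group)[c("low", "middle", "high")]),
               c(1001L, 1000L, 1000L))
  # labels partition the features exactly
  expect_equal(sum(table(g2$group)), 3001L)
  expect_warning(expression_groups(mk(c(0, 0.01))), "below the expression")
})

test_that("TE methylation by distance matches an independent pooling oracle", {
  set.seed(23)
  tes <- random_layout(25, len = 30000L,
                       max_width = 2000L)[, .(id = sprintf("t%02d", .I),
                                              chrom, start, end, strand = ".",
                                              kind = "TE", subkind = NA_character_,
                                              te_class = "I",
                                              te_order = "Gypsy")]
  anchors <- random_layout(8, len = 30000L)[, .(id = sprintf("a%02d", .I),
                                                chrom, start, end,
                                                strand = "+", kind = "PCG",
                                                subkind = NA_character_,
                                                te_class = NA_character_,
                                                te_order = NA_character_)]
  n <- 3000
  recs <- rec(sample(c("c1", "c2"), n, TRUE),
              sample.int(30000L, n, TRUE) - 1L, context = "CG",
              n_meth = 0L, n_total = sample(0:15, n, TRUE))
  recs[, n_meth := as.integer(pmin(n_total, rpois(.N, 5)))]
  md <- methylation_by_distance(tes, anchors, recs, "CG", bin = 500L,
                                max_distance = 8000L)
  # oracle: per TE, quadratic nearest distance; per bin, explicit pooling
  d <- oracle_nearest_distance(tes, anchors)
  for (b in seq_len(nrow(md))) {
    sel <- which(!is.na(d) & d >= md$bin_start[b] & d < md$bin_end[b])
    expect_equal(md$n_tes[b], length(sel))
    nm <- 0; nt <- 0
    for (i in sel) {
      inb <- recs$chrom == tes$chrom[i] & recs$pos >= tes$start[i] &
        recs$pos < tes$end[i] & recs$context == "CG"
      nm <- nm + sum(recs$n_meth[inb]); nt <- nt + sum(recs$n_total[inb])
    }
    if (nt > 0) expect_equal(md$level[b], nm / nt) else expect_true(is.na(md$level[b]))
  }
  # constant methylation: every populated bin sits at the constant
  recs2 <- copy(recs)[, n_meth := as.integer(round(0.8 * n_total))]
  md2 <- methylation_by_distance(tes, anchors, recs2, "CG")
  expect_true(all(abs(md2$level[!is.na(md2$level)] - 0.8) < 0.05))
  # all TEs inside anchors: only bin 0 populated
  inside_te <- copy(anchors)[, `:=`(id = sprintf("ti%02d", .I), kind = "TE",
                                    strand = ".", te_class = "I",
                                    te_order = "Gypsy")]
  md3 <- methylation_by_distance(inside_te, anchors, recs, "CG")
  expect_true(all(md3$n_tes[md3$bin_start > 0] == 0))
})

test_that("group tests match symmetry anchors and a permutation oracle", {
  # equal multisets: Wilcoxon statistic at its null centre, p = 1
  w <- group_tests(c(1, 2, 3), c(1, 2, 3), "wilcoxon")
  expect_equal(w$p_value, 1)
  # exact small-sample case: most extreme of the C(6,3) = 20 orderings
  w2 <- group_tests(c(1, 2, 3), c(4, 5, 6), "wilcoxon")
  expect_equal(w2$p_value, 0.1)
  # permutation oracle on random untied samples
  set.seed(3)
  for (k in 1:5) {
    a <- sample(seq(1, 99, 2), 4); b <- sample(seq(2, 100, 2), 5)
    res <- group_tests(a, b, "wilcoxon")
    pool <- c(a, b)
    combs <- utils::combn(9, 4)
    W_obs <- sum(rank(pool)[1:4]) - 4 * 5 / 2
    W_all <- apply(combs, 2, function(ix) sum(rank(pool)[ix]) - 10)
    p_oracle <- min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
    expect_equal(res$p_value, p_oracle)
  }
  # Welch t on zero-variance groups: degenerate flag
  dg <- group_tests(c(0, 0), c(1, 1), "t")
  expect_true(dg$degenerate)
  tt <- group_tests(rnorm(10), rnorm(10, 1), "t")
  expect_false(tt$degenerate)
  expect_lt(tt$p_value, 1)
})

test_that("profile_by_group keeps only non-empty groups", {
  sx <- small_experiment()
  pcg <- sx$x$features[kind == "PCG"]
  labels <- data.table(id = pcg$id,
                       group = factor("high", levels = c("none", "low",
                                                         "middle", "high")))
  pooled <- rbindlist(sx$x$records[["2x"]])
  warns <- capture_warnings(pr <- profile_by_group(pooled, pcg, labels, "CG"))
  expect_length(warns, 3L)                 # none/low/middle all empty
  expect_match(warns, "no features", all = TRUE)
  expect_equal(names(pr), "high")
  expect_s3_class(pr$high, "methylation_profile")
})
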