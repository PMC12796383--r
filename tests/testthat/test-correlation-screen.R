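test_that("summarise_replicates averages per timepoint", {
  m <- matrix(c(2, 4, 7), 1,
              dimnames = list("g1", c("80_rep1", "80_rep2", "96_rep1")))
  out <- summarise_replicates(m)
  expect_equal(as.numeric(out), c(3, 7))
  expect_equal(attr(out, "timepoints"), c(80, 96))
  # seeded matrix matches a direct per-column re-summation
  cfg <- sim_config(seed = 10, noise_cv = 0.1)
  mm <- gen_expression_timecourse(cfg, 5, 5, 10, planted_rate(cfg$timepoints))
  pm <- summarise_replicates(mm)
  tp <- sub("_rep.*$", "", colnames(mm))
  manual <- sapply(unique(tp), function(x)
    apply(mm[, tp == x, drop = FALSE], 1, function(z) sum(z) / length(z)))
  expect_equal(unname(pm), unname(manual), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(summarise_replicates(unname(mm)), "column names")
})

test_that("Pearson r behaves as the product-moment definition demands", {
  rate <- planted_rate(c(80, 88, 96, 104, 112, 116, 118))
  prof <- rbind(a = 2 * rate + 5, b = -rate)
  res <- correlate_with_growth_rate(prof, rate)
  expect_equal(res$r, c(1, -1), tolerance = 1e-12)
  # 1000 random 7-vectors against the sum-formula oracle
  set.seed(21)
  x <- matrix(rnorm(7000), 1000)
  res2 <- correlate_with_growth_rate(x, rate)
  oracle <- apply(x, 1, oracle_pearson, y = rate)
  expect_equal(res2$r, unname(oracle), tolerance = 1e-12)
  # invariance under positive affine maps, sign flip under negation
  expect_equal(correlate_with_growth_rate(3 * x + 7, rate)$r, res2$r,
               tolerance = 1e-12)
  expect_equal(correlate_with_growth_rate(-x, rate)$r, -res2$r,
               tolerance = 1e-12)
  expect_error(correlate_with_growth_rate(x, rate[-1]), "length")
})

test_that("zero-variance profiles are flagged undefined, not NaN", {
  rate <- planted_rate(c(80, 96, 112, 118))
  prof <- rbind(flat = rep(3, 4), ok = c(1, 2, 3, 4))
  res <- classify_genes(correlate_with_growth_rate(prof, rate))
  expect_true(res$undefined[1])
  expect_false(anyNA(res$class))
  expect_equal(as.character(res$class[1]), "undefined")
})

test_that("classification uses strict inequalities and partitions genes", {
  res <- structure(
    data.frame(gene = c("a", "b", "c", "d"),
               r = c(0.8, -0.9, 0.81, -0.8),
               undefined = FALSE),
    class = c("screen_result", "data.frame"))
  cls <- classify_genes(res)
  expect_equal(as.character(cls$class),
               c("unselected", "negative", "positive", "unselected"))
  expect_equal(sum(table(cls$class)), nrow(cls))
  expect_error(classify_genes(res, threshold = 1), "inside")
})

test_that("noiseless planted screen recovers every planted class", {
  cfg <- sim_config(seed = 14, noise_cv = 0)
  rate <- planted_rate(cfg$timepoints)
  m <- gen_expression_timecourse(cfg, 100, 100, 800, rate)
  res <- classify_genes(correlate_with_growth_rate(
    summarise_replicates(m), rate))
  truth <- attr(m, "truth")$classes
  expect_equal(res$gene, truth$gene)
  map <- c(positive = "tracking", negative = "anti_tracking",
           unselected = "null")
  expect_equal(unname(map[as.character(res$class)]), truth$class)
})

test_that("noisy null false-positive rate matches Monte-Carlo expectation", {
  cfg <- sim_config(seed = 15, noise_cv = 0.1)
  rate <- planted_rate(cfg$timepoints)
  m <- gen_expression_timecourse(cfg, 0, 0, 1000, rate)
  res <- classify_genes(correlate_with_growth_rate(
    summarise_replicates(m), rate))
  fpr <- mean(res$class != "unselected")
  expect_lt(fpr, 0.05)   # guarded null + mild noise keeps the tail small
})

test_that("max_normalize yields unit row maxima and is idempotent", {
  m <- rbind(a = c(1, 2, 4), b = c(3, 3, 3))
  n <- max_normalize(m)
  expect_equal(n["a", ], c(0.25, 0.5, 1), ignore_attr = TRUE)
  expect_equal(n["b", ], c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(max_normalize(n), n)
  expect_true(all(apply(n, 1, max) == 1))
  expect_error(max_normalize(rbind(zero = c(0, 0, 0))), "zero")
})

test_that("ward.D2 merge heights equal the Lance-Williams oracle", {
  set.seed(31)
  for (i in 1:5) {
    mat <- matrix(runif(5 * 7), 5,
                  dimnames = list(paste0("g", 1:5), NULL))
    ch <- cluster_genes(mat)
    expect_equal(ch$height, oracle_ward_d2_heights(mat),
                 tolerance = 1e-10)
    expect_true(all(diff(ch$height) >= -1e-12))
    expect_true(all(ch$height >= 0))
  }
})

test_that("identical rows merge first at height zero and row order is
           immaterial to the heights", {
  mat <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 0),
               d = c(4, 4, 4))
  ch <- cluster_genes(mat)
  expect_equal(ch$height[1], 0)
  expect_true(all(sort(ch$merge[1, ]) == c(-2, -1)))
  perm <- c(3, 1, 4, 2)
  expect_equal(sort(cluster_genes(mat[perm, ])$height), sort(ch$height),
               tolerance = 1e-12)
  expect_error(cluster_genes(mat[1, , drop = FALSE]), "2 genes")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- paste0("g", 1:20)
  sets <- list(s5 = universe[1:5], s8 = universe[4:11],
               s2 = universe[19:20])
  selected <- universe[c(1:4, 12:15)]       # overlap with s5 is 4
  res <- enrich(selected, universe, sets)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 oracle_hyper_tail(res$overlap[i], res$set_size[i],
                                   res$list_size[i], res$universe_size[i]),
                 tolerance = 1e-12)
  }
  expect_equal(res$q, p.adjust(res$p, "BH"))
  # p is monotone non-increasing in overlap at fixed margins
  ps <- vapply(0:5, oracle_hyper_tail, numeric(1),
               set_size = 5, list_size = 8, universe = 20)
  expect_true(all(diff(ps) <= 0) || all(diff(rev(ps)) >= 0))
})

test_that("enrichment edge cases: full list and empty overlap give p = 1", {
  universe <- paste0("g", 1:12)
  sets <- list(all = universe[1:6], none = universe[7:12])
  res <- enrich(universe, universe, sets["all"])
  expect_equal(res$overlap, 6)
  expect_equal(res$p, 1)
  res0 <- enrich(universe[7:9], universe, sets["all"])
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p, 1)
  expect_error(enrich(c("zz"), universe, sets), "outside")
  expect_error(enrich(universe[1], character(0), sets), "empty")
})

test_that("EASE variant decrements the overlap and caps small overlaps", {
  universe <- paste0("g", 1:20)
  sets <- list(s = universe[1:5])
  sel <- universe[1:8]
  plain <- enrich(sel, universe, sets)
  ease <- enrich(sel, universe, sets, ease = TRUE)
  expect_equal(ease$p,
               oracle_hyper_tail(plain$overlap - 1, 5, 8, 20),
               tolerance = 1e-12)
  expect_gt(ease$p, plain$p)
  one <- enrich(universe[1], universe, sets, ease = TRUE)
  expect_equal(one$p, 1)
})

test_that("gmt files round-trip through write_gmt/read_gmt", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})
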