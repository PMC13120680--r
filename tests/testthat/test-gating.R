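# Quadrant gating, positivity fractions, per-image summarization, SEM and
# Welch/Bonferroni statistics.

test_that("quadrant gating partitions every cell with boundary-positive rule", {
  rec <- data.frame(x = c(0, 1, 2, 0.5, 1), y = c(0, 0, 3, 2, 1))
  g <- gate_spec("x", "y", 1, 1)
  q <- quadrant_classify(rec, g)
  expect_equal(sum(q$count), 5L)
  expect_equal(sum(q$percentage), 100, tolerance = 1e-9)
  # boundary counts positive: the (1,1) cell is double-positive
  expect_equal(q$count[q$quadrant == "x+y+"], 2L)
  expect_equal(q$count[q$quadrant == "x-y-"], 1L)

  # all cells at origin with thresholds (1,1): 100% double negative
  rec0 <- data.frame(x = rep(0, 10), y = rep(0, 10))
  q0 <- quadrant_classify(rec0, g)
  expect_equal(q0$percentage[q0$quadrant == "x-y-"], 100)

  expect_error(quadrant_classify(rec0[0, ], g), "no cells")
  expect_error(gate_spec("x", "y", 0, 1), "thresholds")
})

test_that("quadrant percentages recover a designed joint mixture", {
  # 70/10/10/10 double-positive/single/single/negative design via a shared
  # 4-component latent label; gate thresholds far from both component means
  set.seed(7)
  w <- c(0.70, 0.10, 0.10, 0.10)
  hi <- c(300, 25); lo <- c(40, 10)
  xm <- rbind(hi, hi, lo, lo); ym <- rbind(hi, lo, hi, lo)
  lab <- sample.int(4, 1000, replace = TRUE, prob = w)
  rec <- data.frame(x = rnorm(1000, xm[lab, 1], xm[lab, 2]),
                    y = rnorm(1000, ym[lab, 1], ym[lab, 2]))
  q <- quadrant_classify(rec, gate_spec("x", "y", 150, 150))
  expect_equal(q$percentage[q$quadrant == "x+y+"], 100 * mean(lab == 1),
               tolerance = 0.02)
  # counts are multinomial around the design
  expect_lt(abs(q$count[q$quadrant == "x+y+"] - 700), 3 * sqrt(1000 * 0.7 * 0.3))
})

test_that("positive fractions respect the boundary and the mixture weight", {
  v <- c(1, 2, 3, 4)
  expect_equal(positive_fraction(v, threshold = 0.5), 1.0)
  expect_equal(positive_fraction(v, threshold = 10), 0.0)
  expect_equal(positive_fraction(v, threshold = 3), 0.5)  # boundary positive
  set.seed(11)
  vals <- ifelse(runif(2000) < 0.8, rnorm(2000, 300, 25), rnorm(2000, 40, 10))
  expect_lt(abs(positive_fraction(vals, threshold = 150) - 0.8),
            2.576 * sqrt(0.8 * 0.2 / 2000))
})

test_that("per-image summaries use the median (midpoint convention) or mean", {
  rec <- data.frame(image_id = c("a", "a", "a", "b", "b", "b", "b"),
                    v = c(1, 2, 3, 1, 2, 3, 4))
  s <- summarize_per_image(rec, "v", "median")
  expect_equal(s$value[s$image_id == "a"], 2)
  expect_equal(s$value[s$image_id == "b"], 2.5)
  expect_identical(s$n_cells, c(3L, 4L))
  s2 <- summarize_per_image(rec, "v", "mean")
  expect_equal(s2$value[s2$image_id == "b"], 2.5)

  # per-image medians converge to the analytic mixture median as cells grow:
  # 50/50 mixture of N(0,1) and N(2,1) has median 1 by symmetry (overlapping
  # components, so the sample median concentrates there)
  set.seed(3)
  for (n in c(10, 100, 1000)) {
    vals <- ifelse(runif(n) < 0.5, rnorm(n, 0, 1), rnorm(n, 2, 1))
    m <- summarize_per_image(data.frame(image_id = "i", v = vals), "v")$value
    expect_lt(abs(m - 1), 10 / sqrt(n))  # shrinking band, ~5 asymptotic SEs
  }
})

test_that("sem matches its closed form", {
  expect_equal(sem(c(5, 5, 5)), 0)
  expect_equal(sem(c(0, 2)), 1.0)
  expect_error(sem(3), "at least two")
  # mean SEM over draws approximates sigma/sqrt(n)
  set.seed(5)
  sems <- replicate(1000, sem(rnorm(8, 0, 3)))
  expect_lt(abs(mean(sems) - 3 / sqrt(8)) / (3 / sqrt(8)), 0.05)
})

test_that("Welch tests match the closed form and Bonferroni behaves", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 4, 6, 8, 10)
  res <- welch_bonferroni(list(g1 = a, g2 = b), list(c("g1", "g2")))
  o <- oracle_welch(a, b)
  expect_equal(res$t_statistic, o$t, tolerance = 1e-10)
  expect_equal(res$df, o$df, tolerance = 1e-10)
  expect_equal(res$p_value, o$p, tolerance = 1e-10)

  # identical groups: t = 0, p = 1, p_adjusted = 1
  res0 <- welch_bonferroni(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3)))
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$p_adjusted, 1)

  # symmetry: swapping groups negates t, preserves p
  rs <- welch_bonferroni(list(g1 = b, g2 = a), list(c("g1", "g2")))
  expect_equal(rs$t_statistic, -res$t_statistic)
  expect_equal(rs$p_value, res$p_value)

  # Bonferroni caps at 1 and is monotone in the number of comparisons
  r3 <- welch_bonferroni(list(g1 = a, g2 = b), list(c("g1", "g2")),
                         n_comparisons = 3)
  expect_equal(r3$p_adjusted, min(1, r3$p_value * 3))
  r9 <- welch_bonferroni(list(g1 = a, g2 = b), list(c("g1", "g2")),
                         n_comparisons = 9)
  expect_gte(r9$p_adjusted, r3$p_adjusted)
  ph <- welch_bonferroni(list(g1 = c(1, 2, 3), g2 = c(1.1, 2.1, 2.9)),
                         n_comparisons = 3)
  expect_lte(ph$p_adjusted, 1)

  # degenerate groups are rejected by name
  expect_error(welch_bonferroni(list(g1 = 1, g2 = a)), "g1")
  expect_error(welch_bonferroni(list(g1 = c(2, 2, 2), g2 = c(3, 3, 3))),
               "zero variance")
})

test_that("significance stars follow the conventional brackets", {
  expect_identical(significance_stars(c(0.2, 0.03, 0.005, 0.0005, 0.00005)),
                   c("", "*", "**", "***", "****"))
  expect_identical(significance_stars(0.05), "")  # boundary is not significant
})

test_that("gating tables export a consistent CSV bundle", {
  rec <- do.call(rbind, lapply(1:4, function(i) {
    f <- generate_fixed_field(test_field_small(seed = 80 + i, n_cells = 12))
    r <- quantify_cells(f$image, f$mask, quant_config(),
                        sprintf("img%d", i))
    r$condition <- if (i <= 2) "DE" else "control"
    r
  }))
  g <- gate_spec("sox17_dapi_norm", "foxa2_dapi_norm", 0.35, 0.35)
  dir <- withr::local_tempdir()
  paths <- export_gating_tables(rec, g, c("sox17_dapi_norm", "foxa2_dapi_norm"),
                                dir)
  expect_true(all(file.exists(paths)))
  scatter <- read.csv(paths[["scatter"]])
  expect_identical(nrow(scatter), nrow(rec))
  expect_true(all(scatter$quadrant %in% c("x-y-", "x+y-", "x-y+", "x+y+")))
  quad <- read.csv(paths[["quadrants"]])
  agg <- tapply(quad$percentage, quad$condition, sum)
  expect_true(all(abs(agg - 100) < 1e-9))
  cmp <- read.csv(paths[["comparisons"]])
  expect_identical(nrow(cmp), 1L)
  expect_true(all(c("t_statistic", "df", "p_value", "p_adjusted", "stars")
                  %in% names(cmp)))
})
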