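test_that("expression_matrix enforces its invariants", {
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  g <- setNames(c("control", "control", "treated", "treated"), colnames(v))
  expect_s3_class(expression_matrix(v, g), "expr_matrix")
  expect_error(expression_matrix(v, g[1:3]), "without group")
  g2 <- g; g2[1] <- "treated"
  expect_error(expression_matrix(v, g2), "at least 2 samples")
  v2 <- v; v2[1, 1] <- NA
  expect_error(expression_matrix(v2, g), "non-finite")
})

test_that("a feature identical in both groups is null", {
  v <- rbind(f1 = rep(5, 6), f2 = c(1, 2, 3, 1, 2, 3))
  de <- test_differential(make_expr(v))
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$p_value, c(1, 1))
  expect_false(any(de$is_de))
  expect_true(de$zero_variance[1])
  expect_false(de$zero_variance[2])
  expect_equal(de$direction, c("none", "none"))
})

test_that("fold change is exact arithmetic and p matches the t test", {
  ctrl <- c(1.0, 1.2, 0.8)
  trt <- c(2.0, 2.2, 1.8)
  v <- rbind(f1 = c(ctrl, trt))
  de <- test_differential(make_expr(v))
  expect_identical(de$log2fc, 1.0)
  ref <- t.test(trt, ctrl, var.equal = TRUE)
  expect_equal(de$p_value, ref$p.value, tolerance = 1e-12)
  expect_true(de$is_de)
  expect_equal(de$direction, "up")
  de_w <- test_differential(make_expr(v), var_equal = FALSE)
  ref_w <- t.test(trt, ctrl, var.equal = FALSE)
  expect_equal(de_w$p_value, ref_w$p.value, tolerance = 1e-12)
})

test_that("p-values agree with stats::t.test across random features", {
  set.seed(42)
  v <- matrix(rnorm(50 * 8, mean = 8, sd = 0.5), 50, 8,
              dimnames = list(sprintf("f%02d", 1:50), NULL))
  x <- make_expr(v, n_ctrl = 4L, n_trt = 4L)
  for (ve in c(TRUE, FALSE)) {
    de <- test_differential(x, var_equal = ve)
    for (i in c(1, 7, 23, 50)) {
      ref <- t.test(v[i, 5:8], v[i, 1:4], var.equal = ve)
      expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-12)
      expect_equal(de$log2fc[i], unname(ref$estimate[1] - ref$estimate[2]),
                   tolerance = 1e-12)
    }
    expect_equal(de$q_value, p.adjust(de$p_value, "BH"))
  }
})

test_that("DE flag uses strict raw-p and strict fold-change thresholds", {
  flag <- mirtfnet:::de_flag
  expect_true(flag(0.04, 0.6))
  expect_false(flag(0.04, 0.4))
  expect_false(flag(0.04, 0.5))   # boundary |lfc| = 0.5 excluded
  expect_false(flag(0.05, 0.6))   # boundary p = 0.05 excluded
  expect_true(flag(0.04, -0.6))
})

test_that("swapping group labels negates fold changes and preserves p", {
  set.seed(99)
  v <- matrix(rnorm(30 * 6, 8, 0.4), 30, 6,
              dimnames = list(sprintf("f%02d", 1:30), paste0("s", 1:6)))
  g <- setNames(rep(c("control", "treated"), each = 3), colnames(v))
  g_swap <- setNames(rep(c("treated", "control"), each = 3), colnames(v))
  de1 <- test_differential(expression_matrix(v, g))
  de2 <- test_differential(expression_matrix(v, g_swap))
  expect_equal(de2$log2fc, -de1$log2fc)
  expect_equal(de2$p_value, de1$p_value)
})

test_that("groups with fewer than two samples are rejected", {
  v <- matrix(rnorm(9), 3, 3, dimnames = list(paste0("f", 1:3),
                                              paste0("s", 1:3)))
  g <- setNames(c("control", "treated", "treated"), colnames(v))
  expect_error(expression_matrix(v, g), "at least 2 samples")
})

test_that("noiseless planted data partitions exactly by planted direction", {
  cfg <- sim_config(n_mirnas = 50, noise_sd_log2 = 0, de_fraction_mirna = 0.3,
                    seed = 21)
  res <- simulate_expression(cfg, "mirna")
  de <- test_differential(res$matrix)
  part <- de_partition(de)
  planted_up <- res$planted$feature_id[res$planted$direction == "up"]
  planted_down <- res$planted$feature_id[res$planted$direction == "down"]
  expect_setequal(part$up$feature_id, planted_up)
  expect_setequal(part$down$feature_id, planted_down)
  # ordering: |log2fc| descending, ties broken by feature id
  expect_equal(part$up$feature_id,
               part$up$feature_id[order(-abs(part$up$log2fc),
                                        part$up$feature_id,
                                        method = "radix")])
})

test_that("de_partition of an empty table gives two empty lists", {
  de <- toy_de(character(0), numeric(0), logical(0))
  part <- de_partition(de)
  expect_equal(nrow(part$up), 0)
  expect_equal(nrow(part$down), 0)
})

test_that("type-I error is calibrated under the global null", {
  # 20 null datasets of 500 features: fraction p < 0.05 near 0.05
  set.seed(123)
  ps <- unlist(lapply(1:20, function(s) {
    cfg <- sim_config(n_mirnas = 500, de_fraction_mirna = 0, seed = 1000 + s)
    test_differential(simulate_expression(cfg, "mirna")$matrix)$p_value
  }))
  frac <- mean(ps < 0.05)
  se <- sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(frac - 0.05), 3 * se + 0.005)
})

test_that("probe collapsing keeps the best row per gene", {
  de <- toy_de(c("p1", "p2", "p3"), c(2, -1, 0.7))
  de$p_value <- c(0.03, 0.001, 0.2)
  map <- c(p1 = "G1", p2 = "G1", p3 = "G2")
  col <- collapse_features(de, map, method = "min_p")
  expect_equal(nrow(col), 2)
  expect_equal(col$log2fc[col$feature_id == "G1"], -1)
  col2 <- collapse_features(de, map, method = "max_fc")
  expect_equal(col2$log2fc[col2$feature_id == "G1"], 2)
})
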