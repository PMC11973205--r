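test_that("proportions divide counts correctly at ROI and patient level", {
  cells <- rbind(
    make_cells(1:4, rep(0, 4), c("CD8+ T", "CD8+ T", "stromal", "stromal"),
               roi = "R1", patient = "P1"),
    make_cells(1:10, rep(0, 10), c("B cell", rep("stromal", 9)),
               roi = "R2", patient = "P2"),
    make_cells(1:30, rep(0, 30), c(rep("B cell", 3), rep("stromal", 27)),
               roi = "R3", patient = "P2"))
  rois <- data.frame(roi_id = c("R1", "R2", "R3"),
                     patient_id = c("P1", "P2", "P2"),
                     width_um = 50, height_um = 50)
  clin <- data.frame(patient_id = c("P1", "P2"),
                     msi_status = c("MSS", "MSS"),
                     recurrence = c("no", "no"), os_time = 1, os_event = 0)
  co <- new_cohort(cells, rois, clin)

  pm <- proportions(co, "roi")
  expect_equal(pm$fractions["R1", "CD8+ T"], 0.5)
  expect_equal(pm$fractions["R1", "stromal"], 0.5)
  expect_equal(sum(pm$fractions["R1", ]), 1)

  # patient level pools cells before dividing: (1 + 3) / (10 + 30)
  pp <- proportions(co, "patient")
  expect_equal(pp$fractions["P2", "B cell"], 0.1)

  # an empty ROI is excluded with a warning, not a zero row
  rois2 <- rbind(rois, data.frame(roi_id = "R4", patient_id = "P1",
                                  width_um = 50, height_um = 50))
  co2 <- new_cohort(cells, rois2, clin)
  expect_warning(pm2 <- proportions(co2, "roi"), "empty")
  expect_false("R4" %in% rownames(pm2$fractions))
})

test_that("empirical logit matches the direct formula and guards offset 0", {
  counts <- matrix(c(10, 0, 10, 20), 2, 2,
                   dimnames = list(c("u1", "u2"), c("A", "B")))
  pm <- structure(list(counts = counts, fractions = counts / rowSums(counts),
                       meta = data.frame(unit = c("u1", "u2"))),
                  class = "tme_proportions")
  y <- empirical_logit(pm, offset = 0.5)
  expect_equal(y["u1", "A"], 0)                       # log(10.5/10.5)
  expect_equal(y["u2", "A"], log(0.5 / 20.5))         # ~ -3.714
  expect_error(empirical_logit(pm, offset = 0), "offset")
  # strictly increasing in n for fixed N
  ns <- 0:20
  ys <- log((ns + 0.5) / (20 - ns + 0.5))
  expect_true(all(diff(ys) > 0))
})

test_that("bh_adjust equals the direct step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.04, 1.0)), c(0.08, 1.0))
  set.seed(1)
  p <- runif(50)^2
  expect_equal(bh_adjust(p), bh_hand(p))
  # order invariance up to the inverse permutation
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("block correlation estimator recovers limiting and true values", {
  # residuals identical within blocks -> correlation near 1 (capped)
  blocks <- rep(1:6, each = 3)
  design <- matrix(1, 18, 1)
  set.seed(7)
  be <- matrix(rnorm(5 * 6), 5, 6)
  y <- t(be[, blocks] + 0.01 * matrix(rnorm(5 * 18), 5, 18))
  rho <- estimate_block_correlation(y, design, blocks)
  expect_gt(rho, 0.9)
  expect_lte(rho, 0.99)

  # all singleton blocks -> 0 with a warning
  expect_warning(r0 <- estimate_block_correlation(y[1:6, ], design[1:6, ,
                                                  drop = FALSE], 1:6),
                 "singleton")
  expect_equal(r0, 0)

  # parameter recovery at true rho = 0.5, 30 blocks of 4
  set.seed(11)
  blocks <- rep(1:30, each = 4)
  cond <- rep(c(0, 1), 60)
  design <- cbind(1, cond)
  g <- 25
  yb <- matrix(rnorm(g * 30), g, 30)[, blocks] * sqrt(0.5)
  yu <- matrix(rnorm(g * 120), g, 120) * sqrt(0.5)
  rho_hat <- estimate_block_correlation(t(yb + yu), design, blocks)
  expect_lt(abs(rho_hat - 0.5), 0.15)
})

test_that("moderated test: identical arms are all-null", {
  # same values in both arms, nonzero within-arm spread
  y <- matrix(rep(c(1, 2, 1, 2), 5), 4, 5)
  cond <- c("a", "a", "b", "b")
  res <- moderated_group_test(y, cond)
  expect_equal(res$effect, rep(0, 5))
  expect_equal(res$p, rep(1, 5))
  expect_true(all(res$adj_p >= res$p))

  # fully constant input (no residual variance anywhere) is also all-null
  y0 <- matrix(2, 4, 3)
  res0 <- suppressWarnings(moderated_group_test(y0, cond))
  expect_equal(res0$effect, rep(0, 3))
  expect_equal(res0$p, rep(1, 3))
})

test_that("moderated test reduces to per-category OLS when rho = 0", {
  set.seed(3)
  n <- 16
  cond <- factor(rep(c("a", "b"), each = n / 2))
  purity <- runif(n)
  y <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("g", 1:8)))
  y[, 1] <- y[, 1] + 2 * (cond == "b")
  res <- moderated_group_test(y, cond, purity = purity,
                              blocks = seq_len(n), rho = 0)
  s2 <- numeric(8)
  for (g in 1:8) {
    fit <- lm(y[, g] ~ cond + purity)
    expect_equal(res$effect[g], unname(coef(fit)["condb"]), tolerance = 1e-8)
    s2[g] <- summary(fit)$sigma^2
    expect_equal(res$df_residual[g], fit$df.residual)
  }
  # hand-computed empirical-Bayes squeeze: fit the scaled inverse
  # chi-square prior to the OLS variances, form posterior variances and
  # moderated t from first principles, and compare
  fd <- limma::fitFDist(s2, df1 = res$df_residual[1])
  s2_post <- if (is.finite(fd$df2)) {
    (fd$df2 * fd$scale + res$df_residual * s2) /
      (fd$df2 + res$df_residual)
  } else rep(fd$scale, 8)  # infinite prior df: full shrinkage to the prior
  for (g in 1:8) {
    fit <- lm(y[, g] ~ cond + purity)
    se_unscaled <- summary(fit)$coefficients["condb", "Std. Error"] /
      summary(fit)$sigma
    t_hand <- res$effect[g] / (se_unscaled * sqrt(s2_post[g]))
    expect_equal(res$t[g], t_hand, tolerance = 1e-6)
    # total df is capped at the pooled residual df of all categories
    df_tot <- min(fd$df2 + res$df_residual[g], sum(res$df_residual))
    expect_equal(res$p[g], 2 * pt(-abs(t_hand), df = df_tot),
                 tolerance = 1e-6)
  }
  # the planted category is detected
  expect_lt(res$adj_p[1], 0.05)
})

test_that("singular purity covariate is dropped with a warning", {
  set.seed(4)
  y <- matrix(rnorm(40), 10, 4)
  cond <- rep(c("a", "b"), 5)
  expect_warning(res <- moderated_group_test(y, cond, purity = rep(0.5, 10)),
                 "purity")
  expect_s3_class(res, "tme_moderated_test")
})

test_that("spearman correlogram handles monotone, inverse and constant", {
  fr <- cbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8), C = c(8, 6, 4, 2),
              D = rep(0.25, 4))
  fr <- fr / rowSums(fr)
  # re-derive ranks after normalization would break monotonicity, so test
  # on a raw matrix wrapped as proportions
  pm <- structure(list(fractions = cbind(A = c(1, 2, 3, 4) / 10,
                                         B = c(2, 4, 6, 8) / 10,
                                         C = c(8, 6, 4, 2) / 10,
                                         D = rep(0.3, 4)),
                       counts = NULL, meta = NULL),
                  class = "tme_proportions")
  cg <- spearman_correlogram(pm)
  expect_equal(cg$rho["A", "B"], 1)
  expect_equal(cg$rho["A", "C"], -1)
  expect_true(is.na(cg$rho["A", "D"]))
  expect_true(is.na(cg$adj_p["A", "D"]))
  expect_equal(diag(cg$rho), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(cg$rho))
  expect_error(spearman_correlogram(pm, subset = 1:2), "3 units")
})
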