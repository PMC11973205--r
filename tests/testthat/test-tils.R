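til_fixture <- function() {
  # 10-cell region: 8 epithelial tumor + 2 CD8+ T all in a "bulk tumor" CN,
  # plus 4 stromal + 1 CD4+ T + 1 macrophage in a "stromal" CN
  cells <- make_cells(seq(0, 150, length.out = 16), rep(0, 16),
                      c(rep("epithelial tumor", 8), rep("CD8+ T", 2),
                        rep("stromal", 4), "CD4+ T", "macrophage"))
  model <- structure(list(k = 2,
                          centers = rbind(c(1, 0), c(0, 1)),
                          cluster = c(rep(1L, 10), rep(2L, 6)),
                          cell_idx = 1:16, isolated = rep(FALSE, 16),
                          types = c("epithelial tumor", "stromal"),
                          include_index = TRUE,
                          names = c("bulk tumor", "stromal"), seed = 1),
                     class = "tme_cn_model")
  list(cells = cells, model = model)
}

test_that("TIL classes follow lymphocyte and compartment rules", {
  fx <- til_fixture()
  tils <- classify_tils(fx$cells, fx$model, tumor_cns = "bulk tumor",
                        stromal_cns = "stromal")
  expect_equal(tils$til_class[9], "iTIL")      # CD8+ T in bulk tumor CN
  expect_equal(tils$til_class[15], "sTIL")     # CD4+ T in stromal CN
  expect_equal(tils$til_class[16], "none")     # macrophage: not a lymphocyte
  expect_equal(tils$til_class[1], "none")      # tumor cell
  # conservation: every cell gets exactly one class
  expect_equal(sum(table(tils$til_class)), nrow(fx$cells))
  expect_true(all(tils$til_class[!(tils$cell_type %in%
                                     lymphocyte_cell_types())] == "none"))
  expect_error(classify_tils(fx$cells, fx$model, tumor_cns = "missing CN"),
               "available")
})

test_that("TIL proportions support both denominator conventions", {
  fx <- til_fixture()
  tils <- classify_tils(fx$cells, fx$model, tumor_cns = "bulk tumor",
                        stromal_cns = "stromal")
  tp_all <- til_proportions(tils, denominator = "cells_in_compartment_cns")
  expect_equal(tp_all$itil_prop, 2 / 10)   # 2 iTIL / 10 cells in tumor CNs
  tp_tum <- til_proportions(tils,
                            denominator = "compartment_cells_in_compartment_cns")
  expect_equal(tp_tum$itil_prop, 2 / 8)    # 2 iTIL / 8 tumor cells

  # region with no stromal-CN cells -> sTIL missing
  fx2 <- til_fixture()
  fx2$model$cluster <- rep(1L, 16)
  tils2 <- classify_tils(fx2$cells, fx2$model, tumor_cns = "bulk tumor",
                         stromal_cns = "stromal")
  tp2 <- til_proportions(tils2)
  expect_true(is.na(tp2$stil_prop))

  # zero lymphocytes -> proportions 0
  cells3 <- make_cells(1:6, rep(0, 6),
                       c(rep("epithelial tumor", 3), rep("stromal", 3)))
  model3 <- fx$model
  model3$cluster <- c(rep(1L, 3), rep(2L, 3)); model3$cell_idx <- 1:6
  model3$isolated <- rep(FALSE, 6)
  tils3 <- classify_tils(cells3, model3, tumor_cns = "bulk tumor",
                         stromal_cns = "stromal")
  tp3 <- til_proportions(tils3)
  expect_equal(tp3$itil_prop, 0)
  expect_equal(tp3$stil_prop, 0)
})

test_that("otsu split separates bimodal samples and respects affine maps", {
  v <- c(rep(0.05, 10), rep(0.25, 10))
  ot <- otsu_split(v)
  expect_gt(ot$threshold, 0.05)
  expect_lt(ot$threshold, 0.25)
  expect_equal(unname(ot$labels), rep(c("low", "high"), each = 10))

  ot2 <- otsu_split(c(0, 1))
  expect_gt(ot2$threshold, 0)
  expect_lt(ot2$threshold, 1)
  expect_equal(sort(unname(ot2$labels)), c("high", "low"))

  expect_error(otsu_split(rep(0.3, 5)), "constant")

  # affine invariance: threshold maps with the values
  set.seed(41)
  x <- c(rnorm(40, 0.06, 0.02), rnorm(40, 0.2, 0.02))
  t1 <- otsu_split(x)$threshold
  t2 <- otsu_split(3 * x + 1)$threshold
  expect_equal(t2, 3 * t1 + 1, tolerance = 1e-9)
})

test_that("otsu threshold sits near the density valley of a 2-mixture", {
  set.seed(42)
  x <- c(rnorm(50, 0.06, 0.02), rnorm(50, 0.2, 0.02))
  ot <- otsu_split(x)
  grid <- seq(0.06, 0.2, length.out = 2000)
  dens <- 0.5 * dnorm(grid, 0.06, 0.02) + 0.5 * dnorm(grid, 0.2, 0.02)
  valley <- grid[which.min(dens)]
  expect_lt(abs(ot$threshold - valley), 0.02)
})

test_that("KM and log-rank match hand enumeration; degenerate groups warn", {
  # toy: group 1 events at 1, 2; group 2 events at 3, 4
  clin <- data.frame(patient_id = paste0("P", 1:4),
                     msi_status = "MSS", recurrence = "no",
                     os_time = c(1, 2, 3, 4), os_event = 1)
  groups <- setNames(c("low", "low", "high", "high"), clin$patient_id)
  # fully separated toy groups make the Cox fit diverge; log-rank is the check
  sv <- suppressWarnings(survival_compare(clin, groups))
  hand <- logrank_hand(clin$os_time, clin$os_event,
                       factor(groups, levels = c("low", "high")))
  expect_equal(sv$logrank_chisq, hand, tolerance = 1e-9)

  # KM curves match the product-limit formula on a larger toy input
  set.seed(43)
  clin2 <- data.frame(patient_id = paste0("P", 1:20),
                      msi_status = "MSS", recurrence = "no",
                      os_time = sample(1:15, 20, TRUE),
                      os_event = rbinom(20, 1, 0.7))
  groups2 <- setNames(rep(c("low", "high"), 10), clin2$patient_id)
  sv2 <- survival_compare(clin2, groups2)
  for (g in c("low", "high")) {
    sel <- groups2 == g
    hand_km <- km_hand(clin2$os_time[sel], clin2$os_event[sel])
    got <- sv2$km[sv2$km$group == g & sv2$km$n_event > 0, ]
    expect_equal(got$surv, hand_km$surv, tolerance = 1e-9)
    expect_true(all(diff(got$surv) <= 1e-12))
    expect_true(all(diff(got$n_risk) <= 0))
  }
  hand2 <- logrank_hand(clin2$os_time, clin2$os_event,
                        factor(groups2, levels = c("low", "high")))
  expect_equal(sv2$logrank_chisq, hand2, tolerance = 1e-9)

  # identical event tables -> statistic 0, p = 1
  clin3 <- data.frame(patient_id = paste0("P", 1:4),
                      msi_status = "MSS", recurrence = "no",
                      os_time = c(5, 5, 9, 9), os_event = 1)
  groups3 <- setNames(c("low", "high", "low", "high"), clin3$patient_id)
  sv3 <- survival_compare(clin3, groups3)
  expect_equal(sv3$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(sv3$logrank_p, 1, tolerance = 1e-9)

  # zero events in a group: log-rank computed, Cox skipped with warning
  clin4 <- clin3; clin4$os_event <- c(1, 0, 1, 0)
  expect_warning(sv4 <- survival_compare(clin4, groups3), "zero events")
  expect_null(sv4$cox)
  expect_true(is.finite(sv4$logrank_chisq))
})
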