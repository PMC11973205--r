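test_that("directed matrix follows the type-of-interest convention", {
  # one A in contact with two B cells, B cells not touching each other
  cells <- make_cells(c(0, 8, 0), c(0, 0, 8), c("A", "B", "B"), radius = 2)
  adj <- contact_pairs(cells)
  expect_equal(nrow(adj), 2)
  dm <- directed_matrix(adj, cells)
  expect_equal(dm$M["A", "B"], 2)   # 2 contacts / 1 A cell
  expect_equal(dm$M["B", "A"], 1)   # 2 contacts / 2 B cells
  expect_equal(dm$M["A", "A"], 0)

  # homotypic contact counted from both endpoints
  bb <- make_cells(c(0, 8), c(0, 0), c("B", "B"), radius = 2)
  dmb <- directed_matrix(contact_pairs(bb), bb)
  expect_equal(dmb$M["B", "B"], 1)  # 2 incidences / 2 B cells

  # zero contacts -> all defined entries 0
  far <- make_cells(c(0, 100), c(0, 0), c("A", "B"), radius = 2)
  dmf <- directed_matrix(contact_pairs(far), far)
  expect_equal(unname(dmf$M), matrix(0, 2, 2))

  # absent type -> missing row
  dmv <- directed_matrix(adj, cells, type_vocab = c("A", "B", "C"))
  expect_true(all(is.na(dmv$M["C", ])))
})

test_that("permutation p-values match exhaustive enumeration on a toy region", {
  cells <- make_cells(c(0, 1, 2, 3), c(0, 0, 0, 0), c("A", "A", "B", "B"))
  adj <- make_adjacency(c(1, 2, 3), c(2, 3, 4), cells)  # path graph
  n_perm <- 4000
  res <- permutation_interaction_test(cells, adj, n_perm = n_perm,
                                      seed = 99, type_vocab = c("A", "B"))
  oracle <- exhaustive_pair_pvalues(cells$cell_type, adj$a, adj$b,
                                    c("A", "B"))
  for (i in seq_len(nrow(res))) {
    ia <- match(res$type_a[i], c("A", "B"))
    ib <- match(res$type_b[i], c("A", "B"))
    for (side in c("high", "low")) {
      q <- if (side == "high") oracle$q_high[ia, ib] else
        oracle$q_low[ia, ib]
      p_hat <- if (side == "high") res$p_high[i] else res$p_low[i]
      tol <- 3 * sqrt(q * (1 - q) / n_perm) + 2 / n_perm
      expect_lt(abs(p_hat - q), max(tol, 5e-3))
    }
  }
})

test_that("single-type regions yield permutation-invariant nulls", {
  cells <- make_cells(c(0, 8, 16), c(0, 0, 0), rep("A", 3), radius = 2)
  adj <- contact_pairs(cells)
  res <- permutation_interaction_test(cells, adj, n_perm = 200, seed = 5)
  expect_equal(res$label, "none")
  expect_equal(res$p_high, 1)
  expect_equal(res$p_low, 1)
  expect_warning(permutation_interaction_test(cells, adj, n_perm = 50,
                                              seed = 5), "100")
})

test_that("cohort logFC applies +1 smoothing in base 2", {
  mk <- function(lab) data.frame(type_a = "A", type_b = "B", label = lab)
  cls <- do.call(rbind, c(lapply(1:5, function(i) mk("interaction")),
                          lapply(1:5, function(i) mk("avoidance")),
                          lapply(1:3, function(i) mk("none"))))
  lf <- cohort_logfc(cls)
  expect_identical(lf$logfc, 0)           # 5 vs 5 -> exactly 0
  expect_equal(lf$n_regions, 13)

  lf2 <- cohort_logfc(do.call(rbind, lapply(1:10, function(i)
    mk("interaction"))))
  expect_equal(lf2$logfc, log2(11))       # 10 vs 0 -> log2(11/1)

  lf3 <- cohort_logfc(mk("none"))
  expect_equal(lf3$logfc, 0)              # 0 vs 0 -> log2(1/1)
})

test_that("interaction score is the contact fraction with the cell filter", {
  # contacts: A-B x2, B-B x1
  cells <- make_cells(c(0, 8, 0, 8), c(0, 0, 8, 8),
                      c("A", "B", "B", "A"), radius = 2)
  # manual adjacency: (1,2) A-B, (1,3) A-B, (2,3)? use explicit pairs
  adj <- make_adjacency(c(1, 1, 2), c(2, 3, 3), cells)
  sc <- interaction_score(adj, cells, min_cells = 0)
  expect_equal(sc$score[sc$type_a == "A" & sc$type_b == "B"], 2 / 3)
  expect_equal(sc$score[sc$type_a == "B" & sc$type_b == "B"], 1 / 3)
  expect_equal(sum(sc$score), 1)          # normalization over all pairs

  # all contacts A-B -> score 1
  adj2 <- make_adjacency(c(1, 4), c(2, 3), cells)
  sc2 <- interaction_score(adj2, cells, min_cells = 0)
  expect_equal(sc2$score[sc2$type_a == "A" & sc2$type_b == "B"], 1)

  # a type with fewer than min_cells excludes its pairs only
  cells3 <- make_cells(runif(44, 0, 60), runif(44, 0, 60),
                       c(rep("A", 19), rep("B", 25)), radius = 2)
  adj3 <- contact_pairs(cells3)
  sc3 <- interaction_score(adj3, cells3, min_cells = 20)
  expect_false(sc3$included[sc3$type_a == "A" & sc3$type_b == "B"])
  expect_false(sc3$included[sc3$type_a == "A" & sc3$type_b == "A"])
  expect_true(sc3$included[sc3$type_a == "B" & sc3$type_b == "B"])

  # region with zero contacts is excluded outright
  far <- make_cells(c(0, 100), c(0, 0), c("A", "B"), radius = 2)
  sc4 <- interaction_score(contact_pairs(far), far, min_cells = 0)
  expect_true(all(!sc4$included))
  expect_true(all(is.na(sc4$score)))
})

test_that("score test flags nothing on identical arms and honors filters", {
  set.seed(31)
  mkreg <- function(rid, pid) {
    make_cells(runif(120, 0, 120), runif(120, 0, 120),
               sample(c("CD4+ T", "stromal", "epithelial tumor"), 120, TRUE,
                      prob = c(0.3, 0.35, 0.35)),
               radius = 4, roi = rid, patient = pid)
  }
  cells <- do.call(rbind, lapply(1:12, function(i)
    mkreg(paste0("R", i), paste0("P", ceiling(i / 2)))))
  rois <- data.frame(roi_id = paste0("R", 1:12),
                     patient_id = paste0("P", ceiling(1:12 / 2)),
                     width_um = 120, height_um = 120)
  clin <- data.frame(patient_id = paste0("P", 1:6),
                     msi_status = rep(c("MSS", "MSI-H"), 3),
                     recurrence = "no", os_time = 1, os_event = 0)
  co <- new_cohort(cells, rois, clin,
                   type_vocab = c("CD4+ T", "stromal", "epithelial tumor"))
  sc <- cohort_interaction_scores(co, min_cells = 20)
  res <- interaction_score_test(sc, co, c("msi_status", "MSI-H", "MSS"))
  expect_true(all(res$adj_p > 0.05))

  # single pair tested -> BH is the identity
  res1 <- interaction_score_test(sc, co, c("msi_status", "MSI-H", "MSS"),
                                 pairs = data.frame(type_a = "CD4+ T",
                                                    type_b = "stromal"))
  expect_equal(nrow(res1), 1)
  expect_equal(res1$p, res1$adj_p)
})
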