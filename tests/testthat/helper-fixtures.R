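# Fixture builders and independent brute-force oracles, all generated in
# code at test time.

make_cells <- function(x, y, type, radius = 5, roi = "R1", patient = "P1") {
  data.frame(cell_id = paste0("c", seq_along(x)), roi_id = roi,
             patient_id = patient, x_um = x, y_um = y, cell_type = type,
             radius_um = radius, stringsAsFactors = FALSE)
}

make_adjacency <- function(a, b, cells) {
  structure(data.frame(a = a, b = b,
                       cell_a = cells$cell_id[a], cell_b = cells$cell_id[b],
                       border_um = 0, stringsAsFactors = FALSE),
            n_cells = nrow(cells), roi_id = cells$roi_id[1],
            threshold_um = 6, class = c("tme_adjacency", "data.frame"))
}

# Small two-patient cohort with handcrafted coordinates.
toy_cohort <- function() {
  set.seed(42)
  mk <- function(roi, pat, n, types) {
    make_cells(runif(n, 0, 100), runif(n, 0, 100),
               sample(types, n, replace = TRUE), radius = 4,
               roi = roi, patient = pat)
  }
  cells <- rbind(mk("R1", "P1", 40, c("CD8+ T", "stromal")),
                 mk("R2", "P1", 30, c("epithelial tumor", "stromal")),
                 mk("R3", "P2", 35, c("CD8+ T", "epithelial tumor")))
  rois <- data.frame(roi_id = c("R1", "R2", "R3"),
                     patient_id = c("P1", "P1", "P2"),
                     width_um = 100, height_um = 100,
                     tumor_purity = c(0.2, 0.6, 0.5))
  clinical <- data.frame(patient_id = c("P1", "P2"),
                         msi_status = c("MSS", "MSI-H"),
                         recurrence = c("no", "yes"),
                         os_time = c(24, 60), os_event = c(1, 0))
  new_cohort(cells, rois, clinical)
}

# O(n^2) contact oracle under the disc model.
brute_contacts <- function(cells, threshold = 6) {
  n <- nrow(cells)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                (cells$y_um[i] - cells$y_um[j])^2)
    border <- max(0, d - cells$radius_um[i] - cells$radius_um[j])
    if (border <= threshold) out <- rbind(out, c(i, j))
  }
  out
}

# Brute-force sorted-selection k-NN oracle with the (distance, id) tie rule.
brute_knn <- function(cells, k, r) {
  n <- nrow(cells)
  lapply(seq_len(n), function(i) {
    d <- sqrt((cells$x_um - cells$x_um[i])^2 + (cells$y_um - cells$y_um[i])^2)
    d[i] <- Inf
    ord <- order(d, cells$cell_id)
    sel <- ord[seq_len(min(k, n - 1))]
    sel[d[sel] <= r]
  })
}

# Delaunay edge oracle: an edge belongs to some triangle whose open
# circumdisc contains no other point (general-position inputs only).
brute_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    inside <- (x[others] - ux)^2 + (y[others] - uy)^2 < r2 * (1 - 1e-12)
    if (!any(inside)) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# Product-limit Kaplan-Meier oracle by direct enumeration.
km_hand <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Two-group log-rank statistic with the hypergeometric variance.
logrank_hand <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Direct step-up BH formula.
bh_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(ord)]
}

# Exhaustive permutation null of directed pair counts on a fixed graph.
exhaustive_pair_pvalues <- function(labels, a, b, types) {
  lab0 <- match(labels, types)
  Tn <- length(types)
  count_mat <- function(lab) {
    la <- lab[a]; lb <- lab[b]
    matrix(tabulate(c(la + (lb - 1) * Tn, lb + (la - 1) * Tn),
                    nbins = Tn * Tn), Tn, Tn)
  }
  obs <- count_mat(lab0)
  perms <- gtools_permutations(length(labels))
  ge <- matrix(0, Tn, Tn); le <- matrix(0, Tn, Tn)
  for (r in seq_len(nrow(perms))) {
    cm <- count_mat(lab0[perms[r, ]])
    ge <- ge + (cm >= obs)
    le <- le + (cm <= obs)
  }
  list(q_high = ge / nrow(perms), q_low = le / nrow(perms), obs = obs)
}

# All permutations of 1..n (n small).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub), n - 1))
  }))
}
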