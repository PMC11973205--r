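# Tier 1: variance-stabilized composition analysis. Proportions are
# empirical-logit transformed, region replicates from the same patient are
# absorbed through a consensus intra-patient correlation, tumor purity
# enters as a covariate, and per-category tests are moderated by an
# empirical-Bayes variance squeeze. Multiplicity is controlled by
# Benjamini-Hochberg within each comparison.

#' Cell-type (or neighborhood) proportions per region or patient
#'
#' @param cohort a `tme_cohort`.
#' @param level `"roi"` (each region one unit) or `"patient"` (cells pooled
#'   across the patient's regions before dividing).
#' @param categories `"cell_type"` or `"cn_label"`; for the latter supply
#'   `labels`.
#' @param labels optional per-cell category labels aligned with
#'   `cohort$cells` rows (NA cells are excluded, e.g. isolated cells).
#' @return Object of class `tme_proportions`: list with `fractions` and
#'   `counts` (units x categories matrices), `meta` (unit metadata:
#'   patient id, clinical labels, tumor purity), `level`, `categories`.
#' @export
proportions <- function(cohort, level = c("roi", "patient"),
                        categories = c("cell_type", "cn_label"),
                        labels = NULL) {
  level <- match.arg(level)
  categories <- match.arg(categories)
  stopifnot(inherits(cohort, "tme_cohort"))
  cells <- cohort$cells
  lab <- if (categories == "cell_type") {
    factor(cells$cell_type, levels = cohort$type_vocab)
  } else {
    if (is.null(labels)) stop("supply per-cell `labels` for cn_label",
                              call. = FALSE)
    stopifnot(length(labels) == nrow(cells))
    factor(labels)
  }
  keep <- !is.na(lab)
  unit <- if (level == "roi") cells$roi_id else cells$patient_id
  all_units <- if (level == "roi") cohort$rois$roi_id else
    cohort$clinical$patient_id
  counts <- table(factor(unit[keep], levels = all_units), lab[keep])
  counts <- matrix(counts, nrow = length(all_units),
                   dimnames = list(all_units, levels(lab)))
  tot <- rowSums(counts)
  empty <- tot == 0
  if (any(empty)) {
    warning(sprintf("excluding %d empty unit(s): %s", sum(empty),
                    paste(utils::head(all_units[empty], 5), collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
    tot <- tot[!empty]
  }
  fr <- counts / tot
  units <- rownames(counts)
  if (level == "roi") {
    m <- cohort$rois[match(units, cohort$rois$roi_id), ]
    meta <- data.frame(unit = units, patient_id = m$patient_id,
                       stringsAsFactors = FALSE)
    meta$tumor_purity <- if ("tumor_purity" %in% names(m)) m$tumor_purity
    else NA_real_
  } else {
    meta <- data.frame(unit = units, patient_id = units,
                       stringsAsFactors = FALSE)
    # patient-level purity: mean over the patient's regions
    if ("tumor_purity" %in% names(cohort$rois)) {
      mp <- tapply(cohort$rois$tumor_purity, cohort$rois$patient_id, mean,
                   na.rm = TRUE)
      meta$tumor_purity <- as.numeric(mp[units])
    } else meta$tumor_purity <- NA_real_
  }
  cl <- cohort$clinical[match(meta$patient_id, cohort$clinical$patient_id), ]
  meta$msi_status <- cl$msi_status
  meta$recurrence <- cl$recurrence
  stopifnot(all(abs(rowSums(fr) - 1) < 1e-9))
  structure(list(fractions = fr, counts = counts, meta = meta,
                 level = level, categories = categories),
            class = "tme_proportions")
}

#' Empirical logit transform of a proportion matrix
#'
#' `y = log((n + offset) / (N - n + offset))` per cell of the count matrix,
#' where `N` is the unit total. The pseudo-count keeps the transform finite
#' at 0 and N and stabilizes the variance of proportions.
#'
#' @param pm a `tme_proportions`.
#' @param offset pseudo-count (default 0.5).
#' @return units x categories matrix of transformed values, with the unit
#'   metadata attached as attribute `meta`.
#' @export
empirical_logit <- function(pm, offset = 0.5) {
  stopifnot(inherits(pm, "tme_proportions"))
  n <- pm$counts
  N <- rowSums(n)
  if (offset <= 0 && any(n == 0 | n == N)) {
    stop("offset must be > 0 when any count is 0 or N", call. = FALSE)
  }
  y <- log((n + offset) / (N - n + offset))
  structure(y, meta = pm$meta, offset = offset)
}

#' Consensus intra-block correlation of replicate units
#'
#' Estimates, for each category, the common correlation between
#' transformed proportions of units belonging to the same block (patient),
#' by REML under a one-way random-block model, and combines the
#' per-category estimates on the atanh scale (limma's consensus
#' correlation). Used to treat regions as replicates of a patient rather
#' than independent samples.
#'
#' @param y units x categories transformed matrix (may contain NA).
#' @param design model matrix for the fixed effects (condition + purity).
#' @param blocks block (patient) id per unit.
#' @return Single consensus correlation in (-0.99, 0.99).
#' @export
estimate_block_correlation <- function(y, design, blocks) {
  stopifnot(nrow(y) == length(blocks), nrow(design) == nrow(y))
  if (max(table(blocks)) < 2) {
    warning("all blocks are singletons; returning rho = 0")
    return(0)
  }
  dc <- suppressWarnings(
    limma::duplicateCorrelation(t(y), design = design, block = blocks))
  rho <- dc$consensus.correlation
  if (!is.finite(rho)) {
    warning("block correlation not estimable; returning rho = 0")
    return(0)
  }
  max(-0.99, min(0.99, rho))
}

build_design <- function(condition, purity = NULL) {
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2) {
    stop("condition must have exactly two levels", call. = FALSE)
  }
  design <- stats::model.matrix(~condition)
  colnames(design) <- c("(Intercept)", "effect")
  if (!is.null(purity)) {
    if (any(is.na(purity)) || stats::var(purity) < 1e-12) {
      warning("purity covariate constant or missing; dropping it")
    } else {
      d2 <- cbind(design, purity = purity)
      if (qr(d2)$rank < ncol(d2)) {
        warning("purity covariate collinear with design; dropping it")
      } else design <- d2
    }
  }
  design
}

#' Moderated two-condition test of transformed proportions
#'
#' Per category, a linear model with the condition contrast (and optional
#' purity covariate) is fitted by generalized least squares with a
#' block-exchangeable correlation `rho`; residual variances are shrunk
#' toward a pooled prior (empirical-Bayes squeeze) and moderated t
#' statistics are referred to a t distribution with augmented degrees of
#' freedom. P values are BH-adjusted across the categories of this
#' comparison.
#'
#' @param y units x categories transformed matrix (NA allowed).
#' @param condition two-level factor over units; the reported effect is
#'   second level minus first.
#' @param purity optional numeric covariate per unit.
#' @param blocks optional block (patient) ids; enables replicate
#'   correlation.
#' @param rho optional fixed intra-block correlation; estimated from the
#'   data when `blocks` is given and `rho` is NULL.
#' @return Object of class `tme_moderated_test`: data.frame with
#'   `category`, `effect`, `t`, `df_residual`, `df_prior`, `p`, `adj_p`;
#'   attribute `rho`.
#' @export
moderated_group_test <- function(y, condition, purity = NULL, blocks = NULL,
                                 rho = NULL) {
  stopifnot(is.matrix(y), length(condition) == nrow(y))
  if (is.null(colnames(y))) colnames(y) <- paste0("cat", seq_len(ncol(y)))
  cond <- droplevels(as.factor(condition))
  if (min(table(cond)) < 2) {
    stop("need at least 2 units per condition", call. = FALSE)
  }
  design <- build_design(cond, purity)
  use_blocks <- !is.null(blocks) && max(table(blocks)) >= 2
  if (use_blocks && is.null(rho)) {
    rho <- estimate_block_correlation(y, design, blocks)
  }
  if (!use_blocks) rho <- 0
  yt <- t(y)  # categories in rows, limma orientation
  fit <- if (use_blocks && abs(rho) > 1e-12) {
    limma::lmFit(yt, design, block = blocks, correlation = rho)
  } else {
    limma::lmFit(yt, design)
  }
  eb <- tryCatch(limma::eBayes(fit), error = function(e) NULL)
  if (is.null(eb)) {
    # degenerate: no residual variance anywhere (e.g. identical arms)
    eff <- fit$coefficients[, "effect"]
    res <- data.frame(category = rownames(yt), effect = eff,
                      t = ifelse(eff == 0, 0, Inf),
                      df_residual = fit$df.residual,
                      df_prior = 0,
                      p = ifelse(eff == 0, 1, 0),
                      stringsAsFactors = FALSE)
  } else {
    res <- data.frame(category = rownames(yt),
                      effect = eb$coefficients[, "effect"],
                      t = eb$t[, "effect"],
                      df_residual = eb$df.residual,
                      df_prior = eb$df.prior,
                      p = eb$p.value[, "effect"],
                      stringsAsFactors = FALSE)
    # categories with zero variance and zero effect are clean nulls
    bad <- !is.finite(res$t)
    res$t[bad & res$effect == 0] <- 0
    res$p[bad & res$effect == 0] <- 1
  }
  res$adj_p <- bh_adjust(res$p)
  rownames(res) <- NULL
  structure(res, rho = rho, design = design,
            class = c("tme_moderated_test", "data.frame"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pairwise Spearman correlogram of composition fractions
#'
#' All pairwise Spearman correlations between category fractions across
#' units, with BH-adjusted p values and a significance mask at adjusted
#' p <= 0.05. Constant categories yield missing entries that are excluded
#' from the BH family.
#'
#' @param pm a `tme_proportions`.
#' @param subset optional logical or index vector selecting units
#'   (e.g. one clinical condition).
#' @return Object of class `tme_correlogram`: list of symmetric matrices
#'   `rho`, `p`, `adj_p` and logical `sig`.
#' @export
spearman_correlogram <- function(pm, subset = NULL) {
  stopifnot(inherits(pm, "tme_proportions"))
  x <- pm$fractions
  if (!is.null(subset)) x <- x[subset, , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 units after filtering", call. = FALSE)
  k <- ncol(x)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
  diag(rho) <- 1; diag(p) <- NA
  const <- apply(x, 2, function(v) stats::var(v) < 1e-15)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (const[i] || const[j]) next
    ct <- suppressWarnings(stats::cor.test(x[, i], x[, j], method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  adj <- matrix(NA_real_, k, k, dimnames = dimnames(p))
  ut <- upper.tri(p)
  ok <- ut & !is.na(p)
  adj[ok] <- bh_adjust(p[ok])
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  sig <- !is.na(adj) & adj <= 0.05
  structure(list(rho = rho, p = p, adj_p = adj, sig = sig, n_units = nrow(x)),
            class = "tme_correlogram")
}

#' Test composition differences between two clinical conditions
#'
#' Convenience wrapper: subsets units to the two condition levels,
#' empirical-logit transforms, estimates the intra-patient replicate
#' correlation and runs the moderated test with an optional tumor-purity
#' covariate.
#'
#' @param pm a `tme_proportions`.
#' @param contrast character vector `c(variable, level_a, level_b)`, e.g.
#'   `c("msi_status", "MSI-H", "MSS")`; the effect is level_a minus
#'   level_b.
#' @param purity_covariate include tumor purity as covariate?
#' @param offset empirical-logit pseudo-count.
#' @return A `tme_moderated_test`.
#' @export
test_proportions <- function(pm, contrast, purity_covariate = TRUE,
                             offset = 0.5) {
  stopifnot(length(contrast) == 3)
  v <- pm$meta[[contrast[1]]]
  if (is.null(v)) stop(sprintf("unknown condition variable: %s", contrast[1]),
                       call. = FALSE)
  sel <- v %in% contrast[2:3]
  y <- empirical_logit(pm, offset)[sel, , drop = FALSE]
  cond <- factor(v[sel], levels = c(contrast[3], contrast[2])) # effect: a - b
  purity <- if (purity_covariate) pm$meta$tumor_purity[sel] else NULL
  blocks <- pm$meta$patient_id[sel]
  moderated_group_test(y, cond, purity = purity, blocks = blocks)
}
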