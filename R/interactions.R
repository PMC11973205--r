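# Tier 2: directed mean-interaction matrices, the permutation
# interaction/avoidance test with cohort logFC summary, and the
# quantitative interaction score with condition-level testing.

type_index <- function(cells, type_vocab = NULL) {
  types <- if (is.null(type_vocab)) sort(unique(cells$cell_type)) else
    type_vocab
  list(types = types, lab = match(cells$cell_type, types))
}

# Tabulate directed contact incidences for one labeling. Each unordered
# contact (i, j) is counted once from each side, so a homotypic A-A
# contact contributes 2 to the (A, A) cell.
directed_counts <- function(la, lb, n_types) {
  matrix(tabulate(c(la + (lb - 1L) * n_types, lb + (la - 1L) * n_types),
                  nbins = n_types * n_types),
         n_types, n_types)
}

#' Directed mean-interaction matrix of a region
#'
#' `M[A, B]` is the number of A-B contact incidences counted from A's side
#' divided by the number of A cells (the "cell type of interest"). A
#' homotypic contact is counted from both endpoints. Entries for absent
#' types are missing.
#'
#' @param adj `tme_adjacency` for the region.
#' @param cells the region's cell table.
#' @param type_vocab optional fixed type ordering.
#' @return Object of class `tme_directed_matrix`: list with `M` (mean
#'   interactions), `counts` (raw directed contact counts) and
#'   `type_counts`.
#' @export
directed_matrix <- function(adj, cells, type_vocab = NULL) {
  ti <- type_index(cells, type_vocab)
  Tn <- length(ti$types)
  counts <- directed_counts(ti$lab[adj$a], ti$lab[adj$b], Tn)
  tc <- tabulate(ti$lab, nbins = Tn)
  M <- counts / tc           # divides row A by #A (column-major recycling)
  M[tc == 0, ] <- NA_real_
  dimnames(M) <- dimnames(counts) <- list(ti$types, ti$types)
  structure(list(M = M, counts = counts,
                 type_counts = stats::setNames(tc, ti$types)),
            class = "tme_directed_matrix")
}

#' Permutation test for pairwise interaction and avoidance
#'
#' For every ordered type pair the observed mean interaction is compared
#' with its distribution under random re-assignment of the type labels
#' over the fixed contact graph (type counts preserved). Two one-tailed
#' add-one p values are computed; a pair is labeled `interaction` when
#' `p_high < alpha`, `avoidance` when `p_low < alpha` (if both fall below
#' `alpha` the smaller p wins; ties give `none`).
#'
#' @param cells the region's cell table.
#' @param adj `tme_adjacency` computed on the same region.
#' @param n_perm number of label permutations (default 1000).
#' @param alpha per-test significance level (default 0.01, strict `<`).
#' @param seed integer seed.
#' @param type_vocab optional fixed type ordering.
#' @return Object of class `tme_interaction_test`: data.frame with one row
#'   per ordered pair of present types: `type_a`, `type_b`, `obs_count`,
#'   `mean_interaction`, `p_high`, `p_low`, `label`.
#' @export
permutation_interaction_test <- function(cells, adj, n_perm = 1000,
                                         alpha = 0.01, seed = 1L,
                                         type_vocab = NULL) {
  if (n_perm < 100) warning("fewer than 100 permutations; p values are coarse")
  ti <- type_index(cells, type_vocab)
  Tn <- length(ti$types)
  n <- nrow(cells)
  lab <- ti$lab
  ea <- adj$a; eb <- adj$b
  obs <- directed_counts(lab[ea], lab[eb], Tn)
  tc <- tabulate(lab, nbins = Tn)

  n_ge <- matrix(0L, Tn, Tn)
  n_le <- matrix(0L, Tn, Tn)
  E <- length(ea)
  with_seed(seed, {
    chunk <- max(1L, min(n_perm, floor(4e6 / max(1, E))))
    done <- 0L
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      L <- vapply(seq_len(m), function(p) lab[sample.int(n)], integer(n))
      if (E > 0) {
        LA <- L[ea, , drop = FALSE]; LB <- L[eb, , drop = FALSE]
        off <- rep((seq_len(m) - 1L) * Tn * Tn, each = E)
        big <- c(LA + (LB - 1L) * Tn + off, LB + (LA - 1L) * Tn + off)
        tab <- array(tabulate(big, nbins = Tn * Tn * m), c(Tn, Tn, m))
      } else {
        tab <- array(0L, c(Tn, Tn, m))
      }
      # type counts are invariant under shuffling, so comparing raw
      # directed counts is equivalent to comparing mean interactions
      n_ge <- n_ge + rowSums(sweep(tab, c(1, 2), obs, ">=") + 0L, dims = 2)
      n_le <- n_le + rowSums(sweep(tab, c(1, 2), obs, "<=") + 0L, dims = 2)
      done <- done + m
    }
  })
  p_high <- (1 + n_ge) / (1 + n_perm)
  p_low <- (1 + n_le) / (1 + n_perm)

  present <- which(tc > 0)
  grid <- expand.grid(ia = present, ib = present)
  idx <- cbind(grid$ia, grid$ib)
  ph <- p_high[idx]; pl <- p_low[idx]
  label <- rep("none", nrow(grid))
  label[ph < alpha & (pl >= alpha | ph < pl)] <- "interaction"
  label[pl < alpha & (ph >= alpha | pl < ph)] <- "avoidance"
  res <- data.frame(type_a = ti$types[grid$ia], type_b = ti$types[grid$ib],
                    obs_count = obs[idx],
                    mean_interaction = obs[idx] / tc[grid$ia],
                    p_high = ph, p_low = pl, label = label,
                    stringsAsFactors = FALSE)
  res <- res[order(match(res$type_a, ti$types), match(res$type_b, ti$types)), ]
  rownames(res) <- NULL
  structure(res, n_perm = n_perm, alpha = alpha,
            roi_id = attr(adj, "roi_id"),
            class = c("tme_interaction_test", "data.frame"))
}

#' Cohort log fold-change of interacting versus avoiding regions
#'
#' Per ordered pair, `logFC = log2((n_interaction + 1) / (n_avoidance + 1))`
#' over the supplied regions; +1 smoothing keeps the summary finite and 0
#' when the counts are equal.
#'
#' @param classifications list of `tme_interaction_test` objects (one per
#'   region), or a single data.frame row-binding them.
#' @return data.frame with `type_a`, `type_b`, `n_interaction`,
#'   `n_avoidance`, `n_regions`, `logfc`.
#' @export
cohort_logfc <- function(classifications) {
  df <- if (is.data.frame(classifications)) classifications else
    do.call(rbind, lapply(classifications, as.data.frame))
  stopifnot(nrow(df) >= 1)
  key <- interaction(df$type_a, df$type_b, drop = TRUE, sep = "\r")
  n_int <- as.vector(tapply(df$label == "interaction", key, sum))
  n_avoid <- as.vector(tapply(df$label == "avoidance", key, sum))
  n_reg <- as.vector(tapply(df$label, key, length))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(type_a = vapply(parts, `[`, "", 1),
                    type_b = vapply(parts, `[`, "", 2),
                    n_interaction = n_int, n_avoidance = n_avoid,
                    n_regions = n_reg,
                    logfc = log2((n_int + 1) / (n_avoid + 1)),
                    stringsAsFactors = FALSE)
  out[order(out$type_a, out$type_b), , drop = FALSE]
}

#' Quantitative interaction scores of a region
#'
#' For every unordered type pair, the fraction of the region's contacts
#' that join the two types: `score = n_pair_contacts / n_total_contacts`
#' (each contact counted once; homotypic pairs included, so scores over
#' the full pair set sum to 1). A region is excluded for a pair when
#' either member type has fewer than `min_cells` cells, and entirely when
#' it has no contacts.
#'
#' @param adj `tme_adjacency` for the region.
#' @param cells the region's cell table.
#' @param min_cells per-type minimum cell count for inclusion (default 20).
#' @param type_vocab optional fixed type ordering.
#' @return Object of class `tme_interaction_scores`: data.frame with
#'   `type_a`, `type_b` (a <= b in vocabulary order), `n_contacts`,
#'   `n_total`, `score`, `included`.
#' @export
interaction_score <- function(adj, cells, min_cells = 20, type_vocab = NULL) {
  ti <- type_index(cells, type_vocab)
  Tn <- length(ti$types)
  la <- ti$lab[adj$a]; lb <- ti$lab[adj$b]
  u <- pmin(la, lb); v <- pmax(la, lb)
  pair_counts <- matrix(tabulate(u + (v - 1L) * Tn, nbins = Tn * Tn), Tn, Tn)
  total <- length(la)
  tc <- tabulate(ti$lab, nbins = Tn)
  grid <- which(upper.tri(pair_counts, diag = TRUE), arr.ind = TRUE)
  n_pair <- pair_counts[grid]
  included <- total > 0 & tc[grid[, 1]] >= min_cells & tc[grid[, 2]] >= min_cells
  res <- data.frame(type_a = ti$types[grid[, 1]], type_b = ti$types[grid[, 2]],
                    n_contacts = n_pair, n_total = total,
                    score = if (total > 0) n_pair / total else NA_real_,
                    included = included,
                    stringsAsFactors = FALSE)
  res <- res[order(grid[, 1], grid[, 2]), ]
  rownames(res) <- NULL
  structure(res, roi_id = attr(adj, "roi_id"), min_cells = min_cells,
            class = c("tme_interaction_scores", "data.frame"))
}

#' Compute interaction scores for every region of a cohort
#'
#' @param cohort a `tme_cohort`.
#' @param threshold_um membrane contact range.
#' @param min_cells per-type inclusion minimum.
#' @return data.frame row-binding per-region score tables with a `roi_id`
#'   column.
#' @export
cohort_interaction_scores <- function(cohort, threshold_um = 6,
                                      min_cells = 20) {
  regions <- split_by_roi(cohort$cells)
  out <- lapply(names(regions), function(rid) {
    adj <- contact_pairs(regions[[rid]], threshold_um = threshold_um)
    sc <- interaction_score(adj, regions[[rid]], min_cells = min_cells,
                            type_vocab = cohort$type_vocab)
    cbind(roi_id = rid, as.data.frame(sc))
  })
  do.call(rbind, out)
}

#' Test interaction scores between two clinical conditions
#'
#' Scores are logit-transformed on their contact counts with the same
#' pseudo-count convention as composition testing
#' (`log((n + offset)/(N - n + offset))`), then passed through the
#' intra-patient consensus correlation and moderated test machinery.
#' Regions excluded for a pair (count filter or no contacts) are missing
#' for that pair only; pairs with fewer than 2 included regions in either
#' arm are dropped with a warning. BH adjustment runs across the tested
#' pair set.
#'
#' @param scores output of [cohort_interaction_scores()].
#' @param cohort the `tme_cohort` providing patient and clinical metadata.
#' @param contrast `c(variable, level_a, level_b)` as in
#'   [test_proportions()].
#' @param pairs optional data.frame(`type_a`, `type_b`) restricting the
#'   tested pairs (e.g. the immune-involving subset).
#' @param offset pseudo-count for the logit transform.
#' @return A `tme_moderated_test` with one row per tested pair
#'   (`category` = "type_a|type_b").
#' @export
interaction_score_test <- function(scores, cohort, contrast, pairs = NULL,
                                   offset = 0.5) {
  stopifnot(length(contrast) == 3)
  df <- as.data.frame(scores)
  if (!is.null(pairs)) {
    want_f <- paste(pairs$type_a, pairs$type_b, sep = "|")
    want_r <- paste(pairs$type_b, pairs$type_a, sep = "|")
    have <- paste(df$type_a, df$type_b, sep = "|")
    df <- df[have %in% c(want_f, want_r), , drop = FALSE]
  }
  if (!nrow(df)) stop("no pairs to test", call. = FALSE)
  df$pair <- paste(df$type_a, df$type_b, sep = "|")
  rois <- sort(unique(df$roi_id))
  pair_levels <- sort(unique(df$pair))
  y <- matrix(NA_real_, length(rois), length(pair_levels),
              dimnames = list(rois, pair_levels))
  ok <- df$included & df$n_total > 0
  yv <- log((df$n_contacts[ok] + offset) /
              (df$n_total[ok] - df$n_contacts[ok] + offset))
  y[cbind(match(df$roi_id[ok], rois), match(df$pair[ok], pair_levels))] <- yv

  ri <- cohort$rois[match(rois, cohort$rois$roi_id), ]
  cl <- cohort$clinical[match(ri$patient_id, cohort$clinical$patient_id), ]
  v <- cl[[contrast[1]]]
  if (is.null(v)) stop(sprintf("unknown condition variable: %s", contrast[1]),
                       call. = FALSE)
  sel <- v %in% contrast[2:3]
  y <- y[sel, , drop = FALSE]
  cond <- factor(v[sel], levels = c(contrast[3], contrast[2]))
  blocks <- ri$patient_id[sel]

  # drop pairs with < 2 included regions in either arm
  enough <- vapply(seq_len(ncol(y)), function(j) {
    tab <- table(cond[!is.na(y[, j])])
    length(tab) == 2 && min(tab) >= 2
  }, logical(1))
  if (any(!enough)) {
    warning(sprintf("dropping %d pair(s) with < 2 included regions per arm",
                    sum(!enough)))
    y <- y[, enough, drop = FALSE]
  }
  if (!ncol(y)) stop("no pair has enough included regions", call. = FALSE)
  moderated_group_test(y, cond, blocks = blocks)
}
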