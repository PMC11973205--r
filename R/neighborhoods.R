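# Tier 3a: cell-neighborhood (CN) features, K-means CN discovery and
# annotation, and CN-level composition analyses.

#' Neighborhood composition features
#'
#' For each cell, the type-composition vector of its neighborhood: the
#' in-radius nearest neighbors plus, by default, the index cell itself.
#' Cells with no in-radius neighbor are flagged isolated and receive no
#' feature row (and are excluded from clustering downstream).
#'
#' @param neighbors a `tme_neighbors` from [knn_within_radius()].
#' @param cells the region's cell table.
#' @param include_index include the index cell in its own composition?
#' @param type_vocab type ordering for the feature columns.
#' @return Object of class `tme_cn_features`: list with `features` (rows =
#'   non-isolated cells, columns = types, fractions summing to 1),
#'   `cell_idx` (row index into `cells` per feature row), `isolated`
#'   (logical per cell).
#' @export
cn_features <- function(neighbors, cells, include_index = TRUE,
                        type_vocab = NULL) {
  stopifnot(inherits(neighbors, "tme_neighbors"))
  types <- if (is.null(type_vocab)) sort(unique(cells$cell_type)) else
    type_vocab
  lab <- match(cells$cell_type, types)
  n <- nrow(cells)
  stopifnot(length(neighbors$neighbors) == n)
  n_nb <- lengths(neighbors$neighbors)
  isolated <- n_nb == 0
  keep <- which(!isolated)
  Tn <- length(types)
  idx_rep <- rep(seq_along(keep), n_nb[keep])
  nb_lab <- lab[unlist(neighbors$neighbors[keep], use.names = FALSE)]
  feats <- matrix(0, length(keep), Tn, dimnames = list(NULL, types))
  if (length(nb_lab)) {
    tab <- tabulate(idx_rep + (nb_lab - 1L) * length(keep),
                    nbins = length(keep) * Tn)
    feats[] <- tab
  }
  if (include_index) {
    feats[cbind(seq_along(keep), lab[keep])] <-
      feats[cbind(seq_along(keep), lab[keep])] + 1
  }
  feats <- feats / rowSums(feats)
  structure(list(features = feats, cell_idx = keep, isolated = isolated,
                 include_index = include_index, types = types),
            class = "tme_cn_features")
}

#' Neighborhood features for a whole cohort
#'
#' Runs [knn_within_radius()] and [cn_features()] per region and stacks
#' the rows, so CN clustering pools cells across all patients.
#'
#' @param cohort a `tme_cohort`.
#' @param k,radius_um neighbor search parameters (defaults 10 and 40).
#' @param include_index include the index cell in its composition?
#' @return `tme_cn_features` whose `cell_idx` indexes rows of
#'   `cohort$cells`.
#' @export
cohort_cn_features <- function(cohort, k = 10, radius_um = 40,
                               include_index = TRUE) {
  cells <- cohort$cells
  regions <- split_by_roi(cells)
  offsets <- cumsum(c(0, vapply(regions, nrow, 0L)))
  feats <- list(); idx <- list(); iso <- logical(nrow(cells))
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    nb <- knn_within_radius(reg, k = k, radius_um = radius_um)
    cf <- cn_features(nb, reg, include_index = include_index,
                      type_vocab = cohort$type_vocab)
    feats[[i]] <- cf$features
    idx[[i]] <- cf$cell_idx + offsets[i]
    iso[which(cf$isolated) + offsets[i]] <- TRUE
  }
  # regions were split in first-appearance order, matching cells rows
  structure(list(features = do.call(rbind, feats),
                 cell_idx = unlist(idx), isolated = iso,
                 include_index = include_index, types = cohort$type_vocab),
            class = "tme_cn_features")
}

# k-means++ seeding: spread initial centers by sampling points with
# probability proportional to squared distance from the nearest center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    if (sum(d2) <= 0) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = d2)
    }
    centers[j + 1L, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1L, ])^2))
  }
  centers
}

#' Cluster neighborhood compositions into CN classes
#'
#' K-means with squared Euclidean distance on the composition vectors,
#' k-means++ initialization and `n_init` restarts under a fixed seed; the
#' best run by total within-cluster sum of squares is kept.
#'
#' @param features a `tme_cn_features`.
#' @param k number of CN classes (default 8).
#' @param seed integer seed.
#' @param n_init number of restarts (default 10).
#' @return Object of class `tme_cn_model`: list with `k`, `centers`
#'   (k x types), `cluster` (label in 1..k per feature row), `cell_idx`,
#'   `isolated`, `names` (NULL until [annotate_cns()]), `seed`.
#' @export
cluster_cns <- function(features, k = 8, seed = 1L, n_init = 10) {
  stopifnot(inherits(features, "tme_cn_features"))
  X <- features$features
  if (k > nrow(X)) stop("k exceeds the number of feature rows", call. = FALSE)
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      init <- kmeanspp_centers(X, k)
      fit <- suppressWarnings(
        stats::kmeans(X, centers = init, iter.max = 100))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  structure(list(k = k, centers = best$centers, cluster = best$cluster,
                 cell_idx = features$cell_idx, isolated = features$isolated,
                 types = features$types,
                 include_index = features$include_index,
                 names = NULL, seed = seed),
            class = "tme_cn_model")
}

#' Annotate CN classes by centroid composition
#'
#' Default rule: if no type reaches the `dominance` fraction the CN is
#' "mixed immune"; a dominant tumor subtype names the CN "bulk tumor",
#' "p53+ tumor" or "proliferative tumor"; dominant stroma with at least
#' `immune_fraction` summed immune content is "immune-enriched stromal",
#' otherwise "stromal"; a dominant immune type gives "<type> enriched".
#' A user rule table (`data.frame(cluster, name)`) overrides everything.
#'
#' @param model a `tme_cn_model`.
#' @param immune_fraction immune content needed to call enriched stroma.
#' @param dominance minimum dominant-type fraction (default 0.4).
#' @param rules optional data.frame(`cluster`, `name`).
#' @return The model with `names` filled (length k, unique).
#' @export
annotate_cns <- function(model, immune_fraction = 0.25, dominance = 0.4,
                         rules = NULL) {
  stopifnot(inherits(model, "tme_cn_model"))
  centers <- model$centers
  types <- model$types
  tumor_map <- c("epithelial tumor" = "bulk tumor",
                 "p53+ tumor" = "p53+ tumor",
                 "proliferative tumor" = "proliferative tumor")
  immune <- intersect(immune_cell_types(), types)
  nm <- character(model$k)
  for (i in seq_len(model$k)) {
    cc <- centers[i, ]
    dom <- types[which.max(cc)]
    if (max(cc) < dominance) {
      nm[i] <- "mixed immune"
    } else if (dom %in% names(tumor_map)) {
      nm[i] <- tumor_map[[dom]]
    } else if (dom == "stromal") {
      nm[i] <- if (sum(cc[immune]) >= immune_fraction)
        "immune-enriched stromal" else "stromal"
    } else {
      nm[i] <- paste(dom, "enriched")
    }
  }
  if (!is.null(rules)) {
    stopifnot(all(c("cluster", "name") %in% names(rules)))
    nm[rules$cluster] <- rules$name
  }
  # disambiguate duplicates by suffixing an index
  dup <- duplicated(nm) | duplicated(nm, fromLast = TRUE)
  if (any(dup)) {
    for (u in unique(nm[dup])) {
      hits <- which(nm == u)
      nm[hits] <- paste(u, seq_along(hits))
    }
  }
  model$names <- nm
  model
}

#' Per-cell CN labels aligned with a cohort's cell table
#'
#' @param model an annotated `tme_cn_model`.
#' @param n_cells number of rows of the cohort's cell table.
#' @return Character vector of CN names (NA for isolated cells).
#' @export
cn_labels <- function(model, n_cells) {
  stopifnot(inherits(model, "tme_cn_model"))
  nm <- if (is.null(model$names)) as.character(seq_len(model$k)) else
    model$names
  out <- rep(NA_character_, n_cells)
  out[model$cell_idx] <- nm[model$cluster]
  out
}

#' CN proportion analyses
#'
#' Delegates to the composition machinery with categories = CN classes:
#' proportions per unit, the moderated two-condition test, and the
#' Spearman correlogram.
#'
#' @param cohort a `tme_cohort`.
#' @param model an annotated `tme_cn_model` fitted on this cohort.
#' @param contrast `c(variable, level_a, level_b)`; NULL skips testing.
#' @param level `"roi"` or `"patient"`.
#' @param correlogram_subset optional unit filter for the correlogram.
#' @return list with `proportions`, `test` (NULL when degenerate or no
#'   contrast), `correlogram` (NULL when < 3 units or degenerate).
#' @export
cn_proportion_analyses <- function(cohort, model, contrast = NULL,
                                   level = "roi",
                                   correlogram_subset = NULL) {
  labels <- cn_labels(model, nrow(cohort$cells))
  pm <- proportions(cohort, level = level, categories = "cn_label",
                    labels = labels)
  if (ncol(pm$fractions) < 2) {
    warning("all cells share one CN; tests skipped")
    return(list(proportions = pm, test = NULL, correlogram = NULL))
  }
  test <- if (!is.null(contrast)) test_proportions(pm, contrast) else NULL
  cg <- if (nrow(pm$fractions) >= 3)
    spearman_correlogram(pm, subset = correlogram_subset) else NULL
  list(proportions = pm, test = test, correlogram = cg)
}
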