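# Orchestrates simulate -> graph -> proportions -> interactions ->
# neighborhoods -> tils as one configured, logged, reproducible run.

#' Permutation interaction classification for every region of a cohort
#'
#' Runs [contact_pairs()] and [permutation_interaction_test()] per region
#' with a deterministic per-region seed derived from the global seed.
#'
#' @param cohort a `tme_cohort`.
#' @param threshold_um membrane contact range (default 6).
#' @param n_perm,alpha permutation test parameters.
#' @param seed global seed; region i uses substream i.
#' @return data.frame row-binding per-region classifications with a
#'   `roi_id` column.
#' @export
cohort_interaction_classification <- function(cohort, threshold_um = 6,
                                              n_perm = 1000, alpha = 0.01,
                                              seed = 1L) {
  regions <- split_by_roi(cohort$cells)
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    adj <- contact_pairs(reg, threshold_um = threshold_um)
    cls <- permutation_interaction_test(reg, adj, n_perm = n_perm,
                                        alpha = alpha,
                                        seed = substream_seed(seed, i),
                                        type_vocab = NULL)
    out[[i]] <- cbind(roi_id = names(regions)[i], as.data.frame(cls))
  }
  do.call(rbind, out)
}

#' Configure a full pipeline run
#'
#' @param simulate a [simulation_config()], or NULL to load tables.
#' @param input list of paths (`cells`, `rois`, `clinical`) when not
#'   simulating.
#' @param stages stages to run, in dependency order; any subset of
#'   `c("graph", "proportions", "interactions", "neighborhoods", "tils")`.
#' @param contrast clinical contrast `c(variable, level_a, level_b)` for
#'   the testing stages.
#' @param contact_um,n_perm,alpha,min_cells interaction parameters.
#' @param knn,radius_um,k,include_index neighborhood parameters.
#' @param tumor_cns,stromal_cns CN compartments for TILs, or `"auto"` to
#'   take whichever canonical names the annotation produced.
#' @param denominator TIL denominator convention.
#' @param otsu_bins Otsu histogram resolution.
#' @param level unit level for composition tests.
#' @param seed global seed for every stochastic stage.
#' @param out_dir output directory, or NULL to skip writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL,
                            stages = c("graph", "proportions",
                                       "interactions", "neighborhoods",
                                       "tils"),
                            contrast = c("msi_status", "MSI-H", "MSS"),
                            contact_um = 6, n_perm = 1000, alpha = 0.01,
                            min_cells = 20, knn = 10, radius_um = 40,
                            k = 8, include_index = TRUE,
                            tumor_cns = "auto", stromal_cns = "auto",
                            denominator = "cells_in_compartment_cns",
                            otsu_bins = 256, level = "roi", seed = 1L,
                            out_dir = NULL) {
  known <- c("graph", "proportions", "interactions", "neighborhoods", "tils")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop(sprintf("configuration error: unknown stage(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if ("tils" %in% stages && !("neighborhoods" %in% stages)) {
    stop("configuration error: stage 'tils' requires 'neighborhoods'",
         call. = FALSE)
  }
  if ("interactions" %in% stages && !("graph" %in% stages)) {
    stop("configuration error: stage 'interactions' requires 'graph'",
         call. = FALSE)
  }
  if (is.null(simulate) && is.null(input)) {
    stop("configuration error: provide `simulate` or `input`", call. = FALSE)
  }
  stopifnot(contact_um >= 0, n_perm >= 1, alpha > 0, alpha < 1,
            min_cells >= 0, knn >= 1, radius_um > 0, k >= 1,
            otsu_bins >= 2)
  structure(list(simulate = simulate, input = input, stages = stages,
                 contrast = contrast, contact_um = contact_um,
                 n_perm = n_perm, alpha = alpha, min_cells = min_cells,
                 knn = knn, radius_um = radius_um, k = k,
                 include_index = include_index, tumor_cns = tumor_cns,
                 stromal_cns = stromal_cns, denominator = denominator,
                 otsu_bins = otsu_bins, level = level,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

pm_long <- function(pm) {
  data.frame(unit = rep(rownames(pm$fractions), ncol(pm$fractions)),
             category = rep(colnames(pm$fractions),
                            each = nrow(pm$fractions)),
             count = as.vector(pm$counts),
             fraction = as.vector(pm$fractions),
             stringsAsFactors = FALSE)
}

correlogram_long <- function(cg) {
  k <- nrow(cg$rho)
  ut <- which(upper.tri(cg$rho), arr.ind = TRUE)
  data.frame(category_a = rownames(cg$rho)[ut[, 1]],
             category_b = colnames(cg$rho)[ut[, 2]],
             rho = cg$rho[ut], p = cg$p[ut], adj_p = cg$adj_p[ut],
             significant = cg$sig[ut], stringsAsFactors = FALSE)
}

#' Run the configured pipeline
#'
#' Executes the enabled stages in dependency order; all outputs are plain
#' tables stamped (via the manifest) with a hash of the configuration, and
#' a rerun with the identical configuration reproduces them exactly.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages?
#' @return Object of class `tme_pipeline_result`: list with `tables`
#'   (named data.frames), `log` (one row per stage), `cohort`, `config`,
#'   and when simulated, `truth`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  tables <- list()
  log <- list()
  note <- function(stage, detail, rows, t0) {
    log[[length(log) + 1]] <<- data.frame(
      stage = stage, detail = detail, rows = rows,
      seconds = round(as.numeric(Sys.time()) - t0, 2))
    if (!quiet) message(sprintf("[%s] %s (%d rows)", stage, detail, rows))
  }

  t0 <- as.numeric(Sys.time())
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(config$simulate)
    cohort <- sim$cohort
    truth <- sim$truth
    note("simulate", sprintf("seed %d", config$simulate$seed),
         nrow(cohort$cells), t0)
  } else {
    cohort <- load_cohort(config$input$cells, config$input$rois,
                          config$input$clinical)
    note("load", config$input$cells, nrow(cohort$cells), t0)
  }
  regions <- split_by_roi(cohort$cells)
  contrast_ok <- {
    v <- cohort$clinical[[config$contrast[1]]]
    tab <- table(v[v %in% config$contrast[2:3]])
    !is.null(v) && length(tab) == 2 && min(tab) >= 2
  }

  adjacencies <- NULL
  if ("graph" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    adjacencies <- lapply(regions, contact_pairs,
                          threshold_um = config$contact_um)
    edges <- do.call(rbind, lapply(names(adjacencies), function(rid) {
      a <- adjacencies[[rid]]
      if (!nrow(a)) return(NULL)
      data.frame(roi_id = rid, cell_a = a$cell_a, cell_b = a$cell_b,
                 border_um = a$border_um, stringsAsFactors = FALSE)
    }))
    if (is.null(edges)) edges <- data.frame(roi_id = character(0),
                                            cell_a = character(0),
                                            cell_b = character(0),
                                            border_um = numeric(0))
    tables$contact_edges <- edges
    spacing <- do.call(rbind, lapply(names(regions), function(rid) {
      g <- delaunay_graph(regions[[rid]])
      if (!nrow(g)) return(NULL)
      st <- neighbor_distance_stats(g)
      data.frame(roi_id = rid, n_edges = nrow(g), modal_um = st$modal_um)
    }))
    tables$neighbor_spacing <- spacing
    note("graph", sprintf("contact <= %g um", config$contact_um),
         nrow(edges), t0)
  }

  if ("proportions" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    pm <- proportions(cohort, level = config$level)
    tables$proportions <- pm_long(pm)
    if (contrast_ok) {
      tables$proportion_test <-
        as.data.frame(test_proportions(pm, config$contrast))
    } else if (!quiet) message("[proportions] contrast skipped (arms too small)")
    if (nrow(pm$fractions) >= 3) {
      tables$proportion_correlogram <-
        correlogram_long(spearman_correlogram(pm))
    }
    note("proportions", config$level, nrow(tables$proportions), t0)
  }

  if ("interactions" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    cls <- cohort_interaction_classification(cohort,
                                             threshold_um = config$contact_um,
                                             n_perm = config$n_perm,
                                             alpha = config$alpha,
                                             seed = config$seed)
    tables$interaction_classification <- cls
    tables$interaction_logfc <- cohort_logfc(cls)
    sc <- cohort_interaction_scores(cohort, threshold_um = config$contact_um,
                                    min_cells = config$min_cells)
    tables$interaction_scores <- sc
    if (contrast_ok) {
      tst <- tryCatch(
        interaction_score_test(sc, cohort, config$contrast),
        error = function(e) NULL)
      if (!is.null(tst)) tables$interaction_score_test <- as.data.frame(tst)
    }
    note("interactions", sprintf("%d permutations", config$n_perm),
         nrow(cls), t0)
  }

  model <- NULL
  if ("neighborhoods" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    feats <- cohort_cn_features(cohort, k = config$knn,
                                radius_um = config$radius_um,
                                include_index = config$include_index)
    model <- annotate_cns(cluster_cns(feats, k = config$k,
                                      seed = config$seed))
    labs <- cn_labels(model, nrow(cohort$cells))
    tables$cn_cells <- data.frame(roi_id = cohort$cells$roi_id,
                                  cell_id = cohort$cells$cell_id,
                                  cn_name = labs, stringsAsFactors = FALSE)
    tables$cn_centroids <- data.frame(cn_name = model$names,
                                      model$centers, check.names = FALSE)
    cn_an <- cn_proportion_analyses(cohort, model,
                                    contrast = if (contrast_ok)
                                      config$contrast else NULL,
                                    level = config$level)
    tables$cn_proportions <- pm_long(cn_an$proportions)
    if (!is.null(cn_an$test)) tables$cn_test <- as.data.frame(cn_an$test)
    if (!is.null(cn_an$correlogram)) {
      tables$cn_correlogram <- correlogram_long(cn_an$correlogram)
    }
    note("neighborhoods",
         sprintf("k=%d, %d isolated cells", config$k, sum(model$isolated)),
         nrow(tables$cn_cells), t0)
  }

  if ("tils" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    tumor_cns <- config$tumor_cns
    stromal_cns <- config$stromal_cns
    if (identical(tumor_cns, "auto")) {
      tumor_cns <- intersect(c("bulk tumor", "p53+ tumor",
                               "proliferative tumor"), model$names)
    }
    if (identical(stromal_cns, "auto")) {
      stromal_cns <- intersect(c("stromal", "immune-enriched stromal"),
                               model$names)
    }
    if (!length(tumor_cns) || !length(stromal_cns)) {
      stop(sprintf("data error: no tumor or stromal CN among: %s",
                   paste(model$names, collapse = ", ")), call. = FALSE)
    }
    tils <- classify_tils(cohort$cells, model, tumor_cns = tumor_cns,
                          stromal_cns = stromal_cns)
    tables$til_cells <- as.data.frame(tils)
    tp <- til_proportions(tils, level = "patient",
                          denominator = config$denominator)
    tables$til_proportions <- tp
    st <- tp$stil_prop[!is.na(tp$stil_prop)]
    names(st) <- tp$unit[!is.na(tp$stil_prop)]
    surv_done <- FALSE
    if (length(unique(st)) >= 2) {
      ot <- otsu_split(st, n_bins = config$otsu_bins)
      if (min(table(ot$labels)) >= 2) {
        sv <- survival_compare(cohort$clinical, ot$labels)
        tables$til_survival_km <- sv$km
        tables$til_survival_summary <- data.frame(
          otsu_threshold = ot$threshold,
          logrank_chisq = sv$logrank_chisq, logrank_p = sv$logrank_p,
          cox_hr = if (is.null(sv$cox)) NA_real_ else sv$cox$hr,
          n_high = sum(ot$labels == "high"),
          n_low = sum(ot$labels == "low"))
        surv_done <- TRUE
      }
    }
    if (!surv_done && !quiet) {
      message("[tils] survival comparison skipped (degenerate TIL split)")
    }
    note("tils", paste(config$denominator), nrow(tp), t0)
  }

  log_df <- do.call(rbind, log)
  if (!is.null(config$out_dir)) {
    tables_out <- c(tables, list(run_log = log_df))
    write_results(tables_out, config$out_dir, config = config)
  }
  structure(list(tables = tables, log = log_df, cohort = cohort,
                 truth = truth, config = config),
            class = "tme_pipeline_result")
}

#' @export
print.tme_pipeline_result <- function(x, ...) {
  cat("tme_pipeline_result with tables:\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %-28s %6d rows\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` block mirrors [simulation_config()] (arms given as
#' `name: {n_patients: ..., proportions: {...}}` or with `niche_weights`).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    s <- raw$simulate
    args <- s[intersect(names(s),
                        names(formals(simulation_config)))]
    if (!is.null(args$arms)) {
      args$arms <- lapply(args$arms, function(a) {
        if (!is.null(a$proportions)) a$proportions <- unlist(a$proportions)
        if (!is.null(a$niche_weights)) a$niche_weights <- unlist(a$niche_weights)
        a
      })
    }
    if (!is.null(args$attraction)) {
      args$attraction <- do.call(rbind,
                                 lapply(args$attraction, as.data.frame))
    }
    sim <- do.call(simulation_config, args)
  }
  top <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  top$simulate <- sim
  if (!is.null(raw$input)) top$input <- raw$input
  if (!is.null(top$contrast)) top$contrast <- unlist(top$contrast)
  if (!is.null(top$stages)) top$stages <- unlist(top$stages)
  do.call(pipeline_config, top)
}
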