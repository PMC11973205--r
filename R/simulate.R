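# Synthetic multi-patient, multi-region cohorts with known ground truth:
# planted niches, controllable pairwise attraction, clinical arms with
# composition effects, and survival driven by the stromal-TIL fraction.

#' Default planted-niche definitions
#'
#' Six niche archetypes mirroring recurring tumor-microenvironment
#' neighborhoods: three tumor compartments, plain stroma, immune-enriched
#' stroma, and a mixed immune infiltrate. Each niche has a type mixture
#' (simplex over the vocabulary), a number of seed centers per region and
#' a Gaussian dispersion in micrometres.
#'
#' @return Named list of niche definitions.
#' @export
default_niches <- function() {
  v <- default_cell_types()
  mix <- function(...) {
    m <- c(...)
    stopifnot(abs(sum(m) - 1) < 1e-8)
    out <- stats::setNames(numeric(length(v)), v)
    out[names(m)] <- m
    out
  }
  list(
    "bulk tumor" = list(
      mixture = mix("epithelial tumor" = 0.75, "stromal" = 0.08,
                    "macrophage" = 0.05, "proliferative tumor" = 0.03,
                    "p53+ tumor" = 0.02, "CD8+ T" = 0.03, "CD4+ T" = 0.02,
                    "B cell" = 0.005, "ILC/NK" = 0.005,
                    "proliferative immune" = 0.01),
      n_centers = 12, sigma_um = 60),
    "p53+ tumor" = list(
      mixture = mix("p53+ tumor" = 0.75, "epithelial tumor" = 0.08,
                    "stromal" = 0.07, "macrophage" = 0.04, "CD8+ T" = 0.02,
                    "CD4+ T" = 0.02, "proliferative tumor" = 0.01,
                    "proliferative immune" = 0.005, "B cell" = 0.003,
                    "ILC/NK" = 0.002),
      n_centers = 4, sigma_um = 60),
    "proliferative tumor" = list(
      mixture = mix("proliferative tumor" = 0.70, "epithelial tumor" = 0.12,
                    "stromal" = 0.08, "macrophage" = 0.04, "CD8+ T" = 0.02,
                    "CD4+ T" = 0.02, "p53+ tumor" = 0.01,
                    "proliferative immune" = 0.005, "B cell" = 0.003,
                    "ILC/NK" = 0.002),
      n_centers = 4, sigma_um = 60),
    "stromal" = list(
      mixture = mix("stromal" = 0.80, "macrophage" = 0.06,
                    "epithelial tumor" = 0.05, "CD4+ T" = 0.03,
                    "CD8+ T" = 0.02, "B cell" = 0.01, "ILC/NK" = 0.01,
                    "proliferative immune" = 0.01, "p53+ tumor" = 0.005,
                    "proliferative tumor" = 0.005),
      n_centers = 10, sigma_um = 60),
    "immune-enriched stromal" = list(
      mixture = mix("stromal" = 0.45, "CD4+ T" = 0.13, "CD8+ T" = 0.12,
                    "macrophage" = 0.10, "B cell" = 0.08, "ILC/NK" = 0.04,
                    "proliferative immune" = 0.04, "epithelial tumor" = 0.03,
                    "p53+ tumor" = 0.005, "proliferative tumor" = 0.005),
      n_centers = 6, sigma_um = 60),
    "mixed immune" = list(
      mixture = mix("macrophage" = 0.25, "CD8+ T" = 0.18, "CD4+ T" = 0.16,
                    "B cell" = 0.12, "ILC/NK" = 0.10,
                    "proliferative immune" = 0.09, "stromal" = 0.06,
                    "epithelial tumor" = 0.03, "p53+ tumor" = 0.005,
                    "proliferative tumor" = 0.005),
      n_centers = 4, sigma_um = 60)
  )
}

#' Default clinical arms
#'
#' Two MSI arms sized like a stage III colorectal cohort (33 MSS, 9
#' MSI-H), the MSI-H arm weighted toward immune-enriched niches.
#'
#' @return Named list of arm definitions (`n_patients`, `niche_weights`).
#' @export
default_arms <- function() {
  list(
    "MSS" = list(
      n_patients = 33,
      niche_weights = c("bulk tumor" = 0.32, "p53+ tumor" = 0.10,
                        "proliferative tumor" = 0.08, "stromal" = 0.28,
                        "immune-enriched stromal" = 0.12,
                        "mixed immune" = 0.10)),
    "MSI-H" = list(
      n_patients = 9,
      niche_weights = c("bulk tumor" = 0.26, "p53+ tumor" = 0.08,
                        "proliferative tumor" = 0.08, "stromal" = 0.24,
                        "immune-enriched stromal" = 0.19,
                        "mixed immune" = 0.15))
  )
}

#' Configure a synthetic cohort simulation
#'
#' Defaults emulate a stage III colorectal IMC cohort: two MSI arms
#' (33 MSS, 9 MSI-H patients), 3 regions per patient of 1000 x 1000 um at
#' roughly 5500 cells per region (modal neighbor spacing near 10 um), six
#' planted niches, log-normal cell radii around 4 um, and overall survival
#' whose hazard decreases with the patient's stromal-TIL fraction.
#'
#' @param arms named list; each arm has `n_patients` and either
#'   `niche_weights` (named over `niches`) or `proportions` (named simplex
#'   over the vocabulary, placed with no spatial structure); an arm may
#'   also carry its own `attraction` table overriding the global one.
#' @param niches named list of niche definitions, see [default_niches()].
#' @param rois_per_patient integer range `c(min, max)`.
#' @param roi_width_um,roi_height_um region extent in micrometres.
#' @param cells_per_roi cells placed per region.
#' @param attraction data.frame(`type_a`, `type_b`, `strength`) or NULL; a
#'   fraction strength/(1+strength) of `type_b` cells is re-placed within
#'   contact range of a random `type_a` cell.
#' @param radius_meanlog,radius_sdlog log-normal cell-radius parameters (um).
#' @param patient_dirichlet Dirichlet concentration for per-patient
#'   perturbation of niche weights (or proportions); `Inf` disables it.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param stil_hazard_multiplier hazard is baseline * multiplier^sTIL;
#'   values < 1 mean higher stromal-TIL fraction lowers the hazard.
#' @param recurrence_beta logistic intercept and slope on the sTIL fraction.
#' @param censor_quantile administrative censoring horizon as a quantile of
#'   the simulated event times.
#' @param hardcore_factor centroids may not be closer than
#'   `hardcore_factor * (r_i + r_j)`.
#' @param contact_threshold_um membrane contact range used when re-placing
#'   attracted cells.
#' @param stromal_niches niche names counted as stroma for the ground-truth
#'   sTIL fraction.
#' @param type_vocab cell-type vocabulary.
#' @param seed integer; one global seed drives per-region substreams.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(arms = default_arms(),
                              niches = default_niches(),
                              rois_per_patient = c(3, 3),
                              roi_width_um = 1000, roi_height_um = 1000,
                              cells_per_roi = 5500,
                              attraction = NULL,
                              radius_meanlog = log(4), radius_sdlog = 0.15,
                              patient_dirichlet = 100,
                              baseline_hazard = 0.012,
                              stil_hazard_multiplier = 0.1,
                              recurrence_beta = c(0, -4),
                              censor_quantile = 0.9,
                              hardcore_factor = 0.8,
                              contact_threshold_um = 6,
                              stromal_niches = c("stromal",
                                                 "immune-enriched stromal"),
                              type_vocab = default_cell_types(),
                              seed = 1L) {
  stopifnot(length(rois_per_patient) == 2,
            rois_per_patient[1] >= 1,
            rois_per_patient[2] >= rois_per_patient[1],
            roi_width_um > 0, roi_height_um > 0, cells_per_roi >= 1,
            baseline_hazard > 0, stil_hazard_multiplier > 0,
            hardcore_factor >= 0, contact_threshold_um >= 0)
  for (a in arms) {
    if (!is.null(a$proportions)) {
      stopifnot(abs(sum(a$proportions) - 1) < 1e-6, all(a$proportions >= 0))
    } else {
      stopifnot(!is.null(a$niche_weights),
                abs(sum(a$niche_weights) - 1) < 1e-6,
                all(a$niche_weights >= 0),
                all(names(a$niche_weights) %in% names(niches)))
    }
  }
  if (!is.null(attraction)) {
    stopifnot(is.data.frame(attraction),
              all(c("type_a", "type_b", "strength") %in% names(attraction)),
              all(attraction$strength >= 0))
  }
  structure(list(arms = arms, niches = niches,
                 rois_per_patient = rois_per_patient,
                 roi_width_um = roi_width_um, roi_height_um = roi_height_um,
                 cells_per_roi = cells_per_roi, attraction = attraction,
                 radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
                 patient_dirichlet = patient_dirichlet,
                 baseline_hazard = baseline_hazard,
                 stil_hazard_multiplier = stil_hazard_multiplier,
                 recurrence_beta = recurrence_beta,
                 censor_quantile = censor_quantile,
                 hardcore_factor = hardcore_factor,
                 contact_threshold_um = contact_threshold_um,
                 stromal_niches = stromal_niches,
                 type_vocab = type_vocab, seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Counter-based substream: each (global seed, counter) pair yields an
# independent, reproducible seed below 2^31.
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 2654435761 + as.double(counter) * 40503) %%
               2147483647)
}

# Spatial occupancy grid for the hard-core constraint, keyed by bin.
make_grid <- function(bin_um) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  list(env = env, bin = bin_um)
}
grid_key <- function(g, x, y) paste(floor(x / g$bin), floor(y / g$bin))
grid_add <- function(g, i, x, y) {
  k <- grid_key(g, x, y)
  g$env[[k]] <- c(g$env[[k]], i)
}
grid_remove <- function(g, i, x, y) {
  k <- grid_key(g, x, y)
  g$env[[k]] <- setdiff(g$env[[k]], i)
}
grid_neighbors <- function(g, x, y) {
  gx <- floor(x / g$bin); gy <- floor(y / g$bin)
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) {
    v <- g$env[[paste(gx + dx, gy + dy)]]
    if (!is.null(v)) out <- c(out, v)
  }
  out
}

# Place one region: niche centers, Gaussian scatter, types from niche
# mixtures, hard-core rejection, then attraction-driven re-placement.
# With csr = TRUE, `niche_weights` is a simplex over cell types and cells
# are placed uniformly with no niche structure. `attraction` defaults to
# the config-level table; arms may override it.
simulate_region <- function(config, roi_id, patient_id, niche_weights,
                            region_seed, csr = FALSE,
                            attraction = config$attraction) {
  with_seed(region_seed, {
    W <- config$roi_width_um; H <- config$roi_height_um
    n <- config$cells_per_roi
    niches <- config$niches

    radius <- stats::rlnorm(n, config$radius_meanlog, config$radius_sdlog)
    hc <- config$hardcore_factor
    grid <- make_grid(max(1e-6, hc * 2 * max(radius)))

    x <- numeric(n); y <- numeric(n)
    niche_lab <- character(n); type <- character(n)

    if (csr) {
      type_probs <- niche_weights  # actually proportions over the vocabulary
      niche_of <- rep("background", n)
      centers <- NULL
    } else {
      niche_of <- sample(names(niche_weights), n, replace = TRUE,
                         prob = niche_weights)
      centers <- lapply(niches[names(niche_weights)], function(nd) {
        cbind(stats::runif(nd$n_centers, 0, W), stats::runif(nd$n_centers, 0, H))
      })
    }

    # reflect at region borders so Gaussian tails fold back inside
    # instead of piling up on the boundary
    reflect <- function(v, lim) {
      v <- v %% (2 * lim)
      ifelse(v > lim, 2 * lim - v, v)
    }
    propose <- function(i) {
      if (csr) {
        c(stats::runif(1, 0, W), stats::runif(1, 0, H))
      } else {
        nd <- niches[[niche_of[i]]]
        cs <- centers[[niche_of[i]]]
        ctr <- cs[sample.int(nrow(cs), 1L), ]
        p <- ctr + stats::rnorm(2, 0, nd$sigma_um)
        c(reflect(p[1], W), reflect(p[2], H))
      }
    }
    ok_hardcore <- function(i, px, py) {
      nb <- grid_neighbors(grid, px, py)
      if (!length(nb)) return(TRUE)
      d2 <- (x[nb] - px)^2 + (y[nb] - py)^2
      all(d2 >= (hc * (radius[nb] + radius[i]))^2)
    }
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:30) {
        p <- propose(i)
        if (ok_hardcore(i, p[1], p[2])) {
          x[i] <- p[1]; y[i] <- p[2]
          grid_add(grid, i, p[1], p[2])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(paste("simulation error: hard-core constraint unsatisfiable;",
                   "reduce cells_per_roi or cell radii"), call. = FALSE)
      }
    }

    if (csr) {
      type <- sample(names(type_probs), n, replace = TRUE, prob = type_probs)
    } else {
      for (nm in unique(niche_of)) {
        idx <- which(niche_of == nm)
        m <- niches[[nm]]$mixture
        type[idx] <- sample(names(m), length(idx), replace = TRUE, prob = m)
      }
    }

    # Attraction: move a strength/(1+strength) fraction of B cells next to
    # a random A cell, preserving the hard-core constraint.
    if (!is.null(attraction)) {
      for (r in seq_len(nrow(attraction))) {
        A <- attraction$type_a[r]
        B <- attraction$type_b[r]
        s <- attraction$strength[r]
        if (s <= 0) next
        ia <- which(type == A)
        ib <- which(type == B)
        if (!length(ia) || !length(ib)) next
        move <- ib[stats::runif(length(ib)) < s / (1 + s)]
        for (i in move) {
          anchor <- ia[sample.int(length(ia), 1L)]
          for (try in 1:30) {
            d <- stats::runif(1, hc * (radius[i] + radius[anchor]),
                              radius[i] + radius[anchor] +
                                config$contact_threshold_um)
            th <- stats::runif(1, 0, 2 * pi)
            px <- x[anchor] + d * cos(th); py <- y[anchor] + d * sin(th)
            if (px < 0 || px > W || py < 0 || py > H) next
            grid_remove(grid, i, x[i], y[i])
            if (ok_hardcore(i, px, py)) {
              x[i] <- px; y[i] <- py
              grid_add(grid, i, px, py)
              break
            }
            grid_add(grid, i, x[i], y[i])  # revert
          }
        }
      }
    }

    list(cells = data.frame(cell_id = paste0("c", seq_len(n)),
                            roi_id = roi_id, patient_id = patient_id,
                            x_um = x, y_um = y, cell_type = type,
                            radius_um = radius,
                            stringsAsFactors = FALSE),
         niche = data.frame(roi_id = roi_id,
                            cell_id = paste0("c", seq_len(n)),
                            niche = niche_of, stringsAsFactors = FALSE))
  })
}

#' Simulate a cohort with known ground truth
#'
#' Cells are placed by sampling niche centers uniformly in each region,
#' scattering cells around them with Gaussian dispersion and drawing types
#' from the niche mixture; pairwise attraction is imposed by re-placing a
#' fraction of target cells within contact range of a source cell; a
#' hard-core constraint keeps centroids at least 0.8 (r_i + r_j) apart.
#' Survival times are exponential with hazard
#' `baseline * multiplier^(sTIL fraction)` and administrative censoring.
#'
#' @param config a [simulation_config()].
#' @return A list of class `tme_simulation` with elements `cohort`
#'   (a `tme_cohort`) and `truth` (per-cell niche labels, the imposed
#'   attraction table, and per-patient arm and true sTIL fraction).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arm_names <- names(config$arms)
  cells_list <- list(); niche_list <- list(); roi_rows <- list()
  patients <- character(0); patient_arm <- character(0)

  pat_counter <- 0L; roi_counter <- 0L
  for (arm in arm_names) {
    spec <- config$arms[[arm]]
    for (p in seq_len(spec$n_patients)) {
      pat_counter <- pat_counter + 1L
      pid <- sprintf("P%03d", pat_counter)
      patients <- c(patients, pid); patient_arm <- c(patient_arm, arm)
      pseed <- substream_seed(config$seed, 1e6 + pat_counter)
      pat <- with_seed(pseed, {
        rp <- config$rois_per_patient
        n_roi <- if (rp[1] == rp[2]) rp[1] else sample(rp[1]:rp[2], 1L)
        # per-patient Dirichlet perturbation of the arm's composition
        base <- if (is.null(spec$proportions)) spec$niche_weights else
          spec$proportions
        w <- if (is.finite(config$patient_dirichlet)) {
          g <- stats::rgamma(length(base),
                             shape = base * config$patient_dirichlet)
          if (sum(g) <= 0) base else g / sum(g)
        } else base
        names(w) <- names(base)
        list(n_roi = n_roi, w = w, csr = !is.null(spec$proportions))
      })
      for (r in seq_len(pat$n_roi)) {
        roi_counter <- roi_counter + 1L
        rid <- sprintf("R%04d", roi_counter)
        rseed <- substream_seed(config$seed, roi_counter)
        attr_arm <- if (!is.null(spec$attraction)) spec$attraction else
          config$attraction
        reg <- simulate_region(config, rid, pid, pat$w, rseed, csr = pat$csr,
                               attraction = attr_arm)
        cells_list[[rid]] <- reg$cells
        niche_list[[rid]] <- reg$niche
        tumor_frac <- mean(reg$cells$cell_type %in% tumor_cell_types())
        roi_rows[[rid]] <- data.frame(roi_id = rid, patient_id = pid,
                                      width_um = config$roi_width_um,
                                      height_um = config$roi_height_um,
                                      tumor_purity = tumor_frac,
                                      stringsAsFactors = FALSE)
      }
    }
  }

  cells <- do.call(rbind, cells_list); rownames(cells) <- NULL
  niche <- do.call(rbind, niche_list); rownames(niche) <- NULL
  rois <- do.call(rbind, roi_rows); rownames(rois) <- NULL

  # ground-truth stromal-TIL fraction per patient: lymphocytes among cells
  # of stromal niches; falls back to the overall lymphocyte fraction for
  # arms simulated without spatial structure
  lymph <- cells$cell_type %in% lymphocyte_cell_types()
  in_stroma <- niche$niche %in% config$stromal_niches
  true_stil <- vapply(patients, function(pid) {
    sel <- cells$patient_id == pid
    ss <- sel & in_stroma
    if (any(ss)) sum(lymph & ss) / sum(ss) else mean(lymph[sel])
  }, numeric(1))

  clin_seed <- substream_seed(config$seed, 2e6)
  clinical <- with_seed(clin_seed, {
    rate <- config$baseline_hazard *
      config$stil_hazard_multiplier^true_stil
    t_event <- stats::rexp(length(patients), rate = rate)
    horizon <- stats::quantile(t_event, config$censor_quantile, names = FALSE)
    os_time <- pmin(t_event, horizon)
    os_event <- as.integer(t_event <= horizon)
    p_rec <- stats::plogis(config$recurrence_beta[1] +
                             config$recurrence_beta[2] * true_stil)
    rec <- ifelse(stats::rbinom(length(patients), 1, p_rec) == 1, "yes", "no")
    data.frame(patient_id = patients,
               msi_status = ifelse(patient_arm %in% c("MSI-H", "MSS"),
                                   patient_arm, "unknown"),
               recurrence = rec,
               os_time = os_time, os_event = os_event,
               arm = patient_arm,
               stringsAsFactors = FALSE)
  })

  cohort <- new_cohort(cells, rois,
                       clinical[setdiff(names(clinical), "arm")],
                       type_vocab = config$type_vocab)
  truth <- list(niche = niche,
                attraction = config$attraction,
                patients = data.frame(patient_id = patients,
                                      arm = patient_arm,
                                      true_stil = unname(true_stil),
                                      stringsAsFactors = FALSE))
  structure(list(cohort = cohort, truth = truth, config = config),
            class = "tme_simulation")
}

#' Simulate a single completely-spatially-random region
#'
#' Uniform coordinates, multinomial type labels, no spatial structure and
#' no hard-core constraint: the exact null of the permutation interaction
#' test.
#'
#' @param n number of cells.
#' @param width_um,height_um region extent.
#' @param type_probs named probability vector over type labels.
#' @param radius_um fixed cell radius.
#' @param seed integer seed.
#' @param roi_id,patient_id identifiers for the returned table.
#' @return data.frame of cell records for one region.
#' @export
simulate_csr_region <- function(n, width_um = 190, height_um = 190,
                                type_probs, radius_um = 4, seed,
                                roi_id = "R1", patient_id = "P1") {
  stopifnot(n >= 1, abs(sum(type_probs) - 1) < 1e-8)
  with_seed(seed, {
    data.frame(cell_id = paste0("c", seq_len(n)),
               roi_id = roi_id, patient_id = patient_id,
               x_um = stats::runif(n, 0, width_um),
               y_um = stats::runif(n, 0, height_um),
               cell_type = sample(names(type_probs), n, replace = TRUE,
                                  prob = type_probs),
               radius_um = radius_um,
               stringsAsFactors = FALSE)
  })
}

#' Shuffle cell-type labels within each region
#'
#' Coordinates are untouched; within every region the multiset of type
#' labels is preserved exactly. This is the null model of the permutation
#' interaction test.
#'
#' @param cells cell table (one or more regions).
#' @param seed integer seed.
#' @return The cell table with permuted `cell_type`.
#' @export
simulate_null_labels <- function(cells, seed) {
  stopifnot(nrow(cells) >= 1)
  with_seed(seed, {
    for (rid in unique(cells$roi_id)) {
      idx <- which(cells$roi_id == rid)
      cells$cell_type[idx] <- cells$cell_type[sample(idx)]
    }
    cells
  })
}

#' @export
print.tme_simulation <- function(x, ...) {
  cat("tme_simulation\n")
  print(x$cohort)
  cat(sprintf("arms: %s\n",
              paste(unique(x$truth$patients$arm), collapse = ", ")))
  invisible(x)
}
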