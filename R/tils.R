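# Tier 3b: spatial TIL classification (iTIL/sTIL), per-unit TIL
# proportions, Otsu stratification into high/low TIL groups, and survival
# comparison.

#' Classify lymphocytes as intratumoral or stromal TILs
#'
#' Lymphocytes (CD4+ T, CD8+ T, B cells) sitting in a tumor-dominated CN
#' are intratumoral TILs (iTIL); those in a stromal CN are stromal TILs
#' (sTIL). All other cells — and lymphocytes in other CNs or isolated —
#' are `none`.
#'
#' @param cells the cohort's cell table.
#' @param model an annotated `tme_cn_model` fitted on the same cohort.
#' @param tumor_cns,stromal_cns CN name sets defining the compartments.
#' @return Object of class `tme_til_table`: data.frame with `roi_id`,
#'   `cell_id`, `patient_id`, `cell_type`, `cn_name`, `til_class`.
#' @export
classify_tils <- function(cells, model,
                          tumor_cns = c("bulk tumor", "p53+ tumor",
                                        "proliferative tumor"),
                          stromal_cns = c("stromal",
                                          "immune-enriched stromal")) {
  stopifnot(inherits(model, "tme_cn_model"))
  if (is.null(model$names)) stop("annotate the CN model first", call. = FALSE)
  missing_cns <- setdiff(c(tumor_cns, stromal_cns), model$names)
  if (length(missing_cns)) {
    stop(sprintf("CN name(s) not in model: %s; available: %s",
                 paste(missing_cns, collapse = ", "),
                 paste(model$names, collapse = ", ")), call. = FALSE)
  }
  cn <- cn_labels(model, nrow(cells))
  lymph <- cells$cell_type %in% lymphocyte_cell_types()
  til <- rep("none", nrow(cells))
  til[lymph & cn %in% tumor_cns] <- "iTIL"
  til[lymph & cn %in% stromal_cns] <- "sTIL"
  structure(data.frame(roi_id = cells$roi_id, cell_id = cells$cell_id,
                       patient_id = cells$patient_id,
                       cell_type = cells$cell_type,
                       cn_name = cn, til_class = til,
                       stringsAsFactors = FALSE),
            tumor_cns = tumor_cns, stromal_cns = stromal_cns,
            class = c("tme_til_table", "data.frame"))
}

#' Per-unit iTIL and sTIL proportions
#'
#' The iTIL proportion of a unit is the number of iTILs over a denominator
#' taken within the tumor CNs; the sTIL proportion is analogous within the
#' stromal CNs. Two denominator conventions are supported: all cells in
#' the compartment's CNs (default) or only the compartment's own cell
#' types within those CNs (tumor cells in tumor CNs; stromal cells in
#' stromal CNs). Units with an empty denominator get a missing value.
#'
#' @param tils a `tme_til_table`.
#' @param level `"patient"` (default) or `"roi"`.
#' @param denominator `"cells_in_compartment_cns"` or
#'   `"compartment_cells_in_compartment_cns"`.
#' @return data.frame with `unit`, `itil_prop`, `stil_prop`.
#' @export
til_proportions <- function(tils, level = c("patient", "roi"),
                            denominator = c("cells_in_compartment_cns",
                                            "compartment_cells_in_compartment_cns")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  stopifnot(inherits(tils, "tme_til_table"))
  tumor_cns <- attr(tils, "tumor_cns")
  stromal_cns <- attr(tils, "stromal_cns")
  unit <- if (level == "patient") tils$patient_id else tils$roi_id
  units <- unique(unit)
  in_tumor_cn <- !is.na(tils$cn_name) & tils$cn_name %in% tumor_cns
  in_stromal_cn <- !is.na(tils$cn_name) & tils$cn_name %in% stromal_cns
  den_tumor <- if (denominator == "cells_in_compartment_cns") in_tumor_cn
  else in_tumor_cn & tils$cell_type %in% tumor_cell_types()
  den_stromal <- if (denominator == "cells_in_compartment_cns") in_stromal_cn
  else in_stromal_cn & tils$cell_type == "stromal"
  prop <- function(num, den) {
    vapply(units, function(u) {
      s <- unit == u
      d <- sum(den & s)
      if (d == 0) NA_real_ else sum(num & s) / d
    }, numeric(1))
  }
  data.frame(unit = units,
             itil_prop = prop(tils$til_class == "iTIL", den_tumor),
             stil_prop = prop(tils$til_class == "sTIL", den_stromal),
             stringsAsFactors = FALSE)
}

#' Otsu threshold of a one-dimensional sample
#'
#' Histogram split that maximizes between-class variance (equivalently,
#' minimizes the pooled within-class variance), used to dichotomize
#' patients into high and low TIL groups. The histogram has `n_bins`
#' equal-width bins over the observed range; among maximizing bin edges
#' the mean edge is taken.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return Object of class `tme_otsu`: list with `threshold`, `labels`
#'   (`"high"` when value > threshold, named by `names(values)`), `n_bins`.
#' @export
otsu_split <- function(values, n_bins = 256) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2) {
    stop("values are constant; no split exists", call. = FALSE)
  }
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  # cumulative class weight and mean below each interior edge
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mu <- cm[n_bins]
  valid <- cw > 0 & cw < 1
  between <- rep(-Inf, n_bins)
  between[valid] <- (mu * cw[valid] - cm[valid])^2 /
    (cw[valid] * (1 - cw[valid]))
  best <- which(between == max(between))
  threshold <- mean(edges[best + 1L])
  labels <- ifelse(values > threshold, "high", "low")
  names(labels) <- names(values)
  structure(list(threshold = threshold, labels = labels, n_bins = n_bins),
            class = "tme_otsu")
}

#' Compare survival between high and low TIL groups
#'
#' Kaplan-Meier curves per group, the two-group log-rank test, and
#' (when both groups have events) a Cox proportional-hazards fit of the
#' group indicator with a Wald confidence interval.
#'
#' @param clinical clinical table with `patient_id`, `os_time`, `os_event`.
#' @param groups named character vector (patient id -> `"high"`/`"low"`).
#' @return Object of class `tme_survival`: list with `km` (per-group
#'   step function: `group`, `time`, `n_risk`, `n_event`, `surv`),
#'   `logrank_chisq`, `logrank_p`, `cox` (list `hr`, `ci_low`, `ci_high`,
#'   `p`, or NULL), `n` (per-group sizes).
#' @export
survival_compare <- function(clinical, groups) {
  stopifnot(!is.null(names(groups)), all(groups %in% c("high", "low")))
  cl <- clinical[match(names(groups), clinical$patient_id), ]
  ok <- !is.na(cl$os_time) & !is.na(cl$os_event)
  cl <- cl[ok, ]; groups <- groups[ok]
  if (min(table(groups)) < 2) {
    stop("need at least 2 patients per group", call. = FALSE)
  }
  g <- factor(groups, levels = c("low", "high"))
  surv <- survival::Surv(cl$os_time, cl$os_event)
  sf <- survival::survfit(surv ~ g)
  strata_lab <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  km <- data.frame(group = strata_lab, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, surv = sf$surv,
                   stringsAsFactors = FALSE)
  sd <- survival::survdiff(surv ~ g)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  cox <- NULL
  events_per_group <- tapply(cl$os_event, g, sum)
  if (all(events_per_group > 0)) {
    cf <- survival::coxph(surv ~ g)
    beta <- unname(cf$coefficients[1]); se <- sqrt(cf$var[1, 1])
    cox <- list(hr = exp(beta),
                ci_low = exp(beta - 1.96 * se),
                ci_high = exp(beta + 1.96 * se),
                p = 2 * stats::pnorm(-abs(beta / se)))
  } else {
    warning("a group has zero events; proportional-hazards fit skipped")
  }
  structure(list(km = km, logrank_chisq = chisq, logrank_p = p, cox = cox,
                 n = table(g)),
            class = "tme_survival")
}

#' @export
print.tme_survival <- function(x, ...) {
  cat(sprintf("log-rank chisq = %.3f, p = %.4g (n: low %d, high %d)\n",
              x$logrank_chisq, x$logrank_p, x$n[["low"]], x$n[["high"]]))
  if (!is.null(x$cox)) {
    cat(sprintf("Cox HR (high vs low) = %.3f [%.3f, %.3f]\n",
                x$cox$hr, x$cox$ci_low, x$cox$ci_high))
  }
  invisible(x)
}
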