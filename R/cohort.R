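#' Default cell-type vocabulary
#'
#' The ten cell types used throughout the pipeline: three tumor
#' compartments, stroma, and six immune populations.
#'
#' @return Character vector of the ten canonical type labels.
#' @export
default_cell_types <- function() {
  c("epithelial tumor", "p53+ tumor", "proliferative tumor", "stromal",
    "proliferative immune", "macrophage", "B cell", "ILC/NK",
    "CD4+ T", "CD8+ T")
}

#' @rdname default_cell_types
#' @export
tumor_cell_types <- function() {
  c("epithelial tumor", "p53+ tumor", "proliferative tumor")
}

#' @rdname default_cell_types
#' @export
lymphocyte_cell_types <- function() {
  c("CD4+ T", "CD8+ T", "B cell")
}

#' @rdname default_cell_types
#' @export
immune_cell_types <- function() {
  c("proliferative immune", "macrophage", "B cell", "ILC/NK",
    "CD4+ T", "CD8+ T")
}

#' Assemble a cohort from cell, region and clinical tables
#'
#' A cohort bundles the three tables the pipeline operates on: per-cell
#' spatial records, region (ROI) metadata, and per-patient clinical data.
#' All referential and range invariants are checked on construction.
#'
#' @param cells data.frame with columns `cell_id`, `roi_id`, `patient_id`,
#'   `x_um`, `y_um`, `cell_type`, and optionally `radius_um` plus any
#'   number of `marker_*` intensity columns. Coordinates are in micrometres,
#'   origin at the region's top-left corner, y increasing downward.
#' @param rois data.frame with `roi_id`, `patient_id`, `width_um`,
#'   `height_um` and optionally `tumor_purity` in \[0, 1\].
#' @param clinical data.frame with `patient_id`, `msi_status`
#'   (`"MSI-H"`, `"MSS"` or `"unknown"`), `recurrence` (`"yes"`, `"no"`,
#'   `"unknown"`), `os_time`, `os_event` (0/1) and optionally `sidedness`.
#' @param type_vocab allowed cell-type labels.
#' @param default_radius_um radius assigned to cells lacking one; each cell
#'   is modeled as a disc so that membrane (border-to-border) distances are
#'   defined even without segmentation boundaries.
#'
#' @return An object of class `tme_cohort`: a list with elements `cells`,
#'   `rois`, `clinical` and `type_vocab`.
#' @export
new_cohort <- function(cells, rois, clinical,
                       type_vocab = default_cell_types(),
                       default_radius_um = 5) {
  cells <- as.data.frame(cells)
  rois <- as.data.frame(rois)
  clinical <- as.data.frame(clinical)

  req_cells <- c("cell_id", "roi_id", "patient_id", "x_um", "y_um", "cell_type")
  req_rois <- c("roi_id", "patient_id", "width_um", "height_um")
  req_clin <- c("patient_id", "msi_status", "recurrence", "os_time", "os_event")
  check_columns(cells, req_cells, "cell table")
  check_columns(rois, req_rois, "ROI table")
  check_columns(clinical, req_clin, "clinical table")

  if (!("radius_um" %in% names(cells))) {
    if ("area_um2" %in% names(cells)) {
      cells$radius_um <- sqrt(cells$area_um2 / pi)
    } else {
      cells$radius_um <- default_radius_um
    }
  }
  na_r <- is.na(cells$radius_um)
  if (any(na_r)) cells$radius_um[na_r] <- default_radius_um

  bad_xy <- which(!is.finite(cells$x_um) | !is.finite(cells$y_um))
  if (length(bad_xy)) {
    stop(sprintf("format error: non-finite coordinates in cell table row(s) %s",
                 paste(utils::head(bad_xy, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(cells$radius_um <= 0)) {
    stop("format error: radius_um must be > 0", call. = FALSE)
  }
  unknown <- setdiff(unique(cells$cell_type), type_vocab)
  if (length(unknown)) {
    stop(sprintf("format error: cell type(s) not in vocabulary: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  key <- paste(cells$roi_id, cells$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("integrity error: duplicate (roi_id, cell_id): %s",
                 sub("\r", "/", key[duplicated(key)][1])), call. = FALSE)
  }
  if (anyDuplicated(rois$roi_id)) {
    stop("integrity error: duplicate roi_id in ROI table", call. = FALSE)
  }
  if (anyDuplicated(clinical$patient_id)) {
    stop("integrity error: duplicate patient_id in clinical table", call. = FALSE)
  }
  if (any(rois$width_um <= 0) || any(rois$height_um <= 0)) {
    stop("format error: ROI extents must be > 0", call. = FALSE)
  }
  if ("tumor_purity" %in% names(rois)) {
    tp <- rois$tumor_purity
    if (any(!is.na(tp) & (tp < 0 | tp > 1))) {
      stop("format error: tumor_purity must lie in [0, 1]", call. = FALSE)
    }
  }
  orphan_roi <- setdiff(unique(cells$roi_id), rois$roi_id)
  if (length(orphan_roi)) {
    stop(sprintf("integrity error: cell(s) reference unknown roi_id: %s",
                 paste(orphan_roi, collapse = ", ")), call. = FALSE)
  }
  orphan_pat <- setdiff(unique(rois$patient_id), clinical$patient_id)
  if (length(orphan_pat)) {
    stop(sprintf("integrity error: ROI(s) reference unknown patient_id: %s",
                 paste(orphan_pat, collapse = ", ")), call. = FALSE)
  }
  mism <- merge(cells[c("roi_id", "patient_id")], rois[c("roi_id", "patient_id")],
                by = "roi_id", suffixes = c("_cell", "_roi"))
  if (any(mism$patient_id_cell != mism$patient_id_roi)) {
    stop("integrity error: cell patient_id disagrees with its ROI's patient_id",
         call. = FALSE)
  }
  if (any(!is.finite(clinical$os_time)) || any(clinical$os_time < 0)) {
    stop("format error: os_time must be finite and >= 0", call. = FALSE)
  }
  if (!all(clinical$os_event %in% c(0, 1))) {
    stop("format error: os_event must be 0 or 1", call. = FALSE)
  }
  clinical$msi_status <- normalize_unknown(clinical$msi_status, c("MSI-H", "MSS"))
  clinical$recurrence <- normalize_unknown(clinical$recurrence, c("yes", "no"))
  if ("sidedness" %in% names(clinical)) {
    clinical$sidedness <- normalize_unknown(clinical$sidedness, c("left", "right"))
  }

  structure(list(cells = cells, rois = rois, clinical = clinical,
                 type_vocab = type_vocab),
            class = "tme_cohort")
}

# Unknown clinical levels become "unknown"; rows are never dropped here —
# group comparisons subset explicitly downstream.
normalize_unknown <- function(x, levels_ok) {
  x <- as.character(x)
  x[is.na(x) | !(x %in% levels_ok)] <- "unknown"
  x
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("format error: %s is missing column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a cohort from delimited text files
#'
#' Reads the cell, ROI and clinical CSV tables and returns a validated
#' [new_cohort()] object. Because deposited datasets rarely agree on column
#' names, a `column_map` may rename arbitrary input columns onto the
#' canonical schema, and `type_remap` may map free-text type labels onto
#' the configured vocabulary.
#'
#' @param cell_path,roi_path,clinical_path paths to CSV files.
#' @param type_vocab allowed cell-type labels.
#' @param type_remap optional named character vector mapping input labels
#'   to vocabulary labels, e.g. `c("Tcell" = "CD4+ T")`.
#' @param column_map optional named list per table
#'   (`cells`, `rois`, `clinical`), each a named character vector
#'   `c(canonical = "input_name")`.
#' @param default_radius_um fallback cell radius in micrometres.
#' @return A validated `tme_cohort`.
#' @export
load_cohort <- function(cell_path, roi_path, clinical_path,
                        type_vocab = default_cell_types(),
                        type_remap = NULL, column_map = NULL,
                        default_radius_um = 5) {
  for (p in c(cell_path, roi_path, clinical_path)) {
    if (!file.exists(p)) stop(sprintf("I/O error: file not found: %s", p),
                              call. = FALSE)
  }
  read1 <- function(path, map) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(map)) {
      for (canonical in names(map)) {
        if (map[[canonical]] %in% names(df)) {
          names(df)[names(df) == map[[canonical]]] <- canonical
        }
      }
    }
    df
  }
  cells <- read1(cell_path, column_map$cells)
  rois <- read1(roi_path, column_map$rois)
  clinical <- read1(clinical_path, column_map$clinical)

  check_columns(cells, c("cell_id", "roi_id", "patient_id", "x_um", "y_um",
                         "cell_type"), "cell table")
  if (!is.null(type_remap)) {
    hit <- cells$cell_type %in% names(type_remap)
    cells$cell_type[hit] <- unname(type_remap[cells$cell_type[hit]])
  }
  new_cohort(cells, rois, clinical, type_vocab = type_vocab,
             default_radius_um = default_radius_um)
}

#' @export
print.tme_cohort <- function(x, ...) {
  cat(sprintf("tme_cohort: %d cells, %d ROIs, %d patients, %d cell types\n",
              nrow(x$cells), nrow(x$rois), nrow(x$clinical),
              length(x$type_vocab)))
  invisible(x)
}

#' Write a bundle of result tables with a manifest
#'
#' Writes each table as a tab-delimited text file and a `manifest.tsv`
#' recording file names, row counts and a hash of the configuration that
#' produced them, so a run's outputs are auditable and comparable.
#'
#' @param bundle named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param config optional configuration object; hashed into the manifest.
#' @return Invisibly, the manifest data.frame.
#' @export
write_results <- function(bundle, out_dir, config = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("I/O error: cannot create directory %s", out_dir),
                  call. = FALSE)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop(sprintf("I/O error: directory not writable: %s", out_dir),
         call. = FALSE)
  }
  stopifnot(is.list(bundle))
  if (length(bundle) && is.null(names(bundle))) {
    stop("bundle tables must be named", call. = FALSE)
  }
  cfg_hash <- digest::digest(config, algo = "xxhash64")
  files <- character(0); rows <- integer(0)
  for (nm in names(bundle)) {
    fn <- paste0(nm, ".tsv")
    utils::write.table(bundle[[nm]], file.path(out_dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, fn)
    rows <- c(rows, nrow(bundle[[nm]]))
  }
  manifest <- data.frame(file = files, n_rows = rows,
                         config_hash = rep(cfg_hash, length(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write a cohort's three tables as CSV files
#'
#' Inverse of [load_cohort()]; round-trips field-for-field.
#'
#' @param cohort a `tme_cohort`.
#' @param out_dir output directory.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "tme_cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("cells.csv", "rois.csv", "clinical.csv"))
  utils::write.csv(cohort$cells, paths[1], row.names = FALSE)
  utils::write.csv(cohort$rois, paths[2], row.names = FALSE)
  utils::write.csv(cohort$clinical, paths[3], row.names = FALSE)
  invisible(paths)
}

# Split a cohort's cell table by ROI, preserving ROI order.
split_by_roi <- function(cells) {
  split(cells, factor(cells$roi_id, levels = unique(cells$roi_id)))
}
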