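#' Per-class summary statistics for the bundled Pecorino case study
#'
#' Mean, standard deviation and sample size of eight elements (Ba, Ca, Fe,
#' K, Mg, Na, P, Zn) determined by ICP-OES in three Pecorino cheese
#' varieties: Pecorino di Farindola (PF, n = 16), Pecorino Sardo (PS,
#' n = 20) and Pecorino Romano (PR, n = 17). Concentrations refer to dry
#' weight; micro-elements (Ba, Fe, Zn) are in ug/g, macro-elements (Ca, K,
#' Mg, Na, P) in mg/g, as recorded per row in the `unit` column. These
#' summaries parameterise the synthetic generator and the summary-level
#' univariate screen.
#'
#' @return A tibble with columns `class`, `element`, `mean`, `sd`, `n`,
#'   `unit` — one row per (class, element) pair.
#' @export
#' @examples
#' pecorino_class_stats()
pecorino_class_stats <- function() {
  tbl <- tibble::tribble(
    ~class, ~element, ~mean, ~sd, ~n, ~unit,
    "PF", "Ba",  1.2,  0.7,  16L, "ug/g_dry",
    "PF", "Ca", 12,    3,    16L, "mg/g_dry",
    "PF", "Fe",  2.4,  1.7,  16L, "ug/g_dry",
    "PF", "K",   1.7,  0.3,  16L, "mg/g_dry",
    "PF", "Mg",  0.65, 0.19, 16L, "mg/g_dry",
    "PF", "Na", 11,    5,    16L, "mg/g_dry",
    "PF", "P",   8,    2,    16L, "mg/g_dry",
    "PF", "Zn", 40,   12,    16L, "ug/g_dry",
    "PS", "Ba",  2.7,  0.8,  20L, "ug/g_dry",
    "PS", "Ca", 13,    2,    20L, "mg/g_dry",
    "PS", "Fe",  2.5,  1.3,  20L, "ug/g_dry",
    "PS", "K",   1.5,  0.4,  20L, "mg/g_dry",
    "PS", "Mg",  0.70, 0.12, 20L, "mg/g_dry",
    "PS", "Na", 10,    2,    20L, "mg/g_dry",
    "PS", "P",   8,    2,    20L, "mg/g_dry",
    "PS", "Zn", 48,   11,    20L, "ug/g_dry",
    "PR", "Ba",  3.5,  1.1,  17L, "ug/g_dry",
    "PR", "Ca", 13,    3,    17L, "mg/g_dry",
    "PR", "Fe",  3.8,  1.8,  17L, "ug/g_dry",
    "PR", "K",   1.1,  0.3,  17L, "mg/g_dry",
    "PR", "Mg",  0.73, 0.16, 17L, "mg/g_dry",
    "PR", "Na", 21,    5,    17L, "mg/g_dry",
    "PR", "P",   9.0,  1.7,  17L, "mg/g_dry",
    "PR", "Zn", 49,   15,    17L, "ug/g_dry"
  )
  validate_class_stats(tbl)
}

#' Load per-class summary statistics from a table or CSV file
#'
#' Reads a class-summary table (columns `class`, `element`, `mean`, `sd`,
#' `n`, `unit`) and validates it: every (class, element) pair must appear
#' exactly once, standard deviations must be non-negative and each class
#' must hold at least two samples. Units are preserved verbatim and never
#' converted.
#'
#' @param source A data frame with the required columns, or the path to a
#'   CSV file holding one.
#' @return A validated tibble of class statistics.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(pecorino_class_stats(), path)
#' load_class_stats(path)
load_class_stats <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    source <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  }
  validate_class_stats(source)
}

validate_class_stats <- function(tbl) {
  if (!is.data.frame(tbl)) {
    stop("class statistics must be a data frame", call. = FALSE)
  }
  needed <- c("class", "element", "mean", "sd", "n", "unit")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    stop("class statistics table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0) {
    stop("class statistics table is empty", call. = FALSE)
  }
  tbl <- tibble::as_tibble(tbl)[needed]
  tbl$class <- as.character(tbl$class)
  tbl$element <- as.character(tbl$element)
  tbl$n <- as.integer(tbl$n)

  key <- paste(tbl$class, tbl$element, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (class, element) pair in row ", dup[1], ": ",
         tbl$class[dup[1]], ", ", tbl$element[dup[1]], call. = FALSE)
  }
  bad_sd <- which(!is.finite(tbl$sd) | tbl$sd < 0)
  if (length(bad_sd) > 0) {
    stop("negative or non-finite sd in row ", bad_sd[1], " (",
         tbl$class[bad_sd[1]], ", ", tbl$element[bad_sd[1]], ")",
         call. = FALSE)
  }
  bad_n <- which(is.na(tbl$n) | tbl$n < 2)
  if (length(bad_n) > 0) {
    stop("sample size n < 2 in row ", bad_n[1], " (",
         tbl$class[bad_n[1]], ", ", tbl$element[bad_n[1]], ")",
         call. = FALSE)
  }
  if (any(!is.finite(tbl$mean))) {
    stop("non-finite mean in class statistics table", call. = FALSE)
  }
  allowed_units <- c("ug/g_dry", "mg/g_dry")
  bad_unit <- which(!tbl$unit %in% allowed_units)
  if (length(bad_unit) > 0) {
    stop("unit in row ", bad_unit[1], " must be one of ",
         paste(allowed_units, collapse = ", "), call. = FALSE)
  }
  # element set must be identical across classes
  per_class <- split(tbl$element, tbl$class)
  ref <- sort(per_class[[1]])
  same <- vapply(per_class, function(e) identical(sort(e), ref), logical(1))
  if (!all(same)) {
    stop("element set differs between classes: ",
         paste(names(per_class)[!same], collapse = ", "), call. = FALSE)
  }
  tbl
}
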