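#' Write / read a concentration table with a units sidecar
#'
#' The table is written as plain CSV (`sample_id`, `class`, one column
#' per element); per-element units travel in a JSON sidecar next to the
#' CSV (same path with `.units.json` appended), since mixed units
#' (ug/g vs mg/g dry weight) must never be silently merged.
#'
#' @param tbl Concentration tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  units <- concentration_units(tbl)
  if (!is.null(units)) {
    jsonlite::write_json(as.list(units), paste0(path, ".units.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_concentration_table
#' @param check Validate the table (uniqueness, non-negativity, class
#'   sizes) after reading.
#' @export
read_concentration_table <- function(path, check = TRUE) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- paste0(path, ".units.json")
  if (file.exists(sidecar)) {
    units <- unlist(jsonlite::read_json(sidecar))
    attr(tbl, "units") <- units
  }
  if (check) validate_concentration_table(tbl) else tbl
}

validate_concentration_table <- function(tbl) {
  if (!all(c("sample_id", "class") %in% names(tbl))) {
    stop("concentration table needs columns sample_id and class", call. = FALSE)
  }
  elements <- setdiff(names(tbl), c("sample_id", "class"))
  if (length(elements) == 0) stop("no element columns found", call. = FALSE)
  dup <- which(duplicated(tbl$sample_id))
  if (length(dup) > 0) {
    stop("duplicate sample_id in row ", dup[1], ": ", tbl$sample_id[dup[1]],
         call. = FALSE)
  }
  x <- as.matrix(tbl[elements])
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("missing or negative concentration at row ", bad[1, 1],
         ", element ", elements[bad[1, 2]], call. = FALSE)
  }
  tbl
}

default_train_quota <- function(labels) {
  sizes <- table(labels)
  q <- pmax(2L, floor(0.6 * as.vector(sizes)))
  stats::setNames(as.integer(pmin(q, as.vector(sizes) - 1L)), names(sizes))
}

# Shared fit/assess path used for both the full and the VIP-reduced
# model, so variable selection cannot silently change the procedure.
fit_and_assess <- function(train_tbl, test_tbl, elements, max_lv, folds,
                           cv_rule, rule, log10_first, cv_scheme, seed) {
  keep <- c("sample_id", "class", elements)
  train_tbl <- train_tbl[keep]
  if (!is.null(test_tbl)) test_tbl <- test_tbl[keep]
  a_max <- min(max_lv, length(elements), nrow(train_tbl) - 1)
  cv <- cross_validate_lv(train_tbl, a_max = a_max, k = folds, rule = cv_rule,
                          scheme = cv_scheme, seed = seed,
                          log10_first = log10_first)
  a_sel <- cv$a_selected
  model <- plsda_fit(train_tbl, n_components = a_sel,
                     log10_first = log10_first)
  calib_yhat <- if (rule == "bayes") cv$cv_yhat[[a_sel]] else NULL
  model <- plsda_attach_rule(model, rule = rule,
                             yhat_calibration = calib_yhat,
                             labels = train_tbl$class)
  cv_report <- classification_metrics(train_tbl$class, cv$cv_assigned[[a_sel]],
                                      ids = train_tbl$sample_id)
  test_report <- NULL
  test_assign <- NULL
  if (!is.null(test_tbl) && nrow(test_tbl) > 0) {
    test_assign <- plsda_assign(model, test_tbl)
    test_report <- classification_metrics(test_tbl$class, test_assign$assigned,
                                          ids = test_tbl$sample_id)
  }
  list(model = model, cv = cv, a_selected = a_sel,
       cv_report = cv_report, test_report = test_report,
       test_assignment = test_assign,
       vip = vip_scores(model))
}

#' Run the full discrimination workflow
#'
#' Orchestrates the complete authentication study on a concentration
#' table: univariate screen (ANOVA + LSD), PCA exploration, per-class
#' Duplex train/test split, stratified k-fold cross-validated selection
#' of the number of latent variables, final PLS-DA fit with the chosen
#' assignment rule, external-test prediction, VIP variable selection,
#' and a refit of the identical pipeline on the VIP-selected variables.
#'
#' @param tbl Concentration tibble; alternatively supply `class_stats`
#'   (plus optionally `n_per_class`) to simulate one.
#' @param class_stats,n_per_class Passed to [sample_concentrations()]
#'   when `tbl` is NULL.
#' @param pretreatment `"raw"` or `"log10"` (before autoscaling;
#'   autoscaling itself is always applied).
#' @param folds Cross-validation folds (default 5).
#' @param max_lv Largest number of latent variables to explore (capped
#'   at the number of variables).
#' @param split `"duplex"` or `"all-train"`.
#' @param train_per_class Named training quotas for the Duplex split;
#'   default 60% of each class.
#' @param rule Final assignment rule, `"bayes"` (calibrated on CV
#'   predictions) or `"lda"`.
#' @param cv_rule Rule used inside CV for latent-variable selection
#'   (default `"lda"`).
#' @param cv_scheme `"venetian"` (deterministic) or `"random"`.
#' @param alpha Significance level of the univariate screen.
#' @param seed Seed for simulation and any randomised fold scheme.
#' @return A `run_report` list: `data_summary`, `screen`, `pca`
#'   (explained-variance tibble and model), `split`, `error_curve`,
#'   `a_selected`, `explained_x`/`explained_y` at the selected size,
#'   `cv_report`, `test_report`, `vip`, `selected_elements`,
#'   `reduced` (same fields for the VIP-reduced refit), `model`,
#'   `config`.
#' @export
#' @examples
#' rep <- run_discrimination(class_stats = pecorino_class_stats(),
#'                           train_per_class = c(PF = 9, PS = 12, PR = 9),
#'                           seed = 11)
#' rep$split$per_class_counts
run_discrimination <- function(tbl = NULL, class_stats = NULL,
                               n_per_class = NULL,
                               pretreatment = c("raw", "log10"),
                               folds = 5, max_lv = 10,
                               split = c("duplex", "all-train"),
                               train_per_class = NULL,
                               rule = c("bayes", "lda"),
                               cv_rule = c("lda", "bayes"),
                               cv_scheme = c("venetian", "random"),
                               alpha = 0.05, seed = 1) {
  pretreatment <- match.arg(pretreatment)
  split <- match.arg(split)
  rule <- match.arg(rule)
  cv_rule <- match.arg(cv_rule)
  cv_scheme <- match.arg(cv_scheme)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (max_lv < 1) stop("max_lv must be >= 1", call. = FALSE)
  if (is.null(tbl)) {
    if (is.null(class_stats)) {
      stop("supply either `tbl` or `class_stats`", call. = FALSE)
    }
    tbl <- sample_concentrations(class_stats, n_per_class = n_per_class,
                                 seed = seed)
  }
  tbl <- validate_concentration_table(tbl)
  elements <- setdiff(names(tbl), c("sample_id", "class"))
  log10_first <- pretreatment == "log10"

  data_summary <- dplyr::count(tbl, .data$class, name = "n")
  screen <- screen_elements(tbl, alpha = alpha)

  x_all <- as.matrix(tbl[elements])
  scaler_all <- autoscale_fit(x_all, log10_first = log10_first)
  pca <- pca_fit(autoscale_apply(scaler_all, x_all))

  if (split == "duplex") {
    quotas <- if (is.null(train_per_class)) default_train_quota(tbl$class)
      else train_per_class
    sp <- duplex_split(tbl, quotas)
    train_tbl <- tbl[tbl$sample_id %in% sp$train_ids, , drop = FALSE]
    test_tbl <- tbl[tbl$sample_id %in% sp$test_ids, , drop = FALSE]
  } else {
    sp <- NULL
    train_tbl <- tbl
    test_tbl <- NULL
  }

  full <- fit_and_assess(train_tbl, test_tbl, elements, max_lv, folds,
                         cv_rule, rule, log10_first, cv_scheme, seed)

  selected <- full$vip$element[full$vip$selected]
  reduced <- NULL
  if (length(selected) >= 2 && length(selected) < length(elements)) {
    reduced <- fit_and_assess(train_tbl, test_tbl, selected, max_lv, folds,
                              cv_rule, rule, log10_first, cv_scheme, seed)
  }

  structure(
    list(
      data_summary = data_summary,
      screen = screen,
      pca = list(explained_variance = tibble::tibble(
        component = seq_along(pca$explained_variance),
        fraction = pca$explained_variance), model = pca),
      split = sp,
      error_curve = full$cv$error_curve,
      a_selected = full$a_selected,
      explained_x = sum(full$model$explained_x),
      explained_y = sum(full$model$explained_y),
      cv_report = full$cv_report,
      test_report = full$test_report,
      test_assignment = full$test_assignment,
      vip = full$vip,
      selected_elements = selected,
      reduced = reduced,
      model = full$model,
      config = list(pretreatment = pretreatment, folds = folds,
                    max_lv = max_lv, split = split, rule = rule,
                    cv_rule = cv_rule, cv_scheme = cv_scheme,
                    alpha = alpha, seed = seed)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Discrimination run:",
      sum(x$data_summary$n), "samples,",
      nrow(x$screen), "elements,",
      x$a_selected, "latent variables\n")
  if (!is.null(x$split)) {
    cat(sprintf("Duplex split: %d train / %d test\n",
                length(x$split$train_ids), length(x$split$test_ids)))
  }
  cat(sprintf("Explained at A=%d: X %.1f%%, Y %.1f%%\n", x$a_selected,
              100 * x$explained_x, 100 * x$explained_y))
  cat(sprintf("CV accuracy: %.1f%%\n", x$cv_report$total_accuracy))
  if (!is.null(x$test_report)) {
    cat(sprintf("Test accuracy: %.1f%%\n", x$test_report$total_accuracy))
  }
  cat("VIP-selected:", paste(x$selected_elements, collapse = ", "), "\n")
  if (!is.null(x$reduced)) {
    cat(sprintf("Reduced model CV/test accuracy: %.1f%% / %s\n",
                x$reduced$cv_report$total_accuracy,
                if (is.null(x$reduced$test_report)) "-" else
                  sprintf("%.1f%%", x$reduced$test_report$total_accuracy)))
  }
  invisible(x)
}

report_to_list <- function(x) {
  conf_df <- function(r) if (is.null(r)) NULL else
    as.data.frame.matrix(unclass(r$confusion))
  list(
    data_summary = as.data.frame(x$data_summary),
    screen = as.data.frame(x$screen[c("element", "anova_p",
                                      "significant_pairs")]),
    pca_explained = as.data.frame(x$pca$explained_variance),
    split = if (is.null(x$split)) NULL else list(
      train_ids = x$split$train_ids, test_ids = x$split$test_ids,
      per_class_counts = as.data.frame(x$split$per_class_counts)),
    error_curve = as.data.frame(x$error_curve),
    a_selected = x$a_selected,
    explained_x = x$explained_x,
    explained_y = x$explained_y,
    cv_accuracy = x$cv_report$total_accuracy,
    cv_confusion = conf_df(x$cv_report),
    test_accuracy = if (is.null(x$test_report)) NULL else
      x$test_report$total_accuracy,
    test_confusion = conf_df(x$test_report),
    misclassified_test_ids = if (is.null(x$test_report)) NULL else
      x$test_report$misclassified_ids,
    vip = as.data.frame(x$vip),
    selected_elements = x$selected_elements,
    reduced = if (is.null(x$reduced)) NULL else list(
      a_selected = x$reduced$a_selected,
      cv_accuracy = x$reduced$cv_report$total_accuracy,
      test_accuracy = if (is.null(x$reduced$test_report)) NULL else
        x$reduced$test_report$total_accuracy),
    config = x$config)
}

#' Write a run report to disk
#'
#' Emits `report.json` plus CSV side tables (screen, error curve, VIP,
#' confusion matrices, PCA scores/loadings) under `dir`.
#'
#' @param report A `run_report` from [run_discrimination()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  readr::write_csv(report$screen[c("element", "anova_p", "significant_pairs")],
                   file.path(dir, "screen.csv"))
  readr::write_csv(report$error_curve, file.path(dir, "error_curve.csv"))
  readr::write_csv(report$vip, file.path(dir, "vip.csv"))
  pca <- report$pca$model
  utils::write.csv(pca$scores, file.path(dir, "pca_scores.csv"))
  utils::write.csv(pca$loadings, file.path(dir, "pca_loadings.csv"))
  if (!is.null(report$cv_report)) {
    utils::write.csv(as.data.frame.matrix(unclass(report$cv_report$confusion)),
                     file.path(dir, "confusion_cv.csv"))
  }
  if (!is.null(report$test_report)) {
    utils::write.csv(as.data.frame.matrix(unclass(report$test_report$confusion)),
                     file.path(dir, "confusion_test.csv"))
  }
  invisible(dir)
}
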