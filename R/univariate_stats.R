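#' One-way ANOVA on raw data
#'
#' Standard one-way analysis of variance, used to screen which element
#' means differ between classes. The decomposition is delegated to
#' [stats::aov()]; results are returned as a tidy one-row tibble.
#'
#' @param data A data frame, or a list of numeric group vectors.
#' @param value,group Columns of `data` holding the response and the
#'   group label (tidy-eval; ignored when `data` is a list).
#' @return A tibble: `f_stat`, `df_between`, `df_within`, `p_value`,
#'   `ss_between`, `ss_within`.
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
anova_oneway <- function(data, value, group) {
  if (is.data.frame(data)) {
    values <- dplyr::pull(data, {{ value }})
    groups <- as.character(dplyr::pull(data, {{ group }}))
  } else if (is.list(data)) {
    if (is.null(names(data))) names(data) <- sprintf("g%d", seq_along(data))
    values <- unlist(data, use.names = FALSE)
    groups <- rep(names(data), lengths(data))
  } else {
    stop("`data` must be a data frame or a list of numeric vectors",
         call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2) stop("at least 2 groups are required", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 values (offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")", call. = FALSE)
  }
  fit <- stats::aov(values ~ factor(groups))
  tab <- summary(fit)[[1]]
  ssb <- tab[["Sum Sq"]][1]
  ssw <- tab[["Sum Sq"]][2]
  if (ssw == 0 && ssb == 0) {
    stop("zero variance both between and within groups; F is undefined",
         call. = FALSE)
  }
  tibble::tibble(
    f_stat = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1],
    ss_between = ssb,
    ss_within = ssw)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs the one-way ANOVA table from group means, standard
#' deviations and sizes alone, so a printed summary table can be screened
#' without the raw data: `SSB = sum n_i (mean_i - grand_mean)^2`,
#' `SSW = sum (n_i - 1) sd_i^2`, `F = MSB / MSW` on (k - 1, N - k)
#' degrees of freedom. Applied to summaries computed from raw data it
#' agrees with [anova_oneway()] to machine precision.
#'
#' @param stats A data frame with columns `mean`, `sd`, `n` (one row per
#'   group), e.g. one element's rows of [pecorino_class_stats()].
#' @return Same tibble shape as [anova_oneway()].
#' @export
#' @examples
#' k_row <- dplyr::filter(pecorino_class_stats(), element == "K")
#' anova_from_summary(k_row)
anova_from_summary <- function(stats) {
  if (!all(c("mean", "sd", "n") %in% names(stats))) {
    stop("`stats` needs columns mean, sd, n", call. = FALSE)
  }
  m <- stats$mean
  s <- stats$sd
  n <- stats$n
  k <- length(m)
  if (k < 2) stop("at least 2 groups are required", call. = FALSE)
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  big_n <- sum(n)
  gm <- sum(n * m) / big_n
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  if (ssw == 0 && ssb == 0) {
    stop("zero variance both between and within groups; F is undefined",
         call. = FALSE)
  }
  f <- (ssb / (k - 1)) / (ssw / (big_n - k))
  tibble::tibble(
    f_stat = f,
    df_between = k - 1L,
    df_within = as.integer(big_n - k),
    p_value = stats::pf(f, k - 1, big_n - k, lower.tail = FALSE),
    ss_between = ssb,
    ss_within = ssw)
}

#' Fisher's least-significant-difference pairwise test
#'
#' Unconditional pairwise comparisons of all group means using the
#' pooled within-group mean square from the one-way ANOVA:
#' `t = |mean_i - mean_j| / sqrt(MSW (1/n_i + 1/n_j))` on N - k degrees
#' of freedom, two-sided. With `protected = TRUE` pairs are only flagged
#' significant when the overall ANOVA also rejects at `alpha`.
#'
#' @param stats A data frame with columns `mean`, `sd`, `n` and a group
#'   identifier column (`class` by default, else the first
#'   non-statistics column), one row per group.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param protected Require ANOVA p <= alpha before flagging pairs.
#' @return A tibble with one row per unordered pair: `class_1`,
#'   `class_2`, `mean_diff`, `standard_error`, `t_stat`, `p_value`,
#'   `significant`, plus `alpha` as an attribute.
#' @export
#' @examples
#' ba <- dplyr::filter(pecorino_class_stats(), element == "Ba")
#' lsd_pairwise(ba)
lsd_pairwise <- function(stats, alpha = 0.05, protected = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  label_col <- if ("class" %in% names(stats)) "class" else {
    setdiff(names(stats), c("element", "mean", "sd", "n", "unit"))[1]
  }
  labels <- as.character(stats[[label_col]])
  m <- stats$mean
  s <- stats$sd
  n <- stats$n
  k <- length(m)
  if (k < 2) stop("at least 2 groups are required", call. = FALSE)
  big_n <- sum(n)
  msw <- sum((n - 1) * s^2) / (big_n - k)
  if (msw == 0) stop("pooled within-group variance is zero", call. = FALSE)
  df <- big_n - k

  gate <- if (protected) {
    anova_from_summary(stats)$p_value <= alpha
  } else TRUE

  pairs <- utils::combn(k, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    se <- sqrt(msw * (1 / n[i] + 1 / n[j]))
    t_stat <- abs(m[i] - m[j]) / se
    p <- 2 * stats::pt(t_stat, df, lower.tail = FALSE)
    tibble::tibble(class_1 = labels[i], class_2 = labels[j],
                   mean_diff = m[i] - m[j], standard_error = se,
                   t_stat = t_stat, p_value = p,
                   significant = gate && p <= alpha)
  })
  attr(out, "alpha") <- alpha
  attr(out, "df") <- df
  out
}

#' Per-class summary of a concentration table
#'
#' Collapses a sample-level concentration table to the per-class
#' mean/sd/n format used by the summary-level ANOVA and the synthetic
#' generator.
#'
#' @param tbl A concentration tibble (`sample_id`, `class`, one column
#'   per element).
#' @return A class-statistics tibble (`class`, `element`, `mean`, `sd`,
#'   `n`, `unit`).
#' @export
summarize_concentrations <- function(tbl) {
  units <- concentration_units(tbl)
  elements <- setdiff(names(tbl), c("sample_id", "class"))
  long <- tidyr::pivot_longer(tbl, dplyr::all_of(elements),
                              names_to = "element", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$class, .data$element) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(unit = if (is.null(units)) "ug/g_dry" else
      unname(units[.data$element]))
  dplyr::arrange(out, .data$class, .data$element)
}

#' Univariate screen of every element
#'
#' Runs the one-way ANOVA and the LSD pairwise test element by element,
#' reproducing the layout of a per-element screening table: per-class
#' mean and SD, ANOVA p-value, and the list of significantly different
#' class pairs at `alpha`.
#'
#' @param x A concentration tibble (sample level) or a class-statistics
#'   tibble (summary level).
#' @param alpha Significance level for the LSD pairs.
#' @param protected Gate the LSD pairs on the ANOVA rejecting first.
#' @return A tibble with one row per element: `element`, `anova_p`,
#'   `significant_pairs` (semicolon-separated string, `-` when none) and
#'   a nested `lsd` column of per-pair results.
#' @export
#' @examples
#' screen_elements(pecorino_class_stats())
screen_elements <- function(x, alpha = 0.05, protected = FALSE) {
  stats_tbl <- if (all(c("mean", "sd", "n") %in% names(x))) {
    validate_class_stats(x)
  } else {
    summarize_concentrations(x)
  }
  purrr::map_dfr(unique(stats_tbl$element), function(el) {
    sub <- dplyr::filter(stats_tbl, .data$element == el)
    an <- anova_from_summary(sub)
    lsd <- lsd_pairwise(sub, alpha = alpha, protected = protected)
    sig <- dplyr::filter(lsd, .data$significant)
    tibble::tibble(
      element = el,
      anova_p = an$p_value,
      significant_pairs = if (nrow(sig) == 0) "-" else
        paste(paste0(sig$class_1, "-", sig$class_2), collapse = "; "),
      lsd = list(lsd))
  })
}
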