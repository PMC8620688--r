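#' Simulate a concentration table from per-class summary statistics
#'
#' Draws a sample-by-element concentration table whose per-class location
#' and scale match a class-statistics table such as
#' [pecorino_class_stats()]. Two marginal families are supported:
#'
#' * `"truncated-normal"` (default): Gaussian with the stated mean and SD,
#'   truncated at zero by rejection. For rows whose mean sits a few SDs
#'   above zero the truncation bias is negligible.
#' * `"log-normal"`: the log-scale parameters are solved so that the
#'   *arithmetic* mean and SD equal the stated values, which suits
#'   positively skewed concentration data.
#'
#' By default elements are drawn independently (diagonal covariance);
#' an optional per-class correlation matrix induces dependence.
#'
#' @param class_stats Class-statistics tibble (`class`, `element`, `mean`,
#'   `sd`, `n`, `unit`), e.g. from [load_class_stats()].
#' @param n_per_class Optional named integer vector overriding the `n`
#'   column, e.g. `c(PF = 200, PS = 200, PR = 200)`. A single unnamed
#'   value recycles to every class.
#' @param family `"truncated-normal"` or `"log-normal"`.
#' @param correlation Optional element-by-element correlation matrix
#'   (dimnames must name the elements), or a named list of such matrices
#'   keyed by class. Must be symmetric positive semi-definite with unit
#'   diagonal.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A concentration tibble: `sample_id`, `class`, one numeric
#'   column per element (sorted element order), with per-element units in
#'   `attr(, "units")`.
#' @export
#' @examples
#' tbl <- sample_concentrations(pecorino_class_stats(), seed = 1)
#' dplyr::count(tbl, class)
sample_concentrations <- function(class_stats,
                                  n_per_class = NULL,
                                  family = c("truncated-normal", "log-normal"),
                                  correlation = NULL,
                                  seed) {
  stats_tbl <- validate_class_stats(class_stats)
  family <- match.arg(family)
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric `seed` is required", call. = FALSE)
  }

  classes <- unique(stats_tbl$class)
  elements <- sort(unique(stats_tbl$element))
  v <- length(elements)

  n_map <- vapply(classes, function(cl) {
    stats_tbl$n[stats_tbl$class == cl][1]
  }, integer(1))
  if (!is.null(n_per_class)) {
    if (is.null(names(n_per_class))) {
      if (length(n_per_class) != 1) {
        stop("unnamed `n_per_class` must be a single value", call. = FALSE)
      }
      n_map[] <- as.integer(n_per_class)
    } else {
      unknown <- setdiff(names(n_per_class), classes)
      if (length(unknown) > 0) {
        stop("`n_per_class` names unknown class(es): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      n_map[names(n_per_class)] <- as.integer(n_per_class)
    }
  }
  if (any(n_map < 2)) stop("n_per_class must be >= 2 for every class", call. = FALSE)

  chol_for_class <- function(cl) {
    if (is.null(correlation)) return(NULL)
    r <- if (is.list(correlation) && !is.matrix(correlation)) {
      correlation[[cl]]
    } else {
      correlation
    }
    if (is.null(r)) return(NULL)
    if (!is.matrix(r) || nrow(r) != v || ncol(r) != v) {
      stop("correlation matrix must be ", v, " x ", v, call. = FALSE)
    }
    if (is.null(dimnames(r))) dimnames(r) <- list(elements, elements)
    r <- r[elements, elements]
    if (max(abs(r - t(r))) > 1e-10 || max(abs(diag(r) - 1)) > 1e-10) {
      stop("correlation matrix must be symmetric with unit diagonal", call. = FALSE)
    }
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("correlation matrix is not positive semi-definite", call. = FALSE)
    }
    chol(r + diag(1e-12, v))
  }

  units_map <- stats::setNames(rep(NA_character_, v), elements)
  out <- with_local_seed(as.integer(seed) %% .Machine$integer.max, {
    rows <- lapply(classes, function(cl) {
      sub <- stats_tbl[stats_tbl$class == cl, ]
      sub <- sub[match(elements, sub$element), ]
      units_map[sub$element] <<- sub$unit
      n <- n_map[[cl]]
      cf <- chol_for_class(cl)
      x <- draw_class_matrix(n, sub$mean, sub$sd, family, cf)
      colnames(x) <- elements
      tibble::as_tibble(as.data.frame(x)) |>
        dplyr::mutate(class = cl, .before = 1)
    })
    dplyr::bind_rows(rows)
  })

  out <- dplyr::mutate(out,
    sample_id = sprintf("%s_%03d", .data$class,
                        stats::ave(seq_len(nrow(out)), out$class, FUN = seq_along)),
    .before = 1)
  attr(out, "units") <- units_map
  out
}

# Draw one class's n x v matrix with the requested marginal family.
# `cf` is the (upper) Cholesky factor of the correlation matrix, or NULL.
draw_class_matrix <- function(n, means, sds, family, cf = NULL) {
  v <- length(means)
  draw_z <- function(m) {
    z <- matrix(stats::rnorm(m * v), nrow = m)
    if (!is.null(cf)) z <- z %*% cf
    z
  }
  if (family == "truncated-normal") {
    x <- sweep(sweep(draw_z(n), 2, sds, `*`), 2, means, `+`)
    repeat {
      bad <- which(apply(x, 1, function(r) any(r < 0)))
      if (length(bad) == 0) break
      x[bad, ] <- sweep(sweep(draw_z(length(bad)), 2, sds, `*`), 2, means, `+`)
    }
    x
  } else {
    if (any(means <= 0)) {
      stop("log-normal family requires strictly positive means", call. = FALSE)
    }
    sigma2 <- log(1 + (sds / means)^2)
    mu <- log(means) - sigma2 / 2
    z <- draw_z(n)
    exp(sweep(sweep(z, 2, sqrt(sigma2), `*`), 2, mu, `+`))
  }
}

#' Build a linearly separable concentration table
#'
#' Places each class in its own axis-aligned unit box, with consecutive
#' class centres offset by `gap + 1` along the first coordinate so the
#' boxes are separated by at least `gap`. Any reasonable classifier
#' reaches 100% accuracy on this layout; it serves as a ground-truth
#' oracle input for classifier tests.
#'
#' @param n_per_class Samples per class (>= 2).
#' @param n_classes Number of classes (labels `C1`, `C2`, ...).
#' @param n_elements Number of element columns (`E1`, `E2`, ...).
#' @param gap Minimum separation between class boxes (> 0).
#' @param seed Integer seed.
#' @return A concentration tibble as in [sample_concentrations()].
#' @export
make_separable_dataset <- function(n_per_class, n_classes = 3, n_elements = 4,
                                   gap = 10, seed = 1) {
  if (n_per_class < 2) stop("n_per_class must be >= 2", call. = FALSE)
  if (gap <= 0) stop("gap must be positive", call. = FALSE)
  elements <- sprintf("E%d", seq_len(n_elements))
  out <- with_local_seed(as.integer(seed), {
    rows <- lapply(seq_len(n_classes), function(i) {
      x <- matrix(stats::runif(n_per_class * n_elements, -0.5, 0.5),
                  nrow = n_per_class)
      x[, 1] <- x[, 1] + (i - 1) * (gap + 1)
      x <- x + gap + 1  # keep all concentrations positive
      colnames(x) <- elements
      tibble::as_tibble(as.data.frame(x)) |>
        dplyr::mutate(class = sprintf("C%d", i), .before = 1)
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::mutate(out,
    sample_id = sprintf("%s_%03d", .data$class,
                        stats::ave(seq_len(nrow(out)), out$class, FUN = seq_along)),
    .before = 1)
  attr(out, "units") <- stats::setNames(rep("ug/g_dry", n_elements), elements)
  out
}

#' Simulate an ICP-OES calibration fixture
#'
#' Generates standard-solution intensities from a straight-line
#' instrument response (`intensity = intercept + slope * concentration`
#' plus Gaussian noise) together with replicate blank readings of given
#' mean and relative standard deviation, mimicking a multi-standard
#' calibration plus blank.
#'
#' @param element Element name (metadata).
#' @param true_slope Instrument sensitivity, intensity per (ug/mL); > 0.
#' @param true_intercept Intensity at zero concentration.
#' @param blank_mean Mean blank intensity (> 0 when `blank_rsd_pct` > 0).
#' @param blank_rsd_pct Relative SD of the blank replicates, percent.
#' @param standard_concs Strictly increasing standard concentrations
#'   (ug/mL), length >= 2.
#' @param noise_sd SD of the intensity noise on the standards (counts).
#' @param n_blank Number of blank replicates (>= 2).
#' @param seed Integer seed.
#' @return A `calibration_fixture` list: `element`, `standard_concs`,
#'   `standard_intensities`, `blank_intensities`, `true_slope`,
#'   `true_intercept`, `noise_sd`.
#' @export
make_icp_fixture <- function(element, true_slope, true_intercept = 0,
                             blank_mean, blank_rsd_pct, standard_concs,
                             noise_sd = 0, n_blank = 10, seed = 1) {
  if (true_slope <= 0) stop("true_slope must be positive", call. = FALSE)
  if (n_blank < 2) stop("n_blank must be >= 2", call. = FALSE)
  if (length(standard_concs) < 2 || any(diff(standard_concs) <= 0)) {
    stop("standard_concs must be strictly increasing with length >= 2",
         call. = FALSE)
  }
  if (blank_mean <= 0 && blank_rsd_pct > 0) {
    stop("blank_mean must be positive when blank_rsd_pct > 0", call. = FALSE)
  }
  with_local_seed(as.integer(seed), {
    intens <- true_intercept + true_slope * standard_concs +
      stats::rnorm(length(standard_concs), 0, noise_sd)
    blanks <- stats::rnorm(n_blank, blank_mean, blank_mean * blank_rsd_pct / 100)
    structure(
      list(element = element,
           standard_concs = standard_concs,
           standard_intensities = intens,
           blank_intensities = blanks,
           true_slope = true_slope,
           true_intercept = true_intercept,
           noise_sd = noise_sd),
      class = "calibration_fixture")
  })
}

#' Simulate paired genuine/fortified samples for spike recovery
#'
#' The fortified member of each pair equals the genuine concentration
#' plus `spike_conc * true_recovery_pct / 100`, and both members carry
#' independent multiplicative Gaussian noise of the given relative SD.
#'
#' @param native_conc Native analyte concentration of the genuine sample.
#' @param spike_conc Added spike concentration (> 0), same units.
#' @param true_recovery_pct True recovery in percent (>= 0).
#' @param rsd_pct Relative SD of the multiplicative noise, percent.
#' @param n_pairs Number of genuine/fortified pairs (>= 1).
#' @param seed Integer seed.
#' @return A tibble with columns `pair`, `genuine`, `fortified` and the
#'   spike level in `attr(, "spike_conc")`.
#' @export
make_spike_fixture <- function(native_conc, spike_conc, true_recovery_pct = 100,
                               rsd_pct = 0, n_pairs = 6, seed = 1) {
  if (spike_conc <= 0) stop("spike_conc must be positive", call. = FALSE)
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (true_recovery_pct < 0) stop("true_recovery_pct must be >= 0", call. = FALSE)
  with_local_seed(as.integer(seed), {
    genuine <- native_conc * (1 + stats::rnorm(n_pairs, 0, rsd_pct / 100))
    fortified <- (genuine + spike_conc * true_recovery_pct / 100) *
      (1 + stats::rnorm(n_pairs, 0, rsd_pct / 100))
    out <- tibble::tibble(pair = seq_len(n_pairs),
                          genuine = genuine, fortified = fortified)
    attr(out, "spike_conc") <- spike_conc
    out
  })
}

# Run `expr` under a private RNG state: the caller's .Random.seed is
# restored afterwards, so generation never leaks into global RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Per-element units of a concentration table
#' @param tbl A concentration tibble produced by this package.
#' @return Named character vector of units, or NULL if absent.
#' @export
concentration_units <- function(tbl) attr(tbl, "units", exact = TRUE)
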