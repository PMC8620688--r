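#' Dummy-code class labels
#'
#' Builds the binary class-membership matrix used to turn classification
#' into regression: one column per class in sorted label order, a single
#' 1 per row marking membership (class A of three becomes `[1 0 0]`).
#'
#' @param labels Character or factor vector with >= 2 distinct labels.
#' @return Numeric matrix (samples x classes) with class names as
#'   column names.
#' @export
#' @examples
#' dummy_code(c("A", "B", "C", "A"))
dummy_code <- function(labels) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("at least 2 distinct labels required", call. = FALSE)
  y <- matrix(0, nrow = length(labels), ncol = length(lev),
              dimnames = list(NULL, lev))
  y[cbind(seq_along(labels), match(labels, lev))] <- 1
  y
}

#' Decode dummy-coded (or predicted) responses to labels
#' @param y Matrix with class-named columns; each row is assigned the
#'   label of its largest entry.
#' @return Character vector of labels.
#' @export
dummy_decode <- function(y) {
  if (is.null(colnames(y))) stop("response matrix must have class names", call. = FALSE)
  colnames(y)[max.col(y, ties.method = "first")]
}

# NIPALS PLS2 on a scaled X and centred Y. Returns weights W, X-loadings
# P, Y-loadings Q, scores T, per-component explained sums of squares,
# and regression coefficients B for each truncation 1..A.
nipals_pls2 <- function(x, y, n_components, tol = 1e-12, max_iter = 500) {
  x <- as.matrix(x); y <- as.matrix(y)
  s <- nrow(x); v <- ncol(x); cny <- ncol(y)
  a_cap <- min(s - 1, v)
  if (n_components < 1 || n_components > a_cap) {
    stop("n_components must be between 1 and ", a_cap, call. = FALSE)
  }
  ssx_tot <- sum(x^2); ssy_tot <- sum(y^2)
  w_mat <- matrix(0, v, n_components)
  p_mat <- matrix(0, v, n_components)
  q_mat <- matrix(0, cny, n_components)
  t_mat <- matrix(0, s, n_components)
  ssx <- ssy <- numeric(n_components)
  xa <- x; ya <- y
  a_used <- 0
  for (a in seq_len(n_components)) {
    u <- ya[, which.max(colSums(ya^2))]
    if (sum(u^2) < 1e-14 * max(1, ssy_tot)) break  # Y exhausted
    t_old <- rep(Inf, s)
    for (it in seq_len(max_iter)) {
      w <- crossprod(xa, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) stop("NIPALS breakdown: zero X weight", call. = FALSE)
      w <- w / nw
      tt <- xa %*% w
      q <- crossprod(ya, tt) / sum(tt^2)
      u <- ya %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
      if (it == max_iter) stop("NIPALS failed to converge", call. = FALSE)
    }
    # sign convention: largest-|w| entry positive
    flip <- sign(w[which.max(abs(w))]); if (flip == 0) flip <- 1
    w <- w * flip; tt <- tt * flip; q <- q * flip
    p <- crossprod(xa, tt) / sum(tt^2)
    w_mat[, a] <- w; p_mat[, a] <- p; q_mat[, a] <- q; t_mat[, a] <- tt
    ssx[a] <- sum(tt^2) * sum(p^2)
    ssy[a] <- sum(tt^2) * sum(q^2)
    xa <- xa - tcrossprod(tt, p)
    ya <- ya - tcrossprod(tt, q)
    a_used <- a
  }
  if (a_used == 0) stop("no PLS component could be extracted", call. = FALSE)
  keep <- seq_len(a_used)
  w_mat <- w_mat[, keep, drop = FALSE]; p_mat <- p_mat[, keep, drop = FALSE]
  q_mat <- q_mat[, keep, drop = FALSE]; t_mat <- t_mat[, keep, drop = FALSE]
  # B for every truncation a = 1..A (upper-triangular solve of P'W)
  b_list <- lapply(keep, function(a) {
    wa <- w_mat[, 1:a, drop = FALSE]
    pa <- p_mat[, 1:a, drop = FALSE]
    qa <- q_mat[, 1:a, drop = FALSE]
    wa %*% solve(crossprod(pa, wa), t(qa))
  })
  list(weights = w_mat, x_loadings = p_mat, y_loadings = q_mat,
       scores = t_mat, coef_by_a = b_list, n_components = a_used,
       ssx = ssx[keep], ssy = ssy[keep],
       ssx_total = ssx_tot, ssy_total = ssy_tot)
}

#' Fit a PLS2 discriminant model on a concentration table
#'
#' Autoscales the training rows (optionally after a log10 transform),
#' dummy-codes the class labels, centres the dummy matrix (it is not
#' variance-scaled, which would distort class priors), and runs NIPALS
#' PLS2 to the requested number of latent variables. Class assignment
#' parameters are attached afterwards by [plsda_attach_rule()] or by the
#' pipeline.
#'
#' @param tbl Training concentration tibble (`sample_id`, `class`,
#'   element columns).
#' @param n_components Number of latent variables A.
#' @param log10_first log10-transform concentrations before autoscaling.
#' @return A `plsda_model` list: the NIPALS matrices (`weights`,
#'   `x_loadings`, `y_loadings`, `scores`, `coefficients`), `scaler`,
#'   `y_means`, `classes`, `elements`, per-component explained variance
#'   on the X and Y blocks, and the training tibble's ids.
#' @export
#' @examples
#' tbl <- make_separable_dataset(10, n_classes = 3, n_elements = 4, seed = 2)
#' m <- plsda_fit(tbl, n_components = 2)
#' m$explained_y[1:2]
plsda_fit <- function(tbl, n_components, log10_first = FALSE) {
  elements <- setdiff(names(tbl), c("sample_id", "class"))
  x_raw <- as.matrix(tbl[elements])
  scaler <- autoscale_fit(x_raw, log10_first = log10_first)
  xs <- autoscale_apply(scaler, x_raw)
  y <- dummy_code(tbl$class)
  y_means <- colMeans(y)
  yc <- sweep(y, 2, y_means)
  core <- nipals_pls2(xs, yc, n_components)
  rownames(core$weights) <- rownames(core$x_loadings) <- elements
  rownames(core$y_loadings) <- colnames(y)
  b <- core$coef_by_a[[core$n_components]]
  dimnames(b) <- list(elements, colnames(y))
  structure(
    list(weights = core$weights, x_loadings = core$x_loadings,
         y_loadings = core$y_loadings, scores = core$scores,
         coefficients = b, coef_by_a = core$coef_by_a,
         scaler = scaler, y_means = y_means,
         classes = colnames(y), elements = elements,
         n_components = core$n_components,
         explained_x = core$ssx / core$ssx_total,
         explained_y = core$ssy / core$ssy_total,
         train_ids = tbl$sample_id, train_labels = tbl$class,
         rule = NULL),
    class = "plsda_model")
}

#' Predict continuous class responses from a fitted PLS-DA model
#'
#' Applies the stored scaler, then the regression coefficients; returns
#' the continuous (non-categorical) response for every class column.
#' Columns of `tbl` are matched to the model's variables by name.
#'
#' @param model A `plsda_model`.
#' @param tbl New concentration tibble (or numeric matrix with named
#'   columns).
#' @param n_components Truncate the model to fewer latent variables
#'   (default: all fitted).
#' @return Numeric matrix (rows x classes) of predicted responses.
#' @export
plsda_predict <- function(model, tbl, n_components = NULL) {
  x <- if (is.data.frame(tbl)) {
    missing_el <- setdiff(model$elements, names(tbl))
    if (length(missing_el) > 0) {
      stop("new data is missing variable(s): ",
           paste(missing_el, collapse = ", "), call. = FALSE)
    }
    as.matrix(tbl[model$elements])
  } else {
    as.matrix(tbl)[, model$elements, drop = FALSE]
  }
  b <- if (is.null(n_components)) model$coefficients else {
    if (n_components < 1 || n_components > model$n_components) {
      stop("n_components out of fitted range", call. = FALSE)
    }
    model$coef_by_a[[n_components]]
  }
  xs <- autoscale_apply(model$scaler, x)
  yhat <- xs %*% b
  yhat <- sweep(yhat, 2, model$y_means, `+`)
  colnames(yhat) <- model$classes
  rownames(yhat) <- if (is.data.frame(tbl) && "sample_id" %in% names(tbl)) {
    tbl$sample_id
  } else rownames(x)
  yhat
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( V * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )`,
#' where `SSY_a` is the Y-block variance explained by latent variable
#' `a`. Mean squared VIP is 1 by construction, so variables scoring
#' above one carry more than an average share of the discriminant
#' information ("greater-than-one" selection).
#'
#' @param model A fitted `plsda_model`.
#' @return A tibble: `element`, `vip`, `selected` (vip > 1), sorted by
#'   decreasing vip.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "plsda_model")) {
    stop("`model` must be a fitted plsda_model", call. = FALSE)
  }
  w <- model$weights
  ssy <- model$explained_y  # proportional to SSY_a
  wn2 <- sweep(w^2, 2, colSums(w^2), `/`)
  vip <- unname(sqrt(nrow(w) * drop(wn2 %*% ssy) / sum(ssy)))
  out <- tibble::tibble(element = rownames(w), vip = vip, selected = vip > 1)
  dplyr::arrange(out, dplyr::desc(.data$vip))
}

#' LDA assignment on predicted class responses
#'
#' Fits a linear discriminant (pooled within-class covariance, priors
#' proportional to training class frequencies unless given) in the space
#' of the continuous predicted responses, and assigns new responses to
#' the class with the largest discriminant score.
#'
#' @param yhat_train Training predicted/calculated responses (matrix).
#' @param labels_train Training labels.
#' @param yhat_new Responses to classify.
#' @param priors Optional named prior vector.
#' @return Character vector of assigned labels.
#' @export
assign_lda <- function(yhat_train, labels_train, yhat_new, priors = NULL) {
  labels_train <- as.character(labels_train)
  lev <- sort(unique(labels_train))
  if (length(lev) < 2) stop("need >= 2 training classes", call. = FALSE)
  # drop one response column: dummy responses are linearly dependent
  # (rows of Y sum to 1), which would make the pooled covariance singular
  ytr <- as.matrix(yhat_train)
  ynew <- as.matrix(yhat_new)
  if (ncol(ytr) >= length(lev) && length(lev) > 1) {
    ytr <- ytr[, -ncol(ytr), drop = FALSE]
    ynew <- ynew[, -ncol(ynew), drop = FALSE]
  }
  pr <- if (is.null(priors)) {
    as.vector(table(factor(labels_train, levels = lev))) / length(labels_train)
  } else priors[lev] / sum(priors[lev])
  # predicted dummy responses are rank-deficient at small A; MASS::lda
  # handles this via its tolerance but warns about collinearity
  fit <- withCallingHandlers(
    MASS::lda(ytr, grouping = factor(labels_train, levels = lev), prior = pr),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  as.character(stats::predict(fit, ynew)$class)
}

#' Equal-posterior threshold between two univariate Gaussians
#'
#' Solves `prior_in * N(y; mu_in, sd_in) =
#' (1 - prior_in) * N(y; mu_out, sd_out)` for the decision threshold on
#' a single predicted-response axis. With equal SDs the closed form is
#' the midpoint shifted by `sd^2 log((1-prior)/prior) / (mu_in - mu_out)`.
#'
#' @param mu_in,sd_in Gaussian of the in-class responses.
#' @param mu_out,sd_out Gaussian of the out-of-class responses.
#' @param prior_in Prior probability of the in-class group.
#' @return The threshold (scalar).
#' @export
#' @examples
#' bayes_threshold(1, 0.2, 0, 0.2)  # symmetric, equal priors -> 0.5
bayes_threshold <- function(mu_in, sd_in, mu_out, sd_out, prior_in = 0.5) {
  if (sd_in <= 0 || sd_out <= 0) stop("SDs must be positive", call. = FALSE)
  if (abs(sd_in - sd_out) < 1e-12 * max(sd_in, sd_out)) {
    s2 <- sd_in^2
    return((mu_in + mu_out) / 2 +
             s2 * log((1 - prior_in) / prior_in) / (mu_in - mu_out))
  }
  # unequal variances: quadratic in y
  a <- 1 / (2 * sd_out^2) - 1 / (2 * sd_in^2)
  b <- mu_in / sd_in^2 - mu_out / sd_out^2
  cc <- mu_out^2 / (2 * sd_out^2) - mu_in^2 / (2 * sd_in^2) +
    log((prior_in * sd_out) / ((1 - prior_in) * sd_in))
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real equal-posterior point", call. = FALSE)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  lo <- min(mu_in, mu_out); hi <- max(mu_in, mu_out)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside) > 0) inside[1] else
    roots[which.min(abs(roots - (mu_in + mu_out) / 2))]
}

#' Bayesian class assignment on predicted responses
#'
#' One-vs-rest Gaussian posterior assignment: for every class column,
#' univariate Gaussians are fitted to the (cross-validation) predicted
#' responses of the in-class and out-of-class samples; a new sample's
#' posterior membership probability per class follows from Bayes'
#' theorem with the given priors, and the sample is assigned to the
#' class of maximal posterior. Exact posterior ties are broken by the
#' larger raw response margin, then by the lower class index.
#'
#' @param yhat_cv Matrix of predicted responses used to calibrate the
#'   per-class Gaussians (typically CV predictions of the training set).
#' @param labels Labels matching `yhat_cv` rows.
#' @param yhat_new Responses to classify (matrix with the same class
#'   columns).
#' @param priors Optional named prior vector; default training
#'   proportions.
#' @return Character vector of assigned labels.
#' @export
assign_bayes <- function(yhat_cv, labels, yhat_new, priors = NULL) {
  yhat_cv <- as.matrix(yhat_cv); yhat_new <- as.matrix(yhat_new)
  labels <- as.character(labels)
  classes <- colnames(yhat_cv)
  if (is.null(classes)) stop("response matrix must have class names", call. = FALSE)
  pr <- if (is.null(priors)) {
    as.vector(table(factor(labels, levels = classes))) / length(labels)
  } else unname(priors[classes] / sum(priors[classes]))
  params <- lapply(seq_along(classes), function(ci) {
    inside <- yhat_cv[labels == classes[ci], ci]
    outside <- yhat_cv[labels != classes[ci], ci]
    if (length(inside) < 2 || length(outside) < 2) {
      stop("class ", classes[ci], " needs >= 2 in-class and out-of-class ",
           "calibration responses", call. = FALSE)
    }
    p <- list(mu_in = mean(inside), sd_in = stats::sd(inside),
              mu_out = mean(outside), sd_out = stats::sd(outside))
    if (p$sd_in == 0 || p$sd_out == 0) {
      stop("zero variance in calibration responses for class ", classes[ci],
           call. = FALSE)
    }
    p
  })
  post <- vapply(seq_along(classes), function(ci) {
    p <- params[[ci]]
    y <- yhat_new[, ci]
    num <- pr[ci] * stats::dnorm(y, p$mu_in, p$sd_in)
    den <- num + (1 - pr[ci]) * stats::dnorm(y, p$mu_out, p$sd_out)
    ifelse(den == 0, 0, num / den)
  }, numeric(nrow(yhat_new)))
  post <- matrix(post, nrow = nrow(yhat_new))
  vapply(seq_len(nrow(post)), function(i) {
    best <- which(post[i, ] == max(post[i, ]))
    if (length(best) > 1) {
      margin <- yhat_new[i, best]
      best <- best[which.max(margin)]
    }
    classes[best[1]]
  }, character(1))
}

#' Attach an assignment rule to a fitted PLS-DA model
#'
#' @param model A `plsda_model`.
#' @param rule `"bayes"` or `"lda"`.
#' @param yhat_calibration Responses used to calibrate the rule —
#'   cross-validation predictions of the training samples for an honest
#'   rule, or the calculated training responses.
#' @param labels Labels for the calibration responses (default: the
#'   model's training labels).
#' @param priors Optional named priors.
#' @return The model with `rule`, `rule_yhat`, `rule_labels`,
#'   `rule_priors` filled in.
#' @export
plsda_attach_rule <- function(model, rule = c("bayes", "lda"),
                              yhat_calibration = NULL, labels = NULL,
                              priors = NULL) {
  rule <- match.arg(rule)
  if (is.null(yhat_calibration)) {
    yhat_calibration <- model$scores %*% t(model$y_loadings)
    yhat_calibration <- sweep(yhat_calibration, 2, model$y_means, `+`)
    colnames(yhat_calibration) <- model$classes
  }
  model$rule <- rule
  model$rule_yhat <- yhat_calibration
  model$rule_labels <- if (is.null(labels)) model$train_labels else labels
  model$rule_priors <- priors
  model
}

#' Assign class labels to new samples with a fitted model and rule
#' @param model A `plsda_model` with an attached rule.
#' @param tbl New concentration tibble.
#' @return Tibble: `sample_id` (when present), `assigned`, and the
#'   continuous responses per class.
#' @export
plsda_assign <- function(model, tbl) {
  if (is.null(model$rule)) stop("no assignment rule attached; see plsda_attach_rule()",
                                call. = FALSE)
  yhat <- plsda_predict(model, tbl)
  lab <- if (model$rule == "bayes") {
    assign_bayes(model$rule_yhat, model$rule_labels, yhat, model$rule_priors)
  } else {
    assign_lda(model$rule_yhat, model$rule_labels, yhat, model$rule_priors)
  }
  out <- tibble::as_tibble(as.data.frame(yhat))
  names(out) <- paste0("yhat_", colnames(yhat))
  out <- dplyr::mutate(out, assigned = lab, .before = 1)
  if (is.data.frame(tbl) && "sample_id" %in% names(tbl)) {
    out <- dplyr::mutate(out, sample_id = tbl$sample_id, .before = 1)
  }
  out
}

# Stratified fold assignment: within each class, samples ordered by id
# are dealt round-robin ("venetian blinds") into k folds; the random
# scheme shuffles within class first under the seed.
make_folds <- function(ids, labels, k, scheme = c("venetian", "random"),
                       seed = NULL) {
  scheme <- match.arg(scheme)
  fold <- integer(length(ids))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    ord <- idx[order(ids[idx])]
    if (scheme == "random") {
      if (is.null(seed)) stop("random folds need a seed", call. = FALSE)
      ord <- with_local_seed(seed + match(cl, sort(unique(labels))),
                             sample(ord))
    }
    fold[ord] <- ((seq_along(ord) - 1L) %% k) + 1L
  }
  fold
}

#' Cross-validated latent-variable selection
#'
#' Runs stratified k-fold cross-validation of the PLS-DA classifier over
#' 1..`a_max` latent variables and selects the count minimising the
#' misclassification rate (smallest count on ties). Folds are venetian
#' blinds within class by default (deterministic); autoscaling and the
#' PLS fit use the training folds only, and the assignment rule is
#' calibrated on the training folds' calculated responses before being
#' applied to the held-out fold's predicted responses.
#'
#' @param tbl Concentration tibble of the training samples.
#' @param a_max Largest number of latent variables to explore.
#' @param k Number of folds (default 5).
#' @param rule `"lda"` or `"bayes"`.
#' @param scheme Fold scheme, `"venetian"` or `"random"`.
#' @param seed Seed for the random scheme.
#' @param log10_first log10-transform before autoscaling.
#' @return A list: `error_curve` (tibble `n_components` / `error`),
#'   `a_selected`, `cv_yhat` (list over A of CV-predicted response
#'   matrices, rows ordered as `tbl`), `cv_assigned` (list over A of
#'   label vectors), `folds`.
#' @export
cross_validate_lv <- function(tbl, a_max, k = 5, rule = c("lda", "bayes"),
                              scheme = c("venetian", "random"), seed = NULL,
                              log10_first = FALSE) {
  rule <- match.arg(rule); scheme <- match.arg(scheme)
  labels <- as.character(tbl$class)
  fold <- make_folds(tbl$sample_id, labels, k, scheme, seed)
  classes <- sort(unique(labels))
  n <- nrow(tbl)
  cv_yhat <- lapply(seq_len(a_max), function(a)
    matrix(NA_real_, n, length(classes), dimnames = list(tbl$sample_id, classes)))
  cv_assigned <- lapply(seq_len(a_max), function(a) character(n))
  for (f in sort(unique(fold))) {
    tr <- tbl[fold != f, , drop = FALSE]
    te <- tbl[fold == f, , drop = FALSE]
    if (length(unique(tr$class)) < length(classes)) {
      stop("fold ", f, " training part is missing a class; reduce k",
           call. = FALSE)
    }
    m <- plsda_fit(tr, n_components = a_max, log10_first = log10_first)
    for (a in seq_len(a_max)) {
      a_eff <- min(a, m$n_components)
      yhat_tr <- plsda_predict(m, tr, n_components = a_eff)
      yhat_te <- plsda_predict(m, te, n_components = a_eff)
      lab <- if (rule == "bayes") {
        assign_bayes(yhat_tr, tr$class, yhat_te)
      } else {
        assign_lda(yhat_tr, tr$class, yhat_te)
      }
      cv_yhat[[a]][fold == f, ] <- yhat_te
      cv_assigned[[a]][fold == f] <- lab
    }
  }
  err <- vapply(seq_len(a_max), function(a)
    mean(cv_assigned[[a]] != labels), numeric(1))
  a_sel <- which.min(err)  # which.min takes the smallest index on ties
  list(error_curve = tibble::tibble(n_components = seq_len(a_max), error = err),
       a_selected = a_sel, cv_yhat = cv_yhat, cv_assigned = cv_assigned,
       folds = fold)
}

#' Classification performance metrics
#'
#' Confusion matrix, total accuracy, per-class sensitivity and
#' specificity, and the ids of misclassified samples.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param ids Optional sample ids for the misclassification listing.
#' @return A `classification_report` list: `confusion` (true x
#'   predicted), `total_accuracy` (percent), `per_class` tibble
#'   (`class`, `sensitivity`, `specificity`, percents),
#'   `misclassified_ids`, `n`.
#' @export
#' @examples
#' classification_metrics(c("a", "a", "b"), c("a", "b", "b"))$total_accuracy
classification_metrics <- function(true_labels, predicted_labels, ids = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  lev <- sort(unique(c(true_labels, predicted_labels)))
  conf <- table(factor(true_labels, levels = lev),
                factor(predicted_labels, levels = lev))
  names(dimnames(conf)) <- c("true", "predicted")
  n <- length(true_labels)
  acc <- 100 * sum(diag(conf)) / n
  per_class <- purrr::map_dfr(lev, function(cl) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, ]) - tp
    fp <- sum(conf[, cl]) - tp
    tn <- n - tp - fn - fp
    tibble::tibble(
      class = cl,
      sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
      specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp))
  })
  wrong <- which(true_labels != predicted_labels)
  structure(
    list(confusion = conf, total_accuracy = acc, per_class = per_class,
         misclassified_ids = if (is.null(ids)) wrong else ids[wrong],
         n = n),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Total accuracy: %.1f%% (%d samples, %d misclassified)\n",
              x$total_accuracy, x$n, length(x$misclassified_ids)))
  print(x$confusion)
  invisible(x)
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("PLS-DA model:", length(x$train_ids), "samples x",
      length(x$elements), "variables,", x$n_components, "latent variables\n")
  cat(sprintf("Explained variance: X %.1f%%, Y %.1f%%\n",
              100 * sum(x$explained_x), 100 * sum(x$explained_y)))
  if (!is.null(x$rule)) cat("Assignment rule:", x$rule, "\n")
  invisible(x)
}
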