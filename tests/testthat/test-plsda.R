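test_that("dummy coding builds the canonical membership matrix", {
  y <- dummy_code(c("A", "B", "C"))
  expect_equal(unname(y), diag(3))
  expect_equal(colnames(y), c("A", "B", "C"))
  y2 <- dummy_code(c("x", "y", "x"))
  expect_equal(unname(y2), matrix(c(1, 0, 1, 0, 1, 0), 3))
  labs <- c("PS", "PF", "PR", "PS")
  expect_equal(dummy_decode(dummy_code(labs)), labs)
  expect_error(dummy_code("A"), "2 distinct")
})

test_that("a single informative column dominates a one-component model", {
  set.seed(6)
  n <- 20
  cls <- rep(c("A", "B"), each = n / 2)
  x <- tibble::tibble(
    sample_id = paste0("s", 1:n), class = cls,
    inf = ifelse(cls == "A", 0, 4) + rnorm(n, 0, 0.05),
    noise1 = rnorm(n), noise2 = rnorm(n))
  m <- plsda_fit(x, n_components = 1)
  w <- abs(m$weights[, 1])
  expect_equal(names(which.max(w)), "inf")
  # the informative variable is the only one selected by VIP
  v <- vip_scores(m)
  expect_true(v$selected[v$element == "inf"])
  expect_false(any(v$selected[v$element != "inf"]))
})

test_that("PLS with full rank reproduces least-squares predictions", {
  set.seed(7)
  for (rep in 1:20) {
    s <- sample(8:14, 1); v <- sample(2:6, 1)
    x <- matrix(rnorm(s * v), s, v)
    x <- scale(x)
    y <- scale(matrix(rnorm(s * 2), s, 2), scale = FALSE)
    core <- chemauth:::nipals_pls2(x, y, n_components = v)
    expect_equal(core$n_components, v)
    yhat <- x %*% core$coef_by_a[[v]]
    expect_lt(max(abs(yhat - ols_predictions(x, y))), 1e-8)
  }
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(8)
  x <- scale(matrix(rnorm(15 * 6), 15, 6))
  y <- scale(dummy_code(rep(c("A", "B", "C"), each = 5)), scale = FALSE)
  core <- chemauth:::nipals_pls2(x, y, n_components = 5)
  tt <- crossprod(core$scores)
  expect_lt(max(abs(tt - diag(diag(tt)))), 1e-8)
})

test_that("training predictions and name-based column alignment are exact", {
  tbl <- make_separable_dataset(8, n_classes = 3, n_elements = 4, seed = 9)
  m <- plsda_fit(tbl, n_components = 2)
  yhat1 <- plsda_predict(m, tbl)
  # reproduce fitted values: T Q' + centring
  fitted <- sweep(m$scores %*% t(m$y_loadings), 2, m$y_means, `+`)
  expect_equal(unname(yhat1), unname(fitted), tolerance = 1e-10)
  # permuted columns with names intact give identical predictions
  perm <- tbl[c("sample_id", "class", rev(setdiff(names(tbl),
                                                  c("sample_id", "class"))))]
  expect_equal(plsda_predict(m, perm), yhat1)
  expect_error(plsda_predict(m, tbl[-3]), "missing variable")
  # class centroids score highest on their own column
  for (cl in unique(tbl$class)) {
    cent <- dplyr::summarise(dplyr::filter(tbl, class == cl),
                             dplyr::across(dplyr::starts_with("E"), mean))
    yc <- plsda_predict(m, cent)
    expect_equal(colnames(yc)[which.max(yc)], cl)
  }
})

test_that("VIP scores are normalised so the mean square is one", {
  for (seed in c(11, 12)) {
    tbl <- sample_concentrations(pecorino_class_stats(), seed = seed)
    for (a in c(1, 3)) {
      m <- plsda_fit(tbl, n_components = a)
      v <- vip_scores(m)
      expect_equal(sum(v$vip^2), length(m$elements), tolerance = 1e-8)
    }
  }
  # single variable: VIP is exactly 1
  one <- tibble::tibble(sample_id = paste0("s", 1:10),
                        class = rep(c("A", "B"), 5),
                        E1 = rnorm(10, rep(c(0, 3), 5), 0.1))
  m1 <- plsda_fit(one, n_components = 1)
  expect_equal(vip_scores(m1)$vip, 1, tolerance = 1e-12)
  expect_error(vip_scores(list()), "plsda_model")
})

test_that("LDA assignment matches the analytic 1-D boundary", {
  set.seed(13)
  n <- 4000
  mu <- c(a = 0, b = 1); sd0 <- 0.4
  lab <- rep(c("a", "b"), each = n / 2)
  y <- matrix(c(rnorm(n / 2, mu["a"], sd0), rnorm(n / 2, mu["b"], sd0)),
              ncol = 1)
  grid <- matrix(seq(0.3, 0.7, by = 0.001), ncol = 1)
  got <- assign_lda(y, lab, grid)
  boundary_emp <- grid[max(which(got == "a"))]
  # pooled-variance midpoint (equal priors by the balanced design)
  s2 <- ((n / 2 - 1) * var(y[lab == "a"]) +
           (n / 2 - 1) * var(y[lab == "b"])) / (n - 2)
  boundary_analytic <- (mean(y[lab == "a"]) + mean(y[lab == "b"])) / 2
  expect_lt(abs(boundary_emp - boundary_analytic), 2e-3)
  # unequal priors shift the boundary by s^2 log(p1/p2) / (mu2 - mu1)
  got_w <- assign_lda(y, lab, grid, priors = c(a = 2 / 3, b = 1 / 3))
  boundary_w <- grid[max(which(got_w == "a"))]
  shift <- s2 * log(2) / (mean(y[lab == "b"]) - mean(y[lab == "a"]))
  expect_lt(abs(boundary_w - (boundary_analytic + shift)), 2e-3)
})

test_that("two disjoint response clouds give zero LDA training error", {
  y <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
             matrix(rnorm(20, 5, 0.1), ncol = 2))
  lab <- rep(c("A", "B"), each = 10)
  expect_equal(assign_lda(y, lab, y), lab)
})

test_that("Bayesian threshold follows its closed forms", {
  # symmetric Gaussians, equal priors: threshold at the midpoint
  expect_equal(bayes_threshold(1, 0.2, 0, 0.2), 0.5)
  # doubling the in-class prior moves the threshold by s^2 ln 2 / dmu
  s <- 0.3
  t_eq <- bayes_threshold(1, s, 0, s, prior_in = 0.5)
  t_2x <- bayes_threshold(1, s, 0, s, prior_in = 2 / 3)
  expect_equal(t_eq - t_2x, s^2 * log(2) / 1, tolerance = 1e-12)
  # unequal variances: returned point has equal weighted densities
  thr <- bayes_threshold(1, 0.2, 0, 0.5, prior_in = 0.4)
  expect_equal(0.4 * dnorm(thr, 1, 0.2), 0.6 * dnorm(thr, 0, 0.5),
               tolerance = 1e-9)
  expect_error(bayes_threshold(1, 0, 0, 1), "positive")
})

test_that("Bayesian assignment separates calibrated classes", {
  set.seed(14)
  n <- 200
  lab <- rep(c("A", "B"), each = n)
  # predicted responses: own column near 1 in class, near 0 outside
  yhat <- cbind(A = c(rnorm(n, 1, 0.1), rnorm(n, 0, 0.1)),
                B = c(rnorm(n, 0, 0.1), rnorm(n, 1, 0.1)))
  new_draws <- cbind(A = c(0.95, 0.05), B = c(0.02, 1.02))
  expect_equal(assign_bayes(yhat, lab, new_draws), c("A", "B"))
  # perfectly separated distributions: no misassignment on fresh draws
  fresh <- cbind(A = c(rnorm(50, 1, 0.05), rnorm(50, 0, 0.05)),
                 B = c(rnorm(50, 0, 0.05), rnorm(50, 1, 0.05)))
  expect_equal(assign_bayes(yhat, lab, fresh), rep(c("A", "B"), each = 50))
  expect_error(assign_bayes(yhat[c(1, n + 1), ], lab[c(1, n + 1)], new_draws),
               ">= 2")
})

test_that("bayes and lda agree on symmetric 1-D equal-prior problems", {
  set.seed(15)
  n <- 1000
  lab <- rep(c("A", "B"), each = n / 2)
  yhat <- cbind(A = c(rnorm(n / 2, 1, 0.2), rnorm(n / 2, 0, 0.2)))
  yhat <- cbind(yhat, B = 1 - yhat[, 1])
  grid <- cbind(A = seq(0.2, 0.8, 0.01))
  grid <- cbind(grid, B = 1 - grid[, 1])
  expect_equal(assign_bayes(yhat, lab, grid), assign_lda(yhat, lab, grid))
})

test_that("cross-validation selects the smallest sufficient model", {
  tbl <- make_separable_dataset(10, n_classes = 3, n_elements = 5,
                                gap = 10, seed = 16)
  cv <- cross_validate_lv(tbl, a_max = 4, k = 5, rule = "lda")
  expect_equal(min(cv$error_curve$error), 0)
  first_zero <- min(cv$error_curve$n_components[cv$error_curve$error == 0])
  expect_equal(cv$a_selected, first_zero)
})

test_that("pure-noise data cross-validates near the no-information rate", {
  errs <- vapply(1:5, function(s) {
    tbl <- with_seed_tbl(s)
    cv <- cross_validate_lv(tbl, a_max = 2, k = 5, rule = "lda")
    min(cv$error_curve$error)
  }, numeric(1))
  # 3 balanced classes: expected error 2/3; averaged over seeds the
  # minimum over 2 model sizes sits within sampling error below it
  expect_gt(mean(errs), 2 / 3 - 0.12)
  expect_lt(mean(errs), 2 / 3 + 0.12)
})

test_that("fold dealing is stratified venetian blinds", {
  tbl <- sample_concentrations(pecorino_class_stats(), seed = 18)
  fold <- chemauth:::make_folds(tbl$sample_id, tbl$class, k = 5)
  for (cl in unique(tbl$class)) {
    f <- fold[tbl$class == cl]
    ids <- tbl$sample_id[tbl$class == cl]
    expect_equal(f[order(ids)], ((seq_along(f) - 1) %% 5) + 1)
    expect_lte(diff(range(table(factor(f, levels = 1:5)))), 1)
  }
  # every fold's training part contains every class
  for (k in 1:5) {
    expect_setequal(unique(tbl$class[fold != k]), unique(tbl$class))
  }
})

test_that("autoscaling inside CV ignores held-out rows (leakage guard)", {
  tbl <- sample_concentrations(pecorino_class_stats(), seed = 19)
  fold <- chemauth:::make_folds(tbl$sample_id, tbl$class, k = 5)
  tr <- tbl[fold != 1, ]
  te <- tbl[fold == 1, ]
  m <- plsda_fit(tr, n_components = 2)
  yhat_before <- plsda_predict(m, te)
  # mutating the held-out rows must not change the fitted scaler or the
  # training-side model in any way
  te_mut <- te
  te_mut$Na <- te_mut$Na * 100
  m2 <- plsda_fit(tr, n_components = 2)
  expect_identical(m$scaler, m2$scaler)
  expect_identical(m$coefficients, m2$coefficients)
  # and predictions for unchanged rows are unchanged
  expect_equal(plsda_predict(m2, te), yhat_before)
})

test_that("classification metrics reproduce accuracy arithmetic", {
  truth <- c(rep("PF", 9), rep("PS", 12), rep("PR", 9))
  pred <- truth
  pred[1] <- "PS"   # one PF misclassified
  pred[22] <- "PF"  # one PR misclassified
  rep30 <- classification_metrics(truth, pred)
  expect_equal(rep30$total_accuracy, 100 * 28 / 30)
  expect_equal(round(rep30$total_accuracy, 1), 93.3)

  truth23 <- c(rep("PF", 7), rep("PS", 8), rep("PR", 8))
  pred23 <- truth23
  pred23[8:9] <- "PR"  # two PS misclassified
  rep23 <- classification_metrics(truth23, pred23, ids = seq_len(23))
  expect_equal(round(rep23$total_accuracy, 1), 91.3)
  expect_equal(rep23$misclassified_ids, c(8, 9))

  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$total_accuracy, 100)
  expect_equal(sum(diag(perfect$confusion)), 30)
  expect_equal(unname(rowSums(rep30$confusion)), c(9, 9, 12))
  expect_error(classification_metrics(truth, truth[-1]), "equal length")
})
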