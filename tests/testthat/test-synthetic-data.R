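test_that("class statistics load, validate and round-trip", {
  stats <- pecorino_class_stats()
  expect_equal(nrow(stats), 24)
  expect_setequal(unique(stats$class), c("PF", "PS", "PR"))
  ba_pf <- dplyr::filter(stats, class == "PF", element == "Ba")
  expect_equal(ba_pf$mean, 1.2)
  expect_equal(ba_pf$sd, 0.7)
  expect_equal(ba_pf$n, 16L)
  expect_equal(ba_pf$unit, "ug/g_dry")

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(stats, path)
  expect_equal(as.data.frame(load_class_stats(path)), as.data.frame(stats))

  expect_error(load_class_stats(stats[0, ]), "empty")
  expect_error(load_class_stats(dplyr::select(stats, -sd)), "missing column")
  expect_error(load_class_stats(dplyr::bind_rows(stats, stats[1, ])),
               "duplicate")
  bad <- stats; bad$sd[3] <- -1
  expect_error(load_class_stats(bad), "row 3")
})

test_that("sampling is seeded, deterministic, and respects class sizes", {
  stats <- pecorino_class_stats()
  t1 <- sample_concentrations(stats, seed = 7)
  t2 <- sample_concentrations(stats, seed = 7)
  t3 <- sample_concentrations(stats, seed = 8)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  counts <- dplyr::count(t1, class)
  expect_equal(counts$n[match(c("PF", "PS", "PR"), counts$class)],
               c(16L, 20L, 17L))
  expect_false(any(duplicated(t1$sample_id)))
  units <- concentration_units(t1)
  expect_equal(unname(units[c("Ba", "Na")]), c("ug/g_dry", "mg/g_dry"))
})

test_that("zero-noise sampling returns the class mean vector exactly", {
  stats <- tiny_class_stats()
  stats$sd <- 0
  tbl <- sample_concentrations(stats, seed = 1)
  a_rows <- dplyr::filter(tbl, class == "A")
  expect_true(all(a_rows$E1 == 10) && all(a_rows$E2 == 5))
})

test_that("generated moments match the specification at large n", {
  stats <- pecorino_class_stats()
  big <- sample_concentrations(stats, n_per_class = 10000, seed = 42)
  emp <- summarize_concentrations(big)
  merged <- dplyr::inner_join(stats, emp, by = c("class", "element"),
                              suffix = c("_spec", "_emp"))
  # law of large numbers against the analytic mean of the zero-truncated
  # normal: mu + sd * phi(a) / (1 - Phi(a)) with a = -mu/sd
  a <- -merged$mean_spec / merged$sd_spec
  m_trunc <- merged$mean_spec +
    merged$sd_spec * stats::dnorm(a) / (1 - stats::pnorm(a))
  tol <- 4 * merged$sd_spec / sqrt(10000)
  expect_true(all(abs(merged$mean_emp - m_trunc) < tol))
  expect_true(all(as.matrix(big[-(1:2)]) >= 0))
})

test_that("moment recovery holds tightly away from the truncation boundary", {
  stats <- tiny_class_stats()  # means >= 5 sd above zero
  for (fam in c("truncated-normal", "log-normal")) {
    big <- sample_concentrations(stats, n_per_class = 1e5, family = fam,
                                 seed = 9)
    emp <- summarize_concentrations(big)
    merged <- dplyr::inner_join(stats, emp, by = c("class", "element"),
                                suffix = c("_spec", "_emp"))
    rel_tol <- if (fam == "truncated-normal") 0.01 else 0.02
    expect_true(all(abs(merged$mean_emp / merged$mean_spec - 1) < rel_tol),
                label = paste(fam, "means"))
    expect_true(all(abs(merged$sd_emp / merged$sd_spec - 1) < rel_tol),
                label = paste(fam, "sds"))
    expect_true(all(as.matrix(big[-(1:2)]) >= 0))
  }
})

test_that("a supplied correlation matrix is recovered empirically", {
  stats <- tiny_class_stats()
  r <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("E1", "E2"),
                                                    c("E1", "E2")))
  big <- sample_concentrations(stats, n_per_class = 1e5, correlation = r,
                               seed = 5)
  for (cl in c("A", "B")) {
    sub <- dplyr::filter(big, class == cl)
    expect_lt(abs(stats::cor(sub$E1, sub$E2) - 0.8), 0.02)
  }
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = dimnames(r))
  expect_error(
    sample_concentrations(stats, correlation = bad, seed = 1),
    "positive semi-definite")
})

test_that("separable datasets keep classes at least `gap` apart", {
  tbl <- make_separable_dataset(6, n_classes = 3, n_elements = 3, gap = 10,
                                seed = 2)
  expect_identical(tbl, make_separable_dataset(6, n_classes = 3,
                                               n_elements = 3, gap = 10,
                                               seed = 2))
  x <- as.matrix(tbl[-(1:2)])
  labs <- tbl$class
  # exhaustive pairwise scan between classes
  min_between <- Inf
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(x))) {
    if (labs[i] != labs[j]) {
      min_between <- min(min_between, sqrt(sum((x[i, ] - x[j, ])^2)))
    }
  }
  expect_gte(min_between, 10)
  # nearest class centroid classifies perfectly
  cents <- sapply(unique(labs), function(cl) colMeans(x[labs == cl, ]))
  pred <- unique(labs)[apply(x, 1, function(r)
    which.min(colSums((cents - r)^2)))]
  expect_equal(pred, labs)
  expect_error(make_separable_dataset(1), "n_per_class")
})

test_that("calibration fixtures have the requested noise structure", {
  fx0 <- make_icp_fixture("Ba", true_slope = 5, true_intercept = 2,
                          blank_mean = 2, blank_rsd_pct = 0,
                          standard_concs = c(1, 2, 4), noise_sd = 0, seed = 1)
  expect_equal(fx0$standard_intensities, 2 + 5 * c(1, 2, 4))
  expect_true(all(fx0$blank_intensities == 2))

  fx <- make_icp_fixture("Ba", true_slope = 5, blank_mean = 100,
                         blank_rsd_pct = 3, standard_concs = c(1, 2),
                         n_blank = 10000, seed = 2)
  expect_lt(abs(precision_rsd(fx$blank_intensities) / 3 - 1), 0.05)

  expect_error(make_icp_fixture("Ba", true_slope = -1, blank_mean = 1,
                                blank_rsd_pct = 1, standard_concs = c(1, 2)),
               "true_slope")
  expect_error(make_icp_fixture("Ba", true_slope = 1, blank_mean = 0,
                                blank_rsd_pct = 5, standard_concs = c(1, 2)),
               "blank_mean")
})

test_that("spike fixtures encode the true recovery", {
  sf <- make_spike_fixture(native_conc = 2, spike_conc = 6.67,
                           true_recovery_pct = 83, rsd_pct = 0, n_pairs = 6)
  rec <- recovery_percent(sf$genuine, sf$fortified,
                          attr(sf, "spike_conc"))
  expect_equal(rec$mean_recovery_pct, 83)

  # with noise, the mean over many pairs converges to the true value
  sf2 <- make_spike_fixture(2, 6.67, true_recovery_pct = 83, rsd_pct = 12,
                            n_pairs = 20000, seed = 3)
  rec2 <- recovery_percent(sf2$genuine, sf2$fortified, 6.67)
  expect_lt(abs(rec2$mean_recovery_pct - 83), 1)
  expect_error(make_spike_fixture(2, 0), "spike_conc")
  expect_error(make_spike_fixture(2, 1, true_recovery_pct = -5),
               "true_recovery_pct")
})
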