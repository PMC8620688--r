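# Shared fixtures built in code.

# A tiny two-class, two-element summary table with comfortable separation.
tiny_class_stats <- function() {
  tibble::tribble(
    ~class, ~element, ~mean, ~sd, ~n, ~unit,
    "A", "E1", 10, 1, 10L, "ug/g_dry",
    "A", "E2",  5, 1, 10L, "ug/g_dry",
    "B", "E1", 20, 1, 12L, "ug/g_dry",
    "B", "E2",  5, 1, 12L, "ug/g_dry")
}

# Pure-noise 3-class table: all classes share one distribution, so no
# classifier can beat the no-information rate.
with_seed_tbl <- function(seed, n = 15, v = 4) {
  stats <- tidyr::expand_grid(class = c("A", "B", "C"),
                              element = sprintf("E%d", seq_len(v)))
  stats$mean <- 10; stats$sd <- 2; stats$n <- n; stats$unit <- "ug/g_dry"
  sample_concentrations(stats, seed = seed)
}

# Independent normal-equations least-squares predictions (oracle for
# the full-rank PLS check): Yhat = X B with B = (X'X)^{-1} X'Y.
ols_predictions <- function(x, y) {
  b <- solve(crossprod(x), crossprod(x, y))
  x %*% b
}

# Re-walk the Duplex point selection by brute force: at every step,
# scan all remaining points and all distances to confirm the max-min
# choice. Returns per-class train/test id sets.
duplex_bruteforce <- function(x, labels, ids, quota) {
  x <- autoscale_apply(autoscale_fit(x), x)
  res <- list()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    d <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
    n <- length(idx)
    rem <- seq_len(n)
    pick_pair <- function(rem) {
      best <- c(NA, NA); bd <- -Inf
      for (i in rem) for (j in rem) if (i < j && d[i, j] > bd) {
        bd <- d[i, j]; best <- c(i, j)
      }
      best
    }
    pick_maxmin <- function(rem, set) {
      best <- NA; bd <- -Inf
      for (i in rem) {
        mi <- min(d[i, set])
        if (mi > bd) { bd <- mi; best <- i }
      }
      best
    }
    tr <- pick_pair(rem); rem <- setdiff(rem, tr)
    te <- pick_pair(rem); rem <- setdiff(rem, te)
    test_quota <- n - quota[[cl]]
    turn <- "train"
    while (length(rem) > 0) {
      if (length(tr) >= quota[[cl]]) { te <- c(te, rem); rem <- integer(0) }
      else if (length(te) >= test_quota) {
        p <- pick_maxmin(rem, tr); tr <- c(tr, p); rem <- setdiff(rem, p)
      } else if (turn == "train") {
        p <- pick_maxmin(rem, tr); tr <- c(tr, p); rem <- setdiff(rem, p)
        turn <- "test"
      } else {
        p <- pick_maxmin(rem, te); te <- c(te, p); rem <- setdiff(rem, p)
        turn <- "train"
      }
    }
    res[[cl]] <- list(train = sort(ids[idx[tr]]), test = sort(ids[idx[te]]))
  }
  res
}
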