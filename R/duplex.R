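#' Duplex train/test split, applied per class
#'
#' Deterministic representative splitting in the style of Snee's Duplex
#' algorithm, run independently within each class on Euclidean distances
#' in autoscaled space:
#'
#' 1. the two mutually farthest points of the class go to TRAIN;
#' 2. the two farthest remaining points go to TEST;
#' 3. sets then alternate (train, test, train, ...), each receiving the
#'    remaining point with the largest minimum distance to the points it
#'    already holds, until the training quota is met;
#' 4. all remaining points go to TEST.
#'
#' Ties are broken by the lowest row index, so the split is fully
#' deterministic; with no exact distance ties it is invariant to row
#' permutations.
#'
#' @param tbl A concentration tibble (`sample_id`, `class`, element
#'   columns), or a numeric matrix when `labels` and `ids` are given.
#' @param n_train_per_class Named integer vector of training quotas per
#'   class; each quota must satisfy `2 <= quota <= n_class - 1`.
#' @param labels,ids Class labels and sample ids when `tbl` is a matrix.
#' @param autoscale Autoscale (full-data statistics) before computing
#'   distances; default TRUE, matching standard practice for mixed-unit
#'   element profiles.
#' @return A `duplex_split` list: `train_ids`, `test_ids`,
#'   `per_class_counts` (tibble class/train/test), `assignment` (tibble
#'   sample_id/class/set).
#' @export
#' @examples
#' tbl <- sample_concentrations(pecorino_class_stats(), seed = 4)
#' sp <- duplex_split(tbl, c(PF = 9, PS = 12, PR = 9))
#' sp$per_class_counts
duplex_split <- function(tbl, n_train_per_class, labels = NULL, ids = NULL,
                         autoscale = TRUE) {
  if (is.data.frame(tbl)) {
    labels <- as.character(tbl$class)
    ids <- tbl$sample_id
    x <- as.matrix(tbl[setdiff(names(tbl), c("sample_id", "class"))])
  } else {
    x <- as.matrix(tbl)
    if (is.null(labels)) stop("`labels` required for matrix input", call. = FALSE)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  }
  if (autoscale) x <- autoscale_apply(autoscale_fit(x), x)

  classes <- unique(labels)
  if (is.null(names(n_train_per_class)) && length(n_train_per_class) == 1) {
    n_train_per_class <- stats::setNames(
      rep(n_train_per_class, length(classes)), classes)
  }
  missing_q <- setdiff(classes, names(n_train_per_class))
  if (length(missing_q) > 0) {
    stop("missing training quota for class(es): ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  }

  assign_class <- function(cl) {
    idx <- which(labels == cl)
    n <- length(idx)
    quota <- n_train_per_class[[cl]]
    if (quota < 2 || quota > n - 1) {
      stop("training quota for class ", cl, " must be in [2, ", n - 1, "]",
           call. = FALSE)
    }
    d <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
    remaining <- seq_len(n)
    train <- integer(0)
    test <- integer(0)

    # farthest pair of the remaining points, lowest indices on ties
    farthest_pair <- function(rem) {
      dd <- d[rem, rem, drop = FALSE]
      dd[lower.tri(dd, diag = TRUE)] <- -Inf
      best <- which(dd == max(dd), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
      c(rem[best[1, 1]], rem[best[1, 2]])
    }
    # remaining point with max min-distance to `set`, lowest index on ties
    maxmin_point <- function(rem, set) {
      mins <- apply(d[rem, set, drop = FALSE], 1, min)
      rem[which.max(mins)]
    }

    pr <- farthest_pair(remaining)
    train <- pr; remaining <- setdiff(remaining, pr)
    pr <- farthest_pair(remaining)
    test <- pr; remaining <- setdiff(remaining, pr)

    # the test set's implicit quota is the class remainder; once either
    # set is full the other takes every remaining point
    test_quota <- n - quota
    turn <- "train"
    while (length(remaining) > 0) {
      if (length(train) >= quota) {
        test <- c(test, remaining)
        remaining <- integer(0)
      } else if (length(test) >= test_quota) {
        p <- maxmin_point(remaining, train)
        train <- c(train, p); remaining <- setdiff(remaining, p)
      } else if (turn == "train") {
        p <- maxmin_point(remaining, train)
        train <- c(train, p); remaining <- setdiff(remaining, p)
        turn <- "test"
      } else {
        p <- maxmin_point(remaining, test)
        test <- c(test, p); remaining <- setdiff(remaining, p)
        turn <- "train"
      }
    }
    list(train = ids[idx[sort(train)]], test = ids[idx[sort(test)]])
  }

  parts <- lapply(classes, assign_class)
  names(parts) <- classes
  train_ids <- unlist(lapply(parts, `[[`, "train"), use.names = FALSE)
  test_ids <- unlist(lapply(parts, `[[`, "test"), use.names = FALSE)
  counts <- purrr::map_dfr(classes, function(cl) {
    tibble::tibble(class = cl,
                   train = length(parts[[cl]]$train),
                   test = length(parts[[cl]]$test))
  })
  assignment <- tibble::tibble(
    sample_id = ids,
    class = labels,
    set = ifelse(ids %in% train_ids, "train", "test"))
  structure(
    list(train_ids = train_ids, test_ids = test_ids,
         per_class_counts = counts, assignment = assignment,
         distance_metric = "euclidean"),
    class = "duplex_split")
}

#' @export
print.duplex_split <- function(x, ...) {
  cat("Duplex split:", length(x$train_ids), "train /",
      length(x$test_ids), "test\n")
  print(x$per_class_counts)
  invisible(x)
}
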