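#' Fit an autoscaler on training rows
#'
#' Stores per-column means and standard deviations (n - 1 denominator) of
#' the training matrix so that new rows can be centred and scaled with
#' the *training* statistics — the scaler fitted inside a
#' cross-validation fold never sees the held-out rows.
#'
#' @param x Numeric matrix or data frame of training rows (>= 2).
#' @param log10_first Apply a log10 transform before computing the
#'   statistics (and on every later application).
#' @return An `autoscaler` list: `means`, `sds`, `log10_applied`.
#' @export
autoscale_fit <- function(x, log10_first = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("autoscaling needs at least 2 rows", call. = FALSE)
  if (log10_first) x <- log10_transform(x)
  sds <- apply(x, 2, stats::sd)
  const <- which(sds == 0)
  if (length(const) > 0) {
    nm <- colnames(x)[const]
    if (is.null(nm)) nm <- as.character(const)
    stop("constant column(s) cannot be autoscaled: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  structure(list(means = colMeans(x), sds = sds, log10_applied = log10_first),
            class = "autoscaler")
}

#' Apply a fitted autoscaler
#' @param scaler An `autoscaler` from [autoscale_fit()].
#' @param x New rows with the same columns as the training matrix.
#' @return Scaled numeric matrix.
#' @export
autoscale_apply <- function(scaler, x) {
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !is.null(names(scaler$means))) {
    if (!all(names(scaler$means) %in% colnames(x))) {
      stop("new rows are missing column(s): ",
           paste(setdiff(names(scaler$means), colnames(x)), collapse = ", "),
           call. = FALSE)
    }
    x <- x[, names(scaler$means), drop = FALSE]
  }
  if (scaler$log10_applied) x <- log10_transform(x)
  scale(x, center = scaler$means, scale = scaler$sds)[, , drop = FALSE]
}

#' Invert an autoscaler
#' @param scaler An `autoscaler`.
#' @param x_scaled Scaled matrix.
#' @return Matrix on the original scale.
#' @export
autoscale_invert <- function(scaler, x_scaled) {
  x <- sweep(sweep(as.matrix(x_scaled), 2, scaler$sds, `*`),
             2, scaler$means, `+`)
  if (scaler$log10_applied) x <- 10^x
  x
}

#' Elementwise log10 transform
#'
#' @param x Numeric matrix or data frame; all entries must be strictly
#'   positive.
#' @return log10-transformed matrix.
#' @export
log10_transform <- function(x) {
  x <- as.matrix(x)
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    show <- utils::head(apply(bad, 1, paste, collapse = ","), 5)
    stop("log10 requires strictly positive entries; offending [row,col]: ",
         paste(show, collapse = "; "), call. = FALSE)
  }
  log10(x)
}

#' Principal component analysis of a scaled matrix
#'
#' Decomposes the (already centred/scaled) matrix as `X = T P' + E` with
#' orthonormal loadings `P`, mutually orthogonal scores `T` ordered by
#' decreasing explained variance, and residuals `E` from truncating at
#' `n_components`. Computed by singular value decomposition; each
#' component's sign is fixed by making its largest-magnitude loading
#' positive, so repeated runs are bit-identical.
#'
#' @param x_scaled Numeric matrix, typically from [autoscale_apply()].
#' @param n_components Number of components A, `<= min(S - 1, V)`.
#' @return A `pca_model` list: `scores` (S x A), `loadings` (V x A),
#'   `residuals` (S x V), `explained_variance` (fraction per component,
#'   over all min(S-1, V) components), `n_components`.
#' @export
pca_fit <- function(x_scaled, n_components = NULL) {
  x <- as.matrix(x_scaled)
  a_max <- min(nrow(x) - 1, ncol(x))
  if (is.null(n_components)) n_components <- a_max
  if (n_components < 1 || n_components > a_max) {
    stop("n_components must be between 1 and ", a_max, call. = FALSE)
  }
  sv <- svd(x)
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(ncol(sv$v)), function(a) {
    vcol <- sv$v[, a]
    sign(vcol[which.max(abs(vcol))])
  }, numeric(1))
  flip[flip == 0] <- 1
  v <- sweep(sv$v, 2, flip, `*`)
  u <- sweep(sv$u, 2, flip, `*`)
  eig <- sv$d^2
  expl <- eig / sum(eig)
  a <- n_components
  scores <- u[, seq_len(a), drop = FALSE] %*% diag(sv$d[seq_len(a)], a)
  loadings <- v[, seq_len(a), drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- colnames(scores) <- sprintf("PC%d", seq_len(a))
  rownames(scores) <- rownames(x)
  resid <- x - scores %*% t(loadings)
  structure(
    list(scores = scores, loadings = loadings, residuals = resid,
         explained_variance = expl[seq_len(a_max)],
         n_components = a, n_samples = nrow(x), n_variables = ncol(x)),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", x$n_samples, "samples x", x$n_variables, "variables,",
      x$n_components, "components\n")
  ev <- round(100 * x$explained_variance[seq_len(x$n_components)], 1)
  cat("Explained variance (%):", paste(ev, collapse = ", "), "\n")
  invisible(x)
}
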