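#' Binary classification metrics
#'
#' Accuracy, recall, precision and F1 with class 1 (diseased) as the positive
#' class, plus the 2x2 confusion table. F1 is defined as 0 when there are no
#' true positives.
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return An object of class `"metric_report"` with `accuracy`, `recall`,
#'   `precision`, `f1` and `confusion` (rows = truth, columns = prediction).
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty input", call. = FALSE)
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)))
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  confusion <- matrix(c(tn, fn, fp, tp), 2, 2,
                      dimnames = list(truth = c("0", "1"),
                                      predicted = c("0", "1")))
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (tp + tn) / length(y_true), recall = recall,
                 precision = precision, f1 = f1, confusion = confusion),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> accuracy %.4f, recall %.4f, precision %.4f, F1 %.4f\n",
    x$accuracy, x$recall, x$precision, x$f1))
  print(x$confusion)
  invisible(x)
}

#' SMOTE minority oversampling
#'
#' Oversamples the minority class up to the majority count: each synthetic
#' row is `x + u * (x_nn - x)` where `x` is a random minority row, `x_nn` one
#' of its `k_neighbors` nearest minority neighbours (Euclidean distance), and
#' `u ~ Uniform(0, 1)`. Original rows are returned unchanged, with the
#' synthetic rows appended. Missing cells are handled by minority-class mean
#' imputation for the distance and interpolation arithmetic, and a synthetic
#' row inherits the missingness pattern of its seed row.
#'
#' @param x Numeric matrix or data frame of feature rows.
#' @param y Binary labels (0/1), one per row.
#' @param k_neighbors Number of nearest neighbours to interpolate towards.
#' @param seed Integer seed.
#' @return A list with `x` (matrix), `y`, and `n_synthetic`.
#' @export
smote <- function(x, y, k_neighbors = 5, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  counts <- table(factor(y, levels = c(0, 1)))
  if (counts[1] == counts[2]) {
    return(list(x = x, y = y, n_synthetic = 0L))
  }
  min_lab <- as.numeric(names(which.min(counts)))
  n_min <- min(counts)
  n_new <- as.integer(abs(diff(counts)))
  if (n_min < k_neighbors + 1) {
    stop("minority class needs at least k_neighbors + 1 = ", k_neighbors + 1,
         " members (has ", n_min, ")", call. = FALSE)
  }
  xm <- x[y == min_lab, , drop = FALSE]
  xi <- xm
  if (anyNA(xi)) { # impute minority column means for geometry only
    mu <- colMeans(xi, na.rm = TRUE)
    mu[is.na(mu)] <- 0
    for (j in seq_len(ncol(xi))) xi[is.na(xi[, j]), j] <- mu[j]
  }
  D <- as.matrix(stats::dist(xi))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k_neighbors)]))

  set.seed(seed)
  base <- sample.int(n_min, n_new, replace = TRUE)
  pick <- sample.int(k_neighbors, n_new, replace = TRUE)
  u <- stats::runif(n_new)
  synth <- xi[base, , drop = FALSE] +
    (xi[nn[cbind(base, pick)], , drop = FALSE] - xi[base, , drop = FALSE]) * u
  synth[is.na(xm[base, , drop = FALSE])] <- NA # inherit seed-row missingness
  list(x = rbind(x, synth), y = c(y, rep(min_lab, n_new)),
       n_synthetic = n_new)
}

#' Stratified k-fold split
#'
#' Partitions `1:n` into `k` disjoint folds. With labels supplied, each class
#' is shuffled and dealt round-robin so fold class counts differ by at most
#' one from exact stratification. Deterministic given `seed`.
#'
#' @param n Number of samples.
#' @param k Number of folds (at least 2).
#' @param labels Optional label vector of length `n` for stratification.
#' @param seed Integer seed.
#' @return A list of `k` integer index vectors (the test folds).
#' @export
kfold_split <- function(n, k = 5, labels = NULL, seed = 1L) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("need at least k samples", call. = FALSE)
  set.seed(seed)
  folds <- vector("list", k)
  if (is.null(labels)) {
    idx <- sample.int(n)
    for (i in seq_len(k)) folds[[i]] <- sort(idx[seq(i, n, by = k)])
  } else {
    stopifnot(length(labels) == n)
    for (cls in unique(labels)) {
      ci <- which(labels == cls)
      if (length(ci) < k) {
        stop("class ", cls, " has fewer than k members", call. = FALSE)
      }
      ci <- ci[sample.int(length(ci))]
      for (i in seq_len(k)) {
        folds[[i]] <- c(folds[[i]], ci[seq(i, length(ci), by = k)])
      }
    }
    folds <- lapply(folds, sort)
  }
  folds
}
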