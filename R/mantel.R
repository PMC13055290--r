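#' Mantel permutation test between two distance matrices
#'
#' The Mantel statistic is the correlation (Spearman by default) between the
#' upper-triangle entries of two sample-matched distance matrices. The
#' permutation p-value relabels the rows and columns of the second matrix
#' jointly: `p = (1 + #{permuted r >= observed r}) / (1 + n_perm)` for the
#' default one-sided (positive association) test, so the smallest attainable
#' p is `1/(n_perm + 1)`.
#'
#' @param d1,d2 square symmetric distance matrices with matching sample
#'   labels (or `dist` objects); >= 4 samples.
#' @param n_perm number of permutations (default 999).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param seed RNG seed for a reproducible permutation stream.
#' @return Object of class `mantel_result`: `r`, `p`, `n_perm`, `method`,
#'   `alternative`, `n_samples`. Has a `glance()` method.
#' @export
mantel_test <- function(d1, d2, n_perm = 999,
                        method = c("spearman", "pearson"),
                        alternative = c("greater", "less", "two.sided"),
                        seed = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  m1 <- as_distance_matrix(d1)
  m2 <- as_distance_matrix(d2)
  n <- nrow(m1)
  if (n < 4) abort("Mantel test needs at least 4 samples")
  if (!identical(dim(m1), dim(m2))) abort("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) abort("distance matrix labels do not match")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  ut <- which(upper.tri(m1))
  v1 <- m1[ut]; v2 <- m2[ut]
  if (method == "spearman") {
    # rank within the distinct pair values; joint label permutation only
    # rearranges the same multiset, so ranks placed back into the matrix
    # make every permuted statistic a plain Pearson correlation of ranks
    v1 <- rank(v1); m2r <- m2; m2r[upper.tri(m2r)] <- rank(v2)
    m2r[lower.tri(m2r)] <- t(m2r)[lower.tri(m2r)]
    m2 <- m2r; v2 <- m2[ut]
  }
  r_obs <- cor(v1, v2)
  if (!is.null(seed)) set.seed(seed)
  iu <- row(m1)[ut]; ju <- col(m1)[ut]
  r_perm <- vapply(seq_len(n_perm), function(k) {
    pr <- sample.int(n)
    cor(v1, m2[cbind(pr[iu], pr[ju])])
  }, numeric(1))
  p <- switch(alternative,
    greater = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
    less = (1 + sum(r_perm <= r_obs)) / (1 + n_perm),
    two.sided = (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  )
  structure(list(r = r_obs, p = p, n_perm = n_perm, method = method,
                 alternative = alternative, n_samples = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$method, x$alternative, x$r, x$p, x$n_perm, x$n_samples))
  invisible(x)
}

#' @rdname mantel_test
#' @param x a `mantel_result`.
#' @param ... unused.
#' @method glance mantel_result
#' @export
glance.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n_perm = x$n_perm, method = x$method,
                 alternative = x$alternative, n_samples = x$n_samples)
}

#' Euclidean distance on standardised soil properties
#'
#' Z-scores each numeric soil variable then takes Euclidean distances
#' between samples. Zero-variance variables are dropped with a warning;
#' missing values are handled pairwise (distances rescaled to the number of
#' complete variable pairs) and flagged.
#'
#' @param soil data frame with a `sample_id` column and numeric soil
#'   property columns.
#' @param variables variables to use; default all numeric columns.
#' @return Symmetric labelled distance matrix.
#' @export
property_distance <- function(soil, variables = NULL) {
  if (!"sample_id" %in% names(soil)) abort("soil table needs a `sample_id` column")
  num <- names(soil)[vapply(soil, is.numeric, logical(1))]
  variables <- variables %||% num
  miss <- setdiff(variables, names(soil))
  if (length(miss)) abort(paste0("missing soil variable(s): ", paste(miss, collapse = ", ")))
  x <- as.matrix(soil[variables])
  rownames(x) <- as.character(soil$sample_id)
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) abort(paste0("all-missing variable(s): ", paste(variables[all_na], collapse = ", ")))
  v <- apply(x, 2, var, na.rm = TRUE)
  if (any(v == 0)) {
    warn(paste0("dropping zero-variance variable(s): ",
                paste(colnames(x)[v == 0], collapse = ", ")))
    x <- x[, v > 0, drop = FALSE]
  }
  z <- scale(x)
  n <- nrow(z); k <- ncol(z)
  d <- matrix(0, n, n, dimnames = list(rownames(z), rownames(z)))
  had_missing <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(z[i, ]) & !is.na(z[j, ])
    if (!any(ok)) abort("a sample pair shares no observed variables")
    if (sum(ok) < k) had_missing <- TRUE
    d[i, j] <- d[j, i] <- sqrt(sum((z[i, ok] - z[j, ok])^2) * k / sum(ok))
  }
  attr(d, "pairwise_missing") <- had_missing
  d
}
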