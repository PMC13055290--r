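#' @importFrom rlang .data abort warn .env
#' @importFrom stats aov coef cor lm median optim p.adjust pbeta pt qnorm
#'   quantile rbinom rlnorm rmultinom rnorm rpois runif sd setNames TukeyHSD
#'   var dist complete.cases
#' @importFrom utils combn head modifyList
NULL

# Coerce a samples-by-ASVs count table (wide tibble with `sample_id` first
# column, or a numeric matrix with sample rownames) to a numeric matrix.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  } else if (is.data.frame(counts)) {
    if (!"sample_id" %in% names(counts)) {
      abort("count table must have a `sample_id` column (or be a matrix with sample rownames)")
    }
    ids <- as.character(counts$sample_id)
    m <- as.matrix(counts[setdiff(names(counts), "sample_id")])
    rownames(m) <- ids
  } else {
    abort("counts must be a data frame or matrix (samples x ASVs)")
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("count table contains missing values")
  if (any(m < 0)) abort("count table contains negative values")
  if (anyDuplicated(rownames(m))) abort("sample ids must be unique")
  m
}

count_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "sample_id")
}

# Symmetric distance matrix with labels from a dist or matrix.
as_distance_matrix <- function(d) {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) abort("distance matrix must be symmetric")
  diag(m) <- 0
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x
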