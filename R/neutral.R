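#' Per-ASV occurrence statistics
#'
#' For each ASV: `p`, its mean relative abundance across samples (the
#' regional abundance), and `freq`, the fraction of samples where it is
#' detected (>= 1 read). ASVs absent everywhere are excluded.
#'
#' @param counts samples-by-ASVs count tibble or matrix; >= 2 samples.
#' @return Tibble `asv_id`, `p`, `freq`, sorted by `p`.
#' @export
occurrence_stats <- function(counts) {
  m <- as_count_matrix(counts)
  if (nrow(m) < 2) abort("need at least 2 samples")
  rel <- rel_matrix(m)
  p <- colMeans(rel)
  freq <- colMeans(m > 0)
  keep <- p > 0
  tibble::tibble(asv_id = colnames(m)[keep], p = unname(p[keep]),
                 freq = unname(freq[keep])) |>
    dplyr::arrange(.data$p)
}

#' Sloan neutral-model occurrence frequency
#'
#' Under the neutral community model, local relative abundances of a taxon
#' with regional abundance `p` follow Beta(Nm p, Nm (1 - p)); the expected
#' occurrence frequency is the probability of exceeding the detection limit
#' `d`: `1 - pbeta(d, Nm p, Nm (1 - p))`. Non-decreasing in `p`.
#'
#' @param p regional mean relative abundance, in (0, 1) (vectorised).
#' @param Nm metacommunity size times immigration rate, > 0.
#' @param d detection limit, in (0, 1); conventionally one read at mean
#'   sequencing depth.
#' @return Predicted occurrence frequency in \[0, 1\].
#' @export
ncm_predict <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) abort("p must lie strictly between 0 and 1")
  if (Nm <= 0) abort("Nm must be positive")
  if (d <= 0 || d >= 1) abort("detection limit d must lie strictly between 0 and 1")
  1 - pbeta(d, Nm * p, Nm * (1 - p))
}

# Detection probability of a taxon with regional abundance p.
# "beta_cdf": classical Sloan threshold approximation P(w > d).
# "beta_binomial": exact P(>= 1 read among N) when local proportions are
# Beta(Nm p, Nm (1-p)) and reads are sampled from them - the zero-truncation
# probability 1 - B(a, b + N)/B(a, b).
ncm_detect <- function(p, Nm, d, N, model = "beta_binomial") {
  a <- Nm * p
  b <- Nm * (1 - p)
  if (model == "beta_cdf") 1 - pbeta(d, a, b)
  else 1 - exp(lbeta(a, b + round(N)) - lbeta(a, b))
}

fit_Nm <- function(p, freq, d, N, model = "beta_binomial",
                   starts = c(1, 3, 5), lower = 0, upper = 7) {
  obj <- function(l) sum((freq - ncm_detect(p, 10^l, d, N, model))^2)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) abort("neutral-model fit failed")
  10^best$par
}

#' Fit the Sloan neutral community model
#'
#' Estimates `Nm` by bounded nonlinear least squares of observed occurrence
#' frequency against the neutral detection curve (log10(Nm) in \[0, 7\],
#' three log-spaced starts), on untransformed frequencies. `m = Nm / N`
#' where `N` is the community size (mean reads per sample by default) and
#' the detection limit defaults to `d = 1/N`. Fit quality is
#' `R^2 = 1 - SSE/SST` on frequencies (may be negative).
#'
#' Two detection curves are available. `"beta_binomial"` (default) is the
#' exact probability of observing at least one read among N when local
#' proportions follow Beta(Nm p, Nm (1 - p)): `1 - B(a, b + N)/B(a, b)`.
#' It accounts for the read-sampling layer of amplicon data and recovers
#' planted immigration rates essentially unbiasedly. `"beta_cdf"` is the
#' classical Sloan threshold approximation `1 - BetaCDF(d; a, b)` (see
#' [ncm_predict()]), which ignores read sampling and overestimates Nm when
#' dispersal is strong.
#'
#' @param counts samples-by-ASVs count tibble or matrix.
#' @param d detection limit; default `1/N`.
#' @param N_stat `"mean"` (default) or `"median"` reads per sample.
#' @param detection_model `"beta_binomial"` (default) or `"beta_cdf"`.
#' @return Object of class `ncm_fit`: estimates `Nm`, `m`, `N`, `d`, `R2`,
#'   `n_samples`, and `stats`, the per-ASV tibble (`asv_id`, `p`, `freq`,
#'   `pred`, `partition`) with neutral-partition labels from
#'   [ncm_partition()]. Has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
ncm_fit <- function(counts, d = NULL, N_stat = c("mean", "median"),
                    detection_model = c("beta_binomial", "beta_cdf")) {
  N_stat <- match.arg(N_stat)
  detection_model <- match.arg(detection_model)
  m <- as_count_matrix(counts)
  st <- occurrence_stats(m)
  N <- if (N_stat == "mean") mean(rowSums(m)) else median(rowSums(m))
  d <- d %||% (1 / N)
  fitable <- st$p > 0 & st$p < 1
  if (sum(fitable) < 2) abort("too few ASVs with interior regional abundance to fit")
  if (var(st$freq) == 0) abort("neutral-model fit failed: occurrence frequencies have no variance")
  Nm <- fit_Nm(st$p[fitable], st$freq[fitable], d, N, detection_model)
  pred <- rep(NA_real_, nrow(st))
  pred[fitable] <- ncm_detect(st$p[fitable], Nm, d, N, detection_model)
  sse <- sum((st$freq[fitable] - pred[fitable])^2)
  sst <- sum((st$freq[fitable] - mean(st$freq[fitable]))^2)
  fit <- structure(list(
    Nm = Nm, N = N, m = Nm / N, d = d, R2 = 1 - sse / sst,
    n_samples = nrow(m), detection_model = detection_model,
    stats = dplyr::mutate(st, pred = pred)
  ), class = "ncm_fit")
  fit$stats$partition <- ncm_partition(fit)$partition
  fit
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  N = %.1f reads/sample, d = %.3g\n", x$N, x$d))
  cat(sprintf("  Nm = %.1f, m = %.4g, R2 = %.3f\n", x$Nm, x$m, x$R2))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% bootstrap CI (m): %.4g - %.4g (%d reps)\n",
                x$ci["m", "low"], x$ci["m", "high"], x$boot_reps))
  }
  cat("  partition:", paste(names(table(x$stats$partition)),
                            table(x$stats$partition), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname ncm_fit
#' @param x an `ncm_fit`.
#' @param ... unused.
#' @method tidy ncm_fit
#' @export
tidy.ncm_fit <- function(x, ...) x$stats

#' @rdname ncm_fit
#' @method glance ncm_fit
#' @export
glance.ncm_fit <- function(x, ...) {
  out <- tibble::tibble(Nm = x$Nm, m = x$m, N = x$N, d = x$d, R2 = x$R2,
                        n_asvs = nrow(x$stats), n_samples = x$n_samples)
  if (!is.null(x$ci)) {
    out$Nm_low <- x$ci["Nm", "low"]; out$Nm_high <- x$ci["Nm", "high"]
    out$m_low <- x$ci["m", "low"]; out$m_high <- x$ci["m", "high"]
    out$R2_low <- x$ci["R2", "low"]; out$R2_high <- x$ci["R2", "high"]
  }
  out
}

#' Bootstrap confidence intervals for a neutral-model fit
#'
#' Resamples ASVs (the fitting unit) with replacement, refits per replicate,
#' and takes percentile 2.5/97.5 bounds for `Nm`, `m` and `R2`. Deterministic
#' under a fixed seed; a warning is recorded if more than 20% of replicate
#' fits fail.
#'
#' @param fit an [ncm_fit()] result.
#' @param reps bootstrap replicates (1000 in typical use).
#' @param seed RNG seed.
#' @return The fit with `ci` (matrix rows Nm, m, R2), `boot_reps`,
#'   `boot_failures` added.
#' @export
ncm_bootstrap <- function(fit, reps = 1000, seed = NULL) {
  stopifnot(inherits(fit, "ncm_fit"), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  st <- dplyr::filter(fit$stats, .data$p > 0, .data$p < 1)
  n <- nrow(st)
  start <- log10(fit$Nm)
  draws <- matrix(NA_real_, nrow = reps, ncol = 3,
                  dimnames = list(NULL, c("Nm", "m", "R2")))
  fails <- 0L
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- st$p[idx]; fr <- st$freq[idx]
    res <- tryCatch({
      if (var(fr) == 0) stop("degenerate resample")
      Nm <- fit_Nm(p, fr, fit$d, fit$N, fit$detection_model, starts = start)
      pred <- ncm_detect(p, Nm, fit$d, fit$N, fit$detection_model)
      sse <- sum((fr - pred)^2); sst <- sum((fr - mean(fr))^2)
      c(Nm, Nm / fit$N, 1 - sse / sst)
    }, error = function(e) NULL)
    if (is.null(res)) fails <- fails + 1L else draws[b, ] <- res
  }
  if (fails > 0.2 * reps) {
    warn(sprintf("%d of %d bootstrap replicate fits failed", fails, reps))
  }
  fit$ci <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  colnames(fit$ci) <- c("low", "high")
  fit$boot_reps <- reps
  fit$boot_failures <- fails
  fit
}

#' Neutral-partition labels for each ASV
#'
#' Compares each observed occurrence frequency to a Wilson binomial
#' confidence band (at `ci_level`, with n = number of samples) around the
#' model prediction: `above` (more frequent than neutral expectation),
#' `below`, or `neutral`.
#'
#' @param fit an [ncm_fit()] result.
#' @param ci_level confidence level of the band (default 0.95).
#' @return Tibble `asv_id`, `partition`.
#' @export
ncm_partition <- function(fit, ci_level = 0.95) {
  stopifnot(inherits(fit, "ncm_fit"))
  st <- fit$stats
  z <- qnorm(1 - (1 - ci_level) / 2)
  n <- fit$n_samples
  wilson <- function(phat) {
    centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    cbind(lo = centre - half, hi = centre + half)
  }
  lab <- rep("neutral", nrow(st))
  ok <- !is.na(st$pred)
  b <- wilson(st$pred[ok])
  lab[ok][st$freq[ok] > b[, "hi"]] <- "above"
  lab[ok][st$freq[ok] < b[, "lo"]] <- "below"
  tibble::tibble(asv_id = st$asv_id, partition = lab)
}
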