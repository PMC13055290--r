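#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(template copies) over a dilution
#' series (instrument convention: negative slope, ideally -3.32 per decade).
#' Amplification efficiency is `E = 10^(-1/slope) - 1`; curves at or below
#' 90% efficiency are flagged, mirroring common acceptance practice for soil
#' gene quantification.
#'
#' @param log10_copies log10 template copy numbers of the standards
#'   (e.g. 2:6 for a 10^2-10^6 plasmid gradient).
#' @param cq quantification cycles, one per standard.
#' @param min_efficiency flag threshold as a fraction (default 0.9).
#' @return Object of class `std_curve`: `slope`, `intercept`, `r2`,
#'   `efficiency` (fraction), `efficiency_ok`.
#' @export
fit_standard_curve <- function(log10_copies, cq, min_efficiency = 0.9) {
  if (length(unique(log10_copies)) < 3) abort("need at least 3 distinct dilution levels")
  if (length(log10_copies) != length(cq)) abort("dilutions and Cq differ in length")
  fit <- lm(cq ~ log10_copies)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= -1e-8) {
    abort("invalid standard curve: Cq must decrease with template amount (slope < 0)")
  }
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
  eff <- 10^(-1 / slope) - 1
  structure(list(slope = slope, intercept = unname(coef(fit)[1]), r2 = r2,
                 efficiency = eff, efficiency_ok = eff > min_efficiency,
                 min_efficiency = min_efficiency),
            class = "std_curve")
}

#' @export
print.std_curve <- function(x, ...) {
  cat("qPCR standard curve: slope", signif(x$slope, 5),
      " intercept", signif(x$intercept, 5),
      " R2", signif(x$r2, 5), "\n")
  cat("Amplification efficiency:", sprintf("%.1f%%", 100 * x$efficiency),
      if (x$efficiency_ok) "" else sprintf("(FLAG: <= %.0f%%)", 100 * x$min_efficiency), "\n")
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x a `std_curve`.
#' @param ... unused.
#' @method glance std_curve
#' @export
glance.std_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 efficiency_pct = 100 * x$efficiency, efficiency_ok = x$efficiency_ok)
}

#' Fit one standard curve per gene from a standards table
#'
#' @param standards data frame with columns `gene`, `log10_copies`, `cq`.
#' @inheritParams fit_standard_curve
#' @return Named list of `std_curve` objects, one per gene.
#' @export
fit_standard_curves <- function(standards, min_efficiency = 0.9) {
  need <- c("gene", "log10_copies", "cq")
  miss <- setdiff(need, names(standards))
  if (length(miss)) abort(paste0("standards table missing columns: ", paste(miss, collapse = ", ")))
  standards |>
    split(standards$gene) |>
    lapply(function(d) fit_standard_curve(d$log10_copies, d$cq, min_efficiency))
}

#' Absolute gene copy quantification from Cq values
#'
#' Technical replicates are averaged on the Cq scale, then
#' `copies = 10^((Cq - intercept) / slope) x dilution_factor x yield`, giving
#' copies per g dry soil when `yield` is the DNA-extract-to-dry-soil scaling.
#' Non-detects (missing Cq) stay missing; they are never imputed as zero.
#'
#' @param samples data frame with `sample_id`, `gene`, `cq` and optionally
#'   `rep` and `dilution_factor` columns.
#' @param curves named list of `std_curve` objects (per gene), from
#'   [fit_standard_curves()].
#' @param dilution_factor default dilution factor where the table has none.
#' @param yield_per_g_dry_soil normalisation from reaction template to per-g
#'   dry soil (e.g. extract volume / template volume / dry mass), > 0.
#' @return Tibble: `sample_id`, `gene`, `mean_cq`, `copies_per_g_dry_soil`,
#'   `qc_efficiency_ok`.
#' @export
quantify_copies <- function(samples, curves, dilution_factor = 1,
                            yield_per_g_dry_soil = 1) {
  if (yield_per_g_dry_soil <= 0) abort("dry-mass normalisation factor must be positive")
  need <- c("sample_id", "gene", "cq")
  miss <- setdiff(need, names(samples))
  if (length(miss)) abort(paste0("sample table missing columns: ", paste(miss, collapse = ", ")))
  if (!"dilution_factor" %in% names(samples)) samples$dilution_factor <- dilution_factor
  unknown <- setdiff(unique(samples$gene), names(curves))
  if (length(unknown)) abort(paste0("no standard curve for gene(s): ", paste(unknown, collapse = ", ")))
  samples |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(mean_cq = mean(.data$cq, na.rm = TRUE),
                     dilution_factor = .data$dilution_factor[1],
                     .groups = "drop") |>
    dplyr::mutate(
      mean_cq = ifelse(is.nan(.data$mean_cq), NA_real_, .data$mean_cq),
      copies_per_g_dry_soil = purrr::map2_dbl(.data$gene, .data$mean_cq, function(gn, cq) {
        cv <- curves[[gn]]
        if (is.na(cq)) return(NA_real_)
        10^((cq - cv$intercept) / cv$slope)
      }) * .data$dilution_factor * yield_per_g_dry_soil,
      qc_efficiency_ok = purrr::map_lgl(.data$gene, function(gn) curves[[gn]]$efficiency_ok)
    ) |>
    dplyr::select(-"dilution_factor")
}

#' Per-sample copy-number ratio of two genes
#'
#' Ratio of numerator to denominator copies within each sample (e.g.
#' mcrA/pmoA as a CH4 production-vs-oxidation potential proxy). Group means
#' are means of per-sample ratios, not ratios of means.
#'
#' @param quants tibble from [quantify_copies()].
#' @param numerator,denominator gene names.
#' @return Tibble `sample_id`, `ratio`; samples with a missing or zero
#'   denominator are dropped (zero denominator with an error).
#' @export
gene_ratio <- function(quants, numerator, denominator) {
  w <- quants |>
    dplyr::filter(.data$gene %in% c(numerator, denominator)) |>
    dplyr::select("sample_id", "gene", "copies_per_g_dry_soil") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "copies_per_g_dry_soil")
  for (g in c(numerator, denominator)) if (!g %in% names(w)) {
    abort(paste0("no quantifications for gene `", g, "`"))
  }
  w <- dplyr::filter(w, !is.na(.data[[numerator]]), !is.na(.data[[denominator]]))
  if (any(w[[denominator]] == 0)) abort("undefined ratio: zero denominator copies")
  tibble::tibble(sample_id = w$sample_id,
                 ratio = w[[numerator]] / w[[denominator]])
}

#' Gene abundance relative to the 16S rRNA gene
#'
#' @param quants tibble from [quantify_copies()].
#' @param gene target gene name.
#' @param ssu name of the 16S quantification (default `"16S"`).
#' @return Tibble `sample_id`, `relative_abundance` (gene copies / 16S copies).
#' @export
relative_gene_abundance <- function(quants, gene, ssu = "16S") {
  r <- gene_ratio(quants, gene, ssu)
  dplyr::rename(r, relative_abundance = "ratio")
}
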