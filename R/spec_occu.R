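#' Habitat specificity of each ASV
#'
#' Specificity of ASV S for habitat H is the mean relative abundance of S in
#' H's samples divided by the sum of those habitat means over all habitats,
#' so each ASV's specificities sum to 1. The default aggregation is mean of
#' per-sample proportions; `aggregation = "pooled"` instead pools counts
#' within a habitat before normalising.
#'
#' @param counts samples-by-ASVs count tibble or matrix.
#' @param habitat habitat label per sample (named by sample id, or in row
#'   order); >= 2 habitats.
#' @param aggregation `"mean"` (default) or `"pooled"`.
#' @return ASVs-by-habitats matrix of specificities; rows sum to 1. ASVs
#'   absent from every habitat get NA rows.
#' @export
specificity <- function(counts, habitat, aggregation = c("mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  m <- as_count_matrix(counts)
  habitat <- align_labels(habitat, rownames(m))
  lv <- unique(habitat)
  if (length(lv) < 2) abort("need at least 2 habitats")
  hab_mean <- vapply(lv, function(h) {
    sub <- m[habitat == h, , drop = FALSE]
    if (nrow(sub) == 0) abort(paste0("habitat with no samples: ", h))
    if (aggregation == "mean") colMeans(rel_matrix(sub)) else colSums(sub) / sum(sub)
  }, numeric(ncol(m)))
  hab_mean <- matrix(hab_mean, ncol = length(lv), dimnames = list(colnames(m), lv))
  tot <- rowSums(hab_mean)
  out <- hab_mean / tot
  out[tot == 0, ] <- NA_real_
  out
}

#' Habitat occupancy of each ASV
#'
#' Occupancy of ASV S in habitat H is the fraction of H's samples in which S
#' is detected (at least `detection` reads).
#'
#' @inheritParams specificity
#' @param detection minimum read count for "present" (default 1).
#' @return ASVs-by-habitats matrix of occupancies in \[0, 1\].
#' @export
occupancy <- function(counts, habitat, detection = 1) {
  m <- as_count_matrix(counts)
  habitat <- align_labels(habitat, rownames(m))
  lv <- unique(habitat)
  if (length(lv) < 2) abort("need at least 2 habitats")
  occ <- vapply(lv, function(h) {
    sub <- m[habitat == h, , drop = FALSE]
    if (nrow(sub) == 0) abort(paste0("habitat with no samples: ", h))
    colMeans(sub >= detection)
  }, numeric(ncol(m)))
  matrix(occ, ncol = length(lv), dimnames = list(colnames(m), lv))
}

#' Call habitat specialists from specificity and occupancy
#'
#' An ASV is a specialist of habitat H when both its specificity for H and
#' its occupancy in H are at or above the threshold (inclusive comparison at
#' exactly 0.7 by default). With a threshold above 0.5 an ASV can specialise
#' in at most one habitat because specificities sum to 1.
#'
#' @param spec,occ matched ASVs-by-habitats matrices from [specificity()]
#'   and [occupancy()].
#' @param threshold specialist threshold applied to both scores.
#' @return Long tibble: `asv_id`, `habitat`, `specificity`, `occupancy`,
#'   `specialist`.
#' @export
call_specialists <- function(spec, occ, threshold = 0.7) {
  if (!identical(dimnames(spec), dimnames(occ))) {
    abort("specificity and occupancy matrices must share ASVs and habitats")
  }
  tibble::tibble(
    asv_id = rep(rownames(spec), times = ncol(spec)),
    habitat = rep(colnames(spec), each = nrow(spec)),
    specificity = as.vector(spec),
    occupancy = as.vector(occ)
  ) |>
    dplyr::mutate(specialist = !is.na(.data$specificity) &
                    .data$specificity >= threshold & .data$occupancy >= threshold)
}

#' One-call SPEC-OCCU scoring
#'
#' Convenience wrapper computing [specificity()], [occupancy()] and
#' [call_specialists()] in one step.
#'
#' @inheritParams specificity
#' @inheritParams occupancy
#' @inheritParams call_specialists
#' @return See [call_specialists()].
#' @export
spec_occu <- function(counts, habitat, threshold = 0.7, detection = 1,
                      aggregation = c("mean", "pooled")) {
  call_specialists(
    specificity(counts, habitat, aggregation = aggregation),
    occupancy(counts, habitat, detection = detection),
    threshold = threshold
  )
}

#' SPEC-OCCU scatter plot
#'
#' Specificity vs occupancy per ASV and habitat with the specialist
#' thresholds drawn as reference lines.
#'
#' @param scores tibble from [spec_occu()] / [call_specialists()].
#' @param threshold threshold lines to draw.
#' @return A ggplot object.
#' @export
plot_spec_occu <- function(scores, threshold = 0.7) {
  ggplot2::ggplot(dplyr::filter(scores, !is.na(.data$specificity)),
                  ggplot2::aes(x = .data$occupancy, y = .data$specificity,
                               colour = .data$specialist)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::facet_wrap(~habitat) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Occupancy", y = "Specificity", colour = "Specialist") +
    ggplot2::theme_bw()
}
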