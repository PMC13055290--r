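#' Read an ASV count table
#'
#' Reads the common "ASVs as rows" TSV layout (first column ASV ids, one
#' column per sample) or a BIOM file, returning the package-wide wide layout:
#' a tibble with a `sample_id` column followed by one numeric column per ASV.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"` (requires the biomformat package).
#' @return Samples-by-ASVs count tibble.
#' @export
read_asv_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM requires the biomformat package")
    }
    m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
    return(count_tibble(t(m)))
  }
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[-1])
  rownames(m) <- as.character(d[[1]])
  count_tibble(t(m))
}

#' Drop singleton ASVs
#'
#' Removes ASVs whose total count across all samples is exactly one, the
#' standard denoising-pipeline filter applied at ingest.
#'
#' @param counts samples-by-ASVs count tibble or matrix.
#' @return Filtered count tibble.
#' @export
filter_singletons <- function(counts) {
  m <- as_count_matrix(counts)
  count_tibble(m[, colSums(m) != 1, drop = FALSE])
}

#' Relative abundance per sample
#'
#' Divides each sample (row) by its total so rows sum to one. Idempotent.
#'
#' @param counts samples-by-ASVs count tibble or matrix.
#' @return Relative-abundance tibble, rows summing to 1.
#' @export
to_relative <- function(counts) {
  m <- as_count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(paste0("empty sample(s): ", paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  count_tibble(m / tot)
}

rel_matrix <- function(counts) {
  m <- as_count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) abort(paste0("empty sample(s): ", paste(rownames(m)[tot == 0], collapse = ", ")))
  m / tot
}

#' Aggregate relative abundances to a taxonomic rank
#'
#' Pools ASV relative abundances by lineage at the requested rank; ASVs
#' without a taxonomy entry (or unclassified at that rank) pool into
#' `"unclassified"`. Per-sample sums are preserved.
#'
#' @param counts samples-by-ASVs count tibble or matrix.
#' @param taxonomy data frame with `asv_id` and either a semicolon-separated
#'   `lineage` column (phylum;class;order;family;genus) or one column per rank.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return Tibble: `sample_id`, `taxon`, `relative_abundance`.
#' @export
aggregate_taxonomy <- function(counts, taxonomy, rank = "phylum") {
  ranks <- c("phylum", "class", "order", "family", "genus")
  if (!rank %in% ranks) abort(paste0("unknown rank `", rank, "`"))
  rel <- rel_matrix(counts)
  if (!"asv_id" %in% names(taxonomy)) abort("taxonomy needs an `asv_id` column")
  if ("lineage" %in% names(taxonomy)) {
    parts <- strsplit(as.character(taxonomy$lineage), ";", fixed = TRUE)
    lev <- match(rank, ranks)
    tax <- vapply(parts, function(p) {
      v <- trimws(p)
      if (length(v) >= lev && nzchar(v[lev])) v[lev] else "unclassified"
    }, character(1))
  } else if (rank %in% names(taxonomy)) {
    tax <- as.character(taxonomy[[rank]])
    tax[is.na(tax) | !nzchar(tax)] <- "unclassified"
  } else {
    abort("taxonomy needs a `lineage` column or per-rank columns")
  }
  map <- setNames(tax, taxonomy$asv_id)
  lab <- unname(map[colnames(rel)])
  lab[is.na(lab)] <- "unclassified"
  agg <- t(rowsum(t(rel), group = lab))
  tibble::as_tibble(agg, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "taxon",
                        values_to = "relative_abundance")
}

#' Per-sample alpha diversity
#'
#' Richness (ASVs with >= 1 read), Shannon index (natural log) and Simpson
#' index (1 - sum p^2), computed with vegan.
#'
#' @param counts samples-by-ASVs count tibble or matrix.
#' @param metrics subset of `c("richness", "shannon", "simpson")`.
#' @return Tibble with `sample_id` and one column per metric.
#' @export
alpha_diversity <- function(counts, metrics = c("richness", "shannon", "simpson")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  m <- as_count_matrix(counts)
  out <- tibble::tibble(sample_id = rownames(m))
  if ("richness" %in% metrics) out$richness <- unname(rowSums(m > 0))
  if ("shannon" %in% metrics) out$shannon <- unname(vegan::diversity(m, index = "shannon"))
  if ("simpson" %in% metrics) out$simpson <- unname(vegan::diversity(m, index = "simpson"))
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = 1 - 2 sum min(x_i, x_j) / (sum x_i + sum x_j)` on counts,
#' computed with vegan::vegdist.
#'
#' @param counts samples-by-ASVs count tibble or matrix; >= 2 samples.
#' @return Symmetric labelled distance matrix with zero diagonal.
#' @export
bray_curtis <- function(counts) {
  m <- as_count_matrix(counts)
  if (nrow(m) < 2) abort("need at least 2 samples")
  if (any(rowSums(m) == 0)) {
    abort(paste0("empty sample(s): ", paste(rownames(m)[rowSums(m) == 0], collapse = ", ")))
  }
  as_distance_matrix(vegan::vegdist(m, method = "bray"))
}

#' Core-ASV Venn region counts across sample groups
#'
#' An ASV is "present" in a group when detected (>= 1 read) in at least one
#' of the group's samples (`presence_rule = "any"`) or in all of them
#' (`"all"`). Every Venn region is counted; the full intersection is the
#' shared "core".
#'
#' @param counts samples-by-ASVs count tibble or matrix.
#' @param groups group label per sample (named by sample id, or in row order).
#' @param presence_rule `"any"` (default) or `"all"`.
#' @return Tibble: `region` (ampersand-joined group names), `n_groups`,
#'   `n_asvs`; the row with all groups is the core. Regions sum to the union
#'   of detected ASVs.
#' @export
core_asvs <- function(counts, groups, presence_rule = c("any", "all")) {
  presence_rule <- match.arg(presence_rule)
  m <- as_count_matrix(counts)
  groups <- align_labels(groups, rownames(m))
  lv <- unique(groups)
  if (length(lv) < 2) abort("need at least 2 groups")
  pres <- vapply(lv, function(g) {
    sub <- m[groups == g, , drop = FALSE] > 0
    if (presence_rule == "any") apply(sub, 2, any) else apply(sub, 2, all)
  }, logical(ncol(m)))
  pres <- matrix(pres, ncol = length(lv), dimnames = list(colnames(m), lv))
  pres <- pres[rowSums(pres) > 0, , drop = FALSE]
  key <- apply(pres, 1, function(r) paste(lv[r], collapse = " & "))
  combos <- unlist(lapply(seq_along(lv), function(k) {
    apply(combn(lv, k), 2, paste, collapse = " & ")
  }))
  cnt <- table(factor(key, levels = combos))
  tibble::tibble(region = names(cnt),
                 n_groups = lengths(strsplit(names(cnt), " & ", fixed = TRUE)),
                 n_asvs = as.integer(cnt))
}

align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    miss <- setdiff(sample_ids, names(labels))
    if (length(miss)) abort(paste0("samples without a label: ", paste(miss, collapse = ", ")))
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    abort("labels must be named by sample id or match the number of samples")
  }
  as.character(labels)
}

#' Rarefy counts to a common depth
#'
#' Optional even-depth subsampling (without replacement) for diversity
#' comparisons; off by default throughout the pipeline.
#'
#' @param counts samples-by-ASVs count tibble or matrix.
#' @param depth target depth (default the minimum sample total).
#' @param seed RNG seed for reproducibility.
#' @return Rarefied count tibble.
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = NULL) {
  m <- as_count_matrix(counts)
  depth <- depth %||% min(rowSums(m))
  if (any(rowSums(m) < depth)) abort("a sample has fewer reads than the target depth")
  if (!is.null(seed)) set.seed(seed)
  out <- t(apply(m, 1, function(x) {
    picked <- sample(rep.int(seq_along(x), x), depth)
    tabulate(picked, nbins = length(x))
  }))
  dimnames(out) <- dimnames(m)
  count_tibble(out)
}
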