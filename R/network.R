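#' Pairwise ASV correlation matrix
#'
#' Spearman (default) or Pearson correlations between ASV abundance profiles
#' across samples, after a prevalence filter. Two-sided p-values use the
#' t approximation `t = r sqrt((n-2)/(1-r^2))` on n - 2 degrees of freedom
#' (ranks with average ties for Spearman). Constant ASV profiles have
#' undefined correlations and are masked as NA.
#'
#' @param counts samples-by-ASVs count tibble or matrix; >= 4 samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param prevalence_min keep ASVs detected in at least this fraction of
#'   samples (default 0.5); set 0 to keep all.
#' @return List with symmetric matrices `r` and `p` (diagonal r = 1, p = 0)
#'   and `n_samples`.
#' @export
correlation_matrix <- function(counts, method = c("spearman", "pearson"),
                               prevalence_min = 0.5) {
  method <- match.arg(method)
  m <- as_count_matrix(counts)
  n <- nrow(m)
  if (n < 4) abort("need at least 4 samples for correlation networks")
  m <- m[, colMeans(m > 0) >= prevalence_min, drop = FALSE]
  if (ncol(m) < 2) abort("fewer than 2 ASVs pass the prevalence filter")
  x <- if (method == "spearman") apply(m, 2, rank) else m
  const <- apply(x, 2, function(v) var(v) == 0)
  r <- suppressWarnings(cor(x))
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  diag(r) <- ifelse(const, NA_real_, 1)
  rc <- pmin(pmax(r, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rc) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  p[is.na(r)] <- NA_real_
  list(r = r, p = p, n_samples = n)
}

#' Build a thresholded co-occurrence network
#'
#' Edges connect ASV pairs with `|r| >= r_min` and multiplicity-adjusted
#' p-value `<= p_max` (Benjamini-Hochberg over the upper triangle by
#' default). Isolated nodes are dropped, so the node count reflects
#' connected ASVs; edge signs record positive vs negative association.
#'
#' @param cors list from [correlation_matrix()] (or `r`/`p` matrices).
#' @param r_min minimum absolute correlation (default 0.6).
#' @param p_max maximum adjusted p (default 0.05).
#' @param p_adjust method for [stats::p.adjust] (default `"BH"`; `"none"`
#'   disables correction).
#' @return Object of class `cooc_network`: `edges` tibble (`from`, `to`,
#'   `r`, `p_adj`, `sign`), `nodes`, and `graph`, the |r|-weighted igraph
#'   object. Empty networks are valid (with a warning).
#' @export
build_network <- function(cors, r_min = 0.6, p_max = 0.05, p_adjust = "BH") {
  r <- cors$r; p <- cors$p
  if (!identical(dim(r), dim(p))) abort("r and p matrices must match")
  ids <- colnames(r)
  ut <- upper.tri(r)
  idx <- which(ut & !is.na(r), arr.ind = TRUE)
  p_adj <- p.adjust(p[cbind(idx[, 1], idx[, 2])], method = p_adjust)
  rv <- r[cbind(idx[, 1], idx[, 2])]
  keep <- abs(rv) >= r_min & p_adj <= p_max
  edges <- tibble::tibble(
    from = ids[idx[keep, 1]], to = ids[idx[keep, 2]],
    r = rv[keep], p_adj = p_adj[keep],
    sign = ifelse(rv[keep] >= 0, "positive", "negative")
  )
  if (nrow(edges) == 0) warn("empty network: no ASV pair passes the thresholds")
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = FALSE,
                                     vertices = if (length(nodes)) nodes else NULL)
  if (nrow(edges)) igraph::E(g)$weight <- abs(edges$r)
  structure(list(edges = edges, nodes = nodes, graph = g,
                 r_min = r_min, p_max = p_max),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("Co-occurrence network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (|r| >=", x$r_min, ", p_adj <=", x$p_max, ")\n")
  invisible(x)
}

#' @rdname build_network
#' @param x a `cooc_network`.
#' @param ... unused.
#' @method tidy cooc_network
#' @export
tidy.cooc_network <- function(x, ...) x$edges

#' @rdname build_network
#' @method glance cooc_network
#' @export
glance.cooc_network <- function(x, ...) {
  nm <- network_metrics(x)
  tibble::as_tibble(nm$summary)
}

#' Summary metrics of a co-occurrence network
#'
#' Node and edge counts, average degree (2E/V), fraction of positive edges,
#' and the modularity of the best partition found by deterministic greedy
#' and Louvain community detection on |r|-weighted edges (the higher-scoring
#' of the two is kept). Modules are numbered by decreasing size.
#'
#' @param net a [build_network()] result.
#' @return List with `summary` (one-row tibble: `n_nodes`, `n_edges`,
#'   `average_degree`, `modularity`, `positive_edge_fraction`, `n_modules`)
#'   and `modules` (tibble `asv_id`, `module`).
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  V <- length(net$nodes); E <- nrow(net$edges)
  if (V == 0) {
    return(list(summary = tibble::tibble(n_nodes = 0L, n_edges = 0L,
                                         average_degree = 0, modularity = 0,
                                         positive_edge_fraction = NA_real_,
                                         n_modules = 0L, empty = TRUE),
                modules = tibble::tibble(asv_id = character(), module = integer())))
  }
  g <- net$graph
  cands <- list(igraph::cluster_fast_greedy(g),
                igraph::cluster_louvain(g))
  mods <- vapply(cands, igraph::modularity, numeric(1))
  best <- cands[[which.max(mods)]]
  memb <- igraph::membership(best)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  modules <- tibble::tibble(asv_id = names(memb),
                            module = unname(relabel[as.character(memb)]))
  list(
    summary = tibble::tibble(
      n_nodes = V, n_edges = E, average_degree = 2 * E / V,
      modularity = max(mods),
      positive_edge_fraction = mean(net$edges$sign == "positive"),
      n_modules = length(sizes), empty = FALSE
    ),
    modules = modules
  )
}

#' Correlate module relative abundance with cumulative emissions
#'
#' For each network module, sums member-ASV relative abundances per sample,
#' averages over each plot's samples, and correlates against the plot-level
#' cumulative CH4 emission.
#'
#' @param net a [build_network()] result.
#' @param counts samples-by-ASVs count tibble or matrix.
#' @param emissions tibble with `plot_id` and `cumulative_S`.
#' @param sample_plots plot id per sample (named by sample id, or in row
#'   order of the count table).
#' @param method correlation method (default `"spearman"`).
#' @return Tibble: `module`, `n_asvs`, `r`, `p`; modules with a constant
#'   abundance profile are flagged with NA.
#' @export
module_abundance_correlation <- function(net, counts, emissions, sample_plots,
                                         method = "spearman") {
  mets <- network_metrics(net)
  rel <- rel_matrix(counts)
  sample_plots <- align_labels(sample_plots, rownames(rel))
  purrr::map_dfr(split(mets$modules$asv_id, mets$modules$module), function(members) {
    members <- intersect(members, colnames(rel))
    if (length(members) == 0) {
      warn("module with no member ASVs in the count table; skipped")
      return(NULL)
    }
    ab <- rowSums(rel[, members, drop = FALSE])
    per_plot <- tapply(ab, sample_plots, mean)
    d <- dplyr::inner_join(
      tibble::tibble(plot_id = names(per_plot), abundance = as.numeric(per_plot)),
      emissions, by = "plot_id"
    )
    if (nrow(d) < 3 || sd(d$abundance) == 0 || sd(d$cumulative_S) == 0) {
      return(tibble::tibble(n_asvs = length(members), r = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(d$abundance, d$cumulative_S, method = method))
    tibble::tibble(n_asvs = length(members), r = unname(ct$estimate), p = ct$p.value)
  }, .id = "module") |>
    dplyr::mutate(module = as.integer(.data$module))
}
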