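test_that("correlation matrix equals a per-pair pearson-on-ranks oracle", {
  set.seed(41)
  for (i in 1:5) {
    m <- random_counts(10, 6, lambda = 8)
    cm <- correlation_matrix(m, prevalence_min = 0)
    for (a in 1:6) for (b in 1:6) {
      ra <- rank(m[, a]); rb <- rank(m[, b])
      r_oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
        sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
      expect_equal(cm$r[a, b], r_oracle, tolerance = 1e-12)
    }
    expect_equal(cm$r, t(cm$r))
    expect_equal(cm$p, t(cm$p))
  }
  # self correlation 1; anti-ranked pair -1
  m2 <- cbind(up = 1:6, down = 6:1, noise = c(2, 5, 1, 6, 3, 4))
  rownames(m2) <- paste0("s", 1:6)
  cm2 <- correlation_matrix(m2, prevalence_min = 0)
  expect_equal(unname(diag(cm2$r)), rep(1, 3))
  expect_equal(unname(cm2$r["up", "down"]), -1)
  expect_equal(unname(cm2$p["up", "down"]), 0)
  # constant ASV masked
  m3 <- cbind(m2, const = rep(4, 6))
  cm3 <- correlation_matrix(m3, prevalence_min = 0)
  expect_true(all(is.na(cm3$r["const", ])))
})

test_that("network thresholding keeps only strong adjusted-significant pairs", {
  set.seed(51)
  n <- 12
  base <- rnorm(n)
  m <- cbind(
    a = round(50 + 10 * base), b = round(52 + 10 * base),  # planted pair
    replicate(6, rpois(n, 30))
  )
  colnames(m)[3:8] <- paste0("x", 1:6)
  rownames(m) <- paste0("s", 1:n)
  cm <- correlation_matrix(m, prevalence_min = 0)
  net <- build_network(cm, r_min = 0.8, p_max = 0.01)
  expect_true(any(net$edges$from == "a" & net$edges$to == "b"))
  expect_true(all(net$edges$sign[net$edges$from == "a"] == "positive"))
  # impossible threshold -> empty network is a valid (warned) result
  expect_warning(net0 <- build_network(cm, r_min = 1.01), "empty")
  expect_equal(nrow(net0$edges), 0)
  mets0 <- network_metrics(net0)
  expect_equal(mets0$summary$n_nodes, 0L)
  # edge set invariant to ASV column order
  perm <- sample(ncol(m))
  cmp <- correlation_matrix(m[, perm], prevalence_min = 0)
  netp <- build_network(cmp, r_min = 0.8, p_max = 0.01)
  canon <- function(e) {
    k <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    sort(k)
  }
  expect_equal(canon(net$edges), canon(netp$edges))
})

test_that("network metrics: degree identity and modularity on known graphs", {
  tri_edges <- tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a"),
                              r = 1, p_adj = 0, sign = "positive")
  mk_net <- function(edges) {
    g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = FALSE)
    igraph::E(g)$weight <- abs(edges$r)
    structure(list(edges = edges, nodes = sort(unique(c(edges$from, edges$to))),
                   graph = g, r_min = 0, p_max = 1), class = "cooc_network")
  }
  mt <- network_metrics(mk_net(tri_edges))$summary
  expect_equal(mt$n_nodes, 3L)
  expect_equal(mt$n_edges, 3L)
  expect_equal(mt$average_degree, 2)
  # two disconnected triangles: modularity of the 2-module split is 1/2
  two_tri <- dplyr::bind_rows(
    tri_edges,
    tibble::tibble(from = c("d", "e", "f"), to = c("e", "f", "d"),
                   r = 1, p_adj = 0, sign = "positive")
  )
  mt2 <- network_metrics(mk_net(two_tri))
  expect_equal(mt2$summary$modularity, 0.5)
  expect_equal(mt2$summary$n_modules, 2L)
  # modules numbered by decreasing size
  sizes <- table(mt2$modules$module)
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("detected modularity is within 0.05 of the exhaustive optimum on small graphs", {
  set.seed(61)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    repeat {
      adj <- matrix(rbinom(n * n, 1, 0.45), n, n)
      adj[lower.tri(adj, diag = TRUE)] <- 0
      g <- igraph::graph_from_adjacency_matrix(adj + t(adj), mode = "undirected")
      if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
    }
    igraph::V(g)$name <- paste0("v", 1:n)
    ew <- igraph::as_data_frame(g)
    edges <- tibble::tibble(from = ew$from, to = ew$to, r = 1, p_adj = 0,
                            sign = "positive")
    net <- structure(list(edges = edges, nodes = igraph::V(g)$name,
                          graph = g, r_min = 0, p_max = 1),
                     class = "cooc_network")
    got <- network_metrics(net)$summary$modularity
    best <- modularity_oracle(g)
    expect_gte(got, best - 0.05)
  }
})

test_that("module abundance correlates with emissions as planted", {
  set.seed(71)
  n_plots <- 8
  emis <- tibble::tibble(plot_id = paste0("P", 1:n_plots),
                         cumulative_S = seq(100, 800, length.out = n_plots))
  # planted module rises with emissions against a flat background
  up <- sapply(1:3, function(k) round(10 + 5 * (1:n_plots) + rnorm(n_plots, 0, 0.2)))
  bg <- sapply(1:4, function(k) 500 + rpois(n_plots, 3))
  m <- cbind(up, bg)
  colnames(m) <- c(paste0("up", 1:3), paste0("bg", 1:4))
  rownames(m) <- paste0("P", 1:n_plots)
  cm <- correlation_matrix(m, prevalence_min = 0)
  net <- suppressWarnings(build_network(cm, r_min = 0.9, p_max = 0.01))
  mac <- module_abundance_correlation(net, m, emis, setNames(rownames(m), rownames(m)))
  mets <- network_metrics(net)
  up_mod <- mets$modules$module[mets$modules$asv_id == "up1"]
  expect_equal(mac$r[mac$module == up_mod], 1)
  # sign flips when emissions are negated
  mac_neg <- module_abundance_correlation(
    net, m, dplyr::mutate(emis, cumulative_S = -cumulative_S),
    setNames(rownames(m), rownames(m))
  )
  expect_equal(mac_neg$r, -mac$r)
})

test_that("label shuffling destroys planted co-occurrence edges", {
  set.seed(81)
  n <- 20
  driver <- rnorm(n)
  m <- sapply(1:10, function(k) round(40 + 12 * driver + rnorm(n, 0, 1)))
  colnames(m) <- paste0("a", 1:10); rownames(m) <- paste0("s", 1:n)
  cm <- correlation_matrix(m, prevalence_min = 0)
  net <- build_network(cm, r_min = 0.6, p_max = 0.05)
  expect_gt(nrow(net$edges), 20)
  shuf_edges <- replicate(5, {
    ms <- apply(m, 2, sample)
    rownames(ms) <- rownames(m)
    cms <- correlation_matrix(ms, prevalence_min = 0)
    suppressWarnings(nrow(build_network(cms, r_min = 0.6, p_max = 0.05)$edges))
  })
  expect_lte(mean(shuf_edges), 0.05 * nrow(net$edges))
})
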