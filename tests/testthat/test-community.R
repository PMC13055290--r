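test_that("to_relative normalises rows, is idempotent, and names empty samples", {
  rel <- to_relative(tiny_counts())
  m <- as.matrix(rel[-1])
  expect_equal(unname(rowSums(m)), rep(1, 4))
  expect_equal(to_relative(rel), rel)
  set.seed(2)
  for (i in 1:10) {
    r <- to_relative(random_counts(5, 8))
    expect_equal(unname(rowSums(as.matrix(r[-1]))), rep(1, 5), tolerance = 1e-12)
  }
  bad <- tiny_counts(); bad[2, -1] <- 0
  expect_error(to_relative(bad), "S2")
})

test_that("taxonomy aggregation preserves per-sample sums and pools unmapped ASVs", {
  counts <- tiny_counts()
  tax <- tibble::tibble(
    asv_id = paste0("ASV", 1:4),
    lineage = c("Methanobacteriota;A;B;C;Methanobacterium",
                "Methanobacteriota;A;B;C;Methanobrevibacter",
                "Halobacteriota;X;Y;Z;Methanosarcina",
                "")
  )
  out <- aggregate_taxonomy(counts, tax, "phylum")
  sums <- out |> dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(relative_abundance))
  expect_equal(sums$s, rep(1, 4))
  # ASV4 (empty lineage) and ASV5 (unmapped) both land in unclassified
  s1 <- dplyr::filter(out, sample_id == "S1")
  expect_equal(s1$relative_abundance[s1$taxon == "unclassified"], 5 / 20)
  # two-phylum normalisation example
  two <- matrix(c(9357, 643), 1, dimnames = list("s", c("a1", "a2")))
  tax2 <- tibble::tibble(asv_id = c("a1", "a2"), lineage = c("P1;;;;", "P2;;;;"))
  out2 <- aggregate_taxonomy(two, tax2, "phylum")
  expect_equal(sort(out2$relative_abundance), c(0.0643, 0.9357))
  # genus-level aggregation then summing equals phylum-level directly
  expect_error(aggregate_taxonomy(counts, tax, "species"), "unknown rank")
})

test_that("alpha diversity matches closed forms and the entropy bound", {
  one <- matrix(c(7), 1, dimnames = list("s", "a"))
  d1 <- alpha_diversity(one)
  expect_equal(d1$richness, 1)
  expect_equal(d1$shannon, 0)
  k <- 6
  unif <- matrix(rep(10, k), 1, dimnames = list("s", paste0("a", 1:k)))
  expect_equal(alpha_diversity(unif)$shannon, log(k))
  set.seed(9)
  for (i in 1:10) {
    m <- random_counts(4, 12)
    d <- alpha_diversity(m)
    expect_true(all(d$shannon <= log(d$richness) + 1e-12))
  }
})

test_that("bray_curtis matches the naive double-loop oracle", {
  same <- rbind(a = c(3, 1, 4), b = c(3, 1, 4))
  colnames(same) <- paste0("x", 1:3)
  expect_equal(unname(bray_curtis(same)["a", "b"]), 0)
  disj <- rbind(a = c(5, 0), b = c(0, 7)); colnames(disj) <- c("x", "y")
  expect_equal(unname(bray_curtis(disj)["a", "b"]), 1)
  set.seed(21)
  for (i in 1:10) {
    m <- random_counts(5, 8)
    expect_equal(bray_curtis(m), bc_oracle(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("core ASV Venn regions partition the union and match a set oracle", {
  counts <- tiny_counts()
  groups <- setNames(c("g1", "g1", "g2", "g2"), paste0("S", 1:4))
  out <- core_asvs(counts, groups)
  # brute-force oracle from set operations
  m <- as.matrix(counts[-1]); rownames(m) <- counts$sample_id
  in_g1 <- colnames(m)[colSums(m[c("S1", "S2"), ] > 0) > 0]
  in_g2 <- colnames(m)[colSums(m[c("S3", "S4"), ] > 0) > 0]
  expect_equal(out$n_asvs[out$region == "g1 & g2"], length(intersect(in_g1, in_g2)))
  expect_equal(out$n_asvs[out$region == "g1"], length(setdiff(in_g1, in_g2)))
  expect_equal(sum(out$n_asvs), length(union(in_g1, in_g2)))
  # identical groups -> everything core; disjoint -> empty core
  dup <- rbind(m, m)
  rownames(dup) <- paste0("S", 1:8)
  gdup <- setNames(rep(c("a", "b"), each = 4), rownames(dup))
  odup <- core_asvs(dup, gdup)
  expect_equal(odup$n_asvs[odup$region == "a & b"], ncol(m))
  expect_equal(sum(odup$n_asvs[odup$n_groups == 1]), 0)
  disj <- rbind(s1 = c(1, 1, 0, 0), s2 = c(0, 0, 2, 2))
  colnames(disj) <- paste0("a", 1:4)
  odisj <- core_asvs(disj, setNames(c("x", "y"), c("s1", "s2")))
  expect_equal(odisj$n_asvs[odisj$region == "x & y"], 0)
  # random partition property over three groups
  set.seed(5)
  for (i in 1:5) {
    mm <- random_counts(6, 15, lambda = 0.8)
    gg <- setNames(rep(c("a", "b", "c"), each = 2), rownames(mm))
    oo <- core_asvs(mm, gg)
    expect_equal(sum(oo$n_asvs), sum(colSums(mm > 0) > 0))
  }
  expect_error(core_asvs(counts, setNames(rep("g", 4), paste0("S", 1:4))), "2 groups")
})

test_that("singleton filter drops total-count-one ASVs only", {
  m <- cbind(keep = c(2, 0, 0), single = c(1, 0, 0), zero = c(0, 0, 0),
             spread = c(1, 1, 0))
  rownames(m) <- paste0("s", 1:3)
  out <- filter_singletons(m)
  expect_setequal(setdiff(names(out), "sample_id"), c("keep", "zero", "spread"))
})

test_that("ASV tables round-trip through the TSV reader", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  counts <- tiny_counts()
  m <- as.matrix(counts[-1]); rownames(m) <- counts$sample_id
  readr::write_tsv(tibble::as_tibble(t(m), rownames = "asv_id"), tf)
  back <- read_asv_table(tf)
  expect_equal(back, counts)
})

test_that("rarefaction hits the target depth deterministically under a seed", {
  m <- random_counts(4, 10, lambda = 20, seed = 8)
  r1 <- rarefy_counts(m, depth = 50, seed = 1)
  r2 <- rarefy_counts(m, depth = 50, seed = 1)
  expect_equal(r1, r2)
  expect_equal(unname(rowSums(as.matrix(r1[-1]))), rep(50, 4))
})
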