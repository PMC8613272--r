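make_profiles <- function(n_samples = 6, n_genes = 8, seed = 1) {
  set.seed(seed)
  edges <- random_connected_edges(n_genes, 0.4)
  topo <- as_topology(edges)
  genes <- topology_genes(topo)
  cols <- lapply(seq_len(n_samples), function(i)
    sample(0:10, length(genes), replace = TRUE))
  names(cols) <- sprintf("s%d", seq_len(n_samples))
  cn <- tibble::as_tibble(c(list(gene = genes), cols))
  list(topology = topo, cn = cn, profiles = curvature_profiles(topo, cn))
}

test_that("delta curvature is the difference of group means", {
  fx <- make_profiles()
  d <- delta_scalar_curvature(fx$profiles, c("s1", "s2"), c("s3", "s4"))
  mat <- scalar_curvature_matrix(fx$profiles)
  manual <- (mat$s1 + mat$s2) / 2 - (mat$s3 + mat$s4) / 2
  expect_equal(d$delta[match(mat$gene, d$gene)], manual, tolerance = 1e-12)
})

test_that("delta curvature is antisymmetric and zero for mirrored groups", {
  fx <- make_profiles(seed = 2)
  a <- c("s1", "s3"); b <- c("s2", "s5")
  d_ab <- delta_scalar_curvature(fx$profiles, a, b)
  d_ba <- delta_scalar_curvature(fx$profiles, b, a)
  m <- dplyr::left_join(d_ab, d_ba, by = "gene")
  expect_equal(m$delta.x, -m$delta.y, tolerance = 1e-12)

  dup <- fx$profiles[c("s1", "s2")]
  dup2 <- fx$profiles[c("s1", "s2")]
  names(dup2) <- c("t1", "t2")
  dup2 <- lapply(names(dup2), function(nm) {
    p <- dup2[[nm]]; p$sample <- nm; p
  })
  names(dup2) <- c("t1", "t2")
  both <- c(dup, dup2)
  d0 <- delta_scalar_curvature(both, c("s1", "s2"), c("t1", "t2"))
  expect_true(all(abs(d0$delta) < 1e-14))
})

test_that("group validation: disjoint, non-empty, known samples, shared topology", {
  fx <- make_profiles(seed = 3)
  expect_error(delta_scalar_curvature(fx$profiles, "s1", "s1"), "disjoint")
  expect_error(delta_scalar_curvature(fx$profiles, character(), "s1"),
               "non-empty")
  expect_error(delta_scalar_curvature(fx$profiles, "s1", "zz"), "zz")
  other <- make_profiles(n_genes = 7, seed = 4)
  expect_error(delta_scalar_curvature(c(fx$profiles[1], other$profiles[2]),
                                      "s1", "s2"), "topology")
})

test_that("reference delta vanishes for constant-CN cohorts (scale invariance)", {
  edges <- edge_tbl(c("A", "A", "B", "C"), c("B", "C", "C", "D"))
  topo <- as_topology(edges)
  genes <- topology_genes(topo)
  cols <- stats::setNames(lapply(1:3, function(i) rep(4, length(genes))),
                          c("s1", "s2", "s3"))
  cn <- tibble::as_tibble(c(list(gene = genes), cols))
  profs <- curvature_profiles(topo, cn)
  d <- reference_topology_delta(profs, topo)
  expect_true(all(abs(d$delta) < 1e-9))
})

test_that("a single amplified hub shifts curvature in its neighbourhood", {
  # star-plus-path: B is a hub neighbouring A, C, D; E hangs off D
  edges <- edge_tbl(c("A", "B", "B", "D"), c("B", "C", "D", "E"))
  topo <- as_topology(edges)
  genes <- topology_genes(topo)
  base <- stats::setNames(rep(2, 5), genes)
  amp <- base; amp["B"] <- 20
  cn <- tibble::tibble(gene = genes, s1 = unname(amp[genes]))
  profs <- curvature_profiles(topo, cn)
  d <- reference_topology_delta(profs, topo)
  expect_gt(max(abs(d$delta)), 1e-6)
  # the perturbation registers most strongly at the hub or its neighbours
  top_gene <- d$gene[which.max(abs(d$delta))]
  expect_true(top_gene %in% c("A", "B", "C", "D"))
})

test_that("top-k ranking sorts, breaks ties by symbol and drops zeros", {
  delta <- tibble::tibble(gene = c("A", "B", "C"), delta = c(0.3, -0.2, 0))
  tk <- top_k_ranking(delta, k = 1)
  expect_equal(tk$gene[tk$direction == "positive"], "A")
  expect_equal(tk$gene[tk$direction == "negative"], "B")
  expect_false("C" %in% tk$gene)

  # k exceeding available genes returns all of them
  tk2 <- top_k_ranking(delta, k = 10)
  expect_equal(sum(tk2$direction == "positive"), 1L)

  # ties break lexicographically; input order does not matter
  tied <- tibble::tibble(gene = c("Z", "M", "A"), delta = c(0.5, 0.5, 0.5))
  tk3 <- top_k_ranking(tied, k = 2)
  expect_equal(tk3$gene, c("A", "M"))
  tk4 <- top_k_ranking(tied[c(2, 3, 1), ], k = 2)
  expect_equal(tk4$gene, tk3$gene)
})

test_that("positive and negative lists are disjoint", {
  fx <- make_profiles(seed = 5)
  d <- delta_scalar_curvature(fx$profiles, c("s1", "s2", "s3"),
                              c("s4", "s5", "s6"))
  tk <- top_k_ranking(d, k = 4)
  pos <- tk$gene[tk$direction == "positive"]
  neg <- tk$gene[tk$direction == "negative"]
  expect_length(intersect(pos, neg), 0)
})

test_that("comparison wrapper produces the expected comparison set", {
  fx <- make_profiles(n_samples = 8, seed = 6)
  totals <- total_curvatures(fx$profiles)
  sp <- percentile_split(dplyr::rename(totals, value = total_kappa),
                         quiet = TRUE)
  clin <- tibble::tibble(
    sample = totals$sample,
    vital_status = rep(c(TRUE, FALSE), 4),
    sample_type = rep(c("primary", "metastasis"), each = 4)
  )
  rk <- rank_gene_comparisons(fx$profiles, fx$topology, split = sp,
                              clinical = clin, k = 3)
  expect_setequal(unique(rk$comparison), c("risk", "os", "pm", "ref"))
  expect_true(all(rk$rank >= 1 & rk$rank <= 3))
})
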