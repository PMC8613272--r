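test_that("Wasserstein-1 basics: identity, point masses, feasibility", {
  m <- transition_matrix(triangle_network())
  D <- path_metric(m)
  mu <- node_measure(m, "A")
  expect_equal(wasserstein1(mu, mu, D)$cost, 0)

  # point masses transport over the ground distance
  d1 <- c(B = 1); d2 <- c(C = 1)
  expect_equal(wasserstein1(d1, d2, D)$cost, D["B", "C"])

  expect_error(wasserstein1(c(B = 0.5), c(C = 1), D), "mass mismatch")
})

test_that("triangle transport moves half a unit over distance 2", {
  m <- transition_matrix(triangle_network())
  D <- path_metric(m)
  plan <- wasserstein1(node_measure(m, "A"), node_measure(m, "B"), D)
  expect_equal(plan$cost, 1)
  # marginals of the optimal plan are the input measures
  tot <- sum(plan$plan$mass)
  expect_equal(tot, 1, tolerance = 1e-9)
  expect_equal(plan$cost, sum(plan$plan$mass * plan$plan$distance))
})

test_that("solver agrees with the dense LP oracle on random small instances", {
  set.seed(606)
  for (i in 1:80) {
    net <- random_network(sample(4:8, 1), max_cn = 10)
    m <- transition_matrix(net)
    D <- path_metric(m)
    el <- topology_edges(net$topology)
    e <- el[sample(nrow(el), 1), ]
    mu0 <- node_measure(m, e$gene_a)
    mu1 <- node_measure(m, e$gene_b)
    expect_equal(wasserstein1(mu0, mu1, D)$cost, w1_oracle(mu0, mu1, D),
                 tolerance = 1e-8)
  }
})

test_that("W1 is symmetric and the oracle refuses oversized supports", {
  set.seed(707)
  net <- random_network(7)
  m <- transition_matrix(net)
  D <- path_metric(m)
  el <- topology_edges(net$topology)
  mu0 <- node_measure(m, el$gene_a[1]); mu1 <- node_measure(m, el$gene_b[1])
  expect_equal(wasserstein1(mu0, mu1, D)$cost, wasserstein1(mu1, mu0, D)$cost,
               tolerance = 1e-12)
  expect_equal(w1_oracle(mu0, mu0, D), 0, tolerance = 1e-12)
  expect_error(w1_oracle(mu0, mu1, D, max_support = 2), "support too large")
})

test_that("single-edge graph has zero edge curvature exactly", {
  p <- curvature_profile(single_edge_network(c(3, 9)))
  expect_equal(p$edges$kappa, 0)
  expect_equal(p$nodes$kappa, c(0, 0))
  expect_equal(p$total, 0)
})

test_that("uniform-weight triangle: kappa 1/2 per edge, 1/3 per node, 1 total", {
  p <- curvature_profile(triangle_network())
  expect_equal(p$edges$kappa, rep(1 / 2, 3))
  expect_equal(p$nodes$kappa, rep(1 / 3, 3))
  expect_equal(p$total, 1)
})

test_that("edge curvature for the uniform path matches the LP oracle", {
  net <- path_network(c(1, 1, 1))
  m <- transition_matrix(net)
  D <- path_metric(m)
  k <- edge_curvature(m, c("A", "B"), D)
  mu_a <- node_measure(m, "A"); mu_b <- node_measure(m, "B")
  expect_equal(k, 1 - w1_oracle(mu_a, mu_b, D) / D["A", "B"], tolerance = 1e-10)
})

test_that("edge curvature never exceeds 1 and matches the oracle route", {
  set.seed(808)
  for (i in 1:15) {
    net <- random_network(sample(4:8, 1), max_cn = 12)
    m <- transition_matrix(net)
    D <- path_metric(m)
    ec <- edge_curvatures(m, D)
    expect_true(all(ec$kappa <= 1 + 1e-12))
    j <- sample(nrow(ec), 1)
    ko <- 1 - w1_oracle(node_measure(m, ec$gene_a[j]),
                        node_measure(m, ec$gene_b[j]), D) / ec$distance[j]
    expect_equal(ec$kappa[j], ko, tolerance = 1e-8)
  }
})

test_that("scalar curvature contracts edges with stationary mass", {
  net <- triangle_network()
  m <- transition_matrix(net)
  sc <- scalar_curvature(m)
  expect_equal(sc$kappa, rep(1 / 3, 3))
  expect_equal(total_curvature(sc), 1)
})

test_that("total curvature equals both contraction groupings", {
  set.seed(909)
  for (i in 1:6) {
    net <- random_network(sample(5:9, 1))
    p <- curvature_profile(net)
    expect_equal(p$total, sum(p$nodes$kappa), tolerance = 1e-9)
    # regrouping over edges: sum (pi_j + pi_k) kappa_jk
    pi <- stats::setNames(p$nodes$pi, p$nodes$gene)
    by_edges <- sum((pi[p$edges$gene_a] + pi[p$edges$gene_b]) * p$edges$kappa)
    expect_equal(p$total, unname(by_edges), tolerance = 1e-9)
  }
})

test_that("curvature is invariant under uniform weight scaling", {
  set.seed(111)
  net <- random_network(10, max_cn = 10)
  p1 <- curvature_profile(net)
  for (c_scale in c(0.5, 3, 17)) {
    scaled <- net
    scaled$weights <- net$weights * c_scale
    p2 <- curvature_profile(scaled)
    expect_equal(p2$edges$kappa, p1$edges$kappa, tolerance = 1e-9)
    expect_equal(p2$nodes$kappa, p1$nodes$kappa, tolerance = 1e-9)
    expect_equal(p2$total, p1$total, tolerance = 1e-9)
  }
})

test_that("relabelling genes permutes curvature outputs correspondingly", {
  set.seed(222)
  edges <- random_connected_edges(8, 0.4)
  topo <- as_topology(edges)
  genes <- topology_genes(topo)
  cn <- stats::setNames(sample(0:8, length(genes), replace = TRUE), genes)
  p1 <- curvature_profile(attach_weights(topo, cn))

  # apply a random permutation to the labels
  newlab <- stats::setNames(sample(sprintf("Z%02d", seq_along(genes))), genes)
  edges2 <- tibble::tibble(gene_a = unname(newlab[edges$gene_a]),
                           gene_b = unname(newlab[edges$gene_b]))
  cn2 <- stats::setNames(unname(cn), unname(newlab[names(cn)]))
  p2 <- curvature_profile(attach_weights(as_topology(edges2), cn2))

  k1 <- stats::setNames(p1$nodes$kappa, unname(newlab[p1$nodes$gene]))
  k2 <- stats::setNames(p2$nodes$kappa, p2$nodes$gene)
  expect_equal(k2[names(k1)], k1, tolerance = 1e-12)
  expect_equal(p2$total, p1$total, tolerance = 1e-12)
})

test_that("the fused C++ engine matches the modular R route", {
  set.seed(333)
  for (i in 1:5) {
    net <- random_network(sample(5:10, 1), max_cn = 10)
    pc <- curvature_profile(net, engine = "cpp")
    pr <- curvature_profile(net, engine = "r")
    expect_equal(pc$edges$kappa, pr$edges$kappa, tolerance = 1e-10)
    expect_equal(pc$nodes$kappa, pr$nodes$kappa, tolerance = 1e-10)
    expect_equal(pc$total, pr$total, tolerance = 1e-10)
  }
})

test_that("cohort helpers assemble matrices and totals consistently", {
  topo <- as_topology(edge_tbl(c("A", "A", "B", "C"), c("B", "C", "C", "D")))
  cn <- tibble::tibble(gene = c("A", "B", "C", "D"),
                       s1 = c(2, 2, 2, 2), s2 = c(0, 8, 2, 1))
  profs <- curvature_profiles(topo, cn)
  expect_named(profs, c("s1", "s2"))
  mat <- scalar_curvature_matrix(profs)
  expect_equal(mat$s1, profs$s1$nodes$kappa)
  tot <- total_curvatures(profs)
  expect_equal(tot$total_kappa, c(profs$s1$total, profs$s2$total))
})
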