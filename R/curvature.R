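#' Exact Wasserstein-1 distance between two neighbourhood measures
#'
#' Solves the discrete optimal transport problem
#' \deqn{W_1(\mu_0, \mu_1) = \min_{\pi \in \Pi(\mu_0,\mu_1)} \sum_{x,y}
#'   \pi_{xy}\, d(x, y)}
#' exactly, by successive shortest augmenting paths on the bipartite residual
#' graph (a min-cost-flow method of the network-simplex/LP class; no entropic
#' regularisation). Ground distances are the weighted hop metric values
#' between support genes, computed on the full graph.
#'
#' @param mu0,mu1 Measures as returned by [node_measure()] (tibbles with
#'   columns `gene`, `mass`), or named numeric vectors of masses. Each must
#'   sum to 1 within 1e-9.
#' @param metric A distance matrix covering the union of the two supports
#'   (e.g. from [path_metric()]).
#' @return A `transport_plan` object: list with `cost` (the W1 value) and
#'   `plan`, a tibble (`from`, `to`, `mass`, `distance`) of the optimal
#'   coupling restricted to positive masses.
#' @export
wasserstein1 <- function(mu0, mu1, metric) {
  m0 <- as_measure(mu0)
  m1 <- as_measure(mu1)
  if (abs(sum(m0) - sum(m1)) > 1e-9)
    abort("infeasible marginals: mass mismatch exceeds 1e-9")
  sup0 <- names(m0)
  sup1 <- names(m1)
  if (!all(sup0 %in% rownames(metric)) || !all(sup1 %in% colnames(metric)))
    abort("metric does not cover the measure supports")
  C <- metric[sup0, sup1, drop = FALSE]
  res <- cpp_transport(unname(m0), unname(m1), C)
  plan <- res$plan
  idx <- which(plan > 1e-15, arr.ind = TRUE)
  plan_tbl <- tibble(
    from = sup0[idx[, 1L]],
    to = sup1[idx[, 2L]],
    mass = plan[idx],
    distance = C[idx]
  )
  structure(list(cost = res$cost, plan = arrange(plan_tbl, .data$from, .data$to)),
            class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("<transport_plan> cost %.6g over %d moves\n", x$cost, nrow(x$plan)))
  invisible(x)
}

as_measure <- function(mu) {
  if (is.data.frame(mu)) {
    stopifnot(all(c("gene", "mass") %in% names(mu)))
    mu <- setNames(mu$mass, mu$gene)
  }
  if (is.null(names(mu))) abort("measures must be named by gene")
  if (any(mu < 0)) abort("negative mass in measure")
  mu[mu > 0]
}

#' Dense linear-programming oracle for Wasserstein-1
#'
#' Independent verification route: sets up the full coupling polytope as a
#' dense LP (one variable per support pair, marginal equality constraints)
#' and solves it with the two-phase simplex method from the boot package.
#' Intended for tests on small instances only.
#'
#' @param mu0,mu1 Measures as in [wasserstein1()].
#' @param metric Ground-distance matrix covering both supports.
#' @param max_support Refuse instances with a combined support larger than
#'   this (default 12).
#' @return The optimal transport cost (numeric scalar).
#' @export
w1_oracle <- function(mu0, mu1, metric, max_support = 12L) {
  if (!requireNamespace("boot", quietly = TRUE))
    abort("the boot package is required for w1_oracle")
  m0 <- as_measure(mu0)
  m1 <- as_measure(mu1)
  if (length(unique(c(names(m0), names(m1)))) > max_support)
    abort("support too large for the dense LP oracle")
  m0 <- m0 / sum(m0)
  m1 <- m1 / sum(m1)
  m <- length(m0)
  n <- length(m1)
  C <- metric[names(m0), names(m1), drop = FALSE]
  # variables x_{ij} laid out row-major: index (i-1)*n + j
  obj <- as.vector(t(C))
  A3 <- matrix(0, m + n - 1L, m * n)
  b3 <- numeric(m + n - 1L)
  for (i in seq_len(m)) {
    A3[i, (i - 1L) * n + seq_len(n)] <- 1
    b3[i] <- m0[[i]]
  }
  for (j in seq_len(n - 1L)) { # last column constraint is redundant
    A3[m + j, (seq_len(m) - 1L) * n + j] <- 1
    b3[m + j] <- m1[[j]]
  }
  sol <- boot::simplex(a = obj, A3 = A3, b3 = b3, maxi = FALSE, eps = 1e-12)
  if (sol$solved != 1) abort("LP oracle failed to solve")
  unname(sol$value)
}

#' Ollivier-Ricci curvature of one edge
#'
#' \deqn{\kappa_{OR}(j, k) = 1 - W_1(\mu_j, \mu_k) / d_{jk}}
#' where \eqn{\mu_j, \mu_k} are the one-step neighbourhood measures and
#' \eqn{d_{jk}} the weighted hop distance (the graph metric, i.e. the minimum
#' over all paths — which can be smaller than the direct edge length).
#'
#' @param model A `cn_markov`.
#' @param edge Character vector of two gene symbols forming an edge.
#' @param metric Optional precomputed [path_metric()] matrix.
#' @return The edge curvature (numeric scalar, always \eqn{\le 1}).
#' @export
edge_curvature <- function(model, edge, metric = NULL) {
  stopifnot(inherits(model, "cn_markov"), length(edge) == 2L)
  if (is.null(metric)) metric <- path_metric(model)
  d <- metric[edge[1L], edge[2L]]
  stopifnot(d > 0)
  W1 <- wasserstein1(node_measure(model, edge[1L]),
                     node_measure(model, edge[2L]), metric)$cost
  1 - W1 / d
}

#' Curvature of every edge in the network
#'
#' @param model A `cn_markov`.
#' @param metric Optional precomputed [path_metric()] matrix.
#' @return Tibble with columns `gene_a`, `gene_b`, `distance`, `w1`, `kappa`.
#' @export
edge_curvatures <- function(model, metric = NULL) {
  stopifnot(inherits(model, "cn_markov"))
  if (is.null(metric)) metric <- path_metric(model)
  el <- topology_edges(model$network$topology)
  measures <- lapply(rownames(model$P), function(g) node_measure(model, g))
  names(measures) <- rownames(model$P)
  res <- purrr::pmap(el, function(gene_a, gene_b) {
    d <- metric[gene_a, gene_b]
    W1 <- wasserstein1(measures[[gene_a]], measures[[gene_b]], metric)$cost
    c(distance = d, w1 = W1, kappa = 1 - W1 / d)
  })
  as_tibble(cbind(el, as_tibble(do.call(rbind, res))))
}

#' Scalar (nodal) curvature
#'
#' Contracts edge curvatures to genes: the scalar curvature of gene `j` is
#' its stationary mass times the sum of curvatures on incident edges,
#' \eqn{\kappa_j = \pi_j \sum_{j \sim k} \kappa_{OR}(j, k)}.
#'
#' @param model A `cn_markov`.
#' @param edges Optional precomputed [edge_curvatures()] tibble.
#' @return Tibble with columns `gene`, `pi`, `kappa`.
#' @export
scalar_curvature <- function(model, edges = NULL) {
  stopifnot(inherits(model, "cn_markov"))
  if (is.null(edges)) edges <- edge_curvatures(model)
  genes <- names(model$pi)
  acc <- setNames(numeric(length(genes)), genes)
  for (i in seq_len(nrow(edges))) {
    acc[edges$gene_a[i]] <- acc[edges$gene_a[i]] + edges$kappa[i]
    acc[edges$gene_b[i]] <- acc[edges$gene_b[i]] + edges$kappa[i]
  }
  tibble(gene = genes, pi = unname(model$pi), kappa = unname(acc * model$pi))
}

#' Total curvature of a network
#'
#' The net scalar curvature summed over all genes,
#' \eqn{\kappa_G = \sum_j \kappa_j} — the per-sample network summary used for
#' survival stratification.
#'
#' @param x A `curvature_profile`, a [scalar_curvature()] tibble, or a
#'   numeric vector of scalar curvatures.
#' @return Numeric scalar.
#' @export
total_curvature <- function(x) {
  if (inherits(x, "curvature_profile")) return(x$total)
  if (is.data.frame(x)) return(sum(x$kappa))
  sum(x)
}

#' Full curvature profile of one weighted network
#'
#' Computes per-edge Ollivier-Ricci curvature, per-gene scalar curvature and
#' the network total for one sample. The default engine runs the fused C++
#' path (Dijkstra metric + exact transport per edge); `engine = "r"`
#' assembles the same quantities from the modular R operations and is used
#' for cross-checking.
#'
#' @param network A `cn_network` from [attach_weights()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @return A `curvature_profile`: list with `sample`, `edges` (tibble
#'   `gene_a`, `gene_b`, `weight`, `distance`, `w1`, `kappa`), `nodes`
#'   (tibble `gene`, `pi`, `kappa`) and `total`.
#' @export
curvature_profile <- function(network, engine = c("cpp", "r")) {
  stopifnot(inherits(network, "cn_network"))
  engine <- match.arg(engine)
  genes <- names(network$weights)
  el <- topology_edges(network$topology)
  if (engine == "cpp") {
    ei <- match(el$gene_a, genes)
    ej <- match(el$gene_b, genes)
    res <- cpp_curvature_profile(length(genes), ei, ej, unname(network$weights))
    edges <- mutate(el, weight = res$edge_weight, distance = res$edge_distance,
                    w1 = res$edge_w1, kappa = res$edge_kappa)
    nodes <- tibble(gene = genes, pi = res$pi, kappa = res$node_kappa)
    total <- res$total
  } else {
    model <- transition_matrix(network)
    metric <- path_metric(model)
    ec <- edge_curvatures(model, metric)
    edges <- left_join(ec, model$edge_weights, by = c("gene_a", "gene_b"))
    edges <- edges[, c("gene_a", "gene_b", "weight", "distance", "w1", "kappa")]
    nodes <- scalar_curvature(model, ec)
    total <- sum(nodes$kappa)
  }
  structure(list(sample = network$sample, edges = edges, nodes = nodes,
                 total = total),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile> sample %s: %d genes, %d edges, total curvature %.6g\n",
              x$sample, nrow(x$nodes), nrow(x$edges), x$total))
  invisible(x)
}

#' Curvature profiles for a cohort
#'
#' Runs [curvature_profile()] for every sample of a cohort on the shared
#' topology.
#'
#' @param topology A `cn_topology`.
#' @param cn Wide copy-number tibble: column `gene` plus one column per
#'   sample (as from [read_cn_matrix()] or [simulate_cn_cohort()]).
#' @return Named list of `curvature_profile` objects, one per sample.
#' @export
curvature_profiles <- function(topology, cn) {
  stopifnot(inherits(topology, "cn_topology"), "gene" %in% names(cn))
  samples <- setdiff(names(cn), "gene")
  out <- lapply(samples, function(s) {
    net <- attach_weights(topology, setNames(cn[[s]], cn$gene), sample = s)
    curvature_profile(net)
  })
  setNames(out, samples)
}

#' Per-gene scalar curvature matrix of a cohort
#'
#' @param profiles List of `curvature_profile` objects sharing one topology.
#' @return Wide tibble: column `gene` plus one scalar-curvature column per
#'   sample.
#' @export
scalar_curvature_matrix <- function(profiles) {
  check_shared_topology(profiles)
  genes <- profiles[[1L]]$nodes$gene
  cols <- lapply(profiles, function(p) p$nodes$kappa)
  out <- as_tibble(c(list(gene = genes), cols))
  out
}

#' Total curvature of every sample in a cohort
#'
#' @param profiles List of `curvature_profile` objects.
#' @return Tibble with columns `sample`, `total_kappa`.
#' @export
total_curvatures <- function(profiles) {
  tibble(
    sample = unname(vapply(profiles, function(p) p$sample, "")),
    total_kappa = unname(vapply(profiles, function(p) p$total, 0))
  )
}

check_shared_topology <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  ref <- profiles[[1L]]$nodes$gene
  same <- vapply(profiles, function(p) identical(p$nodes$gene, ref), TRUE)
  if (!all(same)) abort("profiles do not share one topology")
  invisible(TRUE)
}
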