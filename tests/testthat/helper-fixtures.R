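# hand-built networks ------------------------------------------------------

edge_tbl <- function(a, b) tibble::tibble(gene_a = a, gene_b = b)

# path A - B - C with node weights w (copy numbers w - 1)
path_network <- function(w = c(1, 2, 3)) {
  topo <- as_topology(edge_tbl(c("A", "B"), c("B", "C")))
  attach_weights(topo, c(A = w[1] - 1, B = w[2] - 1, C = w[3] - 1), sample = "path")
}

triangle_network <- function(cn = 2) {
  topo <- as_topology(edge_tbl(c("A", "A", "B"), c("B", "C", "C")))
  attach_weights(topo, c(A = cn, B = cn, C = cn), sample = "triangle")
}

single_edge_network <- function(cn = c(1, 1)) {
  topo <- as_topology(edge_tbl("A", "B"))
  attach_weights(topo, c(A = cn[1], B = cn[2]), sample = "edge")
}

# random connected graphs ---------------------------------------------------

random_connected_edges <- function(n, p = 0.5) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) >= 1) break
  }
  el <- igraph::as_edgelist(g)
  lab <- sprintf("N%02d", seq_len(n))
  edge_tbl(lab[el[, 1]], lab[el[, 2]])
}

random_network <- function(n, max_cn = 8, p = 0.5) {
  edges <- random_connected_edges(n, p)
  topo <- as_topology(edges)
  genes <- topology_genes(topo)
  cn <- stats::setNames(sample(0:max_cn, length(genes), replace = TRUE), genes)
  attach_weights(topo, cn, sample = "rand")
}

# independent oracles -------------------------------------------------------

# weighted hop distance by exhaustive enumeration over all simple paths
whop_bruteforce <- function(model, from, to) {
  if (from == to) return(0)
  g <- model$network$topology$graph
  ew <- edge_interaction_weights(model)
  key <- paste(ew$gene_a, ew$gene_b)
  cost_of <- function(a, b) {
    k <- paste(pmin(a, b), pmax(a, b))
    1 / ew$weight[match(k, key)]
  }
  paths <- igraph::all_simple_paths(g, from, to)
  lens <- vapply(paths, function(p) {
    nm <- igraph::V(g)$name[as.integer(p)]
    sum(cost_of(nm[-length(nm)], nm[-1]))
  }, 0)
  min(lens)
}

# stationary distribution by power iteration on the lazy chain (P + I)/2,
# which shares its stationary distribution with P but is aperiodic, so the
# iteration converges even on bipartite graphs
power_iteration_pi <- function(P, tol = 1e-14, max_iter = 100000) {
  n <- nrow(P)
  pi <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    nxt <- (as.vector(pi %*% P) + pi) / 2
    if (max(abs(nxt - pi)) < tol) break
    pi <- nxt
  }
  stats::setNames(nxt / sum(nxt), rownames(P))
}

# Kaplan-Meier product-limit computed by hand
km_bruteforce <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- sort(unique(times[events]))
  surv <- numeric(length(ut)); s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  tibble::tibble(time = ut, survival = surv)
}

# exponential survival fixture with a binary group effect
sim_two_group_surv <- function(n_a, n_b, hr = 1, rate = 0.1, cens_rate = 0) {
  n <- n_a + n_b
  grp <- rep(c("a", "b"), c(n_a, n_b))
  t_ev <- stats::rexp(n, rate * ifelse(grp == "b", hr, 1))
  if (cens_rate > 0) {
    t_c <- stats::rexp(n, cens_rate)
    tibble::tibble(sample = sprintf("x%03d", 1:n), group = grp,
                   os_months = pmin(t_ev, t_c), event = t_ev <= t_c)
  } else {
    tibble::tibble(sample = sprintf("x%03d", 1:n), group = grp,
                   os_months = t_ev, event = TRUE)
  }
}
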