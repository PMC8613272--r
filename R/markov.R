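#' Mass-action transition model of a weighted gene network
#'
#' Treats the weighted network as a Markov chain under the principle of mass
#' action: the probability that gene `j` steps to a neighbouring gene `k` is
#' proportional to the product of their node weights, normalised per node,
#'
#' \deqn{p_{jk} = w_k / \sum_{l \sim j} w_l \quad (j \sim k), \qquad 0
#'   \mathrm{\ otherwise.}}
#'
#' The chain is reversible; its stationary distribution has the closed form
#' \eqn{\pi_j \propto w_j \sum_{j \sim k} w_k}. Symmetrised edge interaction
#' weights \eqn{w_{uv} = (p_{uv} + p_{vu})/2} define the weighted hop metric
#' (per-edge length \eqn{1/w_{uv}}), so that strongly interacting genes are
#' metrically close.
#'
#' @param network A `cn_network` from [attach_weights()].
#' @return A `cn_markov` object with elements `network`, `P` (dense
#'   row-stochastic matrix, genes in topology order), `pi` (named stationary
#'   distribution), and `edge_weights` (tibble `gene_a`, `gene_b`, `weight`).
#' @export
transition_matrix <- function(network) {
  stopifnot(inherits(network, "cn_network"))
  g <- network$topology$graph
  w <- network$weights
  genes <- names(w)
  n <- length(genes)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- A[genes, genes]
  S <- drop(A %*% w) # sum of neighbour weights per node
  if (any(S <= 0)) abort("isolated node: cannot normalise transition probabilities")
  P <- A * rep(w, each = n) / S # P[j, k] = A[j,k] * w[k] / S[j]
  dimnames(P) <- list(genes, genes)

  pi_un <- w * S
  pi <- pi_un / sum(pi_un)

  el <- topology_edges(network$topology)
  wuv <- (P[cbind(el$gene_a, el$gene_b)] + P[cbind(el$gene_b, el$gene_a)]) / 2
  structure(
    list(network = network, P = P, pi = pi,
         edge_weights = mutate(el, weight = wuv)),
    class = "cn_markov"
  )
}

#' @export
print.cn_markov <- function(x, ...) {
  cat(sprintf("<cn_markov> %d genes, %d edges; stationary mass range [%.3g, %.3g]\n",
              nrow(x$P), nrow(x$edge_weights), min(x$pi), max(x$pi)))
  invisible(x)
}

#' Stationary distribution of the mass-action chain
#'
#' Returns the closed-form stationary distribution
#' \eqn{\pi_j = w_j \sum_{j \sim k} w_k / Z}, which satisfies
#' \eqn{\pi = \pi P} and detailed balance
#' \eqn{\pi_j p_{jk} = \pi_k p_{kj} = w_j w_k / Z}.
#'
#' @param model A `cn_markov` (or a `cn_network`, which is converted first).
#' @return Named numeric vector summing to 1.
#' @export
stationary_distribution <- function(model) {
  if (inherits(model, "cn_network")) model <- transition_matrix(model)
  stopifnot(inherits(model, "cn_markov"))
  model$pi
}

#' Symmetrised edge interaction weights
#'
#' @param model A `cn_markov`.
#' @return Tibble with columns `gene_a`, `gene_b`, `weight` where
#'   `weight` \eqn{= (p_{uv} + p_{vu})/2}.
#' @export
edge_interaction_weights <- function(model) {
  stopifnot(inherits(model, "cn_markov"))
  model$edge_weights
}

#' Weighted hop metric between genes
#'
#' Shortest-path distance where each edge contributes length equal to the
#' reciprocal of its symmetrised interaction weight; the distance between two
#' genes is the minimum total length over all connecting paths, computed on
#' the full graph. The more likely two genes are to interact, the closer they
#' are.
#'
#' @param model A `cn_markov`.
#' @return A dense symmetric matrix of distances with zero diagonal, genes in
#'   topology order.
#' @export
path_metric <- function(model) {
  stopifnot(inherits(model, "cn_markov"))
  g <- model$network$topology$graph
  el <- igraph::as_edgelist(g)
  key_g <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  ew <- model$edge_weights
  key_w <- paste(ew$gene_a, ew$gene_b)
  wuv <- ew$weight[match(key_g, key_w)]
  D <- igraph::distances(g, weights = 1 / wuv)
  genes <- names(model$pi)
  D[genes, genes]
}

#' Weighted hop distance between two genes
#'
#' @param model A `cn_markov`.
#' @param from,to Gene symbols.
#' @param metric Optional precomputed matrix from [path_metric()].
#' @return The weighted hop distance (numeric scalar).
#' @export
weighted_hop_distance <- function(model, from, to, metric = NULL) {
  if (is.null(metric)) metric <- path_metric(model)
  if (!all(c(from, to) %in% rownames(metric)))
    abort("gene not present in the network")
  d <- metric[from, to]
  if (!is.finite(d)) abort("genes are not connected") # unreachable on a connected topology
  d
}

#' One-step neighbourhood measure of a gene
#'
#' The probability measure attached to gene `j`: mass \eqn{p_{jk}} on each
#' neighbour `k`, zero elsewhere — the distribution of a one-step random walk
#' started at `j`.
#'
#' @param model A `cn_markov`.
#' @param gene Gene symbol.
#' @return Tibble with columns `gene`, `mass` (rows are the neighbours of
#'   `gene`; masses sum to 1), with the centre gene stored in
#'   `attr(, "center")`.
#' @export
node_measure <- function(model, gene) {
  stopifnot(inherits(model, "cn_markov"))
  if (!gene %in% rownames(model$P)) abort("gene not present in the network")
  row <- model$P[gene, ]
  sup <- names(row)[row > 0]
  out <- tibble(gene = sup, mass = unname(row[sup]))
  attr(out, "center") <- gene
  out
}
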