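#' Map copy-number segments to genes
#'
#' Assigns each gene the maximum value of all segments overlapping it (any
#' shared base; both segments and gene models are 1-based inclusive). Genes
#' with no overlapping segment are absent from the result and are treated
#' downstream as missing data.
#'
#' @param segments Tibble of segments with columns `chrom`, `start`, `end`,
#'   `value` and optionally `sample` (multi-sample input is handled
#'   per sample).
#' @param genes Tibble of gene models with columns `symbol`, `chrom`,
#'   `start`, `end` (see [read_gene_models()]).
#' @return A tibble with columns `sample` (if present in `segments`), `gene`
#'   and `cn`.
#' @export
map_segments_to_genes <- function(segments, genes) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(segments)))
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(genes)))
  has_sample <- "sample" %in% names(segments)
  if (!has_sample) segments$sample <- "."

  one_sample <- function(seg) {
    hits <- lapply(split(seq_len(nrow(seg)), seg$chrom), function(idx) {
      chrom <- seg$chrom[idx[1L]]
      g <- genes[genes$chrom == chrom, , drop = FALSE]
      if (nrow(g) == 0L) return(NULL)
      q <- IRanges::IRanges(start = g$start, end = g$end)
      s <- IRanges::IRanges(start = seg$start[idx], end = seg$end[idx])
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0L) return(NULL)
      tibble(
        gene = g$symbol[S4Vectors::queryHits(ov)],
        cn = seg$value[idx][S4Vectors::subjectHits(ov)]
      )
    })
    hits <- bind_rows(hits)
    if (nrow(hits) == 0L) return(tibble(gene = character(), cn = numeric()))
    summarise(group_by(hits, .data$gene), cn = max(.data$cn), .groups = "drop")
  }

  out <- bind_rows(lapply(split(segments, segments$sample), function(seg) {
    res <- one_sample(seg)
    res$sample <- seg$sample[1L]
    res
  }))
  if (nrow(out) == 0L) {
    out <- tibble(sample = character(), gene = character(), cn = numeric())
  }
  out <- out[, c("sample", "gene", "cn")]
  if (!has_sample) out$sample <- NULL
  arrange(out, !!!rlang::syms(intersect(c("sample", "gene"), names(out))))
}

#' Build the shared network topology
#'
#' Restricts the interaction edge set to genes present in the data, then
#' extracts the largest connected component of the induced graph. The
#' resulting topology is simple, connected and undirected, and is shared by
#' every sample of a cohort; only node weights differ between samples. When
#' two components tie in size, the component containing the lexicographically
#' smallest gene symbol wins.
#'
#' @param ppi_edges Tibble of undirected interactions (`gene_a`, `gene_b`),
#'   e.g. from [read_ppi_edges()].
#' @param data_genes Character vector of gene symbols with data available;
#'   genes outside this set are removed before component extraction.
#' @return A `cn_topology` object wrapping an igraph graph.
#' @export
build_topology <- function(ppi_edges, data_genes) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(ppi_edges)))
  data_genes <- unique(as.character(data_genes))
  if (length(data_genes) == 0L) abort("data_genes is empty")

  ppi_genes <- unique(c(ppi_edges$gene_a, ppi_edges$gene_b))
  common <- intersect(ppi_genes, data_genes)
  if (length(common) == 0L) abort("no overlap between PPI and data genes")

  keep <- ppi_edges$gene_a %in% common & ppi_edges$gene_b %in% common
  sub <- ppi_edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                     vertices = data.frame(name = common))
  g <- igraph::simplify(g)

  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # deterministic tie-break: component holding the smallest gene symbol
    first_member <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, "")
    best <- best[order(first_member)][1L]
  }
  members <- igraph::V(g)$name[comp$membership == best]
  if (length(members) < 3L)
    abort("degenerate topology: largest connected component has fewer than 3 genes")
  lcc <- igraph::induced_subgraph(g, members)
  # stable vertex order: lexicographic by symbol
  lcc <- igraph::permute(lcc, order(order(igraph::V(lcc)$name)))
  new_topology(lcc)
}

new_topology <- function(graph) {
  structure(list(graph = graph), class = "cn_topology")
}

#' Construct a topology directly from an edge table
#'
#' Builds a `cn_topology` from an explicit edge list without component
#' extraction. The graph must be simple and connected (self-loops and
#' duplicate edges are removed; disconnection is an error). Useful for small
#' hand-built networks; cohort topologies normally come from
#' [build_topology()].
#'
#' @param edges Tibble with columns `gene_a`, `gene_b`.
#' @return A `cn_topology`.
#' @export
as_topology <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  g <- igraph::simplify(igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE))
  if (!igraph::is_connected(g)) abort("topology must be connected")
  g <- igraph::permute(g, order(order(igraph::V(g)$name)))
  new_topology(g)
}

#' @export
print.cn_topology <- function(x, ...) {
  cat(sprintf("<cn_topology> %d genes, %d interactions, mean degree %.2f\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              2 * igraph::ecount(x$graph) / igraph::vcount(x$graph)))
  invisible(x)
}

#' Genes of a topology
#' @param topology A `cn_topology`.
#' @return Character vector of gene symbols in vertex order.
#' @export
topology_genes <- function(topology) {
  stopifnot(inherits(topology, "cn_topology"))
  igraph::V(topology$graph)$name
}

#' Edge table of a topology
#' @param topology A `cn_topology`.
#' @return Tibble with columns `gene_a`, `gene_b`.
#' @export
topology_edges <- function(topology) {
  stopifnot(inherits(topology, "cn_topology"))
  el <- igraph::as_edgelist(topology$graph)
  tibble(gene_a = pmin(el[, 1L], el[, 2L]), gene_b = pmax(el[, 1L], el[, 2L]))
}

#' Attach per-sample copy-number weights to a topology
#'
#' Converts gene copy-number values into positive node weights via the
#' affine translation `w = CN + 1`, so that a homozygous deletion (CN = 0)
#' still carries weight 1. Every gene of the topology must have a value;
#' genes with missing data must be removed before [build_topology()].
#'
#' @param topology A `cn_topology`.
#' @param cn Copy-number values: a named numeric vector, or a tibble with
#'   columns `gene` and `cn`.
#' @param sample Optional sample identifier attached to the result.
#' @return A `cn_network` object (fixed topology plus node weights).
#' @export
attach_weights <- function(topology, cn, sample = NA_character_) {
  stopifnot(inherits(topology, "cn_topology"))
  if (is.data.frame(cn)) {
    stopifnot(all(c("gene", "cn") %in% names(cn)))
    cn <- setNames(cn$cn, cn$gene)
  }
  genes <- topology_genes(topology)
  missing_genes <- setdiff(genes, names(cn))
  if (length(missing_genes) > 0L)
    abort(paste0("no copy-number value for gene(s): ",
                 paste(head(missing_genes, 5L), collapse = ", "),
                 if (length(missing_genes) > 5L) sprintf(" (+%d more)", length(missing_genes) - 5L) else ""))
  vals <- unname(cn[genes])
  if (any(!is.finite(vals))) abort("non-finite copy-number value")
  if (any(vals < 0)) abort("negative copy-number value")
  if (any(vals != floor(vals))) {
    warn("non-integer copy-number values floored to integers")
    vals <- floor(vals)
  }
  structure(
    list(topology = topology,
         cn = setNames(vals, genes),
         weights = setNames(vals + 1, genes),
         sample = sample),
    class = "cn_network"
  )
}

#' @export
print.cn_network <- function(x, ...) {
  cat(sprintf("<cn_network> sample %s: %d genes, weights in [%g, %g]\n",
              x$sample, length(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}
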