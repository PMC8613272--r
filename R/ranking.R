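#' Between-group change in average scalar curvature
#'
#' For every gene, the unweighted mean scalar curvature over the samples of
#' group A minus the mean over group B. Large positive or negative values
#' flag genes whose local feedback connectivity differs most between the
#' groups (e.g. low- vs high-risk strata).
#'
#' @param profiles Named list of `curvature_profile` objects sharing one
#'   topology, or a wide scalar-curvature tibble from
#'   [scalar_curvature_matrix()].
#' @param group_a,group_b Disjoint, non-empty character vectors of sample
#'   names.
#' @return Tibble with columns `gene`, `delta`, sorted by decreasing `delta`.
#' @export
delta_scalar_curvature <- function(profiles, group_a, group_b) {
  mat <- as_kappa_matrix(profiles)
  if (length(group_a) == 0L || length(group_b) == 0L)
    abort("both groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L)
    abort("groups must be disjoint")
  missing_s <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing_s) > 0L)
    abort(paste0("no curvature profile for sample(s): ",
                 paste(head(missing_s, 5L), collapse = ", ")))
  delta <- rowMeans(mat[, group_a, drop = FALSE]) -
    rowMeans(mat[, group_b, drop = FALSE])
  arrange(tibble(gene = rownames(mat), delta = unname(delta)), desc(.data$delta))
}

#' Curvature change against the unweighted reference topology
#'
#' Computes scalar curvature once on the bare topology (all node weights 1)
#' and returns, per gene, the cohort-mean scalar curvature minus this
#' reference value — a measure of discordance between the copy-number-
#' weighted networks and their underlying connectivity structure.
#'
#' @param profiles Profiles as in [delta_scalar_curvature()].
#' @param topology The shared `cn_topology`.
#' @return Tibble with columns `gene`, `delta`, sorted by decreasing `delta`.
#' @export
reference_topology_delta <- function(profiles, topology) {
  mat <- as_kappa_matrix(profiles)
  stopifnot(inherits(topology, "cn_topology"))
  genes <- topology_genes(topology)
  if (!identical(sort(genes), sort(rownames(mat))))
    abort("profiles do not match the topology gene set")
  ref_net <- attach_weights(topology, setNames(rep(1, length(genes)), genes),
                            sample = "reference")
  ref <- curvature_profile(ref_net)
  ref_kappa <- setNames(ref$nodes$kappa, ref$nodes$gene)
  delta <- rowMeans(mat) - ref_kappa[rownames(mat)]
  arrange(tibble(gene = rownames(mat), delta = unname(delta)), desc(.data$delta))
}

#' Top positive and negative curvature-change genes
#'
#' Selects the `k` genes with the largest positive change (sorted
#' descending) and the `k` with the largest negative change (sorted
#' ascending, i.e. most negative first). Genes with exactly zero change are
#' excluded from both lists; ties are broken by gene symbol.
#'
#' @param delta Tibble with columns `gene`, `delta` (from
#'   [delta_scalar_curvature()] or [reference_topology_delta()]).
#' @param k Number of genes per direction, default 50.
#' @return Tibble with columns `rank` (1-based within direction), `gene`,
#'   `delta`, `direction` (`"positive"`/`"negative"`).
#' @export
top_k_ranking <- function(delta, k = 50L) {
  stopifnot(all(c("gene", "delta") %in% names(delta)), nrow(delta) > 0L)
  pos <- filter(delta, .data$delta > 0)
  pos <- head(arrange(pos, desc(.data$delta), .data$gene), k)
  neg <- filter(delta, .data$delta < 0)
  neg <- head(arrange(neg, .data$delta, .data$gene), k)
  bind_rows(
    mutate(pos, rank = row_number(), direction = "positive"),
    mutate(neg, rank = row_number(), direction = "negative")
  )[, c("rank", "gene", "delta", "direction")]
}

#' Run the standard set of curvature-change comparisons
#'
#' Convenience wrapper producing ranked gene lists for the comparisons of a
#' typical cohort analysis: `risk` (low- vs high-curvature strata), `os`
#' (alive vs dead at last follow-up), `pm` (primary vs metastasis) and `ref`
#' (cohort mean vs unweighted topology), where the needed labels exist.
#'
#' @param profiles Named list of `curvature_profile` objects.
#' @param topology The shared `cn_topology`.
#' @param split Optional `stratified_cohort` from [percentile_split()]
#'   (enables `risk`).
#' @param clinical Optional clinical tibble; a logical-like `vital_status` or
#'   `event` column enables `os`, a `sample_type` column with values
#'   `primary`/`metastasis` enables `pm`.
#' @param k Genes per direction, default 50.
#' @return Tibble with columns `comparison`, `rank`, `gene`, `delta`,
#'   `direction`.
#' @export
rank_gene_comparisons <- function(profiles, topology, split = NULL,
                                  clinical = NULL, k = 50L) {
  out <- list()
  if (!is.null(split)) {
    low <- split$sample[split$group == "low"]
    high <- split$sample[split$group == "high"]
    d <- delta_scalar_curvature(profiles, low, high)
    out$risk <- mutate(top_k_ranking(d, k), comparison = "risk")
  }
  if (!is.null(clinical)) {
    ev_col <- intersect(c("vital_status", "event"), names(clinical))[1]
    if (!is.na(ev_col)) {
      dead <- as.logical(clinical[[ev_col]])
      a <- clinical$sample[!dead]
      b <- clinical$sample[dead]
      if (length(a) > 0L && length(b) > 0L) {
        d <- delta_scalar_curvature(profiles, a, b)
        out$os <- mutate(top_k_ranking(d, k), comparison = "os")
      }
    }
    if ("sample_type" %in% names(clinical)) {
      a <- clinical$sample[clinical$sample_type == "primary"]
      b <- clinical$sample[clinical$sample_type == "metastasis"]
      if (length(a) > 0L && length(b) > 0L) {
        d <- delta_scalar_curvature(profiles, a, b)
        out$pm <- mutate(top_k_ranking(d, k), comparison = "pm")
      }
    }
  }
  d <- reference_topology_delta(profiles, topology)
  out$ref <- mutate(top_k_ranking(d, k), comparison = "ref")
  res <- bind_rows(out)
  res[, c("comparison", "rank", "gene", "delta", "direction")]
}

as_kappa_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    stopifnot("gene" %in% names(profiles))
    mat <- as.matrix(profiles[setdiff(names(profiles), "gene")])
    rownames(mat) <- profiles$gene
    return(mat)
  }
  check_shared_topology(profiles)
  mat <- vapply(profiles, function(p) p$nodes$kappa,
                numeric(nrow(profiles[[1L]]$nodes)))
  rownames(mat) <- profiles[[1L]]$nodes$gene
  mat
}
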