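#' Run the full curvature analysis pipeline
#'
#' Composes the complete analysis: read inputs, build the shared topology
#' (largest connected component of the interaction graph restricted to genes
#' with data), compute per-sample curvature profiles, stratify by total
#' curvature at the `q`-quantile, run the Kaplan-Meier / log-rank comparison,
#' rank genes by between-group curvature change, and write fixed-layout TSV
#' outputs plus a provenance manifest. Outputs are deterministic given
#' identical inputs and parameters.
#'
#' @param ppi Path to a PPI edge list, or a tibble from [read_ppi_edges()].
#' @param cn Path to a copy-number matrix, or a wide tibble from
#'   [read_cn_matrix()]. Alternatively supply `seg` + `genes`.
#' @param clinical Optional path to a clinical TSV, or a tibble from
#'   [read_clinical()]; enables the survival and risk-ranking stages.
#' @param seg,genes Optional segment file and gene-model file (used when
#'   `cn` is `NULL`): segments are mapped to genes by maximum overlapping
#'   value.
#' @param out_dir Output directory (created if needed).
#' @param q Stratification quantile, default 0.25.
#' @param k Genes per ranking direction, default 50.
#' @param ppi_dialect Dialect for [read_ppi_edges()] when `ppi` is a path.
#' @param keep_samples Optional character vector restricting the samples
#'   analysed (e.g. an explicit replicate keep-list). When patient replicate
#'   handling is needed and no list is given, all samples are kept.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters for upstream simulation).
#' @return Invisibly, a list with `topology`, `profiles`, `totals`, `split`,
#'   `logrank`, `rankings`, `manifest` and the output file paths.
#' @export
run_pipeline <- function(ppi, cn = NULL, clinical = NULL, seg = NULL,
                         genes = NULL, out_dir, q = 0.25, k = 50L,
                         ppi_dialect = "two_column", keep_samples = NULL,
                         seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inputs <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  ppi_tbl <- stage("read_ppi", {
    if (is.character(ppi)) {
      inputs$ppi <- ppi
      read_ppi_edges(ppi, dialect = ppi_dialect)
    } else ppi
  })

  cn_tbl <- stage("read_cn", {
    if (is.null(cn)) {
      if (is.null(seg) || is.null(genes))
        abort("either cn or both seg and genes must be supplied")
      seg_tbl <- if (is.character(seg)) { inputs$seg <- seg; read_seg(seg) } else seg
      gm <- if (is.character(genes)) { inputs$genes <- genes; read_gene_models(genes) } else genes
      mapped <- map_segments_to_genes(seg_tbl, gm)
      tidyr::pivot_wider(mapped, names_from = "sample", values_from = "cn")
    } else if (is.character(cn)) {
      inputs$cn <- cn
      read_cn_matrix(cn)
    } else cn
  })

  clin_tbl <- stage("read_clinical", {
    if (is.character(clinical)) {
      if (!file.exists(clinical))
        abort(paste0("clinical file not found: ", clinical))
      inputs$clinical <- clinical
      read_clinical(clinical)
    } else clinical
  })

  samples <- setdiff(names(cn_tbl), "gene")
  if (!is.null(keep_samples)) {
    samples <- intersect(samples, keep_samples)
    cn_tbl <- cn_tbl[c("gene", samples)]
  }
  # genes with missing data are removed before component extraction
  complete <- stats::complete.cases(cn_tbl[samples])
  cn_tbl <- cn_tbl[complete, ]

  topo <- stage("build_topology", build_topology(ppi_tbl, cn_tbl$gene))
  profs <- stage("curvature", curvature_profiles(topo, cn_tbl))
  totals <- total_curvatures(profs)

  paths <- character()
  write_out <- function(x, file) {
    p <- file.path(out_dir, file)
    num <- vapply(x, is.numeric, TRUE)
    x[num] <- lapply(x[num], function(col) {
      ifelse(col == round(col), format(col, scientific = FALSE, trim = TRUE),
             format(signif(col, 9), scientific = FALSE, trim = TRUE,
                    digits = 9))
    })
    readr::write_tsv(x, p, progress = FALSE)
    paths[[file]] <<- p
    p
  }

  write_out(totals, "total_curvature.tsv")
  write_out(scalar_curvature_matrix(profs), "scalar_curvature.tsv")
  edge_tbl <- bind_rows(lapply(profs, function(p)
    mutate(p$edges[, c("gene_a", "gene_b", "kappa")], sample = p$sample)))
  write_out(edge_tbl[, c("sample", "gene_a", "gene_b", "kappa")],
            "edge_curvature.tsv")

  split <- NULL
  lr <- NULL
  if (!is.null(clin_tbl)) {
    split <- stage("survival", {
      sp <- percentile_split(
        rename(totals, value = "total_kappa"), q = q, quiet = TRUE)
      joined <- left_join(as_tibble(sp), clin_tbl, by = "sample")
      lr <- logrank_test(joined)
      km <- bind_rows(lapply(base::split(joined, joined$group), function(gr)
        mutate(km_estimator(gr), group = gr$group[1L])))
      write_out(km[, c("group", "time", "n_risk", "n_event", "n_censor",
                       "survival")], "km_curves.tsv")
      write_out(tibble(
        feature = "total_kappa", q = q,
        cutoff = attr(sp, "cutoff"),
        quantile_type = attr(sp, "quantile_type"),
        n_low = sum(sp$group == "low"), n_high = sum(sp$group == "high"),
        chisq = lr$statistic, p_value = lr$p_value
      ), "logrank.tsv")
      sp
    })
  }

  rankings <- stage("rank_genes",
                    rank_gene_comparisons(profs, topo, split = split,
                                          clinical = clin_tbl, k = k))
  write_out(rankings, "gene_rankings.tsv")

  manifest <- list(
    tool = "netcurv",
    version = as.character(utils::packageVersion("netcurv")),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = list(q = q, k = k, quantile_type = 7,
                      membership_rule = "value <= cutoff -> low",
                      ppi_dialect = ppi_dialect),
    n_genes = length(topology_genes(topo)),
    n_edges = nrow(topology_edges(topo)),
    n_samples = length(samples),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(topology = topo, profiles = profs, totals = totals,
                 split = split, logrank = lr, rankings = rankings,
                 manifest = manifest, paths = c(paths, manifest = manifest_path)))
}
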