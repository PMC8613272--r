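#' Configuration for synthetic cohort simulation
#'
#' Bundles the generator parameters with their defaults: a connected
#' scale-free-like interaction topology near mean degree 5.57, integer
#' copy numbers with a diploid baseline of 2, clustered amplifications up to
#' CN 38 and occasional deletions (CN 0 or 1), and exponential survival whose
#' log-hazard decreases in the standardized total network curvature (so low
#' curvature means poorer prognosis).
#'
#' All randomness flows from `seed` through a fixed splitting scheme:
#' topology uses `seed`, the copy-number cohort `seed + 1`, survival
#' `seed + 2`.
#'
#' @param n_genes Number of genes (nodes), default 150.
#' @param n_samples Cohort size, default 120.
#' @param topology_model `"barabasi_albert"` (default), `"watts_strogatz"`
#'   or `"erdos_renyi"`.
#' @param target_mean_degree Target average node degree, default 5.57.
#' @param baseline_cn Unaltered copy number, default 2 (diploid).
#' @param amp_prob Marginal per-gene probability of amplification in a
#'   sample, default 0.12.
#' @param amp_cn_max Largest copy number reachable by amplification,
#'   default 38.
#' @param del_prob Per-gene probability of deletion, default 0.08.
#' @param hazard_alpha Baseline log-hazard (per month); the default gives a
#'   median survival of 15 months at average curvature.
#' @param hazard_beta Log-hazard coefficient on the standardized total
#'   curvature (positive couples low curvature to high hazard), default 1.
#' @param censoring_rate Expected fraction of censored records, default 0.3.
#' @param seed Integer seed; mandatory.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 150L, n_samples = 120L,
                       topology_model = c("barabasi_albert", "watts_strogatz",
                                          "erdos_renyi"),
                       target_mean_degree = 5.57,
                       baseline_cn = 2L, amp_prob = 0.12, amp_cn_max = 38L,
                       del_prob = 0.08,
                       hazard_alpha = log(log(2) / 15), hazard_beta = 1,
                       censoring_rate = 0.3, seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L ||
      !is.finite(seed)) abort("a seed is mandatory")
  topology_model <- match.arg(topology_model)
  probs <- c(amp_prob = amp_prob, del_prob = del_prob,
             censoring_rate = censoring_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_genes < 10L) abort("n_genes must be at least 10")
  structure(
    list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
         topology_model = topology_model,
         target_mean_degree = target_mean_degree,
         baseline_cn = as.integer(baseline_cn), amp_prob = amp_prob,
         amp_cn_max = as.integer(amp_cn_max), del_prob = del_prob,
         hazard_alpha = hazard_alpha, hazard_beta = hazard_beta,
         censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a connected interaction topology
#'
#' Generates a simple connected undirected graph near the configured mean
#' degree. The default preferential-attachment model yields the heavy-tailed
#' degree distribution typical of protein interaction networks; small-world
#' and uniform random alternatives are available. Generation retries with an
#' advanced seed (at most 100 times) if a draw is disconnected.
#'
#' @param config A [sim_config()].
#' @return A `cn_topology` with genes named `G0001`, `G0002`, ...
#' @export
simulate_topology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  deg <- config$target_mean_degree
  for (attempt in 0:99) {
    set.seed(config$seed + attempt)
    g <- switch(config$topology_model,
      barabasi_albert = {
        base <- floor(deg / 2)
        frac <- deg / 2 - base
        ms <- pmax(1L, base + rbinom(n, 1L, frac))
        ms[1L] <- 0L
        igraph::sample_pa(n, out.seq = ms, directed = FALSE)
      },
      watts_strogatz = igraph::sample_smallworld(1, n, max(1L, round(deg / 2)), 0.05),
      erdos_renyi = igraph::sample_gnm(n, round(n * deg / 2))
    )
    g <- igraph::simplify(g)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- sprintf("G%04d", seq_len(n))
      return(new_topology(g))
    }
    inform(sprintf("disconnected draw, retrying with seed %d", config$seed + attempt + 1L))
  }
  abort("failed to generate a connected topology in 100 attempts")
}

#' Simulate a copy-number cohort on a topology
#'
#' Draws integer copy numbers per gene and sample. Each sample amplifies a
#' binomially drawn number of genes (marginal probability `amp_prob`),
#' chosen by growing random network neighbourhoods so that amplifications
#' cluster on connected gene sets — the spatial structure that creates
#' between-sample curvature signal. Amplified copy numbers follow a
#' geometric tail above baseline, clipped to `amp_cn_max`; deletions hit the
#' remaining genes independently with probability `del_prob` (CN 0 or 1).
#'
#' @param topology A `cn_topology` (from [simulate_topology()]).
#' @param config A [sim_config()].
#' @return Wide tibble: column `gene` plus one integer column per sample
#'   (`S001`, ...), all values in `[0, amp_cn_max]`.
#' @export
simulate_cn_cohort <- function(topology, config) {
  stopifnot(inherits(topology, "cn_topology"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- topology_genes(topology)
  n <- length(genes)
  g <- topology$graph
  nbrs <- lapply(seq_len(n), function(i) as.integer(igraph::neighbors(g, i)))

  draw_sample <- function() {
    cn <- rep(config$baseline_cn, n)
    n_amp <- rbinom(1L, n, config$amp_prob)
    chosen <- logical(n)
    while (sum(chosen) < n_amp) {
      center <- sample(which(!chosen), 1L)
      pool <- c(center, sample(nbrs[[center]]))
      pool <- pool[!chosen[pool]]
      need <- n_amp - sum(chosen)
      chosen[pool[seq_len(min(length(pool), need))]] <- TRUE
    }
    n_chosen <- sum(chosen)
    if (n_chosen > 0L) {
      amp <- config$baseline_cn + 1L + rgeom(n_chosen, 0.35)
      cn[chosen] <- pmin(amp, config$amp_cn_max)
    }
    eligible <- which(!chosen)
    del <- eligible[runif(length(eligible)) < config$del_prob]
    if (length(del) > 0L)
      cn[del] <- rbinom(length(del), 1L, 0.7) # mostly hemizygous (CN 1)
    as.integer(cn)
  }

  cols <- lapply(seq_len(config$n_samples), function(s) draw_sample())
  names(cols) <- sprintf("S%03d", seq_len(config$n_samples))
  as_tibble(c(list(gene = genes), cols))
}

#' Simulate survival records coupled to total curvature
#'
#' Draws exponential survival times with log-hazard
#' `alpha - beta * z(kappa_G)` where `z` standardizes the total curvatures
#' across the cohort, so with `beta > 0` low-curvature samples die sooner.
#' Censoring times are independent exponentials calibrated so that about
#' `censoring_rate` of baseline records are censored; a rate of 1 censors
#' every record.
#'
#' @param total_curvatures Tibble (`sample`, `total_kappa`) from
#'   [total_curvatures()], or a named numeric vector.
#' @param config A [sim_config()].
#' @return Clinical tibble with columns `sample`, `os_months`, `event`.
#' @export
simulate_survival <- function(total_curvatures, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.data.frame(total_curvatures)) {
    tk <- setNames(total_curvatures$total_kappa, total_curvatures$sample)
  } else {
    tk <- total_curvatures
  }
  if (length(tk) < 2L) abort("at least 2 samples are required")
  set.seed(config$seed + 2L)
  s <- stats::sd(tk)
  z <- if (s > 0) (tk - mean(tk)) / s else rep(0, length(tk))
  rate <- exp(config$hazard_alpha - config$hazard_beta * z)
  t_event <- rexp(length(tk), rate)
  cr <- config$censoring_rate
  if (cr >= 1) {
    os <- t_event
    event <- rep(FALSE, length(tk))
  } else if (cr <= 0) {
    os <- t_event
    event <- rep(TRUE, length(tk))
  } else {
    rate_c <- exp(config$hazard_alpha) * cr / (1 - cr)
    t_cens <- rexp(length(tk), rate_c)
    os <- pmin(t_event, t_cens)
    event <- t_event <= t_cens
  }
  tibble(sample = names(tk), os_months = unname(os), event = unname(event))
}

#' Simulate a full synthetic cohort
#'
#' Chains [simulate_topology()], [simulate_cn_cohort()], cohort curvature
#' ([curvature_profiles()]) and [simulate_survival()], and attaches simple
#' categorical labels (`sample_type` primary/metastasis, `vital_status`)
#' so that every downstream comparison is exercisable.
#'
#' @param config A [sim_config()].
#' @param profiles Compute curvature profiles (default `TRUE`; disable when
#'   only the inputs are needed).
#' @return A `sim_cohort` list: `topology`, `cn`, `profiles`, `totals`,
#'   `clinical`, `config`.
#' @export
simulate_cohort <- function(config, profiles = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  topo <- simulate_topology(config)
  cn <- simulate_cn_cohort(topo, config)
  prof <- NULL
  totals <- NULL
  clinical <- NULL
  if (profiles) {
    prof <- curvature_profiles(topo, cn)
    totals <- total_curvatures(prof)
    clinical <- simulate_survival(totals, config)
    set.seed(config$seed + 3L)
    clinical$sample_type <- ifelse(runif(nrow(clinical)) < 0.3,
                                   "primary", "metastasis")
    clinical$vital_status <- clinical$event
  }
  structure(list(topology = topo, cn = cn, profiles = prof, totals = totals,
                 clinical = clinical, config = config),
            class = "sim_cohort")
}

#' Write a synthetic cohort as a fixture file bundle
#'
#' Emits the cohort in exactly the dialects the package readers accept:
#' `ppi.tsv` (two-column edge list), `cn_matrix.tsv` (portal-style gene x
#' sample matrix with an Entrez column), `segments.seg` (per-sample segments
#' derived from runs of equal copy number along synthetic GRCh37-style gene
#' coordinates), `genes.bed` (4-column BED, 0-based half-open) and
#' `clinical.tsv`. Reading the bundle back reproduces the in-memory objects.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_fixture_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gm <- synthetic_gene_models(topology_genes(cohort$topology))

  paths <- c(
    ppi = file.path(dir, "ppi.tsv"),
    cn = file.path(dir, "cn_matrix.tsv"),
    seg = file.path(dir, "segments.seg"),
    genes = file.path(dir, "genes.bed"),
    clinical = file.path(dir, "clinical.tsv")
  )

  el <- topology_edges(cohort$topology)
  readr::write_tsv(el, paths["ppi"], col_names = FALSE)

  cn_out <- cohort$cn
  names(cn_out)[1L] <- "Hugo_Symbol"
  cn_out <- dplyr::bind_cols(cn_out[1L],
                             tibble(Entrez_Gene_Id = seq_len(nrow(cn_out))),
                             cn_out[-1L])
  readr::write_tsv(cn_out, paths["cn"])

  seg <- cn_runs_to_segments(cohort$cn, gm)
  readr::write_tsv(seg, paths["seg"])

  bed <- tibble(chrom = gm$chrom, start = gm$start - 1L, end = gm$end,
                name = gm$symbol)
  readr::write_tsv(bed, paths["genes"], col_names = FALSE)

  if (!is.null(cohort$clinical))
    readr::write_tsv(cohort$clinical, paths["clinical"])

  invisible(paths)
}

# deterministic synthetic GRCh37-style coordinates: genes laid out in order
# on 22 autosome labels, 100 kb genes spaced 1 Mb apart
synthetic_gene_models <- function(genes) {
  n <- length(genes)
  per_chrom <- ceiling(n / 22)
  idx <- seq_len(n) - 1L
  chrom <- paste0("chr", idx %/% per_chrom + 1L)
  pos <- idx %% per_chrom
  start <- pos * 1000000L + 1L
  tibble(symbol = genes, chrom = chrom, start = start, end = start + 99999L)
}

# run-length encode the CN vector of each sample along gene order per
# chromosome; segments tile the gene span without overlap, so max-overlap
# gene assignment recovers the matrix exactly
cn_runs_to_segments <- function(cn, gene_models) {
  samples <- setdiff(names(cn), "gene")
  gm <- gene_models[match(cn$gene, gene_models$symbol), ]
  out <- lapply(samples, function(s) {
    v <- cn[[s]]
    per_chrom <- lapply(split(seq_along(v), gm$chrom), function(ii) {
      ii <- ii[order(gm$start[ii])]
      r <- rle(v[ii])
      stops <- cumsum(r$lengths)
      starts <- c(1L, head(stops, -1L) + 1L)
      tibble(sample = s, chrom = gm$chrom[ii[1L]],
             start = gm$start[ii[starts]], end = gm$end[ii[stops]],
             value = r$values)
    })
    bind_rows(per_chrom)
  })
  arrange(bind_rows(out), .data$sample, .data$chrom, .data$start)
}

#' Read back a fixture bundle
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with elements `ppi`, `cn`, `seg`, `genes`, `clinical` (the
#'   clinical element is `NULL` when absent).
#' @export
read_fixture_bundle <- function(dir) {
  clin_path <- file.path(dir, "clinical.tsv")
  list(
    ppi = read_ppi_edges(file.path(dir, "ppi.tsv")),
    cn = read_cn_matrix(file.path(dir, "cn_matrix.tsv")),
    seg = read_seg(file.path(dir, "segments.seg")),
    genes = read_gene_models(file.path(dir, "genes.bed"), format = "bed"),
    clinical = if (file.exists(clin_path)) read_clinical(clin_path) else NULL
  )
}
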