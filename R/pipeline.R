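# Orchestration: one validated config drives simulate -> normalize -> de ->
# cluster -> enrich -> motif, writing TSV artifacts and a JSON run manifest.

#' Build and validate a pipeline run configuration
#'
#' Collects every stage parameter with its default: conglomerate FDR
#' threshold 0.02, K-means scan k = 6..14 with 30 repeats, 12 consensus
#' clusters, term-grouping overlap 0.70 with p < 0.03, promoter window
#' 1000 bp up / 200 bp down, motif scan threshold 0.80 of the maximum
#' log-odds with Z reporting cutoff 3, and one master seed fanned out to
#' per-stage streams.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param alpha,n_perm,window_size,n0 DE-stage parameters.
#' @param k_min,k_max,repeats,K Consensus-clustering parameters.
#' @param overlap_threshold,p_threshold,ease Enrichment parameters.
#' @param upstream_bp,downstream_bp Promoter window spec.
#' @param pwm_threshold,pseudocount,z_cut Motif-stage parameters.
#' @param simulate List of generator parameters (see [run_all()]), or
#'   `NULL` to run from files.
#' @param expression_path,design_path,promoter_path,pwm_path,pwm_dialect,
#'   annotation_path Input files when not simulating.
#' @return Validated list of class `RunConfig`.
#' @export
run_config <- function(outdir = "tempro_run", seed = 1L,
                       alpha = 0.02, n_perm = 1000L,
                       window_size = 101L, n0 = 10,
                       k_min = 6L, k_max = 14L, repeats = 30L, K = 12L,
                       overlap_threshold = 0.70, p_threshold = 0.03,
                       ease = FALSE,
                       upstream_bp = 1000L, downstream_bp = 200L,
                       pwm_threshold = 0.80, pseudocount = 0.01,
                       z_cut = 3,
                       simulate = list(),
                       expression_path = NULL, design_path = NULL,
                       promoter_path = NULL, pwm_path = NULL,
                       pwm_dialect = "jaspar", annotation_path = NULL) {
  cfg <- as.list(environment())
  checks <- c(
    alpha = alpha > 0 && alpha <= 1,
    n_perm = n_perm >= 100,
    window_size = window_size >= 3 && window_size %% 2 == 1,
    n0 = n0 >= 0,
    k_range = k_min >= 1 && k_min <= k_max,
    repeats = repeats >= 1,
    K = K >= 1,
    overlap_threshold = overlap_threshold > 0 && overlap_threshold <= 1,
    p_threshold = p_threshold > 0 && p_threshold <= 1,
    window = upstream_bp >= 0 && downstream_bp >= 0 &&
      upstream_bp + downstream_bp > 0,
    pwm_threshold = pwm_threshold > 0 && pwm_threshold <= 1,
    z_cut = z_cut > 0,
    seed = is.finite(seed))
  if (!all(checks))
    stop("invalid config parameter(s): ",
         paste(names(checks)[!checks], collapse = ", "), call. = FALSE)
  if (is.null(simulate) &&
      (is.null(expression_path) || is.null(design_path)))
    stop("either enable simulate or provide expression/design paths",
         call. = FALSE)
  class(cfg) <- "RunConfig"
  cfg
}

default_sim_params <- function() {
  list(n_genes_per_cluster = 30L, n_null = 300L, amplitude = 1,
       noise_sd = 0.25, group_sizes = c(4, 6, 5, 8, 8),
       baseline_range = c(4, 12), promoter_length = 1200L,
       planted_motif_rate = 3, background_site_rate = 0.5,
       n_terms = 24L, term_size_range = c(10, 40),
       enrichment_factor = 20)
}

#' Demo position weight matrices
#'
#' Four synthetic motifs of width 8 with strong consensus cores, used by
#' the simulation pipeline and examples. Labelled synthetic; they are not
#' curated database motifs.
#'
#' @return List of [pwm()] objects.
#' @export
demo_pwms <- function() {
  mk <- function(id, consensus) {
    L <- nchar(consensus)
    m <- matrix(2, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    idx <- match(strsplit(consensus, "")[[1L]], c("A", "C", "G", "T"))
    m[cbind(idx, seq_len(L))] <- 40
    pwm(id, m, dialect = "jaspar")
  }
  list(mk("SYN_M1", "TGACGTCA"), mk("SYN_M2", "GGGCGGGG"),
       mk("SYN_M3", "TTTCGCGC"), mk("SYN_M4", "CACGTGAC"))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> quantile + gene-wise normalization ->
#' differential expression -> consensus clustering -> term enrichment ->
#' motif Z scores, writing each stage's TSV outputs under
#' `config$outdir` plus a JSON manifest recording parameters, seeds and
#' stage counts. With `config$simulate` a list (possibly empty, meaning
#' defaults), inputs are generated by the synthetic-data module; motifs
#' are planted in consensus-recoverable clusters round-robin over the
#' demo PWMs.
#'
#' @param config A [run_config()].
#' @param verbose Print one progress line per stage.
#' @return The manifest (invisibly), also written to
#'   `outdir/manifest.json`.
#' @export
run_all <- function(config, verbose = TRUE) {
  if (!inherits(config, "RunConfig")) config <- do.call(run_config, config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("tempro")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "simulate")],
    stages = list())

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sp <- utils::modifyList(default_sim_params(), config$simulate)
    specs <- default_profile_specs(sp$n_genes_per_cluster, sp$amplitude,
                                   sp$noise_sd)
    sim <- simulate_expression(specs, n_null = sp$n_null,
                               group_sizes = sp$group_sizes,
                               baseline_range = sp$baseline_range,
                               seed = derive_seed(config$seed, "expr"))
    em <- sim$expression
    truth <- sim$truth
    pwms <- demo_pwms()
    cl_ids <- as.character(seq_along(specs))
    rates <- setNames(lapply(seq_along(cl_ids), function(i) {
      setNames(sp$planted_motif_rate,
               pwms[[(i - 1L) %% length(pwms) + 1L]]$motif_id)
    }), cl_ids)
    simp <- simulate_promoters(truth, pwms, length = sp$promoter_length,
                               planted_rates = rates,
                               background_rate = sp$background_site_rate,
                               seed = derive_seed(config$seed, "prom"))
    truth <- simp$truth
    sima <- simulate_annotations(truth, n_terms = sp$n_terms,
                                 term_size_range = sp$term_size_range,
                                 enrichment_factor = sp$enrichment_factor,
                                 seed = derive_seed(config$seed, "ann"))
    truth <- sima$truth
    promoters <- simp$promoters
    annotations <- sima$annotations
    write_expression(em, file.path(config$outdir, "expression.tsv"),
                     file.path(config$outdir, "design.tsv"))
    write_fasta_promoters(promoters,
                          file.path(config$outdir, "promoters.fa"))
    write_pwms(pwms, file.path(config$outdir, "motifs.pfm"), "jaspar")
    write_annotations(annotations,
                      file.path(config$outdir, "annotations.gmt"))
    write.table(data.frame(gene_id = names(truth$gene_cluster),
                           cluster = truth$gene_cluster),
                file.path(config$outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$simulate <- list(genes = nrow(em$values),
                                     arrays = ncol(em$values),
                                     planted = sum(truth$gene_cluster !=
                                                     "null"))
    log_stage(verbose, "simulate: %d genes x %d arrays",
              nrow(em$values), ncol(em$values))
  } else {
    em <- read_expression(config$expression_path, config$design_path)
    promoters <- if (!is.null(config$promoter_path))
      read_fasta_promoters(config$promoter_path, config$upstream_bp,
                           config$downstream_bp) else NULL
    pwms <- if (!is.null(config$pwm_path))
      read_pwms(config$pwm_path, config$pwm_dialect) else NULL
    annotations <- if (!is.null(config$annotation_path))
      read_annotations(config$annotation_path) else NULL
    truth <- NULL
  }

  # --- normalize ----------------------------------------------------------
  em_q <- quantile_normalize(em)
  norm <- normalize_gene_wise(em_q)
  write_expression(expression_matrix(norm$values, norm$design),
                   file.path(config$outdir, "normalized.tsv"))
  writeLines(rownames(norm$values)[norm$degenerate],
             file.path(config$outdir, "degenerate_genes.txt"))
  manifest$stages$normalize <- list(genes = nrow(norm$values),
                                    degenerate = sum(norm$degenerate))
  log_stage(verbose, "normalize: %d genes (%d degenerate)",
            nrow(norm$values), sum(norm$degenerate))

  # --- differential expression -------------------------------------------
  de <- de_analysis(em_q, alpha = config$alpha, n_perm = config$n_perm,
                    window_size = min(config$window_size,
                                      nrow(em_q$values) -
                                        (1 - nrow(em_q$values) %% 2)),
                    n0 = config$n0, seed = derive_seed(config$seed, "de"))
  write.table(de, file.path(config$outdir, "de_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(de_genes(de), file.path(config$outdir, "de_genes.txt"))
  manifest$stages$de <- list(genes_in = nrow(de),
                             genes_called = sum(de$de),
                             alpha = config$alpha)
  log_stage(verbose, "de: %d of %d genes at FDR <= %g", sum(de$de),
            nrow(de), config$alpha)

  # --- consensus clustering ----------------------------------------------
  de_ids <- de_genes(de)
  norm_de <- norm
  norm_de$values <- norm$values[de_ids, , drop = FALSE]
  norm_de$degenerate <- norm$degenerate[de_ids]
  norm_de$center <- norm$center[de_ids]
  norm_de$scale <- norm$scale[de_ids]
  ps <- kmeans_scan(norm_de, k_min = config$k_min, k_max = config$k_max,
                    repeats = config$repeats,
                    seed = derive_seed(config$seed, "kmeans"))
  co <- co_occurrence(ps)
  assignment <- consensus_cut(co, K = config$K, norm = norm_de)
  write.table(data.frame(gene_id = names(assignment$membership),
                         cluster = assignment$membership),
              file.path(config$outdir, "membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  prof <- assignment$profiles
  write.table(data.frame(cluster = rownames(prof$mean),
                         stat = "mean", prof$mean, check.names = FALSE),
              file.path(config$outdir, "profiles_mean.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(cluster = rownames(prof$sd),
                         stat = "sd", prof$sd, check.names = FALSE),
              file.path(config$outdir, "profiles_sd.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  export_heatmap_tables(assignment, norm_de,
                        dir = file.path(config$outdir, "heatmaps"))
  manifest$stages$cluster <- list(genes = length(assignment$membership),
                                  runs = ncol(ps$labels), K = config$K)
  log_stage(verbose, "cluster: %d genes, %d runs, K = %d",
            length(assignment$membership), ncol(ps$labels), config$K)

  # --- enrichment ---------------------------------------------------------
  if (!is.null(annotations)) {
    enr <- enrich_clusters(assignment, de_ids, annotations,
                           overlap_threshold = config$overlap_threshold,
                           p_threshold = config$p_threshold,
                           ease = config$ease)
    summ <- attr(enr, "summary")
    if (is.null(summ)) summ <- data.frame()
    write.table(summ, file.path(config$outdir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$enrich <- list(terms = length(annotations),
                                   significant_groups =
                                     if (nrow(summ)) nrow(summ) else 0L)
    log_stage(verbose, "enrich: %d significant term groups",
              if (nrow(summ)) nrow(summ) else 0L)
  }

  # --- motifs -------------------------------------------------------------
  if (!is.null(promoters) && !is.null(pwms)) {
    bg_ids <- intersect(de_ids, names(promoters$sequences))
    bg <- promoter_set(promoters$sequences[bg_ids],
                       promoters$upstream_bp, promoters$downstream_bp)
    freqs <- base_frequencies(bg)
    scorers <- lapply(pwms, build_scorer, background_freqs = freqs,
                      pseudocount = config$pseudocount,
                      threshold_fraction = config$pwm_threshold)
    zm <- zscore_matrix(assignment, bg, scorers, z_cut = config$z_cut)
    write.table(data.frame(cluster = rownames(zm$z), zm$z,
                           check.names = FALSE),
                file.path(config$outdir, "zmatrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(zm$calls, file.path(config$outdir, "motif_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(zm$z) >= 3L) {
      pca <- tryCatch(zmatrix_pca(zm), error = function(e) NULL)
      if (!is.null(pca))
        write.table(data.frame(cluster = rownames(pca$scores),
                               pca$scores),
                    file.path(config$outdir, "zmatrix_pca.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$motif <- list(motifs = length(scorers),
                                  calls = nrow(zm$calls))
    log_stage(verbose, "motif: %d motifs, %d calls", length(scorers),
              nrow(zm$calls))
  }

  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
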