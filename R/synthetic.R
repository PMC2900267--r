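# Synthetic data with planted structure: time-profile clusters, null genes,
# promoters carrying planted motif sites, annotation terms enriched in
# chosen clusters. Ground truth travels with the data so recovery can be
# scored.

#' Derive a reproducible child seed for a named stage
#'
#' One master seed fans out to per-stage streams so that stages can be
#' re-run in isolation. Deterministic, stays below 2^31.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name (character scalar).
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Specify a planted expression time profile
#'
#' @param cluster_id Integer cluster label.
#' @param profile Per-group mean normalized expression, values in [-1, 1];
#'   length must equal the number of time groups.
#' @param n_genes Number of genes carrying the profile.
#' @param amplitude Effect size in log2 units multiplying the profile.
#' @param noise_sd Gaussian noise standard deviation, log2 units.
#' @return Object of class `ProfileSpec`.
#' @export
profile_spec <- function(cluster_id, profile, n_genes, amplitude = 1,
                         noise_sd = 0.25) {
  if (any(abs(profile) > 1)) stop("profile values must lie in [-1, 1]",
                                  call. = FALSE)
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(list(cluster_id = as.integer(cluster_id),
                 profile = as.numeric(profile),
                 n_genes = as.integer(n_genes),
                 amplitude = amplitude, noise_sd = noise_sd),
            class = "ProfileSpec")
}

#' Default planted time profiles
#'
#' Twelve qualitatively distinct five-point time profiles spanning the
#' shapes seen in injury time courses: late down-regulation with varying
#' early response, transient early up-regulation, sustained up-regulation,
#' late up-regulation, early-down-then-up, and strong early down-regulation
#' with partial recovery.
#'
#' @param n_genes Genes per profile.
#' @param amplitude,noise_sd Passed to [profile_spec()]. The default
#'   amplitude of 1 log2 unit with noise_sd 0.25 gives a 4x
#'   signal-to-noise ratio, a clearly separated regime.
#' @return List of 12 `ProfileSpec`s.
#' @export
default_profile_specs <- function(n_genes = 30, amplitude = 1,
                                  noise_sd = 0.25) {
  shapes <- list(
    c( 0.0,  0.0,  0.0, -1.0, -1.0),   # late down, flat early
    c( 1.0,  0.0,  0.5, -0.5, -1.0),   # progressive down from high
    c(-0.5, -1.0,  1.0,  0.0, -1.0),   # mid spike, late down
    c( 0.0,  1.0,  1.0, -1.0, -1.0),   # early up then late down
    c(-1.0,  1.0,  0.0,  0.0, -1.0),   # transient early up
    c(-1.0,  1.0,  1.0,  1.0,  1.0),   # sustained up from day 2
    c(-1.0,  0.5, -1.0,  0.5,  1.0),   # up with mid dip
    c(-1.0, -0.5,  0.0,  0.5,  1.0),   # late up, gradual
    c(-1.0, -1.0, -1.0,  0.5,  1.0),   # late up, delayed onset
    c( 0.5, -1.0, -1.0,  0.5,  1.0),   # early down then up
    c( 1.0,  1.0, -1.0,  0.0,  1.0),   # mid dip from high
    c( 1.0, -1.0, -0.5, -0.25, 0.0))   # strong early down, partial recovery
  lapply(seq_along(shapes), function(i)
    profile_spec(i, shapes[[i]], n_genes, amplitude, noise_sd))
}

new_sim_truth <- function(gene_cluster, cluster_motifs = list(),
                          cluster_terms = list()) {
  if (anyDuplicated(names(gene_cluster)))
    stop("a gene appears more than once in the truth", call. = FALSE)
  structure(list(gene_cluster = gene_cluster,
                 cluster_motifs = cluster_motifs,
                 cluster_terms = cluster_terms),
            class = "SimTruth")
}

#' @export
print.SimTruth <- function(x, ...) {
  planted <- sum(x$gene_cluster != "null")
  cat(sprintf("SimTruth: %d genes (%d planted, %d null), %d clusters\n",
              length(x$gene_cluster), planted,
              sum(x$gene_cluster == "null"),
              length(setdiff(unique(x$gene_cluster), "null"))))
  invisible(x)
}

#' Simulate an expression matrix with planted time profiles
#'
#' Planted genes follow `y_gm = b_g + amplitude * profile[group(m)] + e`,
#' null genes `y_gm = b_g + e`, with `e ~ Normal(0, noise_sd^2)` i.i.d. on
#' the log2 scale and baseline `b_g` uniform over `baseline_range`. The
#' default group sizes 4, 6, 5, 8, 8 are the unbalanced five-time-point
#' design (days 0, 2, 7, 21, 60) the pipeline targets.
#'
#' @param specs List of [profile_spec()]s (may be empty).
#' @param n_null Number of null genes.
#' @param group_sizes Arrays per time group.
#' @param baseline_range Range of the uniform per-gene baseline, log2 units.
#' @param null_noise_sd Noise sd for null genes.
#' @param group_labels Group names; defaults to the day labels when 5
#'   groups.
#' @param seed Integer seed.
#' @return List with elements `expression` (an [expression_matrix()]) and
#'   `truth` (a `SimTruth`).
#' @export
simulate_expression <- function(specs = default_profile_specs(),
                                n_null = 0L,
                                group_sizes = c(4, 6, 5, 8, 8),
                                baseline_range = c(4, 12),
                                null_noise_sd = 0.25,
                                group_labels = NULL,
                                seed = 1L) {
  n_groups <- length(group_sizes)
  for (sp in specs)
    if (length(sp$profile) != n_groups)
      stop("profile length ", length(sp$profile),
           " does not match ", n_groups, " groups", call. = FALSE)
  if (is.null(group_labels))
    group_labels <- if (n_groups == 5L)
      c("day0", "day2", "day7", "day21", "day60")
    else paste0("grp", seq_len(n_groups))
  n_arrays <- sum(group_sizes)
  grp <- rep(seq_len(n_groups), group_sizes)
  n_planted <- sum(vapply(specs, `[[`, 0L, "n_genes"))
  n_genes <- n_planted + n_null
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  array_ids <- sprintf("a%02d", seq_len(n_arrays))
  cluster_of <- c(unlist(lapply(specs, function(sp)
    rep(sp$cluster_id, sp$n_genes))), rep(NA_integer_, n_null))

  with_seed(seed, {
    baseline <- runif(n_genes, baseline_range[1], baseline_range[2])
    vals <- matrix(0, n_genes, n_arrays,
                   dimnames = list(gene_ids, array_ids))
    row <- 0L
    for (sp in specs) {
      idx <- row + seq_len(sp$n_genes)
      mu <- sp$amplitude * sp$profile[grp]       # length n_arrays
      vals[idx, ] <- baseline[idx] +
        matrix(mu, length(idx), n_arrays, byrow = TRUE) +
        matrix(rnorm(length(idx) * n_arrays, 0, sp$noise_sd),
               length(idx), n_arrays)
      row <- row + sp$n_genes
    }
    if (n_null > 0L) {
      idx <- row + seq_len(n_null)
      vals[idx, ] <- baseline[idx] +
        matrix(rnorm(n_null * n_arrays, 0, null_noise_sd), n_null, n_arrays)
    }
  })

  design <- data.frame(array_id = array_ids, group = group_labels[grp])
  truth_labels <- ifelse(is.na(cluster_of), "null",
                         as.character(cluster_of))
  names(truth_labels) <- gene_ids
  list(expression = expression_matrix(vals, design),
       truth = new_sim_truth(truth_labels))
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1L]]), collapse = ""), ""))
}

sample_site <- function(mat) {
  probs <- sweep(mat, 2, colSums(mat), "/")
  paste(apply(probs, 2, function(p)
    sample(c("A", "C", "G", "T"), 1L, prob = p)), collapse = "")
}

#' Simulate promoter sequences with planted motif sites
#'
#' Background sequence is i.i.d. from `base_composition`; motif sites are
#' inserted at uniform non-overlapping positions on a random strand, each
#' site sampled column-wise from the motif's position-specific base
#' distribution. Every promoter receives `Poisson(background_rate)` sites
#' of every motif; promoters of a cluster listed in `planted_rates`
#' additionally receive `Poisson(rate)` sites of the named motif.
#'
#' @param truth A `SimTruth` from [simulate_expression()].
#' @param pwms List of `PWM`s available for planting.
#' @param length Promoter length in bp; the default 1200 matches the
#'   1000 bp upstream + 200 bp downstream window.
#' @param planted_rates Named list: `cluster id -> named numeric vector
#'   (motif id -> expected planted sites per promoter)`.
#' @param background_rate Expected background sites per promoter per motif.
#' @param base_composition Background base probabilities (A, C, G, T).
#' @param seed Integer seed.
#' @return List with `promoters` (a [promoter_set()]) and `truth` (updated
#'   with the planted cluster -> motif map).
#' @export
simulate_promoters <- function(truth, pwms, length = 1200,
                               planted_rates = list(),
                               background_rate = 0,
                               base_composition = rep(0.25, 4),
                               seed = 1L) {
  stopifnot(abs(sum(base_composition) - 1) < 1e-8,
            all(base_composition >= 0))
  motif_ids <- vapply(pwms, `[[`, "", "motif_id")
  names(pwms) <- motif_ids
  for (rates in planted_rates) {
    if (any(rates < 0)) stop("planted rates must be >= 0", call. = FALSE)
    if (!all(names(rates) %in% motif_ids))
      stop("planted motif not among supplied PWMs", call. = FALSE)
  }
  widths <- vapply(pwms, function(p) ncol(p$mat), 0L)
  if (any(widths > length))
    stop("motif longer than the promoter sequence", call. = FALSE)

  genes <- names(truth$gene_cluster)
  seqs <- with_seed(seed, {
    out <- character(length(genes))
    names(out) <- genes
    for (i in seq_along(genes)) {
      g <- genes[i]
      s <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = base_composition)
      cl <- truth$gene_cluster[[g]]
      occupied <- integer(0)   # occupied positions
      for (mid in motif_ids) {
        rate <- background_rate
        if (cl != "null" && !is.null(planted_rates[[cl]]))
          rate <- rate + sum(planted_rates[[cl]][mid], na.rm = TRUE)
        n_sites <- rpois(1L, rate)
        if (n_sites == 0L) next
        L <- widths[[mid]]
        placed <- 0L
        tries <- 0L
        while (placed < n_sites && tries < 200L) {
          tries <- tries + 1L
          pos <- sample.int(length - L + 1L, 1L)
          span <- pos:(pos + L - 1L)
          if (any(span %in% occupied)) next
          site <- sample_site(pwms[[mid]]$mat)
          if (runif(1) < 0.5) site <- revcomp(site)
          s[span] <- strsplit(site, "")[[1L]]
          occupied <- c(occupied, span)
          placed <- placed + 1L
        }
      }
      out[i] <- paste(s, collapse = "")
    }
    out
  })
  planted_map <- lapply(planted_rates, function(r) names(r)[r > 0])
  up <- min(1000L, length)
  list(promoters = promoter_set(seqs, upstream_bp = up,
                                downstream_bp = length - up),
       truth = new_sim_truth(truth$gene_cluster, planted_map,
                             truth$cluster_terms))
}

#' Simulate annotation terms with planted cluster enrichment
#'
#' Background terms draw members uniformly from all genes; planted terms
#' draw each member with weight `enrichment_factor` for genes of the target
#' cluster and weight 1 otherwise, so `enrichment_factor = 1` makes planted
#' terms indistinguishable from background.
#'
#' @param truth A `SimTruth`.
#' @param n_terms Total number of terms to emit.
#' @param term_size_range Integer range of term sizes (members drawn
#'   without replacement from the gene universe).
#' @param enrichment_factor Sampling weight multiplier for target-cluster
#'   genes, >= 1.
#' @param planted_clusters Cluster ids receiving one planted term each;
#'   defaults to all clusters in the truth, truncated to `n_terms`.
#' @param seed Integer seed.
#' @return List with `annotations` (an [annotation_set()]) and `truth`
#'   (updated with the planted cluster -> term map).
#' @export
simulate_annotations <- function(truth, n_terms = 20,
                                 term_size_range = c(10, 40),
                                 enrichment_factor = 1,
                                 planted_clusters = NULL, seed = 1L) {
  if (enrichment_factor < 1)
    stop("enrichment_factor must be >= 1", call. = FALSE)
  genes <- names(truth$gene_cluster)
  term_size_range <- as.integer(round(term_size_range))
  if (term_size_range[1] < 1L || term_size_range[2] > length(genes) ||
      term_size_range[1] > term_size_range[2])
    stop("term_size_range infeasible for ", length(genes), " genes",
         call. = FALSE)
  if (is.null(planted_clusters))
    planted_clusters <- setdiff(unique(truth$gene_cluster), "null")
  planted_clusters <- head(planted_clusters, n_terms)
  n_planted <- length(planted_clusters)

  res <- with_seed(seed, {
    size_choices <- seq(term_size_range[1], term_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), n_terms,
                                     replace = TRUE)]
    members <- vector("list", n_terms)
    classes <- character(n_terms)
    target <- character(n_terms)
    for (i in seq_len(n_terms)) {
      if (i <= n_planted) {
        cl <- planted_clusters[i]
        w <- ifelse(truth$gene_cluster == cl, enrichment_factor, 1)
        members[[i]] <- sample(genes, sizes[i], prob = w)
        classes[i] <- "planted"
        target[i] <- cl
      } else {
        members[[i]] <- sample(genes, sizes[i])
        classes[i] <- "background"
        target[i] <- NA_character_
      }
    }
    list(members = members, classes = classes, target = target)
  })
  term_id <- sprintf("T%03d", seq_len(n_terms))
  names(res$members) <- term_id
  ann <- annotation_set(
    data.frame(term_id = term_id, term_class = res$classes,
               description = ifelse(is.na(res$target), "background term",
                                    paste("planted in cluster",
                                          res$target))),
    res$members)
  planted_terms <- split(term_id[seq_len(n_planted)],
                         res$target[seq_len(n_planted)])
  list(annotations = ann,
       truth = new_sim_truth(truth$gene_cluster, truth$cluster_motifs,
                             planted_terms))
}
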