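# PWM promoter scanning and motif over/under-representation Z scores
# against a pooled background promoter set, plus the Z-matrix analytics
# (two-way clustering and PCA of cluster Z vectors).

# ---------------------------------------------------------------------------
# Scorer
# ---------------------------------------------------------------------------

#' Build a log-odds scorer from a PWM
#'
#' Converts counts to pseudocount-smoothed log-odds against the background
#' base frequencies: `log(((count + pc * bg) / (colsum + pc)) / bg)`. The
#' absolute hit threshold is `threshold_fraction` times the maximum
#' achievable log-odds score (the best-base path). An uninformative matrix
#' whose maximum achievable score is not positive can never produce a hit.
#'
#' @param pwm A [pwm()].
#' @param background_freqs Base frequencies (A, C, G, T), summing to 1 and
#'   strictly positive. Typically estimated from the background promoter
#'   set with [base_frequencies()].
#' @param pseudocount Total pseudocount added per column, spread according
#'   to the background (default 0.01).
#' @param threshold_fraction Hit threshold as a fraction of the maximum
#'   achievable score, in (0, 1] (default 0.80).
#' @return Object of class `ScoredPWM`: list with `motif_id`, `lom` (4 x L
#'   log-odds matrix), `threshold`, `max_score`, `background`, `width`.
#' @export
build_scorer <- function(pwm, background_freqs = rep(0.25, 4),
                         pseudocount = 0.01, threshold_fraction = 0.80) {
  if (any(background_freqs <= 0))
    stop("background frequencies must be strictly positive", call. = FALSE)
  if (abs(sum(background_freqs) - 1) > 1e-6)
    stop("background frequencies must sum to 1", call. = FALSE)
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must lie in (0, 1]", call. = FALSE)
  m <- pwm$mat
  cs <- colSums(m)
  prob <- sweep(m + pseudocount * background_freqs, 2, cs + pseudocount,
                "/")
  lom <- log(prob / background_freqs)
  max_score <- sum(apply(lom, 2, max))
  structure(list(motif_id = pwm$motif_id, lom = lom,
                 threshold = threshold_fraction * max_score,
                 max_score = max_score,
                 background = background_freqs, width = ncol(lom)),
            class = "ScoredPWM")
}

#' @export
print.ScoredPWM <- function(x, ...) {
  cat(sprintf("ScoredPWM %s: width %d, threshold %.3f (max %.3f)\n",
              x$motif_id, x$width, x$threshold, x$max_score))
  invisible(x)
}

#' Base frequencies of a promoter set
#'
#' @param ps A `PromoterSet`.
#' @param pseudo Small count added to every base so no frequency is zero.
#' @return Named numeric vector (A, C, G, T) summing to 1; N bases are
#'   ignored.
#' @export
base_frequencies <- function(ps, pseudo = 1) {
  counts <- c(A = pseudo, C = pseudo, G = pseudo, T = pseudo)
  tab <- table(factor(strsplit(paste(ps$sequences, collapse = ""),
                               "")[[1L]], levels = c("A", "C", "G", "T")))
  counts <- counts + as.numeric(tab)
  counts / sum(counts)
}

encode_seq <- function(s) {
  v <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
  v   # N (or anything else) -> NA
}

window_scores <- function(codes, lom) {
  L <- ncol(lom)
  n <- length(codes)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  s <- numeric(nw)
  idx <- seq_len(nw)
  for (j in seq_len(L)) {
    contrib <- lom[cbind(codes[idx + j - 1L], j)]
    s <- s + contrib
  }
  s[is.na(s)] <- -Inf   # windows containing N never hit
  s
}

revcomp_codes <- function(codes) rev(5L - codes)

#' Count motif hits in one sequence
#'
#' Scans every window on both strands and counts those whose log-odds
#' score reaches the scorer's threshold. Overlapping hits all count, both
#' strands count independently, windows containing N never hit, and a
#' sequence shorter than the motif yields 0.
#'
#' @param seq Nucleotide string over A, C, G, T, N.
#' @param scorer A [build_scorer()] result.
#' @return Integer hit count.
#' @export
count_sites <- function(seq, scorer) {
  codes <- if (is.integer(seq)) seq else encode_seq(toupper(seq))
  if (scorer$max_score <= 0) return(0L)
  fwd <- window_scores(codes, scorer$lom)
  rev <- window_scores(revcomp_codes(codes), scorer$lom)
  sum(fwd >= scorer$threshold) + sum(rev >= scorer$threshold)
}

count_sites_set <- function(ps, scorer) {
  vapply(ps$sequences, count_sites, 0L, scorer = scorer)
}

scannable_windows <- function(ps, width) {
  2L * pmax(nchar(ps$sequences) - width + 1L, 0L)
}

# ---------------------------------------------------------------------------
# Z scores
# ---------------------------------------------------------------------------

#' Motif over/under-representation Z score of a foreground promoter set
#'
#' Estimates the per-window hit probability from the background (total
#' hits over total scannable windows, both strands), then standardizes the
#' foreground hit count under the binomial null: `expected = W * p`,
#' `sd = sqrt(W * p * (1 - p))`, `Z = (observed - expected) / sd` with W
#' the foreground's scannable window count. Positive Z means
#' over-representation. When the background rate is degenerate (0 or 1)
#' the Z is undefined and returned as NA.
#'
#' @param foreground,background `PromoterSet`s; the foreground gene set
#'   must be a subset of the background's.
#' @param scorer A [build_scorer()] result.
#' @param bg_counts Optional precomputed background hit counts (named by
#'   gene id) to avoid rescanning.
#' @return One-row data frame: `motif_id`, `observed`, `expected`, `sd`,
#'   `z`, `defined`.
#' @export
zscore_overrep <- function(foreground, background, scorer,
                           bg_counts = NULL) {
  if (!all(names(foreground$sequences) %in% names(background$sequences)))
    stop("foreground genes must be a subset of the background",
         call. = FALSE)
  if (is.null(bg_counts)) bg_counts <- count_sites_set(background, scorer)
  bg_w <- sum(scannable_windows(background, scorer$width))
  p_hat <- sum(bg_counts) / bg_w
  fg_counts <- bg_counts[names(foreground$sequences)]
  w <- sum(scannable_windows(foreground, scorer$width))
  observed <- sum(fg_counts)
  if (p_hat <= 0 || p_hat >= 1) {
    return(data.frame(motif_id = scorer$motif_id, observed = observed,
                      expected = NA_real_, sd = NA_real_, z = NA_real_,
                      defined = FALSE))
  }
  expected <- w * p_hat
  sdv <- sqrt(w * p_hat * (1 - p_hat))
  data.frame(motif_id = scorer$motif_id, observed = observed,
             expected = expected, sd = sdv,
             z = (observed - expected) / sdv, defined = TRUE)
}

#' Cluster x motif Z-score matrix with |Z| > z_cut calls
#'
#' Scans the pooled promoter background once per motif, then scores every
#' consensus cluster's promoter set against it. Clustered genes without a
#' promoter sequence are dropped with a warning.
#'
#' @param assignment A `ClusterAssignment` or named membership vector.
#' @param promoters A `PromoterSet` covering the background (all DE
#'   genes).
#' @param scorers List of [build_scorer()] results.
#' @param z_cut Reporting cutoff (default 3): `Z > z_cut` is called over-,
#'   `Z < -z_cut` under-represented.
#' @return Object of class `ZScoreMatrix`: list with matrices `z`,
#'   `observed`, `expected`, `sd` (clusters x motifs), logical `defined`,
#'   and `calls` (data frame of cluster, motif, z, observed, expected,
#'   call).
#' @export
zscore_matrix <- function(assignment, promoters, scorers, z_cut = 3) {
  membership <- if (inherits(assignment, "ClusterAssignment"))
    assignment$membership else assignment
  have <- names(membership) %in% names(promoters$sequences)
  if (!all(have)) {
    warning(sum(!have), " clustered genes lack a promoter; excluded")
    membership <- membership[have]
  }
  clusters <- sort(unique(membership))
  motif_ids <- vapply(scorers, `[[`, "", "motif_id")
  z <- obs <- expd <- sdm <-
    matrix(NA_real_, length(clusters), length(scorers),
           dimnames = list(clusters, motif_ids))
  defined <- matrix(FALSE, length(clusters), length(scorers),
                    dimnames = list(clusters, motif_ids))
  for (j in seq_along(scorers)) {
    sc <- scorers[[j]]
    bg_counts <- count_sites_set(promoters, sc)
    for (i in seq_along(clusters)) {
      ids <- names(membership)[membership == clusters[i]]
      fg <- promoter_set(promoters$sequences[ids],
                         promoters$upstream_bp, promoters$downstream_bp)
      r <- zscore_overrep(fg, promoters, sc, bg_counts = bg_counts)
      z[i, j] <- r$z; obs[i, j] <- r$observed
      expd[i, j] <- r$expected; sdm[i, j] <- r$sd
      defined[i, j] <- r$defined
    }
  }
  idx <- which(defined & abs(z) > z_cut, arr.ind = TRUE)
  calls <- data.frame(
    cluster = clusters[idx[, 1]], motif = motif_ids[idx[, 2]],
    z = z[idx], observed = obs[idx], expected = expd[idx],
    call = ifelse(z[idx] > 0, "over", "under"))
  calls <- calls[order(calls$cluster, calls$motif), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(z = z, observed = obs, expected = expd, sd = sdm,
                 defined = defined, calls = calls, z_cut = z_cut),
            class = "ZScoreMatrix")
}

#' @export
print.ZScoreMatrix <- function(x, ...) {
  cat(sprintf("ZScoreMatrix: %d clusters x %d motifs, %d calls at |Z| > %g\n",
              nrow(x$z), ncol(x$z), nrow(x$calls), x$z_cut))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Z-matrix analytics
# ---------------------------------------------------------------------------

#' Two-way hierarchical ordering of the Z matrix
#'
#' Scales each cluster's Z vector to unit variance (clusters whose Z
#' vector is constant, or contains undefined cells, are excluded with a
#' warning; motifs with undefined cells likewise), then clusters motifs
#' and clusters with Ward linkage on Euclidean distances and orders both
#' dendrograms by [optimal_leaf_order()].
#'
#' @param zm A `ZScoreMatrix`.
#' @return List with `scaled` (clusters x motifs, unit-variance rows),
#'   `cluster_hc`, `motif_hc`, `cluster_order`, `motif_order`.
#' @export
zmatrix_cluster <- function(zm) {
  z <- zm$z
  keep_motif <- colSums(!zm$defined) == 0L
  if (!all(keep_motif)) {
    warning("excluding motifs with undefined Z: ",
            paste(colnames(z)[!keep_motif], collapse = ", "))
    z <- z[, keep_motif, drop = FALSE]
  }
  v <- apply(z, 1, sd)
  keep_cl <- is.finite(v) & v > 0
  if (!all(keep_cl)) {
    warning("excluding constant cluster Z vectors: ",
            paste(rownames(z)[!keep_cl], collapse = ", "))
    z <- z[keep_cl, , drop = FALSE]
  }
  if (nrow(z) < 2L || ncol(z) < 2L)
    stop("need at least 2 clusters and 2 motifs", call. = FALSE)
  scaled <- z / apply(z, 1, sd)
  cl_d <- as.matrix(dist(scaled))
  mo_d <- as.matrix(dist(t(scaled)))
  cluster_hc <- hclust(as.dist(cl_d), method = "ward.D")
  motif_hc <- hclust(as.dist(mo_d), method = "ward.D")
  cluster_hc$labels <- rownames(scaled)
  motif_hc$labels <- colnames(scaled)
  list(scaled = scaled, cluster_hc = cluster_hc, motif_hc = motif_hc,
       cluster_order = rownames(scaled)[
         optimal_leaf_order(cluster_hc, cl_d)],
       motif_order = colnames(scaled)[optimal_leaf_order(motif_hc, mo_d)])
}

#' Principal components of the cluster Z vectors
#'
#' Projects each cluster's motif Z vector on the top two principal
#' components (columns centered, unscaled). The sign of each component is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param zm A `ZScoreMatrix` (needs >= 3 clusters with fully defined Z).
#' @return List with `scores` (clusters x 2), `loadings` (motifs x 2),
#'   `sdev` (component standard deviations).
#' @export
zmatrix_pca <- function(zm) {
  z <- zm$z
  keep_motif <- colSums(!zm$defined) == 0L
  z <- z[, keep_motif, drop = FALSE]
  if (nrow(z) < 3L) stop("PCA needs >= 3 clusters", call. = FALSE)
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2L || pc$sdev[2L] < 1e-12)
    stop("Z matrix has rank < 2", call. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  loadings <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings, sdev = pc$sdev[1:2])
}
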