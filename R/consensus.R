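# Consensus clustering of normalized expression time profiles: repeated
# K-means over a range of k, co-occurrence averaging, Ward consensus cut,
# stability diagnostics and optimal leaf ordering.

# ---------------------------------------------------------------------------
# K-means scan
# ---------------------------------------------------------------------------

lloyd_kmeans <- function(x, k, max_iter = 300L) {
  # Lloyd iterations with random-point initialization; an emptied cluster
  # is reseeded to the point farthest from every center
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  assign_old <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) +
      outer(rep(1, n), rowSums(centers^2)) - 2 * x %*% t(centers)
    assign_new <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(assign_new == j)) {
        far <- which.max(apply(d2, 1, min))
        assign_new[far] <- j
        d2[far, ] <- Inf   # cannot be stolen twice in the same sweep
      }
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
  }
  assign_old
}

#' Repeated K-means over a range of cluster counts
#'
#' Runs `repeats` randomized K-means clusterings for every k in
#' `k_min..k_max` on the normalized expression rows (degenerate rows are
#' excluded). The defaults, 30 repeats over k = 6..14, give 270 runs.
#'
#' @param norm A [normalize_gene_wise()] result.
#' @param k_min,k_max Range of cluster counts.
#' @param repeats Randomized runs per k.
#' @param seed Integer seed.
#' @return Object of class `PartitionSet`: list with `labels` (genes x
#'   runs integer matrix), `k` and `rep` per run, `gene_ids`.
#' @export
kmeans_scan <- function(norm, k_min = 6L, k_max = 14L, repeats = 30L,
                        seed = 1L) {
  keep <- !norm$degenerate
  x <- norm$values[keep, , drop = FALSE]
  if (k_max >= nrow(x))
    stop("k_max must be below the number of clustered genes",
         call. = FALSE)
  if (k_min < 1L || k_min > k_max) stop("bad k range", call. = FALSE)
  ks <- rep(seq(k_min, k_max), each = repeats)
  reps <- rep(seq_len(repeats), times = k_max - k_min + 1L)
  labels <- with_seed(seed, {
    vapply(seq_along(ks), function(r) lloyd_kmeans(x, ks[r]),
           integer(nrow(x)))
  })
  rownames(labels) <- rownames(x)
  structure(list(labels = labels, k = ks, rep = reps,
                 gene_ids = rownames(x)),
            class = "PartitionSet")
}

#' @export
print.PartitionSet <- function(x, ...) {
  cat(sprintf("PartitionSet: %d genes, %d runs (k = %d..%d)\n",
              length(x$gene_ids), ncol(x$labels), min(x$k), max(x$k)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Co-occurrence
# ---------------------------------------------------------------------------

#' Co-occurrence matrix of a partition set
#'
#' Entry (i, j) is the exact fraction of runs in which genes i and j fell
#' in the same cluster; the diagonal is 1 and the matrix is symmetric.
#'
#' @param ps A `PartitionSet`.
#' @return Object of class `CoOccurrenceMatrix`: list with `C` (gene x
#'   gene matrix) and `runs`.
#' @export
co_occurrence <- function(ps) {
  labs <- ps$labels
  if (ncol(labs) < 1L) stop("need at least one partition", call. = FALSE)
  n <- nrow(labs)
  acc <- matrix(0, n, n)
  for (r in seq_len(ncol(labs))) {
    k <- max(labs[, r])
    z <- matrix(0, n, k)
    z[cbind(seq_len(n), labs[, r])] <- 1
    acc <- acc + tcrossprod(z)
  }
  C <- acc / ncol(labs)
  dimnames(C) <- list(ps$gene_ids, ps$gene_ids)
  structure(list(C = C, runs = ncol(labs)), class = "CoOccurrenceMatrix")
}

#' @export
print.CoOccurrenceMatrix <- function(x, ...) {
  cat(sprintf("CoOccurrenceMatrix: %d genes over %d runs\n",
              nrow(x$C), x$runs))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Consensus cut
# ---------------------------------------------------------------------------

#' Cut the consensus tree into K clusters
#'
#' Hierarchical clustering with Ward linkage on the dissimilarity
#' `D = 1 - C`, cut into K clusters. Cluster ids are renumbered 1..K in
#' leaf order so cluster 1 is leftmost in the dendrogram. Per-cluster time
#' profiles (mean and sd of normalized expression per group) are attached
#' when `norm` is supplied.
#'
#' @param co A `CoOccurrenceMatrix`.
#' @param K Number of consensus clusters (default 12).
#' @param norm Optional [normalize_gene_wise()] result for profiles.
#' @param leaf_cap Leaf count up to which the exact leaf-ordering dynamic
#'   program is used; larger trees fall back to greedy subtree flipping.
#' @return Object of class `ClusterAssignment`: list with `membership`
#'   (named integer vector), `hc` (hclust tree), `leaf_order` (gene ids),
#'   `profiles` (list of `mean` and `sd`, clusters x groups), `K`.
#' @export
consensus_cut <- function(co, K = 12L, norm = NULL, leaf_cap = 400L) {
  n <- nrow(co$C)
  if (K < 1L || K > n) stop("K must lie in 1..n_genes", call. = FALSE)
  D <- as.dist(1 - co$C)
  hc <- hclust(D, method = "ward.D")
  raw <- cutree(hc, k = K)
  ord <- optimal_leaf_order(hc, 1 - co$C, cap = leaf_cap)
  leaf_ids <- rownames(co$C)[ord]
  # renumber clusters by first appearance along the leaf order
  first_seen <- unique(raw[leaf_ids])
  membership <- match(raw, first_seen)
  names(membership) <- names(raw)
  profiles <- NULL
  if (!is.null(norm)) profiles <- cluster_profiles(membership, norm)
  structure(list(membership = membership, hc = hc, leaf_order = leaf_ids,
                 profiles = profiles, K = K),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  sizes <- table(x$membership)
  cat(sprintf("ClusterAssignment: %d genes in %d consensus clusters\n",
              length(x$membership), x$K))
  cat("sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster time profiles
#'
#' @param membership Named integer vector, gene -> cluster.
#' @param norm A [normalize_gene_wise()] result covering the genes.
#' @return List with matrices `mean` and `sd` (clusters x groups).
#' @export
cluster_profiles <- function(membership, norm) {
  g <- factor(norm$design$group, levels = norm$groups)
  x <- norm$values[names(membership), , drop = FALSE]
  ks <- sort(unique(membership))
  mu <- matrix(NA_real_, length(ks), nlevels(g),
               dimnames = list(ks, levels(g)))
  sdv <- mu
  for (i in seq_along(ks)) {
    rows <- x[membership == ks[i], , drop = FALSE]
    for (j in seq_len(nlevels(g))) {
      v <- as.numeric(rows[, g == levels(g)[j], drop = FALSE])
      mu[i, j] <- mean(v)
      sdv[i, j] <- sd(v)
    }
  }
  list(mean = mu, sd = sdv)
}

# ---------------------------------------------------------------------------
# Stability diagnostic
# ---------------------------------------------------------------------------

#' Cohesion/separation diagnostic over a range of consensus K
#'
#' For each K, cuts the consensus tree and reports the mean co-occurrence
#' over within-cluster gene pairs (cohesion; 1 when every cluster is a
#' perfect co-occurrence block) and over between-cluster pairs
#' (separation). A K beyond which cohesion gains flatten indicates that
#' further splits only subdivide already-coherent profiles.
#'
#' @param co A `CoOccurrenceMatrix`.
#' @param K_range Integer vector of K values to evaluate.
#' @return Data frame with `K`, `cohesion`, `separation`.
#' @export
stability_diagnostic <- function(co, K_range = 2:20) {
  C <- co$C
  n <- nrow(C)
  hc <- hclust(as.dist(1 - C), method = "ward.D")
  off <- upper.tri(C)
  do.call(rbind, lapply(K_range, function(K) {
    cl <- cutree(hc, k = min(K, n))
    same <- outer(cl, cl, "==")
    within <- off & same
    between <- off & !same
    data.frame(K = K,
               cohesion = if (any(within)) mean(C[within]) else 1,
               separation = if (any(between)) mean(C[between]) else 0)
  }))
}

# ---------------------------------------------------------------------------
# Optimal leaf ordering
# ---------------------------------------------------------------------------

hc_children <- function(hc) {
  # children of each merge node; negative entries are leaves
  lapply(seq_len(nrow(hc$merge)), function(i) hc$merge[i, ])
}

node_leaves <- function(hc) {
  # leaves under each merge node, in merge order
  out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    out[[i]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else out[[k]]))
  }
  out
}

#' Order dendrogram leaves to minimize adjacent dissimilarity
#'
#' Finds an ordering consistent with the tree (only subtree flips allowed)
#' minimizing the sum of dissimilarities between adjacent leaves. Up to
#' `cap` leaves the exact dynamic program over (first leaf, last leaf)
#' pairs is used; beyond that, greedy bottom-up subtree flipping. Of the
#' two reversals of an optimal order the one whose first leaf has the
#' smaller label is returned.
#'
#' @param hc An `hclust` tree.
#' @param D Symmetric dissimilarity matrix over the leaves (matrix or
#'   `dist`).
#' @param cap Maximum leaf count for the exact dynamic program.
#' @return Integer vector of leaf indices (into `hc$labels`).
#' @export
optimal_leaf_order <- function(hc, D, cap = 400L) {
  D <- as.matrix(D)
  n <- length(hc$order)
  if (n <= 2L) return(canonical_orientation(hc$order, hc$labels))
  ord <- if (n <= cap) olo_exact(hc, D) else olo_greedy(hc, D)
  canonical_orientation(ord, hc$labels)
}

canonical_orientation <- function(ord, labels) {
  key <- if (is.null(labels)) as.character(ord) else labels[ord]
  if (key[length(key)] < key[1L]) rev(ord) else ord
}

olo_exact <- function(hc, D) {
  # Dynamic program over (first leaf, last leaf) pairs per subtree
  # (Bar-Joseph style). cost[[node]] is a matrix indexed by leaf labels:
  # the minimal adjacent-dissimilarity sum of any tree-consistent ordering
  # of the node's leaves starting at row leaf and ending at column leaf.
  nl <- node_leaves(hc)
  n_nodes <- nrow(hc$merge)
  cost <- vector("list", n_nodes)
  get_cost <- function(k)
    if (k < 0) matrix(0, 1, 1, dimnames = list(-k, -k)) else cost[[k]]
  get_leaves <- function(k) if (k < 0) -k else nl[[k]]

  half_cost <- function(A, B, ca, cb) {
    # orders starting in A, ending in B, across the A|B junction:
    # out[u, w] = min over junction (m in A, r in B) of
    #             ca[u, m] + D[m, r] + cb[r, w]
    dab <- D[A, B, drop = FALSE]
    h <- matrix(Inf, length(A), length(B))        # h[m, w]
    for (w in seq_along(B))
      h[, w] <- do.call(pmin, lapply(seq_along(B), function(r)
        dab[, r] + cb[r, w]))
    out <- matrix(Inf, length(A), length(B),
                  dimnames = list(A, B))
    for (w in seq_along(B))
      out[, w] <- do.call(pmin, lapply(seq_along(A), function(m)
        ca[, m] + h[m, w]))
    out
  }

  for (i in seq_len(n_nodes)) {
    kids <- hc$merge[i, ]
    L <- get_leaves(kids[1]); R <- get_leaves(kids[2])
    ca <- get_cost(kids[1]); cb <- get_cost(kids[2])
    lr <- half_cost(L, R, ca, cb)
    rl <- half_cost(R, L, cb, ca)
    all_lv <- c(L, R)
    Ci <- matrix(Inf, length(all_lv), length(all_lv),
                 dimnames = list(all_lv, all_lv))
    Ci[as.character(L), as.character(R)] <- lr
    Ci[as.character(R), as.character(L)] <- rl
    cost[[i]] <- Ci
  }

  build <- function(node, u, w) {
    if (node < 0) return(-node)
    kids <- hc$merge[node, ]
    L <- get_leaves(kids[1]); R <- get_leaves(kids[2])
    if (u %in% R) { kids <- rev(kids); tmp <- L; L <- R; R <- tmp }
    ca <- get_cost(kids[1]); cb <- get_cost(kids[2])
    uc <- as.character(u); wc <- as.character(w)
    # recover the junction (m, r) achieving cost[[node]][u, w]
    best <- Inf; bm <- L[1]; br <- R[1]
    for (m in L) for (r in R) {
      v <- ca[uc, as.character(m)] + D[m, r] + cb[as.character(r), wc]
      if (v < best) { best <- v; bm <- m; br <- r }
    }
    c(build(kids[1], u, bm), build(kids[2], br, w))
  }

  Ci <- cost[[n_nodes]]
  ix <- which(Ci == min(Ci), arr.ind = TRUE)
  ix <- ix[order(ix[, 1], ix[, 2]), , drop = FALSE][1, ]
  u <- as.integer(rownames(Ci)[ix[1]])
  w <- as.integer(colnames(Ci)[ix[2]])
  build(n_nodes, u, w)
}

olo_greedy <- function(hc, D) {
  # bottom-up: at each merge try the four child orientations, keep the one
  # with the cheapest junction
  n_nodes <- nrow(hc$merge)
  ords <- vector("list", n_nodes)
  get_ord <- function(k) if (k < 0) -k else ords[[k]]
  for (i in seq_len(n_nodes)) {
    a <- get_ord(hc$merge[i, 1])
    b <- get_ord(hc$merge[i, 2])
    cands <- list(c(a, b), c(rev(a), b), c(a, rev(b)), c(rev(a), rev(b)))
    costs <- vapply(cands, function(o) {
      j <- length(a)
      D[o[j], o[j + 1L]]
    }, 0)
    ords[[i]] <- cands[[which.min(costs)]]
  }
  ords[[n_nodes]]
}

# ---------------------------------------------------------------------------
# Heatmap export
# ---------------------------------------------------------------------------

#' Per-cluster normalized expression tables in leaf order
#'
#' @param assignment A `ClusterAssignment`.
#' @param norm A [normalize_gene_wise()] result.
#' @param dir Optional output directory; when given, one TSV per cluster
#'   (`cluster_<id>.tsv`) is written.
#' @return Named list of gene x array matrices, rows in leaf order.
#' @export
export_heatmap_tables <- function(assignment, norm, dir = NULL) {
  ordered_ids <- assignment$leaf_order
  out <- lapply(sort(unique(assignment$membership)), function(k) {
    ids <- ordered_ids[assignment$membership[ordered_ids] == k]
    norm$values[ids, , drop = FALSE]
  })
  names(out) <- paste0("cluster_", sort(unique(assignment$membership)))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      tab <- data.frame(gene_id = rownames(out[[nm]]), out[[nm]],
                        check.names = FALSE)
      write.table(tab, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(out)
}
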