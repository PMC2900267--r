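# Per-cluster annotation over-representation against the DE background,
# with grouping of mutually overlapping significant terms and
# representative-term extraction.

#' Hypergeometric term over-representation for one gene cluster
#'
#' Tests, for every annotation term, whether the cluster contains at least
#' as many term members as expected when drawing `|cluster|` genes from
#' the background without replacement (one-sided upper tail). Terms are
#' intersected with the background before testing. With `ease = TRUE` the
#' observed overlap is jackknifed down by one member before testing
#' (EASE-style penalty for small overlaps).
#'
#' @param cluster_genes Character vector, must be a subset of
#'   `background_genes`.
#' @param background_genes Character vector (the DE gene universe).
#' @param annotations An [annotation_set()].
#' @param ease Apply the count-minus-one penalty (default `FALSE`).
#' @return Data frame with `term_id`, `term_class`, `description`,
#'   `count` (cluster genes in term), `total` (background genes in term),
#'   `p`, and a list column `members_in_cluster` used for term grouping.
#'   Terms with no background members are dropped.
#' @export
term_enrichment <- function(cluster_genes, background_genes, annotations,
                            ease = FALSE) {
  cluster_genes <- unique(as.character(cluster_genes))
  background_genes <- unique(as.character(background_genes))
  if (!all(cluster_genes %in% background_genes))
    stop("cluster genes must be a subset of the background", call. = FALSE)
  n_bg <- length(background_genes)
  n_cl <- length(cluster_genes)
  rows <- lapply(seq_len(nrow(annotations$terms)), function(i) {
    tid <- annotations$terms$term_id[i]
    members <- intersect(annotations$members[[tid]], background_genes)
    total <- length(members)
    if (total == 0L) return(NULL)
    in_cl <- intersect(members, cluster_genes)
    count <- length(in_cl)
    q <- if (ease) max(count - 1L, 0L) else count
    p <- phyper(q - 1L, total, n_bg - total, n_cl, lower.tail = FALSE)
    data.frame(term_id = tid,
               term_class = annotations$terms$term_class[i],
               description = annotations$terms$description[i],
               count = count, total = total, p = p,
               members_in_cluster = I(list(in_cl)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(), term_class = character(),
                      description = character(), count = integer(),
                      total = integer(), p = numeric(),
                      members_in_cluster = I(list()))
  rownames(out) <- NULL
  out
}

overlap_coefficient <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Group overlapping terms and extract representatives
#'
#' Builds a graph on the enriched terms with an edge wherever the gene
#' overlap coefficient `|A n B| / min(|A|, |B|)` of their cluster-restricted
#' member sets reaches `overlap_threshold`; groups are the connected
#' components (so grouping is transitive). A group is significant if it
#' contains a term with `p < p_threshold`; its representative is the
#' significant term with the smallest background total (the most specific
#' term), ties broken by smaller p, then term id.
#'
#' @param enr A [term_enrichment()] table. Terms with zero cluster members
#'   are left ungrouped (each its own non-significant singleton).
#' @param overlap_threshold Minimum overlap coefficient for an edge
#'   (default 0.70).
#' @param p_threshold Significance level for group calls (default 0.03).
#' @return List with `terms` (the input plus `group` id) and `groups`
#'   (one row per group: `group`, `n_terms`, `min_p`, `significant`,
#'   `representative`, representative's class/description/count/total/p).
#' @export
group_terms <- function(enr, overlap_threshold = 0.70, p_threshold = 0.03) {
  n <- nrow(enr)
  if (n == 0L)
    return(list(terms = cbind(enr, group = integer(0)),
                groups = data.frame()))
  sets <- enr$members_in_cluster
  edges <- NULL
  nonempty <- which(lengths(sets) > 0L)
  if (length(nonempty) >= 2L) {
    pairs <- utils::combn(nonempty, 2L)
    keep <- apply(pairs, 2, function(ij)
      overlap_coefficient(sets[[ij[1]]], sets[[ij[2]]]) >=
        overlap_threshold)
    edges <- pairs[, keep, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && ncol(edges) > 0L)
    g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  terms <- enr
  terms$group <- comp
  groups <- do.call(rbind, lapply(sort(unique(comp)), function(cid) {
    sub <- terms[terms$group == cid, , drop = FALSE]
    sig <- sub$p < p_threshold
    significant <- any(sig)
    rep_row <- NA_integer_
    if (significant) {
      cand <- which(sig)
      cand <- cand[order(sub$total[cand], sub$p[cand],
                         sub$term_id[cand])]
      rep_row <- cand[1L]
    }
    data.frame(group = cid, n_terms = nrow(sub), min_p = min(sub$p),
               significant = significant,
               representative = if (significant) sub$term_id[rep_row]
                                else NA_character_,
               rep_class = if (significant) sub$term_class[rep_row]
                           else NA_character_,
               rep_description = if (significant) sub$description[rep_row]
                                 else NA_character_,
               rep_count = if (significant) sub$count[rep_row]
                           else NA_integer_,
               rep_total = if (significant) sub$total[rep_row]
                           else NA_integer_,
               rep_p = if (significant) sub$p[rep_row] else NA_real_)
  }))
  rownames(groups) <- NULL
  list(terms = terms, groups = groups)
}

#' Per-cluster enrichment with term grouping
#'
#' Runs [term_enrichment()] and [group_terms()] for every consensus
#' cluster against the DE background.
#'
#' @param assignment A `ClusterAssignment` (or named membership vector).
#' @param background_genes The DE gene universe.
#' @param annotations An [annotation_set()].
#' @param overlap_threshold,p_threshold,ease Passed through.
#' @return Named list (one element per cluster) of [group_terms()] results;
#'   also carries a flat `summary` data frame attribute with one row per
#'   significant group: cluster, representative term, class, count, total,
#'   group size, p.
#' @export
enrich_clusters <- function(assignment, background_genes, annotations,
                            overlap_threshold = 0.70, p_threshold = 0.03,
                            ease = FALSE) {
  membership <- if (inherits(assignment, "ClusterAssignment"))
    assignment$membership else assignment
  out <- lapply(sort(unique(membership)), function(k) {
    enr <- term_enrichment(names(membership)[membership == k],
                           background_genes, annotations, ease = ease)
    group_terms(enr, overlap_threshold, p_threshold)
  })
  names(out) <- as.character(sort(unique(membership)))
  summary <- do.call(rbind, lapply(names(out), function(k) {
    gr <- out[[k]]$groups
    if (!nrow(gr)) return(NULL)
    gr <- gr[gr$significant, , drop = FALSE]
    if (!nrow(gr)) return(NULL)
    data.frame(cluster = as.integer(k), term = gr$representative,
               class = gr$rep_class, description = gr$rep_description,
               count = gr$rep_count, total = gr$rep_total,
               group_size = gr$n_terms, p = gr$rep_p)
  }))
  attr(out, "summary") <- summary
  out
}
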