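# PWM scoring, promoter scanning, over-representation Z and Z analytics.

uniform_pwm <- function(L = 6) pwm("unif", matrix(1, 4, L))

consensus_pwm <- function(word, id = "cons") {
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0.0001, 4, length(idx))
  m[cbind(idx, seq_along(idx))] <- 1
  pwm(id, m)
}

# independent naive scanner: score every window on both strands by loops
naive_count <- function(seq, scorer) {
  rc <- chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  count_one <- function(s) {
    L <- ncol(scorer$lom)
    n <- nchar(s)
    if (n < L || scorer$max_score <= 0) return(0L)
    hits <- 0L
    for (i in seq_len(n - L + 1)) {
      sc <- 0
      for (j in seq_len(L)) {
        b <- substr(s, i + j - 1, i + j - 1)
        k <- match(b, c("A", "C", "G", "T"))
        sc <- if (is.na(k)) -Inf else sc + scorer$lom[k, j]
      }
      if (sc >= scorer$threshold) hits <- hits + 1L
    }
    hits
  }
  count_one(seq) + count_one(rc)
}

test_that("uniform matrices against uniform background can never hit", {
  sc <- build_scorer(uniform_pwm(), rep(0.25, 4), pseudocount = 0.01,
                     threshold_fraction = 0.5)
  expect_equal(max(abs(sc$lom)), 0, tolerance = 1e-9)
  expect_identical(count_sites(strrep("ACGT", 50), sc), 0L)
})

test_that("scorer validates background and threshold inputs", {
  expect_error(build_scorer(uniform_pwm(), c(0, 0.5, 0.25, 0.25)),
               "strictly positive")
  expect_error(build_scorer(uniform_pwm(), c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
  expect_error(build_scorer(uniform_pwm(), threshold_fraction = 0),
               "threshold_fraction")
})

test_that("consensus-only scoring matches exhaustive 4^L word enumeration", {
  p <- consensus_pwm("ACGG")   # not reverse-complement symmetric
  sc <- build_scorer(p, rep(0.25, 4), pseudocount = 0.01,
                     threshold_fraction = 0.9)
  words <- do.call(expand.grid,
                   rep(list(c("A", "C", "G", "T")), 4))
  hit_words <- apply(words, 1, function(w)
    sum(sc$lom[cbind(match(w, c("A", "C", "G", "T")), 1:4)]) >=
      sc$threshold)
  # exactly the consensus word scores above 90% of the maximum
  expect_identical(sum(hit_words), 1L)
  expect_identical(count_sites("ACGG", sc), 1L)       # forward strand hit
  expect_identical(count_sites("CCGT", sc), 1L)       # reverse strand hit
  expect_identical(count_sites("TTTTT", sc), 0L)

  # threshold_fraction = 1 admits only the maximal-scoring word
  sc1 <- build_scorer(p, rep(0.25, 4), threshold_fraction = 1)
  expect_identical(count_sites("ACGGT", sc1), 1L)
  expect_identical(count_sites("ACGAT", sc1), 0L)
})

test_that("scanning is strand-symmetric, N-safe and short-sequence-safe", {
  p <- consensus_pwm("TGACGTCA", id = "m")
  sc <- build_scorer(p, rep(0.25, 4), threshold_fraction = 0.9)
  expect_identical(count_sites("TGACG", sc), 0L)       # shorter than motif
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_identical(count_sites(s, sc), count_sites(rc, sc))
  # windows containing N never hit
  expect_identical(count_sites("TGACNTCA", sc), 0L)
})

test_that("planted sites are counted exactly, verified by a naive window oracle", {
  word <- "TGACGTCA"
  p <- consensus_pwm(word)
  sc <- build_scorer(p, rep(0.25, 4), threshold_fraction = 0.95)
  set.seed(11)
  # background free of the motif: alternate CT blocks, then plant two sites
  base <- strsplit(strrep("CTACTGAC", 150), "")[[1]]
  base[10:17] <- strsplit(word, "")[[1]]
  base[500:507] <- strsplit(word, "")[[1]]
  s <- paste(base, collapse = "")
  expect_identical(count_sites(s, sc), naive_count(s, sc))
  expect_gte(count_sites(s, sc), 2L)

  # position independence: shifting both sites leaves the count unchanged
  base2 <- strsplit(strrep("CTACTGAC", 150), "")[[1]]
  base2[110:117] <- strsplit(word, "")[[1]]
  base2[600:607] <- strsplit(word, "")[[1]]
  expect_identical(count_sites(s, sc),
                   count_sites(paste(base2, collapse = ""), sc))

  # random-sequence agreement with the naive oracle at a loose threshold
  sc_loose <- build_scorer(p, rep(0.25, 4), threshold_fraction = 0.6)
  set.seed(3)
  for (r in 1:3) {
    sq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
    expect_identical(count_sites(sq, sc_loose), naive_count(sq, sc_loose))
  }
})

make_promoters <- function(n, len = 300, seed = 1, plant = character()) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
  names(seqs) <- sprintf("p%03d", seq_len(n))
  for (id in plant) {
    s <- strsplit(seqs[[id]], "")[[1]]
    s[50:57] <- strsplit("TGACGTCA", "")[[1]]
    s[150:157] <- strsplit("TGACGTCA", "")[[1]]
    seqs[[id]] <- paste(s, collapse = "")
  }
  promoter_set(seqs, 100, 200)
}

test_that("Z of the background against itself is exactly zero", {
  ps <- make_promoters(20, seed = 2,
                       plant = sprintf("p%03d", 1:5))
  sc <- build_scorer(consensus_pwm("TGACGTCA"), rep(0.25, 4),
                     threshold_fraction = 0.85)
  r <- zscore_overrep(ps, ps, sc)
  expect_true(r$defined)
  expect_equal(r$z, 0)
})

test_that("planted foregrounds score Z > 0 and depleted ones Z < 0", {
  planted <- sprintf("p%03d", 1:8)
  ps <- make_promoters(40, seed = 3, plant = planted)
  sc <- build_scorer(consensus_pwm("TGACGTCA"), rep(0.25, 4),
                     threshold_fraction = 0.85)
  fg_plant <- promoter_set(ps$sequences[planted], 100, 200)
  fg_rest <- promoter_set(ps$sequences[setdiff(names(ps$sequences),
                                               planted)], 100, 200)
  z_plant <- zscore_overrep(fg_plant, ps, sc)
  z_rest <- zscore_overrep(fg_rest, ps, sc)
  expect_gt(z_plant$z, 3)
  expect_lt(z_rest$z, 0)
  outsider <- promoter_set(c(q1 = "ACGTACGTACGT"), 100, 200)
  expect_error(zscore_overrep(outsider, ps, sc), "subset")
})

test_that("analytic Z agrees with a resampling oracle on homogeneous sets", {
  # homogeneous background (hits only from chance occurrences at a loose
  # threshold): the regime in which the binomial window null is exact
  ps <- make_promoters(60, seed = 4)
  sc <- build_scorer(consensus_pwm("TGACG"), rep(0.25, 4),
                     threshold_fraction = 0.85)
  counts <- vapply(ps$sequences, count_sites, 0L, scorer = sc)
  expect_gt(sum(counts), 20)            # enough hits to standardize
  ids <- names(ps$sequences)
  fg_ids <- ids[1:12]
  obs <- sum(counts[fg_ids])
  z_analytic <- zscore_overrep(
    promoter_set(ps$sequences[fg_ids], 100, 200), ps, sc,
    bg_counts = counts)$z
  set.seed(7)
  null_counts <- vapply(1:1000, function(b)
    sum(counts[sample(ids, length(fg_ids))]), 0)
  z_resamp <- (obs - mean(null_counts)) / sd(null_counts)
  expect_equal(sign(z_analytic), sign(z_resamp))
  expect_lt(abs(z_analytic - z_resamp), 0.5)

  # heterogeneous (planted) sets: sign agreement still holds
  ps2 <- make_promoters(60, seed = 14, plant = sprintf("p%03d", 1:6))
  sc2 <- build_scorer(consensus_pwm("TGACGTCA"), rep(0.25, 4),
                      threshold_fraction = 0.85)
  counts2 <- vapply(ps2$sequences, count_sites, 0L, scorer = sc2)
  fg2 <- sprintf("p%03d", 1:12)
  z2 <- zscore_overrep(promoter_set(ps2$sequences[fg2], 100, 200), ps2,
                       sc2, bg_counts = counts2)$z
  set.seed(15)
  null2 <- vapply(1:1000, function(b)
    sum(counts2[sample(names(counts2), 12)]), 0)
  expect_equal(sign(z2), sign((sum(counts2[fg2]) - mean(null2)) / sd(null2)))
})

test_that("uniformly drawn foregrounds have near-zero mean Z", {
  ps <- make_promoters(60, seed = 6)
  sc <- build_scorer(consensus_pwm("TGACG"), rep(0.25, 4),
                     threshold_fraction = 0.85)
  counts <- vapply(ps$sequences, count_sites, 0L, scorer = sc)
  ids <- names(ps$sequences)
  set.seed(8)
  zs <- vapply(1:200, function(b) {
    fg <- sample(ids, 15)
    zscore_overrep(promoter_set(ps$sequences[fg], 100, 200), ps, sc,
                   bg_counts = counts)$z
  }, 0)
  expect_lt(abs(mean(zs)), 0.1)
})

test_that("the Z matrix flags undefined cells and applies the |Z| > 3 rule", {
  ps <- make_promoters(30, seed = 10, plant = sprintf("p%03d", 1:10))
  membership <- setNames(rep(1:3, each = 10), names(ps$sequences))
  sc_hit <- build_scorer(consensus_pwm("TGACGTCA"), rep(0.25, 4),
                         threshold_fraction = 0.85)
  sc_none <- build_scorer(consensus_pwm("GGGGGGGGGGGG", id = "never"),
                          rep(0.25, 4), threshold_fraction = 1)
  zm <- zscore_matrix(membership, ps, list(sc_hit, sc_none))
  expect_false(any(zm$defined[, "never"]))     # motif with no hits anywhere
  expect_true(all(is.na(zm$z[, "never"])))
  expect_true(all(zm$defined[, "cons"]))
  over <- zm$calls[zm$calls$call == "over", ]
  expect_true(all(over$z > 3))
  expect_identical(over$cluster, 1L)           # only the planted cluster
  # cells between -3 and 3 are not reported
  expect_true(all(abs(zm$calls$z) > 3))
})

test_that("clustered genes without promoters are excluded with a warning", {
  ps <- make_promoters(10, seed = 12)
  membership <- setNames(rep(1:2, each = 6), sprintf("p%03d", 1:12))
  sc <- build_scorer(consensus_pwm("TGACGTCA"), rep(0.25, 4),
                     threshold_fraction = 0.6)
  expect_warning(zscore_matrix(membership, ps, list(sc)), "lack a promoter")
})

test_that("two-way ordering scales cluster Z vectors to unit variance", {
  set.seed(13)
  z <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(1:8, paste0("m", 1:6)))
  z[1:4, 1:3] <- z[1:4, 1:3] + 6        # block structure
  zm <- structure(list(z = z, defined = matrix(TRUE, 8, 6,
                                               dimnames = dimnames(z))),
                  class = "ZScoreMatrix")
  res <- zmatrix_cluster(zm)
  expect_equal(unname(apply(res$scaled, 1, var)), rep(1, 8))
  # block split first on the cluster dendrogram
  top_split <- cutree(res$cluster_hc, k = 2)
  expect_length(unique(top_split[1:4]), 1L)
  expect_length(unique(top_split[5:8]), 1L)
  # duplicated motif columns end up adjacent
  z2 <- cbind(z, m7 = z[, 1])
  zm2 <- structure(list(z = z2,
                        defined = matrix(TRUE, 8, 7,
                                         dimnames = dimnames(z2))),
                   class = "ZScoreMatrix")
  res2 <- zmatrix_cluster(zm2)
  pos <- match(c("m1", "m7"), res2$motif_order)
  expect_equal(abs(diff(pos)), 1)
})

test_that("PCA of Z vectors matches an eigendecomposition oracle", {
  z <- matrix(c(4, 1, 0,
                1, 3, 1,
                0, 1, 2), 3, 3, byrow = TRUE,
              dimnames = list(1:3, paste0("m", 1:3)))
  zm <- structure(list(z = z, defined = matrix(TRUE, 3, 3,
                                               dimnames = dimnames(z))),
                  class = "ZScoreMatrix")
  res <- zmatrix_pca(zm)
  ctr <- scale(z, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(ctr))
  proj <- ctr %*% eig$vectors[, 1:2]
  for (j in 1:2) {
    top <- which.max(abs(eig$vectors[, j]))
    if (eig$vectors[top, j] < 0) proj[, j] <- -proj[, j]
  }
  expect_equal(unname(res$scores), unname(proj), tolerance = 1e-10)
  expect_gte(var(res$scores[, 1]), var(res$scores[, 2]))

  # identical clusters project identically
  z_dup <- rbind(z, z[3, , drop = FALSE])
  rownames(z_dup) <- 1:4
  zm_dup <- structure(list(z = z_dup,
                           defined = matrix(TRUE, 4, 3,
                                            dimnames = dimnames(z_dup))),
                      class = "ZScoreMatrix")
  res_dup <- zmatrix_pca(zm_dup)
  expect_equal(res_dup$scores[3, ], res_dup$scores[4, ],
               ignore_attr = TRUE)
  expect_error(zmatrix_pca(zm2 <- structure(
    list(z = z[1:2, ], defined = matrix(TRUE, 2, 3)),
    class = "ZScoreMatrix")), ">= 3")
})
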