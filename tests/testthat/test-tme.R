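## small helper: scores for k well-separated Gaussian blobs
blobScores <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ], each = n_per),
                 sd = sd), n_per, ncol(centers))))
  colnames(X) <- colnames(centers)
  rownames(X) <- sprintf("s%03d", seq_len(nrow(X)))
  list(scores = new("ScoreMatrix", scores = X, method = "ssgsea",
                    normalization = "none"),
       truth = rep(seq_len(k), each = n_per))
}

test_that("well-separated blobs are recovered at the correct k", {
  centers <- matrix(c(5, 0, 0, 0,
                      0, 5, 0, 0,
                      0, 0, 5, 0,
                      0, 0, 0, 5), 4, byrow = TRUE,
                    dimnames = list(NULL, paste0("Sig", 1:4)))
  for (method in c("ward", "kmeans")) {
    bl <- blobScores(12, centers, seed = 2)
    a <- clusterScores(bl$scores, clusterConfig(method = method, seed = 1))
    expect_equal(a@k, 4L)
    expect_equal(mclust::adjustedRandIndex(clusterAssignments(a), bl$truth), 1)
    expect_false(a@weakStructure)
  }
})

test_that("clustering is deterministic and invariant to sample order", {
  centers <- matrix(c(4, 0, 0, 4, 4, 4), 3, 2,
                    dimnames = list(NULL, c("Sig1", "Sig2")))
  bl <- blobScores(10, centers, seed = 5)
  cfg <- clusterConfig(method = "kmeans", seed = 11)
  a1 <- clusterScores(bl$scores, cfg)
  a2 <- clusterScores(bl$scores, cfg)
  expect_identical(clusterAssignments(a1), clusterAssignments(a2))

  perm <- sample(nrow(scoreValues(bl$scores)))
  shuffled <- new("ScoreMatrix", scores = scoreValues(bl$scores)[perm, ],
                  method = "ssgsea", normalization = "none")
  a3 <- clusterScores(shuffled, cfg)
  common <- intersect(names(clusterAssignments(a1)), names(clusterAssignments(a3)))
  expect_equal(mclust::adjustedRandIndex(clusterAssignments(a1)[common],
                                         clusterAssignments(a3)[common]), 1)
})

test_that("z-scaling makes clustering invariant to affine rescaling of scores", {
  centers <- matrix(c(4, 0, 0, 4, 4, 4, 0, 0), 4, 2,
                    dimnames = list(NULL, c("Sig1", "Sig2")))
  bl <- blobScores(10, centers, seed = 7)
  X2 <- scoreValues(bl$scores)
  X2[, 1] <- X2[, 1] * 100 - 3
  rescaled <- new("ScoreMatrix", scores = X2, method = "ssgsea",
                  normalization = "none")
  cfg <- clusterConfig(method = "ward", scaling = "zscore", seed = 1)
  a1 <- clusterScores(bl$scores, cfg)
  a2 <- clusterScores(rescaled, cfg)
  expect_equal(mclust::adjustedRandIndex(clusterAssignments(a1),
                                         clusterAssignments(a2)), 1)
})

test_that("structureless data raises the weak-structure flag", {
  set.seed(91)
  ## one isotropic blob across eight uncorrelated signatures: any partition
  ## is arbitrary and the silhouette stays low
  X <- matrix(rnorm(80 * 8), 80, 8,
              dimnames = list(sprintf("s%02d", 1:80), paste0("Sig", 1:8)))
  sm <- new("ScoreMatrix", scores = X, method = "ssgsea",
            normalization = "none")
  a <- clusterScores(sm, clusterConfig(seed = 1))
  expect_true(a@weakStructure)
  expect_lt(a@silhouette, 0.25)
  expect_identical(a@weakStructure, a@silhouette < 0.25)
})

test_that("fixed-k selection and small-sample k_max lowering work", {
  centers <- matrix(c(5, 0, 0, 5), 2, 2,
                    dimnames = list(NULL, c("Sig1", "Sig2")))
  bl <- blobScores(4, centers, seed = 3)   # 8 samples < k_max + 1
  expect_warning(a <- clusterScores(bl$scores,
                                    clusterConfig(selection = "fixed_k",
                                                  k_fixed = 2, seed = 1)),
                 "lowering k_max")
  expect_equal(a@k, 2L)
  expect_error(clusterConfig(selection = "fixed_k"), "requires k_fixed")
})

test_that("semantic labels follow the median-split rule on engineered centroids", {
  ## four clusters at the four corners of (barrier, exhaustion) space
  X <- rbind(matrix(rep(c(2, -2), each = 6), 6),
             matrix(rep(c(-2, 2), each = 6), 6),
             matrix(rep(c(2, 2), each = 6), 6),
             matrix(rep(c(-2, -2), each = 6), 6))
  X <- X + rnorm(length(X), 0, 0.05)
  colnames(X) <- c("barrier", "exhaustion")
  rownames(X) <- sprintf("s%02d", 1:24)
  sm <- new("ScoreMatrix", scores = X, method = "ssgsea", normalization = "none")
  a <- clusterScores(sm, clusterConfig(scaling = "none", seed = 1))
  a <- labelSubtypes(a, "barrier", "exhaustion")
  lab <- sampleSubtypes(a)
  expect_identical(unname(lab[1]), "barrier_dominant")
  expect_identical(unname(lab[7]), "exhaustion_dominant")
  expect_identical(unname(lab[13]), "barrier_with_exhaustion")
  expect_identical(unname(lab[19]), "desert")

  ## relabeling cluster ids does not change the sample -> label map
  b <- a
  perm <- rev(seq_len(b@k))
  b@clusters <- setNames(perm[a@clusters], names(a@clusters))
  b@centroids <- a@centroids[order(perm), , drop = FALSE]
  rownames(b@centroids) <- seq_len(b@k)
  b <- labelSubtypes(b, "barrier", "exhaustion")
  expect_identical(sampleSubtypes(b), lab)

  expect_error(labelSubtypes(a, "barrier", "nope"), "absent")
})

test_that("two clusters get two labels without error", {
  centers <- matrix(c(3, -3, -3, 3), 2, 2,
                    dimnames = list(NULL, c("barrier", "exhaustion")))
  bl <- blobScores(10, centers, sd = 0.2, seed = 9)
  a <- clusterScores(bl$scores, clusterConfig(seed = 1))
  a <- labelSubtypes(a, "barrier", "exhaustion")
  expect_equal(a@k, 2L)
  expect_length(unique(sampleSubtypes(a)), 2L)
})

test_that("end-to-end synthetic subtype recovery is exact under strong effects", {
  for (sd in 1:2) {
    cfg <- bulkSimConfig(n_samples = 60, seed = sd)   # effect = 5 x noise sd
    b <- simulateBulkMixtures(cfg)
    sc <- ssgseaScore(b, cfg$signatures)
    a <- clusterScores(sc, clusterConfig(method = "ward", seed = sd))
    expect_equal(a@k, 4L)
    expect_gte(mclust::adjustedRandIndex(clusterAssignments(a),
                                         cfg$group_assignments), 0.9)
  }
})

test_that("constant score columns are dropped with a warning", {
  X <- cbind(Sig1 = rnorm(30), Sig2 = rep(1, 30))
  rownames(X) <- sprintf("s%02d", 1:30)
  sm <- new("ScoreMatrix", scores = X, method = "ssgsea", normalization = "none")
  expect_warning(a <- clusterScores(sm, clusterConfig(seed = 1)), "constant")
  expect_identical(colnames(a@centroids), "Sig1")
})
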