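test_that("module score is zero on a constant matrix and seed-stable", {
  m <- matrix(3, 60, 10, dimnames = list(sprintf("g%02d", 1:60),
                                         sprintf("c%02d", 1:10)))
  expr <- makeExpr(m, rep("A", 10))
  sc <- moduleScore(expr, list(S = c("g01", "g02", "g03")), n_bins = 5,
                    n_ctrl = 10, seed = 1)
  expect_true(all(abs(scoreValues(sc)) < 1e-12))

  set.seed(99)  # outside seed must not matter
  e2 <- simulateScCounts(scSimConfig(n_cell_types = 2, cells_per_type = 20,
                                     n_genes = 100, seed = 4))
  s1 <- moduleScore(e2, list(S = sprintf("G%05d", 1:5)), seed = 7)
  s2 <- moduleScore(e2, list(S = sprintf("G%05d", 1:5)), seed = 7)
  expect_identical(scoreValues(s1), scoreValues(s2))
})

test_that("a spiked signature scores highest in the spiked cell type", {
  for (sd in 1:3) {
    e <- simulateScCounts(scSimConfig(n_cell_types = 3, cells_per_type = 50,
                                      n_genes = 200, n_markers_per_type = 8,
                                      marker_log2fc = 2, seed = sd))
    truth <- metadata(e)$truth$markers
    sc <- scoreValues(moduleScore(e, list(CT01sig = truth$CT01), seed = 1))
    lab <- cellLabels(e)
    means <- tapply(sc[, 1], lab, mean)
    expect_identical(names(which.max(means)), "CT01")
  }
})

test_that("AUC recovery score hits its extremes", {
  G <- 100
  genes <- sprintf("g%03d", 1:G)
  x <- seq(G, 1)                       # g001 highest ... g100 lowest
  m <- matrix(x, G, 1, dimnames = list(genes, "c1"))
  expr <- makeExpr(m, "A")
  topSig <- list(S = genes[1:5])       # occupies the very top ranks
  expect_equal(scoreValues(aucSetScore(expr, topSig, top_frac = 0.05))[1, 1], 1)
  botSig <- list(S = genes[90:100])    # entirely outside the top 5
  expect_equal(scoreValues(aucSetScore(expr, botSig, top_frac = 0.05))[1, 1], 0)
  expect_error(aucSetScore(expr, topSig, top_frac = 0), "top_frac")
  expect_error(aucSetScore(expr, topSig, top_frac = 1.5), "top_frac")
})

test_that("AUC score equals the step-function integration oracle", {
  set.seed(81)
  G <- 100
  genes <- sprintf("g%03d", 1:G)
  m <- matrix(rpois(G * 4, 5), G, 4, dimnames = list(genes, paste0("c", 1:4)))
  expr <- makeExpr(m, rep("A", 4))
  sigIdx <- sort(sample(G, 10))
  sigs <- list(S = genes[sigIdx])
  got <- scoreValues(aucSetScore(expr, sigs, top_frac = 0.2, seed = 3))
  set.seed(3)
  shuffle <- sample(G)
  for (j in 1:4)
    expect_equal(got[j, 1], oracleAucScore(m[, j], shuffle, sigIdx, 0.2),
                 tolerance = 1e-12)
})

test_that("rank-based scores are invariant to per-sample monotone transforms", {
  set.seed(82)
  G <- 80
  genes <- sprintf("g%03d", 1:G)
  m <- matrix(rlnorm(G * 5, 2, 1), G, 5, dimnames = list(genes, paste0("s", 1:5)))
  mono <- exp(m / 3) + m^2             # strictly increasing transform
  sigs <- list(S1 = genes[1:10], S2 = genes[40:60])
  e1 <- makeExpr(m, rep("A", 5), unit = "sample")
  e2 <- makeExpr(mono, rep("A", 5), unit = "sample")
  expect_equal(scoreValues(ssgseaScore(e1, sigs)),
               scoreValues(ssgseaScore(e2, sigs)), tolerance = 1e-10)
  expect_equal(scoreValues(aucSetScore(e1, sigs, top_frac = 0.2)),
               scoreValues(aucSetScore(e2, sigs, top_frac = 0.2)),
               tolerance = 1e-12)
})

test_that("ssGSEA is monotone in set-gene ranks and matches the running-sum oracle", {
  genes <- sprintf("g%d", 1:8)
  ## sample A ranks all set genes on top, B the reverse
  X <- cbind(A = c(8, 7, 6, 5, 4, 3, 2, 1), B = c(1, 2, 3, 4, 5, 6, 7, 8))
  rownames(X) <- genes
  sigs <- list(S = genes[1:3])
  sc <- scoreValues(ssgseaScore(makeExpr(X, c("x", "y"), unit = "sample"),
                                sigs, ssgseaConfig(normalize = FALSE)))
  expect_gt(sc["A", "S"], sc["B", "S"])

  ## worked 8-gene / 3-sample matrix against the independent oracle
  set.seed(83)
  W <- matrix(rlnorm(24, 3, 1), 8, 3,
              dimnames = list(genes, c("s1", "s2", "s3")))
  sigs2 <- list(S = c("g2", "g5", "g7"))
  for (norm in c(TRUE, FALSE)) {
    got <- scoreValues(ssgseaScore(makeExpr(W, rep("A", 3), unit = "sample"),
                                   sigs2, ssgseaConfig(normalize = norm)))
    want <- oracleSsgsea(W, sigs2, alpha = 0.25, normalize = norm)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("scores are invariant to gene-row reordering", {
  set.seed(84)
  G <- 60
  genes <- sprintf("g%03d", 1:G)
  m <- matrix(rpois(G * 4, 6), G, 4, dimnames = list(genes, paste0("c", 1:4)))
  perm <- sample(G)
  e1 <- makeExpr(m, rep("A", 4), unit = "sample")
  e2 <- makeExpr(m[perm, ], rep("A", 4), unit = "sample")
  sigs <- list(S = genes[5:20])
  expect_equal(scoreValues(ssgseaScore(e1, sigs)),
               scoreValues(ssgseaScore(e2, sigs)), tolerance = 1e-10)
  expect_equal(scoreValues(aucSetScore(e1, sigs, top_frac = 0.25, seed = 1)),
               scoreValues(aucSetScore(e2, sigs, top_frac = 0.25, seed = 1)),
               tolerance = 1e-12)
})

test_that("a gene ranked last everywhere never increases the AUC score", {
  set.seed(85)
  G <- 50
  genes <- sprintf("g%03d", 1:G)
  m <- matrix(rpois(G * 3, 5) + 1, G, 3, dimnames = list(genes, paste0("c", 1:3)))
  m[G, ] <- 0                          # strictly last in every cell
  expr <- makeExpr(m, rep("A", 3))
  base <- list(S = genes[1:8])
  ext <- list(S = c(genes[1:8], genes[G]))
  s1 <- scoreValues(aucSetScore(expr, base, top_frac = 0.3, seed = 2))
  s2 <- scoreValues(aucSetScore(expr, ext, top_frac = 0.3, seed = 2))
  expect_true(all(s2 <= s1 + 1e-12))
})

test_that("ssGSEA subtype ordering follows the planted effects", {
  for (sd in 1:3) {
    cfg <- bulkSimConfig(n_samples = 40, seed = sd)
    b <- simulateBulkMixtures(cfg)
    sc <- scoreValues(ssgseaScore(b, cfg$signatures))
    grp <- cfg$group_assignments
    for (j in 1:4) {
      means <- tapply(sc[, j], grp, mean)
      expect_identical(as.integer(names(which.max(means))), j)
    }
  }
})

test_that("missing and tiny signatures are handled as contracted", {
  m <- matrix(rpois(200, 4), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), paste0("c", 1:4)))
  expr <- makeExpr(m, rep("A", 4), unit = "sample")
  expect_error(moduleScore(expr, list(S = c("nope1", "nope2")), n_bins = 5),
               "no genes")
  expect_warning(
    sc <- ssgseaScore(expr, list(ok = c("g01", "g02", "g03"),
                                 tiny = c("g04", "zzz"))),
    "skipping")
  expect_identical(colnames(scoreValues(sc)), "ok")
  expect_error(suppressWarnings(ssgseaScore(expr, list(tiny = "g01"))),
               "no scorable")
})
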