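## builds a matrix with prescribed per-cell library size and mito fraction
qcFixture <- function(umi, mito_frac) {
  n <- length(umi)
  mito <- round(umi * mito_frac)
  m <- rbind(`MT-1` = mito, G1 = umi - mito)
  colnames(m) <- sprintf("c%d", seq_len(n))
  makeExpr(m, labels = rep("A", n))
}

test_that("UMI and mito thresholds are exclusionary at the boundary", {
  expr <- qcFixture(umi = c(1500, 2000, 2500, 3000, 2100),
                    mito_frac = c(0.01, 0.01, 0.06, 0.02, 0.049))
  out <- filterCells(expr, qcThresholds())
  expect_equal(ncol(out), 2L)
  expect_identical(colnames(out), c("c4", "c5"))
  rep <- metadata(out)$qc_report
  expect_equal(rep$n_removed_library, 2)
  expect_equal(rep$n_removed_mito, 1)

  ## clean cells are all retained
  expr2 <- qcFixture(umi = rep(10000, 4), mito_frac = rep(0, 4))
  expect_equal(ncol(filterCells(expr2)), 4L)
})

test_that("missing mitochondrial genes skip that criterion with a warning", {
  m <- matrix(3000, 1, 3, dimnames = list("G1", paste0("c", 1:3)))
  expr <- makeExpr(m, rep("A", 3))
  expect_warning(out <- filterCells(expr), "mitochondrial")
  expect_equal(ncol(out), 3L)
})

test_that("gene detection filter keeps the exact boundary", {
  m <- matrix(0, 3, 5, dimnames = list(c("g2cells", "g3cells", "g5cells"),
                                       paste0("c", 1:5)))
  m["g2cells", 1:2] <- 1
  m["g3cells", 1:3] <- 1
  m["g5cells", ] <- 1
  expr <- makeExpr(m, rep("A", 5))
  out <- filterGenes(expr, qcThresholds())
  expect_identical(rownames(out), c("g3cells", "g5cells"))

  flagged <- filterGenes(expr, qcThresholds(), mode = "flag")
  expect_equal(nrow(flagged), 3L)
  expect_identical(unname(rowData(flagged)$detected), c(FALSE, TRUE, TRUE))

  expect_error(filterGenes(expr, qcThresholds(min_cells_per_gene = 10)),
               "no genes")
})

test_that("gene filter agrees with a brute-force recount on random data", {
  set.seed(51)
  m <- matrix(rpois(200 * 100, 0.05), 200, 100,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%03d", 1:100)))
  expr <- makeExpr(m, rep("A", 100))
  out <- filterGenes(expr, qcThresholds(min_cells_per_gene = 3))
  keepOracle <- rownames(m)[vapply(seq_len(nrow(m)),
                                   function(i) sum(m[i, ] > 0) >= 3, logical(1))]
  expect_identical(rownames(out), keepOracle)
})

test_that("spot filters apply in the stated order with literal boundaries", {
  set.seed(52)
  ## 250 genes x 6 spots; spots 1-2 detect fewer than 200 genes
  m <- matrix(rpois(250 * 6, 3), 250, 6,
              dimnames = list(sprintf("g%03d", 1:250), sprintf("s%d", 1:6)))
  m[, 1] <- 0; m[1:199, 1] <- 1        # 199 detected -> removed
  m[, 2] <- 0; m[1:200, 2] <- 1        # 200 detected -> kept
  ## gene with total count 9 in the surviving spots -> removed
  m["g250", ] <- 0
  m["g250", 3:5] <- 3
  expr <- makeExpr(m, rep("slide", 6), unit = "spot")
  out <- filterSpots(expr, qcThresholds())
  expect_false("s1" %in% colnames(out))
  expect_true("s2" %in% colnames(out))
  expect_false("g250" %in% rownames(out))

  ## brute-force oracle on the full result
  keepSpot <- colSums(m > 0) >= 200
  m2 <- m[, keepSpot]
  keepGene <- rowSums(m2) >= 10 & rowSums(m2 > 0) >= 3
  expect_identical(dim(out), c(sum(keepGene), sum(keepSpot)))
  expect_identical(rownames(out), rownames(m)[keepGene])
})

test_that("cell and gene filters are idempotent", {
  set.seed(53)
  e <- simulateScCounts(scSimConfig(n_cell_types = 2, cells_per_type = 30,
                                    n_genes = 100, baseline_mean = 30,
                                    seed = 3))
  qc <- qcThresholds(min_umi_exclusive = 2500, max_mito_frac_exclusive = 0.05)
  once <- filterGenes(filterCells(e, qc), qc)
  twice <- filterGenes(filterCells(once, qc), qc)
  expect_identical(dim(once), dim(twice))
  expect_identical(as.matrix(assay(once)), as.matrix(assay(twice)))
})

test_that("planted markers are recovered in their type's signature", {
  for (sd in 1:3) {
    e <- simulateScCounts(scSimConfig(n_cell_types = 3, cells_per_type = 60,
                                      n_genes = 150, n_markers_per_type = 5,
                                      marker_log2fc = 2, seed = sd))
    sigs <- rankMarkers(e, markerCriteria())
    truth <- metadata(e)$truth$markers
    for (ct in names(truth))
      expect_true(all(truth[[ct]] %in% sigs[[ct]]),
                  label = sprintf("seed %d type %s planted markers in signature",
                                  sd, ct))
  }
})

test_that("marker criteria and truncation are enforced", {
  e <- simulateScCounts(scSimConfig(n_cell_types = 2, cells_per_type = 100,
                                    n_genes = 200, n_markers_per_type = 50,
                                    marker_log2fc = 3, seed = 17))
  sigs <- rankMarkers(e, markerCriteria(top_n = 30))
  expect_true(all(lengths(sigs) <= 30))
  expect_equal(length(sigs$CT01), 30L)  # 50 strong markers truncated to 30

  stats <- attr(sigs, "stats")
  ## no selected gene violates either criterion
  for (ct in names(sigs)) {
    sel <- stats[stats$cell_type == ct & stats$gene %in% sigs[[ct]], ]
    expect_true(all(sel$p_adj <= 0.05))
    expect_true(all(sel$avg_log2FC >= 0.15))
  }
  ## genes passing p but failing the fold-change floor are excluded
  weak <- stats[stats$p_adj <= 0.05 & stats$avg_log2FC < 0.15 &
                  stats$cell_type == "CT01", "gene"]
  expect_false(any(weak %in% sigs$CT01))
  ## signatures exclude zero-variance genes
  X <- as.matrix(assay(e))
  zeroVar <- rownames(X)[apply(X, 1, sd) == 0]
  expect_false(any(zeroVar %in% unlist(sigs)))
})

test_that("tiny cell types are skipped with a warning", {
  m <- matrix(rpois(50 * 12, 2), 50, 12,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:12)))
  expr <- makeExpr(m, c(rep("A", 5), rep("B", 5), rep("C", 2)))
  expect_warning(sigs <- rankMarkers(expr), "< 3 cells")
  expect_false("C" %in% names(sigs))
  expect_error(suppressWarnings(rankMarkers(expr[, 1:7])),
               "two cell types")  # only A has >= 3 cells
})
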