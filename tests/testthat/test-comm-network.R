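## fixture with exactly controlled expression: every cell of a type has the
## same column profile, so trimmed means are exact and strengths closed-form
constantExpr <- function(profiles, cells_per_type = 6) {
  types <- colnames(profiles)
  m <- profiles[, rep(types, each = cells_per_type)]
  colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  makeExpr(m, labels = rep(types, each = cells_per_type))
}

test_that("zero ligand expression gives zero strength", {
  profiles <- matrix(c(0, 5, 10,
                       4, 5, 10), nrow = 3,
                     dimnames = list(c("LIG", "REC", "FILL"), c("S", "R")))
  expr <- constantExpr(profiles)
  st <- commStrength(expr, data.frame(ligand = "LIG", receptor = "REC"))
  expect_equal(st$strength[st$sender == "S" & st$receiver == "S"], 0)
  expect_true(all(st$strength >= 0 & st$strength < 1))
})

test_that("strength is 0.5 exactly at half-saturation", {
  profiles <- matrix(c(7, 7, 10), nrow = 3, ncol = 1,
                     dimnames = list(c("LIG", "REC", "FILL"), "A"))
  expr <- constantExpr(profiles)
  ## every cell is identical, so L = R = log1p(7 / 24 * 1e4)
  L <- log1p(7 / 24 * 1e4)
  st <- commStrength(expr, data.frame(ligand = "LIG", receptor = "REC"),
                     commConfig(hill_k = L * L))
  expect_equal(st$strength, 0.5, tolerance = 1e-12)
})

test_that("multi-subunit pairs use the geometric mean and vanish if any subunit is silent", {
  profiles <- matrix(c(4, 9, 5, 10,
                       4, 0, 5, 10), nrow = 4,
                     dimnames = list(c("L1", "L2", "REC", "FILL"), c("A", "B")))
  expr <- constantExpr(profiles)
  st <- commStrength(expr, data.frame(ligand = "L1+L2", receptor = "REC"),
                     commConfig(hill_k = 0.5))
  sB <- st[st$sender == "B", ]
  expect_true(all(sB$strength == 0))    # L2 silent in B
  sA <- st[st$sender == "A" & st$receiver == "A", ]
  lib <- 4 + 9 + 5 + 10
  Lexp <- sqrt(log1p(4 / lib * 1e4) * log1p(9 / lib * 1e4))
  expect_equal(sA$L, Lexp, tolerance = 1e-10)
})

test_that("absent pair genes score zero with a note", {
  profiles <- matrix(c(4, 5), nrow = 2, ncol = 1,
                     dimnames = list(c("LIG", "REC"), "A"))
  expr <- constantExpr(profiles)
  expect_message(
    st <- commStrength(expr, data.frame(ligand = "NOPE", receptor = "REC")),
    "absent")
  expect_true(all(st$strength == 0))
})

test_that("cell types below min_cells are excluded and appear isolated", {
  profiles <- matrix(c(5, 5, 10,
                       5, 5, 10), nrow = 3,
                     dimnames = list(c("LIG", "REC", "FILL"), c("A", "B")))
  m <- profiles[, c(rep("A", 6), rep("B", 3))]
  colnames(m) <- sprintf("c%d", 1:9)
  expr <- makeExpr(m, c(rep("A", 6), rep("B", 3)))
  st <- commStrength(expr, data.frame(ligand = "LIG", receptor = "REC"),
                     commConfig(min_cells = 5))
  expect_false("B" %in% c(st$sender, st$receiver))
  net <- aggregateNetwork(st)
  expect_true("B" %in% networkNodes(net))
  e <- networkEdges(net)
  expect_false("B" %in% c(e$from, e$to))
})

test_that("network aggregation is additive over pairs", {
  profiles <- matrix(c(3, 0, 2, 0, 10,
                       0, 4, 0, 5, 10), nrow = 5,
                     dimnames = list(c("L1", "R1", "L2", "R2", "FILL"),
                                     c("A", "B")))
  expr <- constantExpr(profiles)
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                      pathway = c("p1", "p2"))
  st <- commStrength(expr, pairs)
  net <- aggregateNetwork(st)
  e <- networkEdges(net)
  ab <- e$weight[e$from == "A" & e$to == "B"]
  sAB <- st$strength[st$sender == "A" & st$receiver == "B"]
  expect_equal(ab, sum(sAB), tolerance = 1e-12)
  ## brute-force group-by-sum over the whole table
  agg <- aggregate(strength ~ sender + receiver, st, sum)
  agg <- agg[agg$strength > 0, ]
  for (i in seq_len(nrow(agg)))
    expect_equal(e$weight[e$from == agg$sender[i] & e$to == agg$receiver[i]],
                 agg$strength[i], tolerance = 1e-12)
})

test_that("removing a pair never increases any edge weight", {
  set.seed(61)
  e <- simulateScCounts(scSimConfig(n_cell_types = 3, cells_per_type = 30,
                                    n_genes = 100, seed = 2))
  pairs <- data.frame(ligand = c("G00070", "G00072"),
                      receptor = c("G00071", "G00073"))
  full <- adjacencyMatrix(aggregateNetwork(commStrength(e, pairs)))
  part <- adjacencyMatrix(aggregateNetwork(commStrength(e, pairs[1, ])))
  expect_true(all(part <= full + 1e-12))
})

test_that("planted sender-receiver pairs carry the top directed strength", {
  hits <- vapply(1:10, function(sd) {
    e <- simulateScCounts(scSimConfig(
      n_cell_types = 3, cells_per_type = 80, n_genes = 120,
      n_markers_per_type = 5,
      lr_plants = list(list(ligand = 100, receptor = 101, sender = 1,
                            receiver = 2, fc = 8)), seed = sd))
    st <- commStrength(e, data.frame(ligand = "G00100", receptor = "G00101"))
    top <- st[which.max(st$strength), ]
    top$sender == "CT01" && top$receiver == "CT02"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("group comparison has a valid exchangeable null and add-one floor", {
  set.seed(62)
  mk <- function(sd) simulateScCounts(scSimConfig(
    n_cell_types = 2, cells_per_type = 40, n_genes = 60,
    n_markers_per_type = 0, seed = sd))
  groups <- list(NR = list(mk(1), mk(2), mk(3)), R = list(mk(4), mk(5), mk(6)))
  pairs <- data.frame(ligand = "G00030", receptor = "G00031")
  res <- compareGroups(groups, pairs, n_perm = 99, seed = 1)
  expect_true(all(res$p >= 0.01))
  expect_gte(median(res$p), 0.5)
  expect_error(compareGroups(list(NR = list(mk(1)), R = list(mk(2), mk(3))),
                             pairs), "at least 2 samples")
})

test_that("a planted group-specific boost is detected by permutation", {
  mkBoost <- function(sd) simulateScCounts(scSimConfig(
    n_cell_types = 2, cells_per_type = 60, n_genes = 60,
    n_markers_per_type = 0,
    lr_plants = list(list(ligand = 30, receptor = 31, sender = 1,
                          receiver = 2, fc = 10)), seed = sd))
  mkNull <- function(sd) simulateScCounts(scSimConfig(
    n_cell_types = 2, cells_per_type = 60, n_genes = 60,
    n_markers_per_type = 0, seed = sd))
  hits <- vapply(1:5, function(rep) {
    groups <- list(NR = lapply(rep * 20 + 1:5, mkBoost),
                   R = lapply(rep * 20 + 6:10, mkNull))
    res <- compareGroups(groups, data.frame(ligand = "G00030",
                                            receptor = "G00031"),
                         n_perm = 199, seed = rep)
    key <- res$sender == "CT01" & res$receiver == "CT02"
    res$p[key] < 0.05 && res$diff[key] > 0
  }, logical(1))
  expect_gte(sum(hits), 4)
})
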