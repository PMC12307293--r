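## Degree-preserving rewired null ensemble for motif significance.

## internal: rewire the non-loop arcs of an integer edge list once
#' @noRd
.rewireOnce <- function(f, t, w, n_nodes, attempts, weight_mode) {
  r <- rewire_edges_cpp(f, t, n_nodes, attempts)
  if (weight_mode == "shuffle" && length(w) > 1) w <- sample(w)
  list(from = r$from, to = r$to, weight = w, accepted = r$accepted)
}

#' Degree-preserving rewiring of a communication network
#'
#' Randomizes a simple weighted digraph by attempted directed double-edge
#' swaps: arcs (u1 -> v1, u2 -> v2) become (u1 -> v2, u2 -> v1) unless a
#' self-loop or duplicate arc would arise. Every node keeps its exact in-
#' and out-degree, and (in the default `"ride"` mode) each arc keeps its
#' weight, so the edge-weight multiset is preserved. Self-loop edges present
#' in the input are left untouched and never swapped.
#'
#' @param net a [CommNetwork-class].
#' @param swaps_per_edge attempted swaps per (non-loop) edge; `ceiling(
#'   swaps_per_edge * |E|)` attempts are made.
#' @param weight_mode `"ride"` (weights travel with their arcs) or
#'   `"shuffle"` (weights reassigned at random after rewiring).
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return A rewired [CommNetwork-class] with identical node set, degree
#'   sequences and weight multiset. Graphs admitting no valid swap (e.g. a
#'   directed 3-cycle) come back unchanged.
#' @export
rewireNetwork <- function(net, swaps_per_edge = 10,
                          weight_mode = c("ride", "shuffle"), seed = NULL) {
  stopifnot(is(net, "CommNetwork"))
  weight_mode <- match.arg(weight_mode)
  if (!is.null(seed)) set.seed(seed)
  e <- networkEdges(net)
  nodes <- networkNodes(net)
  loop <- e$from == e$to
  f <- match(e$from[!loop], nodes)
  t <- match(e$to[!loop], nodes)
  attempts <- as.integer(ceiling(swaps_per_edge * length(f)))
  r <- .rewireOnce(f, t, e$weight[!loop], length(nodes), attempts, weight_mode)
  out <- rbind(
    data.frame(from = nodes[r$from], to = nodes[r$to], weight = r$weight,
               stringsAsFactors = FALSE),
    e[loop, c("from", "to", "weight")])
  CommNetwork(out, nodes = nodes,
              metadata = c(net@metadata, list(rewired = TRUE,
                                              swaps_accepted = r$accepted)))
}

## aligned per-class count/strength vectors for all requested sizes
#' @noRd
.censusVectors <- function(A, W, sizes) {
  cnt <- str <- numeric(0)
  for (k in sizes) {
    r <- .censusSize(A, W, k)
    cnt <- c(cnt, r$count)
    str <- c(str, r$strength)
  }
  list(count = cnt, strength = str)
}

#' Motif significance against a rewired null ensemble
#'
#' Compares the observed per-class motif counts and sum-strengths with an
#' ensemble of `n_random` networks, each independently rewired from the
#' observed network by degree-preserving double-edge swaps. Reports per
#' class the null mean and standard deviation, the z-score
#' `(obs - mean) / sd` (NA when sd = 0) and the add-one empirical p-value
#' `p = (1 + #\{null >= obs\}) / (1 + n_random)` (upper tail; a two-sided
#' variant doubles the smaller tail).
#'
#' @param net a [CommNetwork-class] (simple digraph; self-loops are held
#'   fixed and excluded from the census).
#' @param config a [nullConfig()].
#' @param sizes motif sizes to test, subset of `c(2, 3, 4)`.
#' @return A [NullEnsembleStats-class].
#' @examples
#' net <- CommNetwork(data.frame(from = c("A", "B", "C"),
#'                               to = c("B", "C", "A"), weight = 1))
#' ns <- motifSignificance(net, nullConfig(n_random = 50, seed = 1), sizes = 3)
#' subset(nullStats(ns), obs_count > 0)
#' @export
motifSignificance <- function(net, config = nullConfig(), sizes = c(2, 3, 4)) {
  stopifnot(is(net, "CommNetwork"), inherits(config, "null_config"))
  sizes <- sort(unique(as.integer(sizes)))
  obs <- suppressMessages(enumerateMotifs(net, sizes))
  tb <- censusTable(obs)
  obsC <- tb$count
  obsS <- tb$strength
  nc <- nrow(tb)

  e <- networkEdges(net)
  nodes <- networkNodes(net)
  loop <- e$from == e$to
  f0 <- match(e$from[!loop], nodes)
  t0 <- match(e$to[!loop], nodes)
  w0 <- e$weight[!loop]
  n <- length(nodes)
  attempts <- as.integer(ceiling(config$swaps_per_edge * length(f0)))

  set.seed(config$seed)
  sC <- s2C <- geC <- leC <- numeric(nc)
  sS <- s2S <- geS <- leS <- numeric(nc)
  eps <- 1e-9
  for (i in seq_len(config$n_random)) {
    r <- .rewireOnce(f0, t0, w0, n, attempts, config$weight_mode)
    A <- matrix(0L, n, n); W <- matrix(0, n, n)
    A[cbind(r$from, r$to)] <- 1L
    W[cbind(r$from, r$to)] <- r$weight
    cv <- .censusVectors(A, W, sizes)
    sC <- sC + cv$count;   s2C <- s2C + cv$count^2
    sS <- sS + cv$strength; s2S <- s2S + cv$strength^2
    geC <- geC + (cv$count >= obsC);        leC <- leC + (cv$count <= obsC)
    geS <- geS + (cv$strength >= obsS - eps); leS <- leS + (cv$strength <= obsS + eps)
  }
  B <- config$n_random
  mkStats <- function(obsv, s, s2, ge, le) {
    mu <- s / B
    va <- pmax(s2 / B - mu^2, 0)
    sdv <- sqrt(va * B / max(B - 1, 1))
    z <- ifelse(sdv > 0, (obsv - mu) / sdv, NA_real_)
    pUp <- (1 + ge) / (1 + B)
    pLo <- (1 + le) / (1 + B)
    p <- if (config$tail == "upper") pUp else pmin(1, 2 * pmin(pUp, pLo))
    list(mean = mu, sd = sdv, z = z, p = p)
  }
  stC <- mkStats(obsC, sC, s2C, geC, leC)
  stS <- mkStats(obsS, sS, s2S, geS, leS)
  stats <- data.frame(
    class_id = tb$class_id, size = tb$size, alias = tb$alias,
    obs_count = obsC, null_mean_count = stC$mean, null_sd_count = stC$sd,
    z_count = stC$z, p_count = stC$p,
    obs_strength = obsS, null_mean_strength = stS$mean,
    null_sd_strength = stS$sd, z_strength = stS$z, p_strength = stS$p,
    stringsAsFactors = FALSE)
  new("NullEnsembleStats", stats = stats, nRandom = as.integer(B),
      metadata = list(config = config, sizes = sizes))
}
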