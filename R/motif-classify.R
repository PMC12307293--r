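## Canonical classification of small directed graphs (2-4 nodes, no self
## loops). A k-node digraph is encoded as the k*(k-1)-bit string of its
## adjacency matrix read row-major with the diagonal skipped, first bit most
## significant. The canonical id of an isomorphism class is the
## lexicographically smallest bit-string over all k! node permutations.
## Tables over all 2^(k(k-1)) codes are built once per size and cached.

.motifEnv <- new.env(parent = emptyenv())

## ordered (row, col) index pairs behind the bit encoding
#' @noRd
.pairOrder <- function(k) {
  g <- expand.grid(col = seq_len(k), row = seq_len(k))  # col varies fastest
  g <- g[g$row != g$col, , drop = FALSE]
  unname(cbind(g$row, g$col))
}

#' @noRd
.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- vector("list", k)
  for (pos in seq_len(k)) {
    m <- matrix(0L, nrow(sub), k)
    m[, pos] <- k
    m[, -pos] <- sub
    out[[pos]] <- m
  }
  do.call(rbind, out)
}

## weak-connectivity of a code's underlying undirected graph (<= 4 nodes)
#' @noRd
.weaklyConnected <- function(bits, pairs, k) {
  comp <- seq_len(k)
  for (j in seq_len(nrow(pairs))) {
    if (bits[j]) {
      a <- comp[pairs[j, 1]]; b <- comp[pairs[j, 2]]
      if (a != b) comp[comp == b] <- a
    }
  }
  length(unique(comp)) == 1L
}

## full code table for size k: canonical code, connectivity flag
#' @noRd
.codeTable <- function(k) {
  key <- as.character(k)
  if (!is.null(.motifEnv[[key]])) return(.motifEnv[[key]])
  stopifnot(k >= 2, k <= 4)
  pairs <- .pairOrder(k)
  m <- nrow(pairs)
  codes <- 0:(2^m - 1)
  bits <- matrix(FALSE, length(codes), m)
  for (j in seq_len(m))
    bits[, j] <- bitwAnd(codes, bitwShiftL(1L, m - j)) > 0
  weights <- 2^(m - seq_len(m))
  perms <- .permutations(k)
  canon <- rep(Inf, length(codes))
  pairKey <- pairs[, 1] * (k + 1L) + pairs[, 2]
  for (p in seq_len(nrow(perms))) {
    pm <- perms[p, ]
    ## bit j of the permuted graph reads bit source[j] of the original:
    ## B[a,b] = A[pm[a], pm[b]]
    src <- match(pm[pairs[, 1]] * (k + 1L) + pm[pairs[, 2]], pairKey)
    canon <- pmin(canon, as.numeric(bits[, src, drop = FALSE] %*% weights))
  }
  conn <- vapply(codes, function(cd) .weaklyConnected(bits[cd + 1L, ], pairs, k),
                 logical(1))
  tab <- list(k = k, m = m, pairs = pairs, canon = as.integer(canon),
              conn = conn)
  assign(key, tab, envir = .motifEnv)
  tab
}

#' @noRd
.codeToId <- function(k, code) {
  m <- k * (k - 1L)
  bits <- as.integer(bitwAnd(code, bitwShiftL(1L, m - seq_len(m))) > 0)
  sprintf("%d:%s", k, paste(bits, collapse = ""))
}

## named representatives for motif classes with standard aliases
#' @noRd
.aliasAdjacency <- function() {
  e <- function(k, ...) {
    A <- matrix(0L, k, k)
    ed <- matrix(c(...), ncol = 2, byrow = TRUE)
    A[ed] <- 1L
    A
  }
  list(
    single_arc  = e(2, 1, 2),
    mutual_dyad = e(2, 1, 2, 2, 1),
    chain       = e(3, 1, 2, 2, 3),
    out_fan     = e(3, 1, 2, 1, 3),
    in_fan      = e(3, 2, 1, 3, 1),
    ffl         = e(3, 1, 2, 1, 3, 2, 3),
    cycle3      = e(3, 1, 2, 2, 3, 3, 1),
    bifan       = e(4, 1, 3, 1, 4, 2, 3, 2, 4),
    cycle4      = e(4, 1, 2, 2, 3, 3, 4, 4, 1)
  )
}

#' @noRd
.aliasTable <- function() {
  if (is.null(.motifEnv$aliases)) {
    reps <- .aliasAdjacency()
    ids <- vapply(reps, function(A) canonicalClass(A)$id, character(1))
    .motifEnv$aliases <- setNames(names(ids), ids)  # id -> alias
  }
  .motifEnv$aliases
}

#' Canonical isomorphism class of a small digraph
#'
#' Computes the canonical identifier of the directed-isomorphism class of a
#' 2-4 node digraph: the lexicographic minimum, over all node permutations,
#' of the adjacency bit-string (row-major, diagonal skipped). Two digraphs
#' get the same id exactly when they are isomorphic.
#'
#' @param adj square 0/1 adjacency matrix on 2-4 nodes (diagonal ignored).
#' @return list with `size`, `id` (e.g. `"3:011001"`), `alias` (standard
#'   name such as `"ffl"` or `"cycle3"` where one exists, else NA) and
#'   `connected` (weak connectivity).
#' @examples
#' ffl <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3)  # A->B, A->C, B->C
#' canonicalClass(ffl)$alias
#' @export
canonicalClass <- function(adj) {
  adj <- as.matrix(adj)
  k <- nrow(adj)
  if (k != ncol(adj)) stop("adjacency matrix must be square")
  if (k < 2 || k > 4) stop("only sizes 2-4 are supported")
  tab <- .codeTable(k)
  bits <- (adj[tab$pairs] != 0)
  code <- sum(bits * 2^(tab$m - seq_len(tab$m)))
  cc <- tab$canon[code + 1L]
  id <- .codeToId(k, cc)
  if (is.null(.motifEnv$aliases) && !isTRUE(.motifEnv$building)) {
    ## building the alias table itself calls canonicalClass; guard recursion
    .motifEnv$building <- TRUE
    on.exit(.motifEnv$building <- FALSE, add = TRUE)
    .aliasTable()
  }
  al <- .motifEnv$aliases
  alias <- if (!is.null(al) && id %in% names(al)) unname(al[id]) else NA_character_
  list(size = k, id = id, alias = alias, connected = tab$conn[code + 1L])
}

#' Representative adjacency matrix of a named motif
#'
#' @param name a standard motif alias: one of `"single_arc"`,
#'   `"mutual_dyad"`, `"chain"`, `"out_fan"`, `"in_fan"`, `"ffl"`,
#'   `"cycle3"`, `"bifan"`, `"cycle4"`.
#' @return 0/1 adjacency matrix of a representative of the class.
#' @export
motifAdjacency <- function(name) {
  reps <- .aliasAdjacency()
  if (!name %in% names(reps))
    stop("unknown motif alias '", name, "'; known: ",
         paste(names(reps), collapse = ", "))
  reps[[name]]
}

## all weakly-connected canonical classes of size k, as a data.frame
#' @noRd
.connectedClasses <- function(k) {
  tab <- .codeTable(k)
  cc <- sort(unique(tab$canon[tab$conn]))
  ids <- vapply(cc, function(x) .codeToId(k, x), character(1))
  al <- .aliasTable()
  data.frame(class_id = ids, size = k, code = cc,
             alias = ifelse(ids %in% names(al), al[ids], NA_character_),
             stringsAsFactors = FALSE, row.names = NULL)
}
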