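#' Fused per-protein scores (LSG)
#'
#' For each protein, sums over its neighbours the topological weight
#' times the sum of the biological weights:
#' `LSG(u) = sum over v in NG(u) of ADN(u,v) * (CLN(u,v) + CEN(u,v))`.
#' Isolated proteins get 0. This single score per protein is what the
#' transition matrix is built from.
#'
#' @param adn,cen,cln `weighted_layer` objects sharing the network's
#'   node order and edge set.
#' @param network A [ppi_network()].
#' @return An `lsg_vector`: list with `scores` (named numeric, network
#'   node order) and `total`.
#' @export
lsg_scores <- function(adn, cen, cln, network) {
  for (layer in list(adn, cen, cln)) {
    if (layer$n_nodes != network$n_nodes ||
        !identical(layer$edges, network$edges)) {
      stop("layer/network node-order or edge-set mismatch (",
           layer$tag, ")", call. = FALSE)
    }
  }
  fused <- adn$weights * (cln$weights + cen$weights)
  lsg_from_edge_weights(network, fused)
}

# Accumulate a per-edge weight into per-node sums; shared by the full
# fusion and by the single-layer ablation variants.
lsg_from_edge_weights <- function(network, edge_weights) {
  scores <- numeric(network$n_nodes)
  e <- network$edges
  if (nrow(e) > 0L) {
    acc <- tapply(c(edge_weights, edge_weights), c(e[, 1L], e[, 2L]), sum)
    scores[as.integer(names(acc))] <- as.numeric(acc)
  }
  structure(
    list(scores = stats::setNames(scores, network$node_ids),
         total = sum(scores)),
    class = "lsg_vector"
  )
}

#' Build the comprehensive transition matrix (PCIN)
#'
#' Symmetric matrix over the network's proteins with diagonal
#' `LSG(i) / sum_k LSG(k)` and, on every edge `(i,j)`,
#' `min(LSG(i), LSG(j)) / sum_k LSG(k)`; zero elsewhere. The global
#' normalisation makes every column sum at most 1 (sub-stochastic), so
#' the damped iteration has a unique fixed point for any positive
#' restart weight. Stored sparsely (`n + |E|` entries).
#'
#' With `dense = TRUE` the off-diagonal term is instead applied to every
#' protein pair, ignoring the edge set — a literal all-pairs reading
#' kept for comparison; the default edge-restricted matrix is the one
#' that lets the network topology drive the ranking.
#'
#' @param network A [ppi_network()].
#' @param lsg An [lsg_scores()] result.
#' @param dense If `TRUE`, put `min(LSG(i),LSG(j))/sum LSG` on all pairs
#'   `i != j` rather than only on edges.
#' @return A `dsCMatrix` (symmetric sparse, from the Matrix package)
#'   with protein IDs as dimnames; dense variant returns `dsyMatrix`.
#' @export
build_pcin <- function(network, lsg, dense = FALSE) {
  s <- as.numeric(lsg$scores)
  tot <- lsg$total
  if (tot <= 0) {
    stop("degenerate network: all fused weights zero ",
         "(missing or constant biological data)", call. = FALSE)
  }
  n <- network$n_nodes
  ids <- network$node_ids
  if (dense) {
    m <- outer(s, s, pmin) / tot
    diag(m) <- s / tot
    dimnames(m) <- list(ids, ids)
    return(Matrix::forceSymmetric(Matrix::Matrix(m, sparse = FALSE)))
  }
  e <- network$edges
  off <- if (nrow(e) > 0L) pmin(s[e[, 1L]], s[e[, 2L]]) / tot else numeric(0)
  Matrix::sparseMatrix(
    i = c(seq_len(n), e[, 1L]),
    j = c(seq_len(n), e[, 2L]),
    x = c(s / tot, off),
    dims = c(n, n),
    dimnames = list(ids, ids),
    symmetric = TRUE
  )
}
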