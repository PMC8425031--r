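#' Orthology-conservatism seed vector
#'
#' Normalises the per-protein ortholog counts to a probability vector:
#' `O_score(i) = I(i) / sum_k I(k)`, in network node order; proteins
#' without an orthology row count 0. Conservation across reference
#' organisms is a strong prior for essentiality, so this vector seeds
#' (and, via the restart term, continually re-anchors) the iteration.
#' If every count is zero the seed falls back to the uniform vector
#' `1/N` with a warning.
#'
#' @param orth An [orthology_table()].
#' @param network A [ppi_network()].
#' @return Named numeric vector of length `n_nodes`, summing to 1.
#' @export
conservatism_seed <- function(orth, network) {
  counts <- stats::setNames(numeric(network$n_nodes), network$node_ids)
  hit <- intersect(names(orth$counts), network$node_ids)
  counts[hit] <- orth$counts[hit]
  total <- sum(counts)
  if (total == 0) {
    warning("all ortholog counts are zero; using the uniform seed 1/N",
            call. = FALSE)
    return(stats::setNames(rep(1 / network$n_nodes, network$n_nodes),
                           network$node_ids))
  }
  counts / total
}

#' Damped fixed-point iteration over the transition matrix
#'
#' Iterates `P_{t+1} = (1 - alpha) * PCIN %*% P_t + alpha * P0` from
#' `P_0` until the L1 change per edge drops below `gamma`:
#' `||P_{t+1} - P_t||_1 / |E| < gamma`. Because the matrix is
#' nonnegative and column-sub-stochastic, the damped map is a
#' contraction with factor at most `1 - alpha`, so the iteration
#' converges geometrically to the unique fixed point for any
#' `alpha > 0`. `alpha` balances the network against the conservatism
#' seed: `alpha = 1` returns the seed, `alpha = 0` pure propagation.
#'
#' @param pcin Transition matrix from [build_pcin()] (any Matrix or base
#'   matrix with matching dimension).
#' @param p0 Seed vector from [conservatism_seed()].
#' @param n_edges Edge count `|E|` used to normalise the residual.
#' @param alpha Restart weight in `[0, 1]`; default 0.3.
#' @param gamma Convergence threshold on the normalised L1 residual;
#'   default 1e-10.
#' @param max_iter Iteration cap; default 1000.
#' @param residual_divisor `"edges"` (default) divides the residual by
#'   `|E|`; `"nodes"` divides by `N` instead.
#' @return A `score_vector`: list with `scores` (named), `iterations`,
#'   `residual` (last normalised residual), `converged`,
#'   `residual_trace`.
#' @export
iterate_scores <- function(pcin, p0, n_edges, alpha = 0.3, gamma = 1e-10,
                           max_iter = 1000L,
                           residual_divisor = c("edges", "nodes")) {
  stopifnot(alpha >= 0, alpha <= 1, gamma > 0, max_iter >= 1L)
  residual_divisor <- match.arg(residual_divisor)
  n <- length(p0)
  stopifnot(nrow(pcin) == n)
  divisor <- if (residual_divisor == "edges") max(n_edges, 1L) else n
  p0 <- as.numeric(p0)
  p <- p0
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(max_iter)) {
    p_next <- as.numeric((1 - alpha) * (pcin %*% p)) + alpha * p0
    res <- sum(abs(p_next - p)) / divisor
    trace <- c(trace, res)
    p <- p_next
    iter <- t
    if (!all(is.finite(p))) {
      stop("non-finite scores at iteration ", t,
           " (internal invariant violated)", call. = FALSE)
    }
    if (res < gamma) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      scores = stats::setNames(p, rownames(pcin)),
      iterations = iter,
      residual = trace[length(trace)],
      converged = converged,
      residual_trace = trace
    ),
    class = "score_vector"
  )
}

#' Closed-form fixed point of the damped iteration
#'
#' Solves `P* = alpha * (I - (1 - alpha) * PCIN)^{-1} P0` directly.
#' Exists for `alpha > 0` because the sub-stochastic matrix scaled by
#' `1 - alpha` has spectral radius below 1. Used as an exact reference
#' for the iterative solver.
#'
#' @inheritParams iterate_scores
#' @return Named numeric vector of fixed-point scores.
#' @export
solve_scores <- function(pcin, p0, alpha = 0.3) {
  stopifnot(alpha > 0, alpha <= 1)
  n <- length(p0)
  m <- diag(n) - (1 - alpha) * as.matrix(pcin)
  stats::setNames(alpha * solve(m, as.numeric(p0)), rownames(pcin))
}

#' Sort proteins by score into a ranked list
#'
#' Descending by score; ties broken by ascending protein ID so the
#' ranking is reproducible. Ranks run 1..N without gaps.
#'
#' @param scores Named numeric vector (names are protein IDs), or a
#'   `score_vector` from [iterate_scores()].
#' @param node_ids Optional protein IDs if `scores` is unnamed.
#' @return Data frame with columns `rank`, `protein`, `score`.
#' @export
rank_proteins <- function(scores, node_ids = NULL) {
  if (inherits(scores, "score_vector")) scores <- scores$scores
  ids <- node_ids %||% names(scores)
  if (is.null(ids)) stop("protein IDs required to rank", call. = FALSE)
  s <- as.numeric(scores)
  ord <- order(-s, ids)
  data.frame(
    rank = seq_along(s),
    protein = ids[ord],
    score = s[ord],
    stringsAsFactors = FALSE
  )
}

#' Top K percent of a ranked list
#'
#' Returns the first `round(N * k_percent / 100)` proteins, with
#' half-up rounding (e.g. 1% of 5093 proteins is 51, 1% of 3672 is 37).
#'
#' @param ranked Data frame from [rank_proteins()].
#' @param k_percent Percentage in `(0, 100]`.
#' @return Character vector of protein IDs.
#' @export
top_k_percent <- function(ranked, k_percent) {
  stopifnot(is.data.frame(ranked), nrow(ranked) > 0L)
  if (!is.numeric(k_percent) || k_percent <= 0 || k_percent > 100) {
    stop("k_percent must be in (0, 100]", call. = FALSE)
  }
  k <- top_k_count(nrow(ranked), k_percent)
  ranked$protein[seq_len(min(k, nrow(ranked)))]
}

# half-up rounding (round() in R rounds halves to even)
top_k_count <- function(n, k_percent) {
  as.integer(floor(n * k_percent / 100 + 0.5))
}
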