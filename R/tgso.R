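#' Rank proteins by essentiality from a PPI network and biological data
#'
#' Fits the full multi-layer ranking model: builds the three weighted
#' layers on the PPI edge set (topological aggregation degree,
#' co-expression, co-localization), fuses them into per-protein LSG
#' scores and the comprehensive transition matrix, then runs the damped
#' fixed-point iteration seeded with orthology-conservatism scores and
#' sorts the proteins by the converged score.
#'
#' Any biological table may be omitted: a missing expression or
#' localization table contributes an all-zero layer, and a missing
#' orthology table yields the uniform seed. Note that with the default
#' full fusion the model needs at least one informative biological
#' layer, since the fused edge weight is the topological weight times
#' the sum of the two biological weights.
#'
#' @param network A [ppi_network()].
#' @param expression Optional `expression_table` (see
#'   [read_expression_table()]).
#' @param localization Optional `localization_table`.
#' @param orthology Optional [orthology_table()].
#' @param alpha Restart weight in `[0, 1]` balancing network propagation
#'   against the conservatism seed; default 0.3.
#' @param gamma Convergence threshold on the per-edge L1 residual;
#'   default 1e-10.
#' @param max_iter Iteration cap; default 1000.
#' @param variant Which edge weighting feeds the transition matrix:
#'   `"pcin"` (default) the full three-layer fusion; `"adn"`, `"cen"`,
#'   `"cln"` a single layer; `"ppi"` unit weights on every edge (the
#'   unweighted-network control used in ablation).
#' @param dense_pcin If `TRUE`, build the all-pairs transition matrix
#'   instead of restricting off-diagonal entries to network edges.
#' @param residual_divisor `"edges"` (default) or `"nodes"`; see
#'   [iterate_scores()].
#' @param uniform_seed If `TRUE`, ignore orthology and seed uniformly.
#' @return An object of class `tgso`: list with `ranking` (data frame
#'   `rank`/`protein`/`score`), `scores`, `seed`, `lsg`, `pcin`,
#'   `layers`, `iterations`, `residual`, `converged`, `config`,
#'   `network`, `call`.
#' @seealso [evaluate_ranking()], [run_ablation()], [generate_bundle()]
#' @export
#' @examples
#' b <- generate_bundle(benchmark_config(n_proteins = 60, seed = 1))
#' fit <- tgso(b$network, b$expression, b$localization, b$orthology)
#' head(fit$ranking)
tgso <- function(network, expression = NULL, localization = NULL,
                 orthology = NULL, alpha = 0.3, gamma = 1e-10,
                 max_iter = 1000L,
                 variant = c("pcin", "adn", "cen", "cln", "ppi"),
                 dense_pcin = FALSE,
                 residual_divisor = c("edges", "nodes"),
                 uniform_seed = FALSE) {
  stopifnot(inherits(network, "ppi_network"))
  variant <- match.arg(variant)
  residual_divisor <- match.arg(residual_divisor)
  if (network$n_edges == 0L) {
    stop("the PPI network has no edges", call. = FALSE)
  }

  zero_layer <- function(tag) weighted_layer(network,
                                             numeric(network$n_edges), tag)
  adn <- build_adn(network)
  cen <- if (is.null(expression)) zero_layer("CEN")
         else build_cen(network, expression)
  cln <- if (is.null(localization)) zero_layer("CLN")
         else build_cln(network, localization)

  lsg <- switch(variant,
    pcin = lsg_scores(adn, cen, cln, network),
    adn = lsg_from_edge_weights(network, adn$weights),
    cen = lsg_from_edge_weights(network, cen$weights),
    cln = lsg_from_edge_weights(network, cln$weights),
    ppi = lsg_from_edge_weights(network, rep(1, network$n_edges))
  )
  pcin <- build_pcin(network, lsg, dense = dense_pcin)

  seed <- if (uniform_seed || is.null(orthology)) {
    stats::setNames(rep(1 / network$n_nodes, network$n_nodes),
                    network$node_ids)
  } else {
    conservatism_seed(orthology, network)
  }

  scores <- iterate_scores(pcin, seed, n_edges = network$n_edges,
                           alpha = alpha, gamma = gamma,
                           max_iter = max_iter,
                           residual_divisor = residual_divisor)
  ranking <- rank_proteins(scores$scores)

  structure(
    list(
      ranking = ranking,
      scores = scores$scores,
      seed = seed,
      lsg = lsg,
      pcin = pcin,
      layers = list(ADN = adn, CEN = cen, CLN = cln),
      iterations = scores$iterations,
      residual = scores$residual,
      converged = scores$converged,
      residual_trace = scores$residual_trace,
      config = list(alpha = alpha, gamma = gamma, max_iter = max_iter,
                    variant = variant, dense_pcin = dense_pcin,
                    residual_divisor = residual_divisor,
                    uniform_seed = uniform_seed),
      network = network,
      call = match.call()
    ),
    class = "tgso"
  )
}

#' @export
print.tgso <- function(x, ...) {
  cat("Essential-protein ranking (", x$config$variant, " variant)\n",
      sep = "")
  cat("  proteins:", x$network$n_nodes, " interactions:",
      x$network$n_edges, "\n")
  cat(sprintf("  alpha = %g, converged in %d iterations (residual %.3g)\n",
              x$config$alpha, x$iterations, x$residual))
  cat("  top proteins:",
      paste(utils::head(x$ranking$protein, 5L), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tgso <- function(object, top_percents = c(1, 5, 10, 25), ...) {
  n <- object$network$n_nodes
  counts <- vapply(top_percents, function(k) top_k_count(n, k), 1L)
  structure(
    list(
      n_nodes = n,
      n_edges = object$network$n_edges,
      config = object$config,
      iterations = object$iterations,
      residual = object$residual,
      converged = object$converged,
      top_percents = top_percents,
      top_counts = counts,
      head = utils::head(object$ranking, 10L),
      lsg_total = object$lsg$total
    ),
    class = "summary.tgso"
  )
}

#' @export
print.summary.tgso <- function(x, ...) {
  cat("Essential-protein ranking over", x$n_nodes, "proteins /",
      x$n_edges, "interactions\n")
  cat(sprintf(
    "variant %s, alpha %g; %s after %d iterations (residual %.3g)\n",
    x$config$variant, x$config$alpha,
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$residual))
  cat(sprintf("total fused score (LSG): %.6g\n", x$lsg_total))
  cat("candidate counts at top-K%:",
      paste(sprintf("%g%%=%d", x$top_percents, x$top_counts),
            collapse = ", "), "\n\n")
  cat("Top of the ranking:\n")
  print(x$head, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tgso <- function(object, ...) object$scores

#' @export
residuals.tgso <- function(object, ...) object$residual_trace

#' Plot the converged score profile of a ranking
#'
#' Scores against rank on a log y-axis; if an essential set is given,
#' true essentials are marked so the enrichment of the top of the list
#' is visible.
#'
#' @param x A [tgso()] fit.
#' @param essential Optional character vector of essential protein IDs.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tgso <- function(x, essential = NULL, ...) {
  r <- x$ranking
  pos <- r$score > 0
  graphics::plot(r$rank[pos], r$score[pos], log = "y", type = "p",
                 pch = 16, cex = 0.4, col = "grey50",
                 xlab = "rank", ylab = "score", ...)
  if (!is.null(essential)) {
    hit <- pos & r$protein %in% essential
    graphics::points(r$rank[hit], r$score[hit], pch = 16, cex = 0.5,
                     col = "firebrick")
    graphics::legend("topright", legend = c("essential", "other"),
                     col = c("firebrick", "grey50"), pch = 16, bty = "n")
  }
  invisible(x)
}
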