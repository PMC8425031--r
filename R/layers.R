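#' Aggregation-degree (DBN) weight of one edge
#'
#' Topological edge weight capturing how densely the two endpoints'
#' neighbourhoods overlap: `(|NG(u) n NG(v)| + 1) / min(|NG(u)|, |NG(v)|)`.
#' Essential proteins tend to sit in tightly connected modules, which
#' this local density metric rewards. Both endpoint degrees are at least
#' 1 because the edge exists, so the ratio is always defined and
#' positive.
#'
#' @param network A [ppi_network()].
#' @param u,v Node indices (1-based, in network node order) of an
#'   existing edge.
#' @return A positive number.
#' @export
dbn_weight <- function(network, u, v) {
  nu <- network$adj[[u]]
  if (!(v %in% nu)) {
    stop("dbn_weight() requires an existing edge; (", u, ",", v,
         ") is not in E", call. = FALSE)
  }
  nv <- network$adj[[v]]
  common <- length(intersect(nu, nv))
  (common + 1) / min(length(nu), length(nv))
}

#' Build the aggregation-degree network (ADN) layer
#'
#' Computes the DBN weight of every edge of the PPI network, yielding
#' the topological layer of the fusion.
#'
#' @param network A [ppi_network()].
#' @return A `weighted_layer` (see [weighted_layer()]) tagged `"ADN"`.
#' @export
build_adn <- function(network) {
  e <- network$edges
  w <- numeric(nrow(e))
  if (nrow(e) > 0L) {
    adj <- network$adj
    deg <- network$degree
    for (k in seq_len(nrow(e))) {
      i <- e[k, 1L]; j <- e[k, 2L]
      common <- sum(adj[[i]] %in% adj[[j]])
      w[k] <- (common + 1) / min(deg[i], deg[j])
    }
  }
  weighted_layer(network, w, "ADN")
}

#' Pearson correlation of two expression profiles
#'
#' Sample Pearson correlation over time points, computed with the
#' sample (n-1) standard deviation so a profile is perfectly correlated
#' with itself. Missing coverage or a zero-variance profile yields 0 by
#' convention: the pair then contributes no co-expression evidence
#' without invalidating the pipeline.
#'
#' @param x,y Numeric vectors of equal length `T >= 2`, or `NULL`/all-NA
#'   for an uncovered protein.
#' @return Correlation in `[-1, 1]`, or 0 under the missing/constant
#'   convention.
#' @export
pearson_cc <- function(x, y) {
  if (is.null(x) || is.null(y) || anyNA(x) || anyNA(y)) return(0)
  if (length(x) != length(y)) {
    stop("expression vectors differ in length: ", length(x), " vs ",
         length(y), call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 time points", call. = FALSE)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (n - 1)
}

# Pairwise PCC matrix over all proteins; uncovered or zero-variance rows
# give 0 against everything. Rows of `values` are protein profiles.
pcc_matrix <- function(expr) {
  v <- expr$values
  n <- nrow(v)
  ok <- expr$covered & apply(v, 1L, function(r) !anyNA(r) && stats::sd(r) > 0)
  p <- matrix(0, n, n, dimnames = dimnames(v)[c(1L, 1L)])
  if (any(ok)) {
    z <- v[ok, , drop = FALSE]
    z <- (z - rowMeans(z)) / apply(z, 1L, stats::sd)
    p[ok, ok] <- tcrossprod(z) / (ncol(v) - 1)
  }
  p
}

#' Co-expression connection weight of one edge
#'
#' The correlation of the endpoints plus, for every common neighbour,
#' the product of the endpoints' correlations with that neighbour:
#' `PCC(u,v) + sum over common e of PCC(u,e) * PCC(v,e)`. A shared,
#' co-expressed neighbourhood strengthens the edge beyond the pairwise
#' correlation. The result is floored at 0 so downstream fusion and the
#' damped iteration operate on nonnegative weights.
#'
#' @param network A [ppi_network()].
#' @param expr An `expression_table` aligned to `network`.
#' @param u,v Node indices of an existing edge.
#' @return A nonnegative number.
#' @export
connection_weight <- function(network, expr, u, v) {
  if (!(v %in% network$adj[[u]])) {
    stop("connection_weight() requires an existing edge", call. = FALSE)
  }
  p <- pcc_matrix(expr)
  common <- intersect(network$adj[[u]], network$adj[[v]])
  val <- p[u, v] + sum(p[u, common] * p[v, common])
  max(val, 0)
}

#' Build the co-expression network (CEN) layer
#'
#' Computes the connection weight ([connection_weight()]) of every edge.
#'
#' @param network A [ppi_network()].
#' @param expr An `expression_table` aligned to `network`.
#' @return A `weighted_layer` tagged `"CEN"`.
#' @export
build_cen <- function(network, expr) {
  p <- pcc_matrix(expr)
  e <- network$edges
  w <- numeric(nrow(e))
  adj <- network$adj
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1L]; j <- e[k, 2L]
    common <- intersect(adj[[i]], adj[[j]])
    w[k] <- max(p[i, j] + sum(p[i, common] * p[j, common]), 0)
  }
  weighted_layer(network, w, "CEN")
}

#' Relative frequency of each subcellular compartment
#'
#' `sub(i)` counts the proteins annotated to compartment `i`;
#' `sub_score(i) = sub(i) / sum_k sub(k)` normalises over compartments,
#' so the scores form a distribution over the location vocabulary and
#' heavily populated compartments (e.g. the nucleus in yeast) weigh
#' more.
#'
#' @param loc A `localization_table`.
#' @return A `location_frequency`: list with `counts` and `scores`
#'   (named by compartment; scores sum to 1).
#' @export
location_frequency <- function(loc) {
  vocab <- loc$vocabulary
  counts <- stats::setNames(integer(length(vocab)), vocab)
  observed <- table(unlist(loc$sets, use.names = FALSE))
  counts[names(observed)] <- as.integer(observed)
  total <- sum(counts)
  if (total == 0L) {
    stop("no localization annotations: the co-localization layer needs ",
         "at least one protein-compartment pair (or disable the layer)",
         call. = FALSE)
  }
  structure(list(counts = counts, scores = counts / total),
            class = "location_frequency")
}

#' Self-localization score of one protein
#'
#' Sum of the compartment frequency scores over the protein's
#' localization set; 0 for unannotated proteins, 1 for a protein
#' annotated to the full vocabulary.
#'
#' @param freq A [location_frequency()].
#' @param loc A `localization_table`.
#' @param id Protein ID string.
#' @return A number in `[0, 1]`.
#' @export
self_localization_score <- function(freq, loc, id) {
  s <- loc$sets[[id]]
  if (is.null(s) || length(s) == 0L) return(0)
  sum(freq$scores[s])
}

#' Co-localization weight of one edge
#'
#' Jaccard similarity of the two localization sets, scaled by the mean
#' of the endpoints' self-localization scores:
#' `(|L(u) n L(v)| / |L(u) u L(v)|) * (S(u) + S(v)) / 2`.
#' Returns 0 when both proteins are unannotated (empty union).
#'
#' @param freq A [location_frequency()].
#' @param loc A `localization_table`.
#' @param u_id,v_id Protein ID strings.
#' @return A number in `[0, 1]`.
#' @export
colocalization_weight <- function(freq, loc, u_id, v_id) {
  lu <- loc$sets[[u_id]] %||% character(0)
  lv <- loc$sets[[v_id]] %||% character(0)
  uni <- union(lu, lv)
  if (length(uni) == 0L) return(0)
  jac <- length(intersect(lu, lv)) / length(uni)
  jac * (self_localization_score(freq, loc, u_id) +
           self_localization_score(freq, loc, v_id)) / 2
}

#' Build the co-localization network (CLN) layer
#'
#' Computes the co-localization weight ([colocalization_weight()]) of
#' every edge. When no protein carries any annotation the layer is all
#' zero (rather than an error), mirroring the missing-data convention of
#' the co-expression layer.
#'
#' @param network A [ppi_network()].
#' @param loc A `localization_table`.
#' @return A `weighted_layer` tagged `"CLN"`.
#' @export
build_cln <- function(network, loc) {
  e <- network$edges
  w <- numeric(nrow(e))
  total_ann <- sum(lengths(loc$sets))
  if (total_ann > 0L && nrow(e) > 0L) {
    freq <- location_frequency(loc)
    ids <- network$node_ids
    sscore <- vapply(ids, function(id) self_localization_score(freq, loc, id),
                     0)
    sets <- lapply(ids, function(id) loc$sets[[id]] %||% character(0))
    for (k in seq_len(nrow(e))) {
      i <- e[k, 1L]; j <- e[k, 2L]
      uni <- union(sets[[i]], sets[[j]])
      if (length(uni) == 0L) next
      jac <- length(intersect(sets[[i]], sets[[j]])) / length(uni)
      w[k] <- jac * (sscore[i] + sscore[j]) / 2
    }
  }
  weighted_layer(network, w, "CLN")
}

#' Construct a weighted layer on a network's edge set
#'
#' A layer stores one symmetric nonnegative weight per edge of the PPI
#' network (zero implicitly elsewhere), in the network's canonical edge
#' order.
#'
#' @param network A [ppi_network()].
#' @param weights Numeric vector, one nonnegative finite value per edge.
#' @param tag Layer label, e.g. `"ADN"`, `"CEN"`, `"CLN"`.
#' @return A `weighted_layer`: list with `weights`, `tag`, `n_nodes`,
#'   `edges` (shared with the network).
#' @export
weighted_layer <- function(network, weights, tag) {
  weights <- as.numeric(weights)
  if (length(weights) != network$n_edges) {
    stop("need one weight per edge (", network$n_edges, "), got ",
         length(weights), call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("layer weights must be finite and nonnegative", call. = FALSE)
  }
  structure(
    list(weights = weights, tag = tag, n_nodes = network$n_nodes,
         edges = network$edges),
    class = "weighted_layer"
  )
}

#' @export
print.weighted_layer <- function(x, ...) {
  cat(sprintf("%s layer: %d edges, weight range [%.4g, %.4g]\n",
              x$tag, length(x$weights),
              if (length(x$weights)) min(x$weights) else 0,
              if (length(x$weights)) max(x$weights) else 0))
  invisible(x)
}

#' Dense symmetric matrix view of a weighted layer
#'
#' @param layer A [weighted_layer()].
#' @return An `n_nodes` x `n_nodes` symmetric matrix, zero off the edge
#'   set.
#' @export
layer_matrix <- function(layer) {
  m <- matrix(0, layer$n_nodes, layer$n_nodes)
  if (nrow(layer$edges) > 0L) {
    m[layer$edges] <- layer$weights
    m[layer$edges[, 2:1, drop = FALSE]] <- layer$weights
  }
  m
}
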