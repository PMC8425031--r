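# Independent brute-force oracles. These deliberately re-derive every
# quantity from the dense adjacency matrix and naive loops (stats::cor
# for correlation), never touching the package's edge-based code paths.

# random test instance: graph + expression + localization + orthology
random_instance <- function(n = 12, p = 0.3, seed = 1, t_points = 8,
                            p_uncovered = 0.2, p_unannotated = 0.2,
                            n_compartments = 5, n_organisms = 10) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  net <- if (nrow(idx) > 0) {
    ppi_network(ids[idx[, 1]], ids[idx[, 2]], nodes = ids)
  } else {
    ppi_network(character(0), character(0), nodes = ids)
  }
  covered <- runif(n) > p_uncovered
  profiles <- lapply(seq_len(n), function(i) rnorm(t_points))
  names(profiles) <- ids
  expr <- expression_table(profiles[covered], net)
  vocab <- sprintf("V%02d", seq_len(n_compartments))
  sets <- lapply(seq_len(n), function(i) {
    if (runif(1) < p_unannotated) character(0)
    else sample(vocab, sample.int(n_compartments, 1))
  })
  names(sets) <- ids
  loc <- localization_table(sets[lengths(sets) > 0], vocabulary = vocab)
  orth <- orthology_table(setNames(rbinom(n, n_organisms, 0.4), ids),
                          n_organisms)
  list(net = net, a = a, ids = ids, expr = expr, loc = loc, orth = orth,
       vocab = vocab)
}

oracle_degree <- function(a) rowSums(a)

oracle_dbn <- function(a, i, j) {
  nbr <- function(k) which(a[k, ] == 1)
  (length(intersect(nbr(i), nbr(j))) + 1) /
    min(length(nbr(i)), length(nbr(j)))
}

# PCC via stats::cor with the missing/constant-profile convention
oracle_pcc <- function(expr, i, j) {
  v <- expr$values
  if (!expr$covered[i] || !expr$covered[j]) return(0)
  if (sd(v[i, ]) == 0 || sd(v[j, ]) == 0) return(0)
  cor(v[i, ], v[j, ])
}

oracle_connection <- function(a, expr, i, j) {
  common <- which(a[i, ] == 1 & a[j, ] == 1)
  val <- oracle_pcc(expr, i, j)
  for (e in common) val <- val + oracle_pcc(expr, i, e) * oracle_pcc(expr, j, e)
  max(val, 0)
}

oracle_sub_scores <- function(loc) {
  counts <- setNames(numeric(length(loc$vocabulary)), loc$vocabulary)
  for (s in loc$sets) for (c in s) counts[c] <- counts[c] + 1
  counts / sum(counts)
}

oracle_sscore <- function(loc, id) {
  s <- loc$sets[[id]]
  if (is.null(s)) return(0)
  sum(oracle_sub_scores(loc)[s])
}

oracle_colo <- function(loc, id1, id2) {
  l1 <- loc$sets[[id1]]; if (is.null(l1)) l1 <- character(0)
  l2 <- loc$sets[[id2]]; if (is.null(l2)) l2 <- character(0)
  uni <- union(l1, l2)
  if (length(uni) == 0) return(0)
  length(intersect(l1, l2)) / length(uni) *
    (oracle_sscore(loc, id1) + oracle_sscore(loc, id2)) / 2
}

# dense layer matrices and the fused per-node scores
oracle_layer_matrices <- function(inst) {
  n <- length(inst$ids)
  dbn <- cen <- cln <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (inst$a[i, j] == 1) {
      dbn[i, j] <- dbn[j, i] <- oracle_dbn(inst$a, i, j)
      cen[i, j] <- cen[j, i] <- oracle_connection(inst$a, inst$expr, i, j)
      cln[i, j] <- cln[j, i] <- oracle_colo(inst$loc, inst$ids[i],
                                            inst$ids[j])
    }
  }
  list(dbn = dbn, cen = cen, cln = cln)
}

oracle_lsg <- function(inst, mats = oracle_layer_matrices(inst)) {
  n <- length(inst$ids)
  sapply(seq_len(n), function(u) {
    s <- 0
    for (v in which(inst$a[u, ] == 1)) {
      s <- s + mats$dbn[u, v] * (mats$cln[u, v] + mats$cen[u, v])
    }
    s
  })
}

oracle_pcin <- function(a, lsg) {
  n <- length(lsg)
  tot <- sum(lsg)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- if (i == j) lsg[i] / tot
               else if (a[i, j] == 1) min(lsg[i], lsg[j]) / tot else 0
  }
  m
}

# AUROC as the Mann-Whitney rank statistic with midranks for ties
oracle_auroc <- function(scores, labels) {
  r <- rank(scores)
  npos <- sum(labels); nneg <- sum(!labels)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# max F1 by exhaustively trying every top-k prefix of the sorted list
oracle_max_f1 <- function(scores, labels) {
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  npos <- sum(y)
  best <- 0
  for (k in seq_along(s)) {
    # only prefixes ending at a score change are realisable thresholds
    if (k < length(s) && s[k + 1] == s[k]) next
    tp <- sum(y[seq_len(k)])
    prec <- tp / k; rec <- tp / npos
    if (prec + rec > 0) best <- max(best, 2 * prec * rec / (prec + rec))
  }
  best
}
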