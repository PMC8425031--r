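#' Precision of the top K percent of a ranking
#'
#' @param ranked Data frame from [rank_proteins()] (or a [tgso()] fit).
#' @param essential Character vector of essential protein IDs.
#' @param k_percent Percentage in `(0, 100]`.
#' @return List with `count` (true essentials in the top K) and
#'   `precision` (`count` over the top-K size).
#' @export
precision_at_top <- function(ranked, essential, k_percent) {
  ranked <- as_ranking(ranked)
  top <- top_k_percent(ranked, k_percent)
  count <- sum(top %in% essential)
  list(count = count, precision = count / length(top))
}

#' Jackknife curve: cumulative essentials against rank depth
#'
#' `curve[r]` is the number of true essential proteins among the first
#' `r` ranked proteins, for `r = 1..depth`. A steeper early curve means
#' better prioritisation; the curve is non-decreasing and ends at the
#' number of essentials within the examined depth.
#'
#' @param ranked Data frame from [rank_proteins()] (or a [tgso()] fit).
#' @param essential Character vector of essential protein IDs.
#' @param depth How many ranks to examine (default all).
#' @return Integer vector of length `depth`.
#' @export
jackknife_curve <- function(ranked, essential, depth = NULL) {
  ranked <- as_ranking(ranked)
  depth <- depth %||% nrow(ranked)
  stopifnot(depth >= 1L, depth <= nrow(ranked))
  cumsum(ranked$protein[seq_len(depth)] %in% essential)
}

#' ROC and precision-recall curves for scored proteins
#'
#' Sweeps a score threshold over the unique score values in descending
#' order (tied scores move as one step), accumulating true/false
#' positives. AUROC uses trapezoidal integration; AUPR uses step
#' interpolation (precision held constant across each recall
#' increment), the conservative convention for the heavily skewed
#' essential/non-essential split.
#'
#' @param scores Named numeric vector of protein scores (or a [tgso()]
#'   fit).
#' @param essential Character vector of essential protein IDs; proteins
#'   absent from `scores` are ignored with a message.
#' @return List with `roc` (data frame `fpr`, `tpr`), `pr` (data frame
#'   `recall`, `precision`), `auroc`, `aupr`.
#' @export
roc_pr_curves <- function(scores, essential) {
  lb <- score_labels(scores, essential)
  npos <- sum(lb$label)
  nneg <- sum(!lb$label)
  if (npos == 0L || nneg == 0L) {
    stop("ROC/PR need both essential and non-essential proteins among ",
         "the scored set", call. = FALSE)
  }
  # group tied scores into single threshold steps
  ord <- order(-lb$score)
  s <- lb$score[ord]
  y <- lb$label[ord]
  step_end <- which(diff(s) != 0)
  step_end <- c(step_end, length(s))
  tp <- cumsum(y)[step_end]
  fp <- cumsum(!y)[step_end]
  tpr <- c(0, tp / npos)
  fpr <- c(0, fp / nneg)
  recall <- tp / npos
  precision <- tp / (tp + fp)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(
    roc = data.frame(fpr = fpr, tpr = tpr),
    pr = data.frame(recall = recall, precision = precision),
    auroc = auroc,
    aupr = aupr
  )
}

#' F1 scores of a protein ranking
#'
#' Two readings of a single-number F1 for a ranked list: the maximum
#' F1 over the full threshold sweep, and the F1 when exactly the top
#' `|essential|` proteins are called positive (the natural cutoff when
#' the number of essentials is known).
#'
#' @inheritParams roc_pr_curves
#' @return List with `max_f1` and `f1_at_essential_count`.
#' @export
f1_scores <- function(scores, essential) {
  lb <- score_labels(scores, essential)
  npos <- sum(lb$label)
  if (npos == 0L || npos == length(lb$label)) {
    stop("F1 needs both classes among the scored proteins", call. = FALSE)
  }
  curves <- roc_pr_curves(scores, essential)
  pr <- curves$pr
  f1 <- ifelse(pr$precision + pr$recall > 0,
               2 * pr$precision * pr$recall / (pr$precision + pr$recall), 0)
  # cutoff = |essential| top-ranked proteins, deterministic tie order
  ranked <- rank_proteins(stats::setNames(lb$score, lb$protein))
  top <- ranked$protein[seq_len(npos)]
  tp <- sum(top %in% essential)
  prec <- tp / npos
  rec <- tp / npos
  f1_at <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(max_f1 = max(f1), f1_at_essential_count = f1_at)
}

#' Evaluate a ranking against a known-essential set
#'
#' Bundles the four evaluation instruments — precision at several top-K
#' percentages, the jackknife cumulative curve, ROC/PR curves with
#' their areas, and F1 — into one report. Essential IDs absent from the
#' ranking are excluded from every denominator (benchmark lists often
#' extend beyond a given interactome), with the excluded count
#' reported.
#'
#' @param fit A [tgso()] fit, or a ranking data frame, or a named score
#'   vector.
#' @param essential Character vector of essential protein IDs.
#' @param top_percents Percentages for the precision table.
#' @param jackknife_depth Depth of the jackknife curve (default
#'   `min(1000, N)`).
#' @return A `tgso_eval` object: list with `precision` (data frame),
#'   `jackknife`, `roc`, `pr`, `auroc`, `aupr`, `max_f1`,
#'   `f1_at_essential_count`, `n_ranked`, `n_essential_used`,
#'   `n_essential_dropped`.
#' @export
evaluate_ranking <- function(fit, essential,
                             top_percents = c(1, 5, 10, 15, 20, 25),
                             jackknife_depth = NULL) {
  scores <- as_scores(fit)
  ranked <- rank_proteins(scores)
  essential <- unique(essential)
  used <- intersect(essential, ranked$protein)
  dropped <- length(essential) - length(used)
  if (dropped > 0L) {
    message(dropped, " essential IDs not in the ranking; excluded")
  }
  prec <- do.call(rbind, lapply(top_percents, function(k) {
    p <- precision_at_top(ranked, used, k)
    data.frame(k_percent = k, n_top = top_k_count(nrow(ranked), k),
               n_essential = p$count, precision = p$precision)
  }))
  depth <- jackknife_depth %||% min(1000L, nrow(ranked))
  curves <- roc_pr_curves(scores, used)
  f1 <- f1_scores(scores, used)
  structure(
    list(
      precision = prec,
      jackknife = jackknife_curve(ranked, used, depth),
      roc = curves$roc,
      pr = curves$pr,
      auroc = curves$auroc,
      aupr = curves$aupr,
      max_f1 = f1$max_f1,
      f1_at_essential_count = f1$f1_at_essential_count,
      n_ranked = nrow(ranked),
      n_essential_used = length(used),
      n_essential_dropped = dropped
    ),
    class = "tgso_eval"
  )
}

#' @export
print.tgso_eval <- function(x, ...) {
  cat("Ranking evaluation:", x$n_ranked, "proteins,",
      x$n_essential_used, "essential")
  if (x$n_essential_dropped > 0L) {
    cat(" (", x$n_essential_dropped, " outside the ranking excluded)",
        sep = "")
  }
  cat("\n")
  cat(sprintf("AUROC %.4f  AUPR %.4f  max-F1 %.4f  F1@|essential| %.4f\n",
              x$auroc, x$aupr, x$max_f1, x$f1_at_essential_count))
  cat("Precision at top-K%:\n")
  print(x$precision, row.names = FALSE)
  invisible(x)
}

#' Degree-centrality baseline ranking
#'
#' Scores each protein by its interaction degree — the classical
#' centrality baseline the weighted model is expected to beat.
#'
#' @param network A [ppi_network()].
#' @return Named numeric vector of degrees.
#' @export
degree_centrality <- function(network) {
  stats::setNames(as.numeric(network$degree), network$node_ids)
}

#' Layer-ablation experiment
#'
#' Fits the model five times on identical inputs — unit edge weights
#' (the unweighted-network control), each single layer alone, and the
#' full fusion — runs the identical iteration on each, and evaluates
#' every variant against the same essential set. Comparing the variants
#' shows how much each data layer contributes and whether the fusion
#' beats its parts.
#'
#' @inheritParams tgso
#' @param essential Character vector of essential protein IDs.
#' @param top_percents Passed to [evaluate_ranking()].
#' @return An `ablation_table`: list with `summary` (data frame of
#'   AUROC/AUPR/F1 per variant) and `reports` (named list of
#'   `tgso_eval` objects).
#' @export
run_ablation <- function(network, expression = NULL, localization = NULL,
                         orthology = NULL, essential,
                         alpha = 0.3, gamma = 1e-10, max_iter = 1000L,
                         top_percents = c(1, 5, 10, 15, 20, 25)) {
  variants <- c(InitPPI = "ppi", ADN = "adn", CEN = "cen", CLN = "cln",
                PCIN = "pcin")
  reports <- lapply(variants, function(v) {
    fit <- tgso(network, expression, localization, orthology,
                alpha = alpha, gamma = gamma, max_iter = max_iter,
                variant = v)
    evaluate_ranking(fit, essential, top_percents = top_percents)
  })
  summary_df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(variant = nm, auroc = r$auroc, aupr = r$aupr,
               max_f1 = r$max_f1,
               f1_at_essential_count = r$f1_at_essential_count,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary_df, reports = reports),
            class = "ablation_table")
}

#' @export
print.ablation_table <- function(x, ...) {
  cat("Layer ablation (identical inputs, seed and iteration):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

# -- internal ---------------------------------------------------------------

as_ranking <- function(x) {
  if (inherits(x, "tgso")) return(x$ranking)
  if (is.data.frame(x)) {
    stopifnot(all(c("rank", "protein", "score") %in% names(x)))
    return(x)
  }
  rank_proteins(x)
}

as_scores <- function(x) {
  if (inherits(x, "tgso")) return(x$scores)
  if (inherits(x, "score_vector")) return(x$scores)
  if (is.data.frame(x)) return(stats::setNames(x$score, x$protein))
  stopifnot(is.numeric(x), !is.null(names(x)))
  x
}

score_labels <- function(scores, essential) {
  s <- as_scores(scores)
  data.frame(protein = names(s), score = as.numeric(s),
             label = names(s) %in% essential, stringsAsFactors = FALSE)
}
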