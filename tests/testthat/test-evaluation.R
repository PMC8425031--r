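mk_ranked <- function(ids) {
  data.frame(rank = seq_along(ids), protein = ids,
             score = rev(seq_along(ids)), stringsAsFactors = FALSE)
}

test_that("precision at top-K counts set intersections", {
  ranked <- mk_ranked(sprintf("P%02d", 1:20))
  all_ess <- sprintf("P%02d", 1:2)
  expect_equal(precision_at_top(ranked, all_ess, 10)$precision, 1.0)
  expect_equal(precision_at_top(ranked, character(0), 10)$precision, 0)
  # K = 100%: |essential in list| / N exactly
  expect_equal(precision_at_top(ranked, all_ess, 100)$precision, 2 / 20)
  # random ranking vs a counting oracle
  set.seed(3)
  for (rep in 1:10) {
    ids <- sample(sprintf("Q%02d", 1:40))
    ess <- sample(ids, 12)
    k <- sample(c(5, 10, 25, 50), 1)
    got <- precision_at_top(mk_ranked(ids), ess, k)
    ktop <- floor(40 * k / 100 + 0.5)
    oracle <- length(intersect(ids[seq_len(ktop)], ess))
    expect_equal(got$count, oracle)
    expect_equal(got$precision, oracle / ktop)
  }
})

test_that("jackknife curve is the cumulative essential count by rank", {
  ids <- sprintf("P%02d", 1:10)
  # perfect ranking: identity up to |essential|, then flat
  expect_equal(jackknife_curve(mk_ranked(ids), ids[1:4], 10),
               c(1, 2, 3, 4, 4, 4, 4, 4, 4, 4))
  expect_equal(jackknife_curve(mk_ranked(ids), character(0), 10),
               rep(0, 10))
  set.seed(7)
  for (rep in 1:10) {
    perm <- sample(ids)
    ess <- sample(ids, 3)
    curve <- jackknife_curve(mk_ranked(perm), ess)
    expect_equal(curve, cumsum(perm %in% ess))
    expect_true(all(diff(curve) %in% c(0, 1)))  # monotone, unit steps
    expect_equal(curve[10], 3)
  }
})

test_that("AUROC matches the Mann-Whitney rank statistic", {
  # perfect separation
  s <- setNames(c(10, 9, 8, 1, 2, 3), sprintf("P%d", 1:6))
  perfect <- roc_pr_curves(s, sprintf("P%d", 1:3))
  expect_equal(perfect$auroc, 1.0)
  expect_equal(perfect$aupr, 1.0)
  # constant scores: chance level
  flat <- roc_pr_curves(setNames(rep(1, 10), sprintf("P%d", 1:10)),
                        sprintf("P%d", 1:4))
  expect_equal(flat$auroc, 0.5)
  # random scores with ties vs the rank-statistic oracle
  set.seed(12)
  for (rep in 1:10) {
    scores <- setNames(sample(seq(0, 1, 0.05), 200, replace = TRUE),
                       sprintf("P%03d", 1:200))
    labels <- runif(200) < 0.3
    ess <- names(scores)[labels]
    got <- roc_pr_curves(scores, ess)
    expect_equal(got$auroc, oracle_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_pr_curves(setNames(1:3, c("a", "b", "c")),
                             c("a", "b", "c")), "both")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(21)
  scores <- setNames(runif(100), sprintf("P%03d", 1:100))
  ess <- names(scores)[runif(100) < 0.25]
  base <- roc_pr_curves(scores, ess)$auroc
  expect_equal(roc_pr_curves(exp(5 * scores), ess)$auroc, base,
               tolerance = 1e-12)
  expect_equal(roc_pr_curves(rank(scores), ess)$auroc, base,
               tolerance = 1e-12)
})

test_that("F1 readings match exhaustive threshold sweeps", {
  s <- setNames(c(10, 9, 8, 1, 2, 3), sprintf("P%d", 1:6))
  f <- f1_scores(s, sprintf("P%d", 1:3))
  expect_equal(f$max_f1, 1.0)
  expect_equal(f$f1_at_essential_count, 1.0)
  set.seed(31)
  for (rep in 1:10) {
    scores <- setNames(sample(seq(0, 1, 0.1), 80, replace = TRUE),
                       sprintf("P%02d", 1:80))
    labels <- runif(80) < 0.3
    if (!any(labels) || all(labels)) next
    ess <- names(scores)[labels]
    got <- f1_scores(scores, ess)
    expect_equal(got$max_f1, oracle_max_f1(scores, labels),
                 tolerance = 1e-12)
    # F1 at cutoff |essential|: precision = recall there
    k <- sum(labels)
    top <- rank_proteins(scores)$protein[seq_len(k)]
    expect_equal(got$f1_at_essential_count, sum(top %in% ess) / k,
                 tolerance = 1e-12)
  }
})

test_that("evaluation reports drop essentials outside the ranking", {
  b <- generate_bundle(benchmark_config(n_proteins = 80, seed = 9))
  fit <- tgso(b$network, b$expression, b$localization, b$orthology)
  outside <- c(b$essential, "NOT_IN_NETWORK1", "NOT_IN_NETWORK2")
  expect_message(ev <- evaluate_ranking(fit, outside), "excluded")
  expect_equal(ev$n_essential_dropped, 2)
  expect_equal(ev$n_essential_used, length(b$essential))
  expect_equal(ev$n_ranked, 80)
  expect_true(ev$auroc >= 0 && ev$auroc <= 1)
  expect_true(ev$aupr >= 0 && ev$aupr <= 1)
  tail_val <- ev$jackknife[length(ev$jackknife)]
  expect_equal(tail_val, sum(fit$ranking$protein %in% b$essential))
})

test_that("ablation evaluates five variants on identical bookkeeping", {
  b <- generate_bundle(benchmark_config(n_proteins = 80, seed = 13))
  ab <- run_ablation(b$network, b$expression, b$localization,
                     b$orthology, b$essential)
  expect_equal(ab$summary$variant,
               c("InitPPI", "ADN", "CEN", "CLN", "PCIN"))
  ns <- vapply(ab$reports, function(r) r$n_ranked, 1)
  expect_true(all(ns == 80))
  ks <- vapply(ab$reports, function(r) r$n_essential_used, 1)
  expect_true(all(ks == ks[1]))
  expect_true(all(ab$summary$auroc >= 0 & ab$summary$auroc <= 1))
})

test_that("ablation ranks the informative layer above a noise layer", {
  # localization carries signal; expression is pure noise and orthology
  # uniform, so the CLN variant should not lose to the CEN variant
  aurocs <- sapply(1:5, function(seed) {
    cfg <- benchmark_config(n_proteins = 150, seed = 100 + seed,
                            expr_noise_essential = 1.0,
                            ortholog_prob_essential = 0.2)
    b <- generate_bundle(cfg)
    # break the expression latent signal: regenerate as background
    noise <- lapply(seq_len(150), function(i) rnorm(36))
    names(noise) <- b$network$node_ids
    expr <- expression_table(noise, b$network)
    vars <- c("cen", "cln")
    vapply(vars, function(v) {
      fit <- tgso(b$network, expr, b$localization, b$orthology,
                  variant = v, uniform_seed = TRUE)
      evaluate_ranking(fit, b$essential)$auroc
    }, 0)
  })
  expect_gte(mean(aurocs["cln", ]), mean(aurocs["cen", ]))
})
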