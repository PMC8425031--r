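test_that("DBN weight matches hand-computed small graphs", {
  # path a-b-c: edge (a,b) has no common neighbour, min degree 1
  path <- ppi_network(c("a", "b"), c("b", "c"))
  expect_equal(dbn_weight(path, 1, 2), 1.0)
  # 4-cycle: edge (a,b) has no common neighbour, both degrees 2
  cyc <- ppi_network(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  expect_equal(dbn_weight(cyc, 1, 2), 0.5)
  # triangle: one common neighbour, degrees 2
  tri <- ppi_network(c("a", "b", "c"), c("b", "c", "a"))
  expect_equal(dbn_weight(tri, 1, 2), 1.0)
  # star: leaves have degree 1
  star <- ppi_network(c("h", "h", "h"), c("l1", "l2", "l3"))
  w <- build_adn(star)$weights
  expect_equal(w, rep(1.0, 3))
  # non-edge is a contract violation
  expect_error(dbn_weight(path, 1, 3), "existing edge")
})

test_that("ADN equals the brute-force neighbour-set oracle on random graphs", {
  for (seed in 1:25) {
    inst <- random_instance(n = 12, p = 0.3, seed = seed)
    adn <- build_adn(inst$net)
    for (k in seq_len(nrow(inst$net$edges))) {
      i <- inst$net$edges[k, 1]; j <- inst$net$edges[k, 2]
      expect_equal(adn$weights[k], oracle_dbn(inst$a, i, j),
                   tolerance = 1e-12)
      expect_equal(dbn_weight(inst$net, i, j), oracle_dbn(inst$a, i, j),
                   tolerance = 1e-12)
    }
  }
})

test_that("pearson_cc implements the sample correlation exactly", {
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson_cc(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_cc(c(5, 5, 5), c(1, 2, 3)), 0)  # zero variance
  expect_error(pearson_cc(c(1, 2), c(1, 2, 3)), "length")
  expect_error(pearson_cc(1, 2), "2 time points")
  set.seed(99)
  for (rep in 1:100) {
    x <- rnorm(36); y <- rnorm(36)
    direct <- sum((x - mean(x)) / sd(x) * (y - mean(y)) / sd(y)) / 35
    expect_equal(pearson_cc(x, y), direct, tolerance = 1e-12)
    expect_equal(pearson_cc(x, y), cor(x, y), tolerance = 1e-12)
  }
})

test_that("connection weight adds common-neighbour correlation products", {
  # two nodes, one edge, no common neighbours: weight is just PCC
  net <- ppi_network("u", "v")
  expr <- expression_table(list(u = c(1, 2, 4), v = c(1, 3, 4)), net)
  expect_equal(connection_weight(net, expr, 1, 2),
               cor(c(1, 2, 4), c(1, 3, 4)), tolerance = 1e-12)
  # identical profiles, one common neighbour: 1 + 1*1 = 2
  tri <- ppi_network(c("u", "v", "w"), c("v", "w", "u"))
  same <- expression_table(list(u = c(1, 2, 3), v = c(1, 2, 3),
                                w = c(1, 2, 3)), tri)
  expect_equal(connection_weight(tri, same, 1, 2), 2.0)
  expect_error(connection_weight(net, expr, 1, 1), "existing edge")
})

test_that("CEN equals the per-edge loop oracle and respects the zero floor", {
  for (seed in 1:10) {
    inst <- random_instance(n = 10, p = 0.4, seed = seed, t_points = 36)
    cen <- build_cen(inst$net, inst$expr)
    for (k in seq_len(nrow(inst$net$edges))) {
      i <- inst$net$edges[k, 1]; j <- inst$net$edges[k, 2]
      expect_equal(cen$weights[k],
                   oracle_connection(inst$a, inst$expr, i, j),
                   tolerance = 1e-12)
    }
    expect_true(all(cen$weights >= 0))
  }
})

test_that("CEN is all zero when no protein has expression coverage", {
  net <- ppi_network(c("a", "b"), c("b", "c"))
  expr <- expression_table(list(), net)
  expect_equal(build_cen(net, expr)$weights, c(0, 0))
})

test_that("compartment frequencies are a distribution over the vocabulary", {
  loc <- localization_table(list(P1 = "Nucleus", P2 = "Nucleus",
                                 P3 = c("Nucleus", "Cytosol")))
  freq <- location_frequency(loc)
  expect_equal(unname(freq$scores[c("Nucleus", "Cytosol")]), c(0.75, 0.25))
  expect_equal(sum(freq$scores), 1)
  # single compartment: score 1
  one <- localization_table(list(P1 = "X", P2 = "X"))
  expect_equal(unname(location_frequency(one)$scores), 1)
  expect_error(location_frequency(localization_table(list())),
               "localization")
})

test_that("random annotations match the counting oracle and sum to one", {
  for (seed in 1:5) {
    inst <- random_instance(n = 200, p = 0.02, seed = seed,
                            n_compartments = 11)
    freq <- location_frequency(inst$loc)
    expect_equal(freq$scores, oracle_sub_scores(inst$loc),
                 tolerance = 1e-12)
    expect_lt(abs(sum(freq$scores) - 1), 1e-12)
  }
})

test_that("self-localization score sums the compartment scores of L(u)", {
  loc <- localization_table(list(P1 = c("A", "B"), P2 = "A"),
                            vocabulary = c("A", "B"))
  freq <- location_frequency(loc)
  expect_equal(self_localization_score(freq, loc, "P1"), 1.0)  # full vocab
  expect_equal(self_localization_score(freq, loc, "P3"), 0)    # unannotated
  expect_equal(self_localization_score(freq, loc, "P2"),
               unname(freq$scores["A"]))
})

test_that("co-localization weight is Jaccard times mean self-score", {
  loc <- localization_table(list(u = "A", v = "A", w = "B", x = "B",
                                 y = "B"),
                            vocabulary = c("A", "B"))
  freq <- location_frequency(loc)
  # identical singleton sets: weight = sub_score of that compartment
  expect_equal(colocalization_weight(freq, loc, "u", "v"),
               unname(freq$scores["A"]))
  # disjoint nonempty sets: Jaccard 0
  expect_equal(colocalization_weight(freq, loc, "u", "w"), 0)
  # both unannotated: empty union convention
  expect_equal(colocalization_weight(freq, loc, "z1", "z2"), 0)
})

test_that("CLN equals the set-algebra oracle on random annotations", {
  for (seed in 1:10) {
    inst <- random_instance(n = 12, p = 0.35, seed = seed)
    cln <- build_cln(inst$net, inst$loc)
    for (k in seq_len(nrow(inst$net$edges))) {
      i <- inst$net$edges[k, 1]; j <- inst$net$edges[k, 2]
      expect_equal(cln$weights[k],
                   oracle_colo(inst$loc, inst$ids[i], inst$ids[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("CLN handles a fully unannotated protein set as all zero", {
  net <- ppi_network(c("a", "b"), c("b", "c"))
  loc <- localization_table(list())
  expect_equal(build_cln(net, loc)$weights, c(0, 0))
})

test_that("all layers are symmetric, nonnegative, finite, edge-supported", {
  for (seed in 1:8) {
    inst <- random_instance(n = 14, p = 0.3, seed = seed)
    adn <- build_adn(inst$net)
    cen <- build_cen(inst$net, inst$expr)
    cln <- build_cln(inst$net, inst$loc)
    mindeg_inv <- 1 / pmin(inst$net$degree[inst$net$edges[, 1]],
                           inst$net$degree[inst$net$edges[, 2]])
    expect_true(all(adn$weights >= mindeg_inv - 1e-15))  # DBN >= 1/min-deg
    expect_true(all(cln$weights >= 0 & cln$weights <= 1))  # Jaccard bound
    for (layer in list(adn, cen, cln)) {
      m <- layer_matrix(layer)
      expect_equal(m, t(m))
      expect_true(all(is.finite(layer$weights)))
      expect_true(all(layer$weights >= 0))
      expect_true(all(m[inst$a == 0] == 0))  # support only on E
    }
  }
})
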