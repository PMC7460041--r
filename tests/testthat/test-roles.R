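test_that("weighted degree sums incident weights both ways", {
  ids <- c("A", "B", "C")
  w <- matrix(0, 3, 3, dimnames = list(ids, ids))
  w["A", "B"] <- 0.4
  net <- wnet(w)
  wd <- weighted_degree(net)
  expect_equal(unname(wd), c(0.4, 0.4, 0))  # C is an isolate

  set.seed(6)
  m <- matrix(runif(25) * 0.3, 5, 5)
  diag(m) <- 0
  net2 <- wnet(m, ids = paste0("n", 1:5))
  expect_equal(unname(weighted_degree(net2)),
               unname(rowSums(m) + colSums(m)))
})

test_that("closeness normalization hits closed forms and path oracle", {
  # complete unit-weight network: every node scores exactly 1
  for (n in c(3, 5, 8)) {
    w <- matrix(1, n, n)
    diag(w) <- 0
    net <- wnet(w, ids = paste0("n", 1:n))
    expect_equal(unname(closeness_norm(net)), rep(1, n))
  }
  # isolate scores 0
  w <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  w["a", "b"] <- 1
  expect_equal(unname(suppressWarnings(closeness_norm(wnet(w)))[3]), 0)

  # 4-node directed path with unit weights: brute-force distances
  w4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  w4["a", "b"] <- w4["b", "c"] <- w4["c", "d"] <- 1
  net4 <- wnet(w4)
  D <- brute_distances(w4)
  n <- 4
  expected <- vapply(1:4, function(i) {
    dv <- D[i, -i]
    r <- sum(is.finite(dv))
    if (r == 0) 0 else (r / (n - 1)) * (r / sum(dv[is.finite(dv)]))
  }, numeric(1))
  expect_equal(unname(suppressWarnings(closeness_norm(net4))), expected)
  # in-mode reverses the path direction
  expect_equal(unname(suppressWarnings(closeness_norm(net4, "in"))),
               rev(expected))
})

test_that("betweenness normalization: star centres 1, leaves 0", {
  for (n in 3:10) {
    ids <- paste0("n", 1:n)
    w <- matrix(0, n, n, dimnames = list(ids, ids))
    w[1, 2:n] <- 1
    bn <- betweenness_norm(wnet(w))
    expect_equal(unname(bn[1]), 1)
    expect_equal(unname(bn[-1]), rep(0, n - 1))
  }
  expect_error(betweenness_norm(wnet(matrix(0, 2, 2))),
               class = "focalsna_invalid_value")
})

test_that("betweenness matches brute-force path enumeration", {
  set.seed(77)
  for (rep in 1:3) {
    n <- 5
    w <- matrix(runif(n * n) * rbinom(n * n, 1, 0.6), n, n)
    diag(w) <- 0
    w <- w / max(w)
    net <- wnet(w, ids = paste0("n", 1:n))
    bn <- betweenness_norm(net)
    expect_equal(unname(bn),
                 2 * brute_betweenness(w) / (n^2 - 3 * n + 2),
                 tolerance = 1e-10)
  }
})

test_that("node metrics are invariant under node relabeling", {
  g <- small_synth(seed = 15)
  net <- suppressWarnings(
    simple_ratio_index(count_nearest_neighbour(g$dataset)))
  m0 <- node_metric_table(net)
  p <- sample(seq_along(net$ids))
  wperm <- net$w[p, p]
  netp <- weighted_network(wperm, layer = net$layer,
                           period_label = net$period_label)
  mp <- suppressWarnings(node_metric_table(netp))
  m0p <- suppressWarnings(m0[match(netp$ids, m0$id), ])
  expect_equal(mp$weighted_degree, m0p$weighted_degree)
  expect_equal(mp$closeness, m0p$closeness)
  expect_equal(mp$betweenness, m0p$betweenness)
})

test_that("role models find a planted dominance effect", {
  set.seed(880)
  n <- 50
  att <- data.frame(id = sprintf("i%02d", 1:n),
                    sex = sample(c("female", "male"), n, replace = TRUE),
                    age = runif(n, 1, 20),
                    dominance = rnorm(n, 0, 3),
                    stringsAsFactors = FALSE)
  metrics <- data.frame(id = att$id,
                        planted = 0.5 * att$dominance + rnorm(n, 0, 0.3))
  rm <- role_models(metrics, att, n_perm = 1000, seed = 5)
  m <- rm$models$planted
  expect_equal(m$selected, "dominance")
  co <- m$coefficients[m$coefficients$term == "dominance", ]
  expect_lt(abs(co$estimate - 0.5), 0.1)
  expect_lte(co$p_perm, 0.05)
})

test_that("structure-free metrics are mostly unexplained", {
  set.seed(99)
  n <- 40
  att <- data.frame(id = sprintf("i%02d", 1:n),
                    sex = sample(c("female", "male"), n, replace = TRUE),
                    age = runif(n, 1, 20),
                    dominance = rnorm(n),
                    stringsAsFactors = FALSE)
  picks <- character(8)
  for (r in 1:8) {
    metrics <- data.frame(id = att$id, m = rnorm(n))
    rm <- role_models(metrics, att, n_perm = 200, seed = r)
    picks[r] <- rm$models$m$selected
  }
  expect_gte(sum(picks == "none"), 5)

  # constant metric: intercept-only, no factors reported
  rmc <- role_models(data.frame(id = att$id, m = rep(1, n)), att,
                     n_perm = 100, seed = 1)
  expect_equal(rmc$models$m$selected, "none")
})

test_that("temporal stability is exact on identical tables and robust to
          node set changes", {
  g <- small_synth(seed = 33)
  net <- suppressWarnings(
    simple_ratio_index(count_nearest_neighbour(g$dataset)))
  m1 <- suppressWarnings(node_metric_table(net))
  res <- temporal_stability(m1, m1, n_perm = 500, seed = 2)
  expect_equal(res$observed, 1)
  expect_lte(res$p_value, 0.002 * 2.5)

  # dropping a node leaves the remaining alignment intact
  m2 <- m1[m1$id != m1$id[1], ]
  res2 <- temporal_stability(m1, m2, n_perm = 200, seed = 3)
  expect_equal(res2$n_nodes, nrow(m1) - 1)
  expect_equal(res2$observed, 1)

  # shuffled second-period metrics: alignment no longer significant (the
  # raw stacked r stays high from between-metric scale blocks, which the
  # permutation null shares; only the p-value is informative here)
  m3 <- m1
  set.seed(4)
  m3[, -1] <- m3[sample(nrow(m3)), -1]
  res3 <- temporal_stability(m1, m3, n_perm = 200, seed = 5)
  expect_gt(res3$p_value, 0.05)
  expect_lt(res3$observed, res$observed)
  pm <- temporal_stability(m1, m1, n_perm = 100, seed = 6,
                           mode = "per_metric")
  expect_named(pm, c("weighted_degree", "closeness", "betweenness"))
  expect_equal(pm$closeness$observed, 1)

  expect_error(temporal_stability(m1, m1[0, ]),
               class = "focalsna_invalid_value")
})
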