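test_that("node-label permutations preserve topology and are seeded", {
  g <- small_synth(seed = 61)
  net <- suppressWarnings(
    simple_ratio_index(count_nearest_neighbour(g$dataset)))
  perms <- node_label_permutations(net, 5, seed = 4)
  for (pn in perms) {
    expect_equal(sort(focalsna:::vec_offdiag(pn$w)),
                 sort(focalsna:::vec_offdiag(net$w)))
    expect_equal(unname(sort(rowSums(pn$w))), unname(sort(rowSums(net$w))))
    expect_equal(unname(sort(colSums(pn$w))), unname(sort(colSums(net$w))))
    p <- attr(pn, "perm")
    expect_equal(pn$w, unname(net$w[p, p]), ignore_attr = TRUE)
  }
  perms2 <- node_label_permutations(net, 5, seed = 4)
  expect_identical(lapply(perms, `[[`, "w"), lapply(perms2, `[[`, "w"))
  # the identity relabeling reproduces the network
  idw <- net$w[seq_along(net$ids), seq_along(net$ids)]
  expect_identical(idw, net$w)
})

test_that("discrete assortativity hits its closed-form extremes", {
  ids <- letters[1:4]
  # all weight within classes {a,b} and {c,d}
  w <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w["a", "b"] <- w["b", "a"] <- 0.5
  w["c", "d"] <- w["d", "c"] <- 0.5
  lab <- c("u", "u", "v", "v")
  expect_equal(assortment_discrete(wnet(w), lab), 1)
  # balanced two-class bipartite weight
  w2 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w2["a", "c"] <- w2["c", "a"] <- w2["b", "d"] <- w2["d", "b"] <- 0.5
  expect_equal(assortment_discrete(wnet(w2), lab), -1)
  expect_error(assortment_discrete(wnet(w), rep("u", 4)),
               class = "focalsna_degenerate")
})

test_that("discrete assortativity equals brute-force mixing-matrix", {
  set.seed(8)
  n <- 10
  w <- matrix(runif(n * n) * rbinom(n * n, 1, 0.4), n, n)
  diag(w) <- 0
  net <- wnet(w / max(w), ids = paste0("n", 1:n))
  lab <- sample(c("x", "y", "z"), n, replace = TRUE)
  # direct evaluation of the definition
  tot <- sum(net$w)
  cls <- sort(unique(lab))
  e <- matrix(0, 3, 3)
  for (i in 1:n) for (j in 1:n)
    e[match(lab[i], cls), match(lab[j], cls)] <-
      e[match(lab[i], cls), match(lab[j], cls)] + net$w[i, j] / tot
  r_brute <- (sum(diag(e)) - sum(rowSums(e) * colSums(e))) /
    (1 - sum(rowSums(e) * colSums(e)))
  expect_equal(assortment_discrete(net, lab), r_brute)
})

test_that("continuous assortativity matches weighted-correlation oracle", {
  # identical endpoint values within components -> r = 1
  ids <- letters[1:4]
  w <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w["a", "b"] <- w["b", "a"] <- 0.3
  w["c", "d"] <- w["d", "c"] <- 0.6
  expect_equal(assortment_continuous(wnet(w), c(2, 2, 5, 5)), 1)
  # two nodes with opposite values -> r = -1
  w2 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  w2["a", "b"] <- w2["b", "a"] <- 0.4
  expect_equal(assortment_continuous(wnet(w2), c(1, -1)), -1)
  expect_error(assortment_continuous(wnet(w2), c(3, 3)),
               class = "focalsna_degenerate")

  # weighted Pearson hand computation on a small fixture
  set.seed(21)
  n <- 6
  wr <- matrix(runif(n * n) * rbinom(n * n, 1, 0.5), n, n)
  diag(wr) <- 0
  net <- wnet(wr / max(wr), ids = paste0("n", 1:n))
  v <- rnorm(n)
  ww <- c()
  xs <- c()
  ys <- c()
  for (i in 1:n) for (j in 1:n) {
    if (i == j || net$w[i, j] == 0) next
    ww <- c(ww, net$w[i, j])
    xs <- c(xs, v[i])
    ys <- c(ys, v[j])
  }
  mx <- weighted.mean(xs, ww)
  my <- weighted.mean(ys, ww)
  r_brute <- sum(ww * (xs - mx) * (ys - my)) /
    sqrt(sum(ww * (xs - mx)^2) * sum(ww * (ys - my)^2))
  expect_equal(assortment_continuous(net, v), r_brute)
})

test_that("assortment permutation test flags planted structure", {
  # perfectly assorted two-block network: observed r exceeds every null
  ids <- paste0("n", 1:10)
  w <- matrix(0, 10, 10, dimnames = list(ids, ids))
  w[1:5, 1:5] <- 0.5
  w[6:10, 6:10] <- 0.5
  diag(w) <- 0
  net <- wnet(w)
  res <- assortment_test(net, rep(c("u", "v"), each = 5),
                         kind = "discrete", n_perm = 500, seed = 6)
  expect_equal(res$r, 1)
  expect_lte(res$p_value, 0.01)
  # determinism under seed
  res2 <- assortment_test(net, rep(c("u", "v"), each = 5),
                          kind = "discrete", n_perm = 500, seed = 6)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$null_values, res2$null_values)
})

test_that("assortativity is invariant to global weight rescaling", {
  set.seed(13)
  n <- 8
  w <- matrix(runif(n * n) * rbinom(n * n, 1, 0.5), n, n)
  diag(w) <- 0
  w <- w / max(w)
  v <- rnorm(n)
  lab <- sample(c("u", "v"), n, replace = TRUE)
  r1c <- assortment_continuous(wnet(w), v)
  r1d <- assortment_discrete(wnet(w), lab)
  expect_equal(assortment_continuous(wnet(w * 0.2), v), r1c)
  expect_equal(assortment_discrete(wnet(w * 0.2), lab), r1d)
})

test_that("MRQAP recovers an exact linear relationship", {
  set.seed(3)
  n <- 12
  ids <- paste0("n", 1:n)
  x <- matrix(runif(n * n) * 0.4, n, n)
  diag(x) <- 0
  px <- wnet(x, ids = ids)
  py <- wnet(x * 2, ids = ids)
  fit <- mrqap(py, list(pred = px), n_perm = 1000, seed = 5)
  expect_equal(fit$coefficients$estimate, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_lte(fit$coefficients$p_perm, 0.002)
})

test_that("MRQAP coefficients equal vectorized OLS for any permutations", {
  set.seed(14)
  n <- 9
  ids <- paste0("n", 1:n)
  mk <- function() {
    m <- matrix(runif(n * n) * 0.5, n, n)
    diag(m) <- 0
    wnet(m, ids = ids)
  }
  y <- mk(); x1 <- mk(); x2 <- mk()
  fit <- mrqap(y, list(a = x1, b = x2), n_perm = 120, seed = 2)
  off <- function(net) focalsna:::vec_offdiag(net$w)
  ref <- lm(off(y) ~ off(x1) + off(x2))
  expect_equal(fit$coefficients$estimate, unname(coef(ref)[2:3]),
               tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit$coefficients$t,
               unname(summary(ref)$coefficients[2:3, 3]),
               tolerance = 1e-10)
  # changing the seed changes only p, not the estimates
  fit2 <- mrqap(y, list(a = x1, b = x2), n_perm = 120, seed = 3)
  expect_identical(fit$coefficients$estimate, fit2$coefficients$estimate)
})

test_that("MRQAP names a collinear predictor pair", {
  set.seed(4)
  n <- 8
  m <- matrix(runif(n * n), n, n)
  diag(m) <- 0
  a <- wnet(m / max(m), ids = paste0("n", 1:n))
  b <- wnet(m / max(m) * 0.5, ids = paste0("n", 1:n))
  y <- wnet(matrix(runif(n * n) * 0.2, n, n, dimnames = dimnames(a$w)))
  err <- tryCatch(mrqap(y, list(first = a, second = b), n_perm = 100,
                        seed = 1), condition = function(e) e)
  expect_s3_class(err, "focalsna_collinear")
  expect_match(conditionMessage(err), "first")
})

test_that("QAP correlation handles exact and mismatched inputs", {
  x <- setNames(rnorm(20), paste0("n", 1:20))
  res <- qap_correlation(x, x, n_perm = 300, seed = 8)
  expect_equal(res$observed, 1)
  expect_lte(res$p_value, 1 / 100)
  res2 <- qap_correlation(x, -x, n_perm = 300, seed = 8)
  expect_equal(res2$observed, -1)
  expect_lte(res2$p_value, 1 / 100)
  expect_error(qap_correlation(x, rnorm(5)),
               class = "focalsna_invalid_value")
  # named vectors are aligned before correlating
  y <- 2 * x + 0.001
  res3 <- qap_correlation(x, y[sample(names(y))], n_perm = 100, seed = 1)
  expect_equal(res3$observed, 1)
})

test_that("permutation p-values obey the add-one rule and bounds", {
  pt <- focalsna:::new_perm_test("s", 5, c(1, 2, 6), "two_sided", 3, 1)
  expect_equal(pt$p_value, (1 + 1) / (1 + 3))
  pt2 <- focalsna:::new_perm_test("s", 10, c(1, 2, 3), "greater", 3, 1)
  expect_equal(pt2$p_value, 1 / 4)
  expect_true(pt$p_value > 0 && pt$p_value <= 1)
})
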