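test_that("dyad samples cover ordered pairs with positive denominators", {
  g <- small_synth(seed = 41, n = 3, days = 6, fpd = 3)
  cn <- count_nearest_neighbour(g$dataset)
  sm <- dyad_samples(cn)
  expect_equal(nrow(sm), 6)  # 3 x 2 ordered pairs, all co-sampled
  # x and d match an independent recount
  brute <- brute_scan_counts(g$dataset)
  for (i in seq_len(nrow(sm))) {
    a <- sm$a[i]; b <- sm$b[i]
    expect_equal(sm$x[i], unname(brute$X[a, b]))
    expect_equal(sm$d[i],
                 unname(brute$S[a] + brute$S[b] - brute$X[b, a]))
  }
  # a pair with zero sampling effort on both sides is absent
  for (id in c("AAX", "ABX")) {
    cn$S[id] <- 0
    cn$X[id, ] <- 0
    cn$X[, id] <- 0
  }
  sm2 <- dyad_samples(cn)
  expect_false(any(sm2$a == "AAX" & sm2$b == "ABX"))
  expect_false(any(sm2$a == "ABX" & sm2$b == "AAX"))
})

test_that("K = 1 fit is the closed-form pooled proportion", {
  x <- c(0, 3, 5, 1)
  d <- c(10, 20, 30, 10)
  fit <- fit_binmix(x, d, K = 1)
  expect_identical(fit$p, sum(x) / sum(d))
  expect_identical(fit$q, 1)
  expect_equal(fit$loglik, sum(dbinom(x, d, sum(x) / sum(d), log = TRUE)))
})

test_that("EM log-likelihood is non-decreasing on varied inputs", {
  set.seed(99)
  for (rep in 1:5) {
    d <- sample(20:200, 120, replace = TRUE)
    k <- sample(1:3, 120, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    x <- rbinom(120, d, c(0.01, 0.1, 0.4)[k])
    fit <- fit_binmix(x, d, K = sample(2:4, 1), seed = rep)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("EM recovers planted two-class mixture parameters", {
  set.seed(2024)
  k <- sample(1:2, 1000, replace = TRUE, prob = c(0.7, 0.3))
  x <- rbinom(1000, 200, c(0.01, 0.3)[k])
  fit <- fit_binmix(x, rep(200, 1000), K = 2, seed = 1)
  expect_lt(max(abs(fit$q - c(0.7, 0.3))), 0.05)
  expect_lt(max(abs(fit$p - c(0.01, 0.3))), 0.05)
  expect_true(fit$converged)
})

test_that("mixture fits reject impossible K and degenerate requests", {
  expect_error(fit_binmix(c(1, 2), c(5, 5), K = 3),
               class = "focalsna_invalid_value")
  expect_error(fit_binmix(c(1), c(5), K = 0),
               class = "focalsna_invalid_value")
})

test_that("ICL components follow their definitions", {
  # K = 1: z all ones, E = 0, ICL = BIC = -2 loglik + ln n
  x <- c(1, 2, 3)
  d <- c(10, 10, 10)
  f1 <- fit_binmix(x, d, K = 1)
  sc <- icl_score(f1)
  expect_equal(unname(sc["E"]), 0)
  expect_equal(unname(sc["ICL"]), unname(sc["BIC"]))
  expect_equal(unname(sc["BIC"]), -2 * f1$loglik + 1 * log(3))

  # hard classification implies E = 0 and ICL = BIC
  f_hard <- f1
  f_hard$K <- 2
  f_hard$z <- cbind(c(1, 0, 1), c(0, 1, 0))
  sc2 <- icl_score(f_hard)
  expect_equal(unname(sc2["E"]), 0)
  expect_equal(unname(sc2["ICL"]), unname(sc2["BIC"]))

  # soft z: E equals the brute-force double sum
  f_soft <- f1
  f_soft$K <- 2
  f_soft$z <- cbind(c(0.8, 0.5, 0.1), c(0.2, 0.5, 0.9))
  E_brute <- 0
  for (i in 1:3) for (kk in 1:2) {
    zik <- f_soft$z[i, kk]
    E_brute <- E_brute - zik * log(zik)
  }
  expect_equal(unname(icl_score(f_soft)["E"]), E_brute)
})

test_that("ICL selection recovers a planted K = 3 design", {
  set.seed(512)
  q <- c(0.8, 0.15, 0.05)
  p <- c(0.005, 0.05, 0.3)
  k <- sample(1:3, 1800, replace = TRUE, prob = q)
  x <- rbinom(1800, 100, p[k])
  sel <- select_binmix(x, rep(100, 1800), Kmax = 6, seed = 77)
  expect_equal(sel$selected_K, 3)
  expect_equal(sel$table$ICL, sel$table$BIC + 2 * sel$table$E)
  expect_equal(nrow(sel$table), 6)
  expect_true(sel$H >= 0 && sel$H <= log(sel$selected_K) + 1e-12)
})

test_that("degenerate all-zero data selects a single class", {
  sel <- select_binmix(rep(0, 60), rep(25, 60), Kmax = 4, seed = 2)
  expect_equal(sel$selected_K, 1)
  expect_equal(sel$H, 0)
})

test_that("Shannon entropy has its closed-form values and guards", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  q <- c(0.772, 0.166, 0.042, 0.019)
  q <- q / sum(q)
  expect_equal(shannon_entropy(q), -sum(q * log(q)))
  expect_error(shannon_entropy(c(0.5, 0.4)),
               class = "focalsna_invalid_value")
  expect_error(shannon_entropy(c(1.2, -0.2)),
               class = "focalsna_invalid_value")
})

test_that("fit object methods behave like a standard model fit", {
  set.seed(5)
  x <- rbinom(200, 50, 0.1)
  fit <- fit_binmix(x, rep(50, 200), K = 2, seed = 3)
  expect_equal(sum(coef(fit)$q), 1, tolerance = 1e-10)
  expect_equal(attr(logLik(fit), "df"), 3)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_true(all(sims[[1]]$x <= sims[[1]]$d))
  z <- predict(fit, data.frame(x = c(0, 25), d = c(50, 50)))
  expect_equal(rowSums(z), c(1, 1))
  expect_output(print(fit), "Binomial mixture fit")
})

test_that("halving sampling effort pushes selection toward smaller K", {
  # fewer trials per dyad blur class separation, so the chosen K should
  # not increase on average when d is halved
  set.seed(31)
  q <- c(0.8, 0.15, 0.05)
  p <- c(0.005, 0.05, 0.3)
  ks_full <- ks_half <- integer(6)
  for (r in 1:6) {
    k <- sample(1:3, 600, replace = TRUE, prob = q)
    x_full <- rbinom(600, 60, p[k])
    x_half <- rbinom(600, 30, p[k])
    ks_full[r] <- suppressWarnings(
      select_binmix(x_full, rep(60, 600), Kmax = 4, seed = r))$selected_K
    ks_half[r] <- suppressWarnings(
      select_binmix(x_half, rep(30, 600), Kmax = 4, seed = r))$selected_K
  }
  expect_lte(mean(ks_half), mean(ks_full))
})
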