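test_that("nearest-neighbour counts match a brute-force recount", {
  ds <- tiny_dataset()
  # GHI is never focal-sampled and is kept as an isolate, with a warning
  expect_warning(cn <- count_nearest_neighbour(ds), "isolates")
  # 1 scan A~{B}, 1 scan A~{B,C}, 1 scan A~{C}; B: {A}, {C}
  expect_equal(cn$X["ABC", "DEF"], 2)
  expect_equal(cn$X["ABC", "GHI"], 2)
  expect_equal(cn$X["DEF", "ABC"], 1)
  expect_equal(unname(cn$S), c(3, 2, 0))

  for (seed in c(2, 20)) {
    g <- small_synth(seed = seed, n = 5, days = 4, fpd = 5)
    cn <- count_nearest_neighbour(g$dataset)
    brute <- brute_scan_counts(g$dataset)
    expect_equal(cn$X, brute$X)
    expect_equal(cn$S, brute$S)
    # X + Y_A never exceeds A's total scan points
    YA <- focalsna:::counts_YA(cn)
    expect_true(all(cn$X + YA <= matrix(cn$S, 5, 5) + 1e-12))
  }
})

test_that("interaction-duration counts are directed and match recount", {
  ds <- tiny_dataset()
  aff <- count_interaction_durations(ds, "affiliative")
  agg <- count_interaction_durations(ds, "aggressive")
  # one 30 s affiliative A->B inside A's focal
  expect_equal(aff$X["ABC", "DEF"], 30)
  expect_equal(sum(aff$X), 30)
  # GHI->ABC event in ABC's focal is not actor-side for the focal
  expect_equal(agg$X["GHI", "ABC"], 0)
  expect_equal(agg$X["DEF", "GHI"], 7)
  # receiver-side switch attributes the focal's received time
  agg2 <- count_interaction_durations(ds, "aggressive",
                                      include_received = TRUE)
  expect_equal(agg2$X["ABC", "GHI"], 12)

  g <- small_synth(seed = 31)
  for (cat in c("affiliative", "aggressive")) {
    cn <- count_interaction_durations(g$dataset, cat)
    expect_equal(cn$X, brute_duration_counts(g$dataset, cat))
  }
})

test_that("empty category yields an all-zero count matrix", {
  ds <- tiny_dataset()
  ds$interactions <- ds$interactions[ds$interactions$category ==
                                       "aggressive", ]
  aff <- count_interaction_durations(validate_dataset(ds), "affiliative")
  expect_true(all(aff$X == 0))
  net <- suppressWarnings(simple_ratio_index(aff))
  expect_true(all(net$w == 0))
})

test_that("the association index follows its defining ratio", {
  # X = 5, Y_A = 5, Y_B = 10, Y_AB = 0 -> 5/20
  ids <- c("A", "B")
  X <- matrix(c(0, 5, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(ids, ids))
  cn <- focalsna:::new_dyadic_counts(X, S = c(A = 10, B = 10),
                                     mode = "scan_count",
                                     layer = "association", period = "t")
  net <- simple_ratio_index(cn)
  expect_equal(net$w["A", "B"], 5 / (0 + 5 + 10 + 5))
  # X = 0 -> 0; exclusive partners (Y_A = Y_B = 0) -> 1
  X2 <- matrix(c(0, 10, 10, 0), 2, 2, dimnames = list(ids, ids))
  cn2 <- focalsna:::new_dyadic_counts(X2, S = c(A = 10, B = 10),
                                      mode = "scan_count",
                                      layer = "association", period = "t")
  net2 <- simple_ratio_index(cn2)
  expect_equal(net2$w["A", "B"], 1)
  expect_equal(net2$w["B", "A"], 1)
})

test_that("SRI networks equal the brute-force index on random data", {
  for (seed in c(7, 13)) {
    g <- small_synth(seed = seed, n = 6, days = 5, fpd = 6)
    net <- suppressWarnings(
      simple_ratio_index(count_nearest_neighbour(g$dataset)))
    expect_equal(net$w, brute_sri(g$dataset), tolerance = 1e-12)
    expect_true(all(net$w >= 0 & net$w <= 1))
    expect_true(all(diag(net$w) == 0))
  }
})

test_that("SRI is invariant to focal record order and duration scaling", {
  g <- small_synth(seed = 23)
  ds <- g$dataset
  net1 <- suppressWarnings(
    simple_ratio_index(count_interaction_durations(ds, "affiliative")))
  shuf <- ds
  ord <- rev(seq_len(nrow(shuf$interactions)))
  shuf$interactions <- shuf$interactions[ord, ]
  net2 <- suppressWarnings(
    simple_ratio_index(count_interaction_durations(shuf, "affiliative")))
  expect_equal(net1$w, net2$w)
  # scaling every duration by k leaves the ratio unchanged
  scaled <- ds
  scaled$interactions$duration_s <- scaled$interactions$duration_s * 3
  net3 <- suppressWarnings(
    simple_ratio_index(count_interaction_durations(scaled, "affiliative")))
  expect_equal(net3$w, net1$w, tolerance = 1e-12)
})

test_that("networks round-trip through GraphML, edge list and matrix", {
  g <- small_synth(seed = 3)
  net <- suppressWarnings(
    simple_ratio_index(count_nearest_neighbour(g$dataset)))
  dir <- withr::local_tempdir()

  p1 <- file.path(dir, "net.graphml")
  write_network(net, p1)
  back <- read_network(p1)
  expect_equal(back$w[net$ids, net$ids], net$w, tolerance = 1e-12)
  expect_equal(back$layer, net$layer)

  p2 <- file.path(dir, "net.edges")
  write_network(net, p2, format = "edgelist")
  back2 <- read_network(p2, format = "edgelist", ids = net$ids)
  expect_equal(back2$w, net$w)

  p3 <- file.path(dir, "net.csv")
  write_network(net, p3, format = "matrix")
  back3 <- read_network(p3, format = "matrix")
  expect_equal(back3$w, net$w)

  # empty network round trips
  empty <- wnet(matrix(0, 3, 3), ids = c("A", "B", "C"))
  write_network(empty, p1)
  expect_equal(read_network(p1)$w, empty$w)

  # a known 3-node network serializes to the hand-written edge list
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- 0.25
  w["B", "C"] <- 0.5
  write_network(wnet(w), p2, format = "edgelist")
  got <- read.csv(p2, stringsAsFactors = FALSE)
  expect_equal(got$source, c("A", "B"))
  expect_equal(got$target, c("B", "C"))
  expect_equal(as.numeric(got$weight), c(0.25, 0.5))

  expect_error(read_network(file.path(dir, "nothing.graphml")),
               class = "focalsna_parse_error")
})
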