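# Fixtures built in code, shared across test files.

# A tiny hand-written dataset: 3 bats, 2 focals, scans and interactions
# with known counts.
tiny_dataset <- function() {
  individuals <- data.frame(
    id = c("ABC", "DEF", "GHI"),
    sex = c("female", "male", "female"),
    birth_date = c("2010-01-01", "2015-06-15", "2012-03-01"),
    stringsAsFactors = FALSE)
  focals <- data.frame(
    focal_id = c("ABC", "DEF"),
    date = c("2019-06-01", "2019-06-01"),
    duration_s = c(180, 120),
    stringsAsFactors = FALSE)
  scans <- data.frame(
    focal_id = c("ABC", "ABC", "ABC", "DEF", "DEF"),
    timestamp = c("2019-06-01 09:00:00", "2019-06-01 09:01:00",
                  "2019-06-01 09:02:00", "2019-06-01 10:00:00",
                  "2019-06-01 10:01:00"),
    neighbour_ids = c("DEF", "DEF;GHI", "GHI", "ABC", "GHI"),
    stringsAsFactors = FALSE)
  interactions <- data.frame(
    focal_id = c("ABC", "ABC", "DEF"),
    timestamp = c("2019-06-01 09:00:30", "2019-06-01 09:02:10",
                  "2019-06-01 10:00:40"),
    actor_id = c("ABC", "GHI", "DEF"),
    receiver_id = c("DEF", "ABC", "GHI"),
    category = c("affiliative", "aggressive", "aggressive"),
    duration_s = c(30, 12, 7),
    stringsAsFactors = FALSE)
  obs_dataset(individuals, focals, scans, interactions,
              period_label = "tiny")
}

# Small random dataset through the public generator.
small_synth <- function(seed = 101, n = 8, days = 5, fpd = 6, ...) {
  generate_dataset(synthetic_spec(
    n_individuals = n, n_female = ceiling(n / 2), n_days = days,
    focals_per_day = fpd, seed = seed, ...))
}

# Brute-force recount of nearest-neighbour X and per-focal scan totals,
# row by row over the scan table (independent of the package's tallying).
brute_scan_counts <- function(ds) {
  ids <- ds$individuals$id
  n <- length(ids)
  X <- matrix(0, n, n, dimnames = list(ids, ids))
  S <- setNames(numeric(n), ids)
  for (i in seq_len(nrow(ds$scans))) {
    f <- ds$scans$focal_id[i]
    nbs <- strsplit(ds$scans$neighbour_ids[i], ";", fixed = TRUE)[[1]]
    S[f] <- S[f] + 1
    for (b in unique(nbs)) X[f, b] <- X[f, b] + 1
  }
  list(X = X, S = S)
}

# Brute-force recount of category interaction seconds (focal as actor).
brute_duration_counts <- function(ds, category) {
  ids <- ds$individuals$id
  n <- length(ids)
  X <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(ds$interactions))) {
    ev <- ds$interactions[i, ]
    if (ev$category != category) next
    if (ev$focal_id != ev$actor_id) next
    X[ev$actor_id, ev$receiver_id] <-
      X[ev$actor_id, ev$receiver_id] + ev$duration_s
  }
  X
}

# Brute-force SRI from brute-force counts: for each ordered pair assemble
# X, Y_A, Y_B, Y_AB directly from their definitions.
brute_sri <- function(ds) {
  bc <- brute_scan_counts(ds)
  ids <- ds$individuals$id
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in ids) for (b in ids) {
    if (a == b) next
    X <- bc$X[a, b]
    Y_A <- bc$S[a] - bc$X[a, b]   # A focal, B not its neighbour
    Y_B <- bc$S[b] - bc$X[b, a]   # B focal, A not its neighbour
    Y_AB <- 0
    den <- Y_AB + Y_A + Y_B + X
    W[a, b] <- if (den > 0) X / den else 0
  }
  W
}

# A weighted network straight from a matrix (for closed-form cases).
wnet <- function(w, ids = NULL, layer = "association",
                 period = "fixture") {
  if (!is.null(ids)) dimnames(w) <- list(ids, ids)
  weighted_network(w, layer = layer, period_label = period)
}

# Dijkstra shortest-path distances by hand (lengths = 1/weight).
brute_distances <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    done <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which(!done & dist == min(dist[!done]))[1]
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (v in seq_len(n)) {
        if (is.finite(len[u, v]) && dist[u] + len[u, v] < dist[v])
          dist[v] <- dist[u] + len[u, v]
      }
    }
    D[s, ] <- dist
  }
  D
}

# Brute-force betweenness by enumerating all shortest paths between every
# ordered pair (fractional counting), on the symmetrized network.
brute_betweenness <- function(w) {
  ws <- w + t(w)
  n <- nrow(ws)
  len <- ifelse(ws > 0, 1 / ws, Inf)
  # all simple paths between s and t via DFS
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path, node) {
      if (node == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible(NULL))
      }
      for (v in seq_len(n)) {
        if (is.finite(len[node, v]) && !(v %in% path))
          walk(c(path, v), v)
      }
    }
    walk(s, s)
    paths
  }
  B <- rep(0, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    paths <- all_paths(s, t)
    if (!length(paths)) next
    plen <- vapply(paths, function(p)
      sum(len[cbind(p[-length(p)], p[-1])]), numeric(1))
    shortest <- paths[abs(plen - min(plen)) < 1e-12]
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      B[inner] <- B[inner] + 1 / length(shortest)
    }
  }
  B
}
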