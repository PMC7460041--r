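#' Specification for a synthetic focal-sampling study
#'
#' Describes a simulated captive colony observed by focal sampling with
#' per-minute nearest-neighbour scans and timed dyadic interactions, with
#' planted social structure: per-layer latent relationship classes (a
#' binomial-mixture ground truth), an attribute-similarity assortment bias,
#' and a latent dominance order driving the direction of aggressive events.
#' The defaults emulate a colony observed over one summer season: 44
#' individuals (24 female, 20 male), 35 observation days with 18 ten-minute
#' focals per day and one nearest-neighbour scan per minute.
#'
#' @param n_individuals colony size.
#' @param n_female number of females (the rest are male).
#' @param birth_range character/Date length-2: uniform birth-date window.
#' @param start_date first observation day (ages are computed here).
#' @param n_days number of observation days.
#' @param focals_per_day distinct individuals focal-sampled per day.
#' @param focal_minutes focal duration in minutes.
#' @param scans_per_minute nearest-neighbour scans per minute.
#' @param tie_prob probability a scan records two equidistant neighbours.
#' @param mixtures per-layer ground truth: named list
#'   (`association`, `affiliation`, `aggression`) of `list(q, p)` class
#'   frequencies and association probabilities.
#' @param assort_variable node attribute biasing class placement (`"age"`,
#'   `"none"`).
#' @param assort_strength weight of standardized attribute similarity
#'   (relative to unit Gaussian noise) when ranking a focal's dyads for
#'   class placement; 0 gives a uniformly random allocation.
#' @param affiliative_rate,aggressive_rate interaction events per focal
#'   minute.
#' @param affiliative_mean_s,aggressive_mean_s mean bout duration
#'   (geometric, integer seconds >= 1).
#' @param win_bias probability the higher-ranked member of a dyad is the
#'   actor (winner) of an aggressive event.
#' @param period_label label stamped on the generated dataset.
#' @param seed RNG seed (mandatory: generation is fully deterministic).
#' @param individuals optional pre-built individuals table (id, sex,
#'   birth_date) overriding `n_individuals`/`n_female`/`birth_range`; used
#'   to carry a colony into a second collection period.
#' @param latent optional latent structure from a previous period's ground
#'   truth (`$classes`, `$dominance_rank`), reused for the dyads whose both
#'   members persist.
#' @return a validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_individuals = 44,
                           n_female = 24,
                           birth_range = c("1995-06-01", "2017-06-01"),
                           start_date = "2019-06-01",
                           n_days = 35,
                           focals_per_day = 18,
                           focal_minutes = 10,
                           scans_per_minute = 1,
                           tie_prob = 0.05,
                           mixtures = list(
                             association = list(q = c(0.80, 0.15, 0.05),
                                                p = c(0.005, 0.05, 0.30)),
                             affiliation = list(q = c(0.80, 0.15, 0.05),
                                                p = c(0.01, 0.08, 0.30)),
                             aggression  = list(q = c(0.90, 0.07, 0.03),
                                                p = c(0.005, 0.05, 0.20))),
                           assort_variable = "age",
                           assort_strength = 1,
                           affiliative_rate = 0.2,
                           affiliative_mean_s = 30,
                           aggressive_rate = 0.1,
                           aggressive_mean_s = 10,
                           win_bias = 0.9,
                           period_label = "Summer2019",
                           seed,
                           individuals = NULL,
                           latent = NULL) {
  if (missing(seed) || is.null(seed))
    fsna_stop("a seed is mandatory for synthetic generation",
              "focalsna_invalid_value")
  spec <- structure(as.list(environment()), class = "synthetic_spec")
  for (l in names(spec$mixtures)) {
    mx <- spec$mixtures[[l]]
    if (abs(sum(mx$q) - 1) > 1e-8)
      fsna_stop(sprintf("mixture q for layer '%s' must sum to 1", l),
                "focalsna_invalid_value")
    if (length(mx$q) != length(mx$p) || any(mx$p < 0) || any(mx$p > 1))
      fsna_stop(sprintf("invalid mixture for layer '%s'", l),
                "focalsna_invalid_value")
  }
  if (affiliative_rate < 0 || aggressive_rate < 0 ||
      affiliative_mean_s < 1 || aggressive_mean_s < 1)
    fsna_stop("interaction rates must be >= 0 and mean durations >= 1 s",
              "focalsna_invalid_value")
  # expected interaction seconds per focal minute cannot exceed the minute
  load_s <- affiliative_rate * affiliative_mean_s +
    aggressive_rate * aggressive_mean_s
  if (load_s > 60)
    fsna_stop(sprintf(
      "infeasible spec: %.1f expected interaction seconds per focal minute",
      load_s), "focalsna_invalid_value")
  if (!is.null(individuals)) {
    spec$n_individuals <- nrow(individuals)
    spec$n_female <- sum(individuals$sex == "female")
  }
  if (spec$focals_per_day > spec$n_individuals)
    fsna_stop("focals_per_day cannot exceed n_individuals (one focal per individual per day)",
              "focalsna_invalid_value")
  if (spec$tie_prob < 0 || spec$tie_prob > 1)
    fsna_stop("tie_prob must be in [0, 1]", "focalsna_invalid_value")
  spec
}

# Deterministic pool of distinct three-letter codes.
make_ids <- function(n) {
  stopifnot(n <= 26^2)
  first <- LETTERS[(seq_len(n) - 1) %/% 26 + 1]
  second <- LETTERS[(seq_len(n) - 1) %% 26 + 1]
  paste0(first, second, "X")
}

#' Generate a synthetic focal-sampling dataset with known ground truth
#'
#' Individuals are drawn per `spec`; each ordered dyad receives, per
#' layer, a latent class giving a dyadic affinity `p_k`. Classes are
#' allocated within each focal's row in the mixture proportions `q`
#' (largest remainder) and placed preferentially on attribute-similar
#' dyads (score = `assort_strength` x standardized similarity + Gaussian
#' noise), which plants assortment while keeping realized association
#' probabilities in exactly K bands. Nearest neighbours are sampled per
#' minute with probability proportional to affinity (with probability
#' `tie_prob` a second equidistant neighbour is recorded in the same
#' scan). Interaction bouts arrive as Poisson counts
#' per focal with geometric integer durations; affiliative events run focal
#' to partner, while the actor of an aggressive event is the higher-ranked
#' member with probability `win_bias` under the planted dominance order.
#' One focal per individual per day; scheduling is random. Fully
#' deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (an [obs_dataset()]) and `truth` (class
#'   `ground_truth`: per-layer dyad class matrices, affinity matrices, the
#'   dominance rank, the attribute table, and the generating parameters).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_dataset_(spec))
}

generate_dataset_ <- function(spec) {
  n <- spec$n_individuals
  start <- as.Date(spec$start_date)
  if (!is.null(spec$individuals)) {
    ind <- spec$individuals
    ind$birth_date <- as.Date(ind$birth_date)
  } else {
    ids <- make_ids(n)
    sex <- sample(c(rep("female", spec$n_female),
                    rep("male", n - spec$n_female)))
    births <- as.Date(spec$birth_range[1]) +
      round(stats::runif(n) *
              as.numeric(diff(as.Date(spec$birth_range))))
    ind <- data.frame(id = ids, sex = sex, birth_date = births,
                      stringsAsFactors = FALSE)
  }
  ids <- ind$id
  age <- age_at(ind$birth_date, start)

  # latent per-layer dyad classes. Classes are allocated within each
  # focal's row in (near-exact) proportions q, so every individual's total
  # neighbour-choice propensity is the same and the realized per-scan
  # association probabilities stay in exactly K bands. Assortment is
  # planted by *placement*: within a row, higher-affinity classes go
  # preferentially to dyads whose partner is similar on the assortment
  # variable (score = strength x standardized similarity + Gaussian
  # noise); strength 0 reduces to a uniformly random allocation.
  sim_std <- matrix(0, n, n)
  if (!identical(spec$assort_variable, "none") &&
      spec$assort_strength > 0) {
    v <- switch(spec$assort_variable, age = age,
                fsna_stop("unsupported assort_variable",
                          "focalsna_invalid_value"))
    sdv <- stats::sd(v)
    if (sdv > 0) sim_std <- -abs(outer(v, v, "-")) / sdv
  }
  alloc_counts <- function(q, m) {
    base <- floor(q * m)
    rem <- q * m - base
    extra <- order(rem, decreasing = TRUE)[seq_len(m - sum(base))]
    base[extra] <- base[extra] + 1
    base
  }
  layers <- names(spec$mixtures)
  classes <- list()
  affinity <- list()
  for (l in layers) {
    mx <- spec$mixtures[[l]]
    K <- length(mx$q)
    nk <- alloc_counts(mx$q, n - 1)
    cl <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      score <- spec$assort_strength * sim_std[i, others] +
        stats::rnorm(n - 1)
      # class K (largest p) on the best-scoring dyads, then K-1, ...
      cl[i, others[order(score, decreasing = TRUE)]] <-
        rep.int(seq(K, 1), nk[seq(K, 1)])
    }
    if (!is.null(spec$latent) && !is.null(spec$latent$classes[[l]])) {
      old <- spec$latent$classes[[l]]
      keep <- intersect(rownames(old), ids)
      cl[keep, keep] <- old[keep, keep]
    }
    af <- matrix(0, n, n, dimnames = list(ids, ids))
    af[!is.na(cl)] <- mx$p[cl[!is.na(cl)]]
    classes[[l]] <- cl
    affinity[[l]] <- af
  }
  choice <- lapply(affinity, function(af) {
    pr <- af
    # guard: any focal must have at least one possible partner
    pr[pr <= 0] <- 1e-12
    diag(pr) <- 0
    pr
  })

  # planted dominance order: rank 1 = most dominant
  dominance_rank <- if (!is.null(spec$latent) &&
                        !is.null(spec$latent$dominance_rank)) {
    old <- spec$latent$dominance_rank
    keep <- intersect(names(old), ids)
    newcomers <- setdiff(ids, keep)
    # persisting individuals keep their relative order; newcomers are
    # inserted at random positions
    pool <- c(stats::setNames(rank(old[keep]), keep),
              stats::setNames(stats::runif(length(newcomers), 0.5,
                                           length(keep) + 0.5),
                              newcomers))
    stats::setNames(rank(pool[ids]), ids)
  } else {
    stats::setNames(sample.int(n), ids)
  }

  # focal schedule: one focal per individual per day
  focal_rows <- list()
  scan_rows <- list()
  int_rows <- list()
  n_scans_per_focal <- spec$focal_minutes * spec$scans_per_minute
  for (day in seq_len(spec$n_days)) {
    date <- start + day - 1
    todays <- sample(ids, spec$focals_per_day)
    for (fi in seq_along(todays)) {
      f <- todays[fi]
      f_idx <- match(f, ids)
      t0 <- as.POSIXct(paste(date, "09:00:00"), tz = "UTC") +
        (fi - 1) * spec$focal_minutes * 60
      focal_rows[[length(focal_rows) + 1]] <-
        data.frame(focal_id = f, date = date,
                   duration_s = spec$focal_minutes * 60,
                   stringsAsFactors = FALSE)
      # nearest-neighbour scans
      pr <- choice$association[f_idx, ]
      nb1 <- sample(ids, n_scans_per_focal, replace = TRUE, prob = pr)
      tie <- stats::runif(n_scans_per_focal) < spec$tie_prob
      nbs <- vapply(seq_len(n_scans_per_focal), function(s) {
        if (!tie[s]) return(nb1[s])
        pr2 <- pr
        pr2[match(nb1[s], ids)] <- 0
        paste(c(nb1[s], sample(ids, 1, prob = pr2)), collapse = ";")
      }, character(1))
      scan_rows[[length(scan_rows) + 1]] <-
        data.frame(focal_id = f,
                   timestamp = format(t0 + (seq_len(n_scans_per_focal) - 1) *
                                        60 / spec$scans_per_minute,
                                      "%Y-%m-%d %H:%M:%S"),
                   neighbour_ids = nbs, stringsAsFactors = FALSE)
      # interaction bouts
      for (cat in c("affiliative", "aggressive")) {
        rate <- if (cat == "affiliative") spec$affiliative_rate else
          spec$aggressive_rate
        mean_s <- if (cat == "affiliative") spec$affiliative_mean_s else
          spec$aggressive_mean_s
        layer <- if (cat == "affiliative") "affiliation" else "aggression"
        n_ev <- min(stats::rpois(1, rate * spec$focal_minutes),
                    spec$focal_minutes * 60)
        if (n_ev == 0) next
        partners <- sample(ids, n_ev, replace = TRUE,
                           prob = choice[[layer]][f_idx, ])
        dur <- stats::rgeom(n_ev, 1 / mean_s) + 1
        if (cat == "affiliative") {
          actor <- rep(f, n_ev)
          receiver <- partners
        } else {
          higher <- ifelse(dominance_rank[f] < dominance_rank[partners],
                           f, partners)
          lower <- ifelse(higher == f, partners, f)
          win <- stats::runif(n_ev) < spec$win_bias
          actor <- ifelse(win, higher, lower)
          receiver <- ifelse(win, lower, higher)
        }
        int_rows[[length(int_rows) + 1]] <-
          data.frame(focal_id = f,
                     timestamp = format(t0 + sort(sample.int(
                       spec$focal_minutes * 60, n_ev)), "%Y-%m-%d %H:%M:%S"),
                     actor_id = actor, receiver_id = receiver,
                     category = cat, duration_s = dur,
                     stringsAsFactors = FALSE)
      }
    }
  }
  empty_int <- data.frame(focal_id = character(0), timestamp = character(0),
                          actor_id = character(0),
                          receiver_id = character(0),
                          category = character(0), duration_s = numeric(0),
                          stringsAsFactors = FALSE)
  ds <- obs_dataset(
    ind,
    do.call(rbind, focal_rows),
    do.call(rbind, scan_rows),
    if (length(int_rows)) do.call(rbind, int_rows) else empty_int,
    period_label = spec$period_label)
  truth <- structure(
    list(classes = classes, affinity = affinity,
         dominance_rank = dominance_rank,
         attributes = data.frame(id = ids, sex = ind$sex,
                                 birth_date = as.character(ind$birth_date),
                                 age = age, stringsAsFactors = FALSE),
         mixtures = spec$mixtures,
         assort_variable = spec$assort_variable,
         assort_strength = spec$assort_strength,
         win_bias = spec$win_bias,
         period_label = spec$period_label,
         seed = spec$seed),
    class = "ground_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth '%s': %d individuals; layers: %s; assortment on %s (strength %g)\n",
    x$period_label, nrow(x$attributes),
    paste(names(x$classes), collapse = ", "), x$assort_variable,
    x$assort_strength))
  invisible(x)
}

#' Serialize / read ground truth
#'
#' JSON round trip of a `ground_truth` object (class matrices stored as
#' arrays with their ID ordering).
#'
#' @param truth a `ground_truth`.
#' @param path file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the
#'   reconstructed `ground_truth`.
#' @export
write_truth <- function(truth, path) {
  ser <- unclass(truth)
  ser$classes <- lapply(ser$classes, function(m)
    list(ids = rownames(m), values = as.vector(m)))
  ser$affinity <- lapply(ser$affinity, function(m)
    list(ids = rownames(m), values = as.vector(m)))
  ser$dominance_rank <- list(ids = names(truth$dominance_rank),
                             rank = as.vector(truth$dominance_rank))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  unmat <- function(s) {
    n <- length(s$ids)
    matrix(s$values, n, n, dimnames = list(s$ids, s$ids))
  }
  ser$classes <- lapply(ser$classes, unmat)
  ser$affinity <- lapply(ser$affinity, unmat)
  ser$dominance_rank <- stats::setNames(ser$dominance_rank$rank,
                                        ser$dominance_rank$ids)
  ser$mixtures <- lapply(ser$mixtures, function(m)
    list(q = as.numeric(m$q), p = as.numeric(m$p)))
  structure(ser, class = "ground_truth")
}

#' Two-period synthetic colony
#'
#' Convenience wrapper emulating a two-season study: a summer period (44
#' individuals, 24 female, 35 days) and a shorter spring period (50
#' individuals, 28 female, 20 days with 19 focals/day) in which 42 of the
#' original individuals persist (one female and one male leave, five
#' females and three males join). Latent dyad classes and the dominance
#' order are carried over for persisting individuals so that social
#' structure — and hence node metrics — are correlated across periods.
#'
#' @param seed RNG seed controlling both periods.
#' @param ... overrides passed to both [synthetic_spec()]s.
#' @return list with `period1`, `period2`, each a
#'   `list(dataset, truth)`.
#' @export
generate_colony <- function(seed, ...) {
  spec1 <- synthetic_spec(seed = seed, ...)
  g1 <- generate_dataset(spec1)
  ind1 <- g1$dataset$individuals
  with_seed(seed + 1L, {
    leave <- c(sample(ind1$id[ind1$sex == "female"], 1),
               sample(ind1$id[ind1$sex == "male"], 1))
    stay <- ind1[!(ind1$id %in% leave), ]
    pool <- setdiff(make_ids(60), ind1$id)
    joiners <- data.frame(
      id = pool[seq_len(8)],
      sex = c(rep("female", 5), rep("male", 3)),
      birth_date = as.Date("2019-04-01") - round(stats::runif(8, 300, 3000)),
      stringsAsFactors = FALSE)
    ind2 <- rbind(stay, joiners)
    ind2 <- ind2[order(ind2$id), ]
  })
  args2 <- utils::modifyList(
    list(seed = seed + 2L, start_date = "2020-02-01", n_days = 20,
         focals_per_day = 19, period_label = "Spring2020"),
    list(...))
  args2$individuals <- ind2
  args2$latent <- list(classes = g1$truth$classes,
                       dominance_rank = g1$truth$dominance_rank)
  args2$period_label <- "Spring2020"
  spec2 <- do.call(synthetic_spec, args2)
  g2 <- generate_dataset(spec2)
  list(period1 = g1, period2 = g2)
}
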