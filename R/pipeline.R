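#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Input is either a synthetic-colony request (`synthetic = TRUE`, governed
#' by `seed` and `synthetic_args`) or paths to directories of observation
#' CSV files (see [read_dataset()]), one per collection period.
#'
#' @param outdir output directory for artifacts and reports.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it and logs it.
#' @param synthetic generate the data with [generate_colony()]?
#' @param synthetic_args named list of overrides for [synthetic_spec()].
#' @param input_dirs named list of input directories (`period1`,
#'   optionally `period2`) when `synthetic = FALSE`.
#' @param layers network layers to build.
#' @param Kmax largest mixture size tried.
#' @param n_perm permutations for every permutation test (>= 100).
#' @param ds_variant David's score dyadic proportion variant.
#' @param include_received attribute the focal's time as receiver to
#'   interaction counts (see [count_interaction_durations()]).
#' @param closeness_mode `"out"` or `"in"` closeness.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed, synthetic = TRUE,
                            synthetic_args = list(), input_dirs = NULL,
                            layers = c("association", "affiliation",
                                       "aggression"),
                            Kmax = 6, n_perm = 1000,
                            ds_variant = "Dij", include_received = FALSE,
                            closeness_mode = "out") {
  if (missing(seed) || is.null(seed))
    fsna_stop("a seed is mandatory", "focalsna_invalid_value")
  if (n_perm < 100)
    fsna_stop("n_perm must be >= 100", "focalsna_invalid_value")
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, synthetic_args = synthetic_args,
                 input_dirs = input_dirs, layers = layers, Kmax = Kmax,
                 n_perm = n_perm, ds_variant = ds_variant,
                 include_received = include_received,
                 closeness_mode = closeness_mode),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; keys as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (tolower(tools::file_ext(path)) %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      fsna_stop("the 'yaml' package is needed for YAML configs",
                "focalsna_invalid_value")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, cfg)
}

plog <- function(state, fmt, ...) {
  line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
  message(line)
  cat(line, "\n", file = state$logfile, append = TRUE, sep = "")
}

stage_seed <- function(config, offset) config$seed + offset

#' Run the analysis pipeline
#'
#' Orchestrates the full workflow over one or two collection periods:
#' `simulate` (or ingest) the observation data, `build` the
#' Simple-Ratio-Index networks, `complexity` (binomial mixture + ICL +
#' Shannon H per layer), `assort` (sex/age/dominance assortment with
#' permutation tests), `mrqap` (affiliation and aggression regressed on
#' association), `dominance` (David's scores, linearity, age/sex model),
#' `roles` (node metrics + class-membership models), `stability` (QAP
#' across periods, two-period runs only), or `all` in dependency order.
#' Each stage writes CSV (and GraphML) artifacts under `config$outdir` and
#' appends to `pipeline_log.txt`; stages run individually read their
#' upstream artifacts from the same directory and fail naming the missing
#' stage.
#'
#' @param config a [pipeline_config()] (or path to a YAML/JSON config).
#' @param stages character vector of stage names, or `"all"`.
#' @return invisibly, a list with the in-memory results of the stages run.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "build", "complexity", "assort", "mrqap",
                  "dominance", "roles", "stability")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    fsna_stop(paste("unknown stage(s):", paste(bad, collapse = ", ")),
              "focalsna_invalid_value")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$outdir, "reports"), showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$logfile <- file.path(config$outdir, "pipeline_log.txt")
  plog(state, "pipeline start: seed=%d n_perm=%d Kmax=%d stages=%s",
       config$seed, config$n_perm, config$Kmax,
       paste(stages, collapse = ","))
  for (st in stages)
    switch(st,
           simulate = stage_simulate(config, state),
           build = stage_build(config, state),
           complexity = stage_complexity(config, state),
           assort = stage_assort(config, state),
           mrqap = stage_mrqap(config, state),
           dominance = stage_dominance(config, state),
           roles = stage_roles(config, state),
           stability = stage_stability(config, state))
  plog(state, "pipeline done")
  invisible(as.list(state))
}

need_datasets <- function(config, state) {
  if (!is.null(state$datasets)) return(state$datasets)
  dirs <- Filter(function(d) dir.exists(d),
                 list(period1 = file.path(config$outdir, "data", "period1"),
                      period2 = file.path(config$outdir, "data", "period2")))
  if (!config$synthetic && !is.null(config$input_dirs))
    dirs <- config$input_dirs
  if (!length(dirs))
    fsna_stop("no observation data found: run the 'simulate' stage first",
              "focalsna_missing_stage")
  state$datasets <- lapply(names(dirs), function(p)
    read_dataset(file.path(dirs[[p]], "individuals.csv"),
                 file.path(dirs[[p]], "focals.csv"),
                 file.path(dirs[[p]], "scans.csv"),
                 file.path(dirs[[p]], "interactions.csv"),
                 period_label = p))
  names(state$datasets) <- names(dirs)
  state$datasets
}

stage_simulate <- function(config, state) {
  if (!config$synthetic) {
    if (is.null(config$input_dirs))
      fsna_stop("synthetic = FALSE requires input_dirs",
                "focalsna_invalid_value")
    state$datasets <- NULL
    need_datasets(config, state)
    plog(state, "simulate: ingested %d period(s) from input_dirs",
         length(state$datasets))
    return(invisible(NULL))
  }
  seed <- stage_seed(config, 0L)
  plog(state, "simulate: generating two-period synthetic colony, seed=%d",
       seed)
  col <- do.call(generate_colony, c(list(seed = seed),
                                    config$synthetic_args))
  state$datasets <- list(period1 = col$period1$dataset,
                         period2 = col$period2$dataset)
  state$truths <- list(period1 = col$period1$truth,
                       period2 = col$period2$truth)
  for (p in names(state$datasets)) {
    write_dataset(state$datasets[[p]],
                  file.path(config$outdir, "data", p))
    write_truth(state$truths[[p]],
                file.path(config$outdir, paste0("truth_", p, ".json")))
  }
  plog(state, "simulate: wrote data and ground truth for %d periods",
       length(state$datasets))
}

build_one <- function(config, ds, layer) {
  counts <- switch(layer,
    association = count_nearest_neighbour(ds),
    affiliation = count_interaction_durations(
      ds, "affiliative", include_received = config$include_received),
    aggression = count_interaction_durations(
      ds, "aggressive", include_received = config$include_received))
  list(counts = counts, net = suppressWarnings(simple_ratio_index(counts)))
}

need_networks <- function(config, state) {
  if (!is.null(state$networks)) return(state$networks)
  # rebuild from matrix dumps if a previous 'build' run left them
  state$networks <- list()
  state$counts <- list()
  found <- FALSE
  for (p in c("period1", "period2")) {
    f <- file.path(config$outdir, "networks",
                   paste0(p, "_", config$layers, ".csv"))
    if (all(file.exists(f))) {
      found <- TRUE
      state$networks[[p]] <- lapply(seq_along(config$layers), function(i)
        read_network(f[i], format = "matrix", layer = config$layers[i],
                     period_label = p))
      names(state$networks[[p]]) <- config$layers
    }
  }
  if (!found)
    fsna_stop("no networks found: run the 'build' stage first",
              "focalsna_missing_stage")
  state$networks
}

stage_build <- function(config, state) {
  datasets <- need_datasets(config, state)
  dir.create(file.path(config$outdir, "networks"), showWarnings = FALSE)
  state$networks <- list()
  state$counts <- list()
  for (p in names(datasets)) {
    built <- lapply(config$layers, function(l)
      build_one(config, datasets[[p]], l))
    names(built) <- config$layers
    state$counts[[p]] <- lapply(built, `[[`, "counts")
    state$networks[[p]] <- lapply(built, `[[`, "net")
    for (l in config$layers) {
      base <- file.path(config$outdir, "networks", paste0(p, "_", l))
      write_network(state$networks[[p]][[l]], paste0(base, ".graphml"))
      write_network(state$networks[[p]][[l]], paste0(base, ".edges"),
                    format = "edgelist")
      write_network(state$networks[[p]][[l]], paste0(base, ".csv"),
                    format = "matrix")
    }
    plog(state, "build: period %s -> %d SRI networks (%s)", p,
         length(config$layers), paste(config$layers, collapse = ", "))
  }
}

need_counts <- function(config, state) {
  if (is.null(state$counts) || !length(state$counts)) {
    datasets <- need_datasets(config, state)
    state$counts <- lapply(datasets, function(ds) {
      out <- lapply(config$layers, function(l)
        build_one(config, ds, l)$counts)
      names(out) <- config$layers
      out
    })
  }
  state$counts
}

stage_complexity <- function(config, state) {
  counts <- need_counts(config, state)
  seed0 <- stage_seed(config, 100L)
  reports <- list()
  for (pi in seq_along(counts)) {
    p <- names(counts)[pi]
    sels <- list()
    for (li in seq_along(config$layers)) {
      l <- config$layers[li]
      sm <- dyad_samples(counts[[p]][[l]])
      seed <- seed0 + 10L * pi + li
      sels[[l]] <- select_binmix(sm, Kmax = config$Kmax, seed = seed)
      plog(state,
           "complexity: %s/%s n=%d seed=%d -> K=%d H=%.4f", p, l,
           nrow(sm), seed, sels[[l]]$selected_K, sels[[l]]$H)
    }
    state$complexity[[p]] <- sels
    reports[[p]] <- complexity_report(sels, period_label = p)
  }
  utils::write.csv(do.call(rbind, lapply(reports, `[[`, "classes")),
                   file.path(config$outdir, "reports", "complexity.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(reports, `[[`, "criteria")),
                   file.path(config$outdir, "reports",
                             "complexity_criteria.csv"),
                   row.names = FALSE)
}

# David's scores per period, computed from the aggression event data.
need_ds_scores <- function(config, state) {
  if (!is.null(state$ds_scores)) return(state$ds_scores)
  datasets <- need_datasets(config, state)
  state$ds_scores <- lapply(datasets, function(ds)
    davids_score(win_loss_from_aggression(ds), variant = config$ds_variant))
  state$ds_scores
}

node_attributes <- function(ds, ds_scores) {
  ref <- min(ds$focals$date)
  data.frame(id = ds$individuals$id,
             sex = ds$individuals$sex,
             age = age_at(ds$individuals$birth_date, ref),
             dominance = as.numeric(ds_scores[ds$individuals$id]),
             stringsAsFactors = FALSE)
}

stage_assort <- function(config, state) {
  nets <- need_networks(config, state)
  datasets <- need_datasets(config, state)
  scores <- need_ds_scores(config, state)
  seed0 <- stage_seed(config, 200L)
  rows <- list()
  for (pi in seq_along(nets)) {
    p <- names(nets)[pi]
    att <- node_attributes(datasets[[p]], scores[[p]])
    for (li in seq_along(config$layers)) {
      l <- config$layers[li]
      net <- nets[[p]][[l]]
      vars <- list(sex = list(v = att$sex, kind = "discrete"),
                   age = list(v = att$age, kind = "continuous"),
                   dominance = list(v = att$dominance,
                                    kind = "continuous"))
      for (vi in seq_along(vars)) {
        seed <- seed0 + 100L * pi + 10L * li + vi
        res <- tryCatch(
          assortment_test(net, vars[[vi]]$v, kind = vars[[vi]]$kind,
                          variable = names(vars)[vi],
                          n_perm = config$n_perm, seed = seed),
          focalsna_degenerate = function(e) e)
        if (inherits(res, "condition")) {
          plog(state, "assort: %s/%s by %s undefined (%s)", p, l,
               names(vars)[vi], conditionMessage(res))
          next
        }
        state$assortment[[p]][[l]][[names(vars)[vi]]] <- res
        rows[[length(rows) + 1]] <-
          data.frame(network = l, period = p, variable = names(vars)[vi],
                     r = res$r, p_value = res$p_value,
                     n_perm = config$n_perm, seed = seed,
                     stringsAsFactors = FALSE)
        plog(state, "assort: %s/%s by %s seed=%d r=%.4f p=%.4g", p, l,
             names(vars)[vi], seed, res$r, res$p_value)
      }
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(config$outdir, "reports", "assortment.csv"),
                   row.names = FALSE)
}

stage_mrqap <- function(config, state) {
  nets <- need_networks(config, state)
  seed0 <- stage_seed(config, 300L)
  rows <- list()
  for (pi in seq_along(nets)) {
    p <- names(nets)[pi]
    if (!"association" %in% names(nets[[p]])) next
    for (resp in intersect(c("affiliation", "aggression"),
                           names(nets[[p]]))) {
      seed <- seed0 + 10L * pi + match(resp, config$layers)
      fit <- mrqap(nets[[p]][[resp]],
                   list(association = nets[[p]]$association),
                   n_perm = config$n_perm, seed = seed)
      state$mrqap[[p]][[resp]] <- fit
      rows[[length(rows) + 1]] <-
        cbind(data.frame(period = p, response = resp,
                         stringsAsFactors = FALSE),
              fit$coefficients,
              data.frame(r_squared = fit$r_squared,
                         n_perm = config$n_perm, seed = seed))
      plog(state, "mrqap: %s %s ~ association seed=%d t=%.3f p=%.4g", p,
           resp, seed, fit$coefficients$t[1], fit$coefficients$p_perm[1])
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(config$outdir, "reports", "mrqap.csv"),
                   row.names = FALSE)
}

stage_dominance <- function(config, state) {
  datasets <- need_datasets(config, state)
  scores <- need_ds_scores(config, state)
  seed0 <- stage_seed(config, 400L)
  score_rows <- list()
  test_rows <- list()
  for (pi in seq_along(datasets)) {
    p <- names(datasets)[pi]
    ds <- datasets[[p]]
    W <- win_loss_from_aggression(ds)
    seed <- seed0 + pi
    lin <- linearity_h(W, n_perm = config$n_perm, seed = seed)
    model <- dominance_model(scores[[p]], ds$individuals,
                             reference_date = min(ds$focals$date))
    state$dominance[[p]] <- list(scores = scores[[p]], linearity = lin,
                                 model = model)
    score_rows[[p]] <- data.frame(
      period = p, id = names(scores[[p]]),
      DS = as.numeric(scores[[p]]),
      rank = rank(-as.numeric(scores[[p]])),
      variant = config$ds_variant, stringsAsFactors = FALSE)
    age_co <- if (!is.null(model$coefficients) &&
                  "age" %in% model$coefficients$term)
      model$coefficients[model$coefficients$term == "age", ] else NULL
    test_rows[[p]] <- data.frame(
      period = p, h_prime = lin$h_prime, h_landau = lin$h_landau,
      linearity_p = lin$p_value, n_perm = config$n_perm, seed = seed,
      best_model = model$selected,
      age_effect = if (is.null(age_co)) NA else age_co$estimate,
      age_se = if (is.null(age_co)) NA else age_co$se,
      shapiro_W = model$shapiro["W"], stringsAsFactors = FALSE)
    plog(state,
         "dominance: %s h'=%.4f p=%.4g best_model=%s seed=%d", p,
         lin$h_prime, lin$p_value, model$selected, seed)
  }
  utils::write.csv(do.call(rbind, score_rows),
                   file.path(config$outdir, "reports", "dominance.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, test_rows),
                   file.path(config$outdir, "reports",
                             "dominance_tests.csv"),
                   row.names = FALSE)
}

need_metrics <- function(config, state) {
  if (!is.null(state$metrics)) return(state$metrics)
  nets <- need_networks(config, state)
  state$metrics <- lapply(nets, function(per)
    lapply(per, node_metric_table,
           closeness_mode = config$closeness_mode))
  state$metrics
}

stage_roles <- function(config, state) {
  datasets <- need_datasets(config, state)
  scores <- need_ds_scores(config, state)
  metrics <- need_metrics(config, state)
  seed0 <- stage_seed(config, 500L)
  fits <- list()
  for (pi in seq_along(metrics)) {
    p <- names(metrics)[pi]
    att <- node_attributes(datasets[[p]], scores[[p]])
    for (li in seq_along(config$layers)) {
      l <- config$layers[li]
      seed <- seed0 + 10L * pi + li
      rm <- role_models(metrics[[p]][[l]], att, n_perm = config$n_perm,
                        seed = seed)
      state$roles[[p]][[l]] <- rm
      fits[[length(fits) + 1]] <- rm
      plog(state, "roles: %s/%s seed=%d best models: %s", p, l, seed,
           paste(vapply(rm$models, `[[`, character(1), "selected"),
                 collapse = ", "))
    }
  }
  utils::write.csv(role_report(fits),
                   file.path(config$outdir, "reports", "roles.csv"),
                   row.names = FALSE)
}

stage_stability <- function(config, state) {
  metrics <- need_metrics(config, state)
  if (length(metrics) < 2) {
    plog(state, "stability: skipped (single collection period)")
    return(invisible(NULL))
  }
  seed0 <- stage_seed(config, 600L)
  rows <- list()
  for (li in seq_along(config$layers)) {
    l <- config$layers[li]
    seed <- seed0 + li
    res <- temporal_stability(metrics[[1]][[l]], metrics[[2]][[l]],
                              n_perm = config$n_perm, seed = seed)
    state$stability[[l]] <- res
    rows[[l]] <- data.frame(layer = l, r = res$observed,
                            p_value = res$p_value, n_nodes = res$n_nodes,
                            n_perm = config$n_perm, seed = seed,
                            stringsAsFactors = FALSE)
    plog(state, "stability: %s seed=%d r=%.4f p=%.4g (%d conserved nodes)",
         l, seed, res$observed, res$p_value, res$n_nodes)
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(config$outdir, "reports", "stability.csv"),
                   row.names = FALSE)
}
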