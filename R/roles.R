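#' Node metrics: weighted degree, closeness, betweenness
#'
#' Per-individual network position summaries on an association-index
#' network. Path-based metrics treat the index weights as affinities and
#' use edge lengths `1/weight` (zero-weight edges are absent).
#'
#' * `weighted_degree()`: sum of in- and out-edge weights incident to the
#'   node (direction-agnostic).
#' * `closeness_norm()`: directed shortest-path closeness, normalized so a
#'   node reaching all others at unit distance scores 1. With `r` reachable
#'   nodes and total distance `sum d`, the score is
#'   `(r / (n - 1)) * (r / sum d)` — on a strongly connected network this
#'   is the raw closeness multiplied by `n - 1`, and nodes that cannot
#'   reach part of the network are penalised proportionally. Nodes with no
#'   outgoing (or, for `mode = "in"`, incoming) paths score 0.
#' * `betweenness_norm()`: weighted shortest-path betweenness (fractional
#'   counting over equal-length paths) on the symmetrized network (weights
#'   summed across directions), normalized as `2B / (n^2 - 3n + 2)` so a
#'   star centre scores 1 regardless of network size.
#'
#' @param net a [weighted_network()].
#' @param mode for closeness, `"out"` (default: distances from the node)
#'   or `"in"` (distances to the node).
#' @return named numeric vector over the node IDs.
#' @name node_metrics
NULL

#' @rdname node_metrics
#' @export
weighted_degree <- function(net) {
  rowSums(net$w) + colSums(net$w)
}

#' @rdname node_metrics
#' @export
closeness_norm <- function(net, mode = c("out", "in")) {
  mode <- match.arg(mode)
  n <- length(net$ids)
  g <- net_igraph(net)
  dm <- igraph::distances(g, mode = mode,
                          weights = 1 / igraph::E(g)$weight)
  diag(dm) <- Inf
  reach <- is.finite(dm)
  r <- rowSums(reach)
  totd <- rowSums(ifelse(reach, dm, 0))
  out <- ifelse(r > 0 & totd > 0, (r / (n - 1)) * (r / totd), 0)
  if (any(r == 0))
    warning(sprintf("%d node(s) reach no others; closeness set to 0",
                    sum(r == 0)), call. = FALSE)
  names(out) <- net$ids
  out
}

#' @rdname node_metrics
#' @export
betweenness_norm <- function(net) {
  n <- length(net$ids)
  if (n < 3)
    fsna_stop("betweenness normalization needs at least 3 nodes",
              "focalsna_invalid_value")
  ws <- net$w + t(net$w)
  g <- igraph::graph_from_adjacency_matrix(ws, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  B <- igraph::betweenness(g, directed = FALSE,
                           weights = 1 / igraph::E(g)$weight)
  out <- 2 * B / (n^2 - 3 * n + 2)
  names(out) <- net$ids
  out
}

#' All three node metrics as a table
#'
#' @param net a [weighted_network()].
#' @param closeness_mode passed to [closeness_norm()].
#' @return data.frame `id`, `weighted_degree`, `closeness`, `betweenness`
#'   with the network's layer and period as attributes.
#' @export
node_metric_table <- function(net, closeness_mode = "out") {
  out <- data.frame(id = net$ids,
                    weighted_degree = unname(weighted_degree(net)),
                    closeness = unname(closeness_norm(net, closeness_mode)),
                    betweenness = unname(betweenness_norm(net)),
                    stringsAsFactors = FALSE)
  attr(out, "layer") <- net$layer
  attr(out, "period_label") <- net$period_label
  out
}

role_formulas <- function() {
  preds <- c("sex", "age", "dominance")
  subsets <- unlist(lapply(0:3, function(k)
    utils::combn(preds, k, simplify = FALSE)), recursive = FALSE)
  names(subsets) <- vapply(subsets, function(s)
    if (!length(s)) "(intercept)" else paste(s, collapse = "+"),
    character(1))
  subsets
}

#' Social-role models of node metrics with permutation-null inference
#'
#' For each node metric, fits all 8 Gaussian linear models over subsets of
#' {sex, age, dominance}, selects by AIC (most parsimonious model within 2
#' dAIC of the minimum; intercept-only or a tie means `"none"`), and tests
#' the selected model's coefficients against a node-label-permutation null:
#' because the metrics are invariant under relabeling, refitting the model
#' with the metric vector dealt along each of `n_perm` random node
#' permutations reproduces exactly the distribution obtained by recomputing
#' the metrics on label-permuted networks. Two-sided p per coefficient by
#' the add-one rule.
#'
#' @param metrics a [node_metric_table()] (or data.frame with column `id`
#'   and one column per metric).
#' @param attributes data.frame with columns `id`, `sex`, `age`,
#'   `dominance` covering every node.
#' @param n_perm permutations for the coefficient null.
#' @param seed optional RNG seed.
#' @return object of class `role_models`: per metric, the AIC table, the
#'   selected factors, and a coefficient table (estimate, SE, permutation
#'   p).
#' @export
role_models <- function(metrics, attributes, n_perm = 1000, seed = NULL) {
  stopifnot(all(c("id", "sex", "age", "dominance") %in% names(attributes)))
  idx <- match(metrics$id, attributes$id)
  if (any(is.na(idx)))
    fsna_stop("attributes missing for some nodes", "focalsna_invalid_value")
  att <- data.frame(sex = factor(attributes$sex[idx],
                                 levels = c("female", "male")),
                    age = attributes$age[idx],
                    dominance = attributes$dominance[idx])
  n <- nrow(att)
  subsets <- role_formulas()
  metric_cols <- setdiff(names(metrics), "id")
  seeds <- with_seed(seed,
                     as.list(sample.int(.Machine$integer.max,
                                        length(metric_cols))))
  names(seeds) <- metric_cols
  out <- lapply(metric_cols, function(mc) {
    y <- metrics[[mc]]
    dat <- cbind(att, .y = y)
    fits <- lapply(subsets, function(s) {
      f <- stats::reformulate(if (length(s)) s else "1", response = ".y")
      stats::lm(f, data = dat)
    })
    Xfull <- stats::model.matrix(~ sex + age + dominance, dat)
    if (qr(Xfull)$rank < ncol(Xfull))
      fsna_stop("rank-deficient design: attributes are collinear",
                "focalsna_collinear")
    aic <- vapply(fits, stats::AIC, numeric(1))
    pick <- aic_select(aic, lengths(subsets))
    selected <- if (pick %in% c("none", "(intercept)")) "none" else pick
    coefs <- NULL
    if (selected != "none") {
      fit <- fits[[selected]]
      X <- stats::model.matrix(fit)
      qrX <- qr(X)
      s <- summary(fit)$coefficients
      b_obs <- stats::coef(fit)
      b_null <- with_seed(seeds[[mc]], {
        Yp <- vapply(seq_len(n_perm), function(i) y[sample.int(n)],
                     numeric(n))
        qr.coef(qrX, Yp)  # coefficients for every permuted metric at once
      })
      p_perm <- vapply(seq_along(b_obs), function(j)
        perm_pvalue(b_obs[j], b_null[j, ], "two_sided"), numeric(1))
      coefs <- data.frame(term = rownames(s), estimate = s[, 1],
                          se = s[, 2], p_perm = p_perm,
                          row.names = NULL, stringsAsFactors = FALSE)
    }
    list(metric = mc,
         aic_table = data.frame(model = names(subsets), AIC = aic,
                                dAIC = aic - min(aic),
                                stringsAsFactors = FALSE),
         selected = selected, coefficients = coefs)
  })
  names(out) <- metric_cols
  structure(list(models = out, n_perm = n_perm, seed = seed,
                 layer = attr(metrics, "layer"),
                 period_label = attr(metrics, "period_label")),
            class = "role_models")
}

#' @export
print.role_models <- function(x, ...) {
  cat(sprintf("Social-role models (layer '%s', period '%s'):\n",
              x$layer %||% "?", x$period_label %||% "?"))
  for (m in x$models) {
    cat(sprintf("  %s: best model = %s\n", m$metric, m$selected))
    if (!is.null(m$coefficients))
      print(transform(m$coefficients, estimate = signif(estimate, 4),
                      se = signif(se, 3), p_perm = signif(p_perm, 4)),
            row.names = FALSE)
  }
  invisible(x)
}

#' Flatten role-model results into a report table
#'
#' One row per metric and (for selected models) per non-intercept
#' coefficient: network, period, metric, factors, effect size, SE,
#' permutation p.
#'
#' @param rm_list list of `role_models` objects (or a single one).
#' @return data.frame.
#' @export
role_report <- function(rm_list) {
  if (inherits(rm_list, "role_models")) rm_list <- list(rm_list)
  do.call(rbind, lapply(rm_list, function(x) {
    do.call(rbind, lapply(x$models, function(m) {
      if (is.null(m$coefficients))
        return(data.frame(network = x$layer %||% NA,
                          period = x$period_label %||% NA,
                          metric = m$metric, factors = "None",
                          term = NA, estimate = NA, se = NA, p_perm = NA,
                          stringsAsFactors = FALSE))
      co <- m$coefficients[m$coefficients$term != "(Intercept)", ,
                           drop = FALSE]
      data.frame(network = x$layer %||% NA, period = x$period_label %||% NA,
                 metric = m$metric, factors = m$selected,
                 term = co$term, estimate = co$estimate, se = co$se,
                 p_perm = co$p_perm, stringsAsFactors = FALSE)
    }))
  }))
}

#' Temporal stability of social roles
#'
#' Correlates the node metrics of the individuals observed in both
#' collection periods. By default the three normalized metrics are stacked
#' into one vector per period ("stacked" mode) and compared by QAP: the
#' observed Pearson r against a null in which the node alignment between
#' periods is randomly permuted (one permutation applied to all three
#' metric blocks simultaneously). `mode = "per_metric"` runs one QAP test
#' per metric instead.
#'
#' @param metrics_t1,metrics_t2 [node_metric_table()]s from the two
#'   periods.
#' @param n_perm permutations.
#' @param seed optional RNG seed.
#' @param mode `"stacked"` or `"per_metric"`.
#' @param tail passed to the permutation p-value (default two-sided).
#' @return a `perm_test` (stacked) or named list of `perm_test`s.
#' @export
temporal_stability <- function(metrics_t1, metrics_t2, n_perm = 1000,
                               seed = NULL, mode = c("stacked",
                                                     "per_metric"),
                               tail = "two_sided") {
  mode <- match.arg(mode)
  common <- intersect(metrics_t1$id, metrics_t2$id)
  if (!length(common))
    fsna_stop("no individuals present in both periods",
              "focalsna_invalid_value")
  m1 <- metrics_t1[match(common, metrics_t1$id), , drop = FALSE]
  m2 <- metrics_t2[match(common, metrics_t2$id), , drop = FALSE]
  cols <- setdiff(intersect(names(m1), names(m2)), "id")
  nc <- length(common)
  if (mode == "per_metric") {
    seeds <- with_seed(seed, as.list(sample.int(.Machine$integer.max,
                                                length(cols))))
    out <- lapply(seq_along(cols), function(i)
      qap_correlation(stats::setNames(m1[[cols[i]]], common),
                      stats::setNames(m2[[cols[i]]], common),
                      n_perm = n_perm, seed = seeds[[i]], tail = tail))
    names(out) <- cols
    return(out)
  }
  y1 <- unlist(m1[cols], use.names = FALSE)
  y2 <- unlist(m2[cols], use.names = FALSE)
  observed <- stats::cor(y1, y2)
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(nc)
    stats::cor(y1, unlist(lapply(cols, function(cl) m2[[cl]][p]),
                          use.names = FALSE))
  }, numeric(1)))
  out <- new_perm_test("temporal stability r (stacked node metrics)",
                       observed, null_values, tail, n_perm, seed)
  out$n_nodes <- nc
  out
}
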