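#' Node-label permutations of a network
#'
#' Each permutation relabels the nodes, applying one random permutation
#' simultaneously to the rows and columns of the weight matrix (conjugation
#' by a permutation matrix). This preserves the network's topology — every
#' individual's out-strength/in-strength multiset and the multiset of edge
#' weights — while breaking any attribute-to-position association, which is
#' the null model used throughout for significance testing.
#'
#' @param net a [weighted_network()].
#' @param n_perm number of permutations.
#' @param seed optional RNG seed; the same seed yields the same sequence.
#' @return list of `n_perm` weighted networks; each carries the permutation
#'   used as attribute `"perm"`.
#' @export
node_label_permutations <- function(net, n_perm, seed = NULL) {
  stopifnot(n_perm >= 1)
  n <- length(net$ids)
  with_seed(seed, {
    perms <- rand_perms(n, n_perm)
    lapply(seq_len(n_perm), function(i) {
      p <- perms[i, ]
      w <- net$w[p, p, drop = FALSE]
      dimnames(w) <- list(net$ids, net$ids)
      out <- weighted_network(w, layer = net$layer,
                              period_label = net$period_label)
      attr(out, "perm") <- p
      out
    })
  })
}

#' Weighted assortativity for a discrete node attribute
#'
#' Directed, weighted mixing-matrix assortativity:
#' `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)` where `e_ij` is
#' the fraction of total edge weight running from class i to class j,
#' `a_i = sum_j e_ij` and `b_j = sum_i e_ij`. `r = 1` when all weight stays
#' within classes, negative when it runs between them.
#'
#' @param net a [weighted_network()].
#' @param labels class label per node (in `net$ids` order, or named).
#' @return assortativity coefficient in `[-1, 1]`.
#' @export
assortment_discrete <- function(net, labels) {
  labels <- align_attr(net, labels)
  f <- factor(labels)
  if (nlevels(f) < 2)
    fsna_stop("assortment undefined with a single class present",
              "focalsna_degenerate")
  w <- net$w
  tot <- sum(w)
  if (tot <= 0)
    fsna_stop("assortment undefined on an empty network",
              "focalsna_degenerate")
  e <- rowsum(t(rowsum(w, f)), f) / tot  # class-by-class weight fractions
  a <- rowSums(e)
  b <- colSums(e)
  ab <- sum(a * b)
  if (abs(1 - ab) < 1e-14)
    fsna_stop("assortment undefined: all weight in one class pair",
              "focalsna_degenerate")
  (sum(diag(e)) - ab) / (1 - ab)
}

#' Weighted assortativity for a continuous node attribute
#'
#' Edge-weighted Pearson correlation between the source-node value and the
#' target-node value over all weighted directed edges.
#'
#' @param net a [weighted_network()].
#' @param values finite numeric value per node (in `net$ids` order, or
#'   named).
#' @return assortativity coefficient in `[-1, 1]`.
#' @export
assortment_continuous <- function(net, values) {
  v <- align_attr(net, values)
  if (!all(is.finite(v)))
    fsna_stop("all node values must be finite", "focalsna_invalid_value")
  w <- net$w
  tot <- sum(w)
  if (tot <= 0)
    fsna_stop("assortment undefined on an empty network",
              "focalsna_degenerate")
  ws <- rowSums(w)  # weight emitted by each source node
  wt <- colSums(w)  # weight received by each target node
  mx <- sum(ws * v) / tot
  my <- sum(wt * v) / tot
  vx <- sum(ws * (v - mx)^2) / tot
  vy <- sum(wt * (v - my)^2) / tot
  tol0 <- 1e-12 * (1 + mx^2 + my^2)  # guard against rounding of a constant
  if (vx <= tol0 || vy <= tol0)
    fsna_stop("assortment undefined: zero variance at edge endpoints",
              "focalsna_degenerate")
  cv <- sum(w * outer(v - mx, v - my)) / tot
  cv / sqrt(vx * vy)
}

align_attr <- function(net, x) {
  if (!is.null(names(x))) {
    if (!all(net$ids %in% names(x)))
      fsna_stop("attribute missing for some nodes", "focalsna_invalid_value")
    x <- x[net$ids]
  }
  if (length(x) != length(net$ids))
    fsna_stop("attribute length must equal the number of nodes",
              "focalsna_invalid_value")
  x
}

#' Assortment with node-label permutation significance
#'
#' Computes the observed assortativity, then its null distribution over
#' node-label permutations of the network (the attribute-to-label mapping
#' held fixed, so each permutation re-deals the attributes over network
#' positions). Two-sided p by the add-one rule.
#'
#' @param net a [weighted_network()].
#' @param value attribute vector (one per node).
#' @param kind `"continuous"` or `"discrete"`.
#' @param variable name of the attribute, for reporting.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed.
#' @return object of class `assortment_test` (also a [new_perm_test()]
#'   result): `r`, `kind`, `variable`, `p_value`, `null_values`.
#' @export
assortment_test <- function(net, value, kind = c("continuous", "discrete"),
                            variable = deparse(substitute(value)),
                            n_perm = 1000, seed = NULL) {
  kind <- match.arg(kind)
  value <- align_attr(net, value)
  stat <- function(v) {
    if (kind == "discrete") assortment_discrete(net, v)
    else assortment_continuous(net, v)
  }
  observed <- stat(value)
  n <- length(net$ids)
  # conjugating w by a permutation equals evaluating r with the attribute
  # vector dealt along the inverse permutation; both sides are label-free
  null_values <- with_seed(seed,
    vapply(seq_len(n_perm), function(i) stat(value[sample.int(n)]),
           numeric(1)))
  out <- new_perm_test(paste0("assortment r (", variable, ")"), observed,
                       null_values, "two_sided", n_perm, seed)
  out$r <- observed
  out$kind <- kind
  out$variable <- variable
  class(out) <- c("assortment_test", class(out))
  out
}

#' @export
print.assortment_test <- function(x, ...) {
  cat(sprintf("Assortment by %s (%s): r = %.4f, p = %.4g (%d permutations)\n",
              x$variable, x$kind, x$r, x$p_value, x$n_perm))
  invisible(x)
}

vec_offdiag <- function(m) m[row(m) != col(m)]

# Rebuild a zero-diagonal matrix from an off-diagonal vector.
mat_offdiag <- function(v, n) {
  m <- matrix(0, n, n)
  m[row(m) != col(m)] <- v
  m
}

#' MRQAP network regression with Dekker double-semi-partialling
#'
#' Regresses the response network on one or more predictor networks over
#' the vectorized off-diagonal dyads (ordinary least squares). Dyadic
#' observations are not independent, so per-predictor significance comes
#' from double-semi-partialling (DSP): each predictor's residual matrix
#' (that predictor regressed on the remaining predictors) is permuted by
#' node relabeling, the model refitted, and the observed t statistic
#' compared two-sided to the permuted t distribution (add-one rule).
#'
#' @param response a [weighted_network()].
#' @param predictors a named list of [weighted_network()]s on the same node
#'   set.
#' @param n_perm number of DSP permutations per predictor.
#' @param seed optional RNG seed.
#' @return object of class `mrqap`: `coefficients` data.frame (`predictor`,
#'   `estimate`, `t`, `p_perm`), `intercept`, `r_squared`, `n_perm`, `seed`,
#'   `null_t` matrix.
#' @export
mrqap <- function(response, predictors, n_perm = 1000, seed = NULL) {
  if (inherits(predictors, "weighted_network"))
    predictors <- list(predictor = predictors)
  stopifnot(length(predictors) >= 1)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    names(predictors) <- paste0("x", seq_along(predictors))
  ids <- response$ids
  for (p in predictors)
    if (!identical(p$ids, ids))
      fsna_stop("response and predictors must share one node set",
                "focalsna_invalid_value")
  n <- length(ids)
  y <- vec_offdiag(response$w)
  Xm <- vapply(predictors, function(p) vec_offdiag(p$w),
               numeric(length(y)))
  Xm <- matrix(Xm, ncol = length(predictors),
               dimnames = list(NULL, names(predictors)))
  X <- cbind(`(Intercept)` = 1, Xm)
  if (qr(X)$rank < ncol(X)) {
    cors <- suppressWarnings(stats::cor(Xm))
    bad <- which(abs(cors) > 1 - 1e-10 & upper.tri(cors), arr.ind = TRUE)
    pair <- if (nrow(bad)) paste(rownames(cors)[bad[1, 1]],
                                 colnames(cors)[bad[1, 2]], sep = " ~ ")
            else "unidentified pair"
    fsna_stop(paste("collinear predictors:", pair), "focalsna_collinear")
  }

  fit_t <- function(X, y) {
    qrX <- qr(X)
    b <- qr.coef(qrX, y)
    res <- y - X %*% b
    df <- length(y) - ncol(X)
    s2 <- sum(res^2) / df
    se <- sqrt(diag(chol2inv(qr.R(qrX))) * s2)
    list(b = b, t = b / se, r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
  }
  obs <- fit_t(X, y)

  k <- length(predictors)
  null_t <- with_seed(seed, {
    perms <- rand_perms(n, n_perm)
    sapply(seq_len(k), function(j) {
      Xo <- X[, -(j + 1), drop = FALSE]
      ej <- Xm[, j] - Xo %*% qr.coef(qr(Xo), Xm[, j])  # DSP residuals
      Ej <- mat_offdiag(ej, n)
      vapply(seq_len(n_perm), function(i) {
        p <- perms[i, ]
        Xp <- X
        Xp[, j + 1] <- vec_offdiag(Ej[p, p])
        fit_t(Xp, y)$t[j + 1]
      }, numeric(1))
    })
  })
  null_t <- matrix(null_t, ncol = k, dimnames = list(NULL, names(predictors)))
  p_perm <- vapply(seq_len(k), function(j)
    perm_pvalue(obs$t[j + 1], null_t[, j], "two_sided"), numeric(1))
  structure(
    list(coefficients = data.frame(predictor = names(predictors),
                                   estimate = unname(obs$b[-1]),
                                   t = unname(obs$t[-1]),
                                   p_perm = p_perm,
                                   stringsAsFactors = FALSE),
         intercept = unname(obs$b[1]),
         r_squared = obs$r2,
         n_dyads = length(y), n_perm = n_perm, seed = seed,
         null_t = null_t),
    class = "mrqap")
}

#' @export
print.mrqap <- function(x, ...) {
  cat(sprintf(
    "MRQAP (DSP) over %d dyads, %d permutations; R^2 = %.4f\n",
    x$n_dyads, x$n_perm, x$r_squared))
  print(transform(x$coefficients, estimate = signif(estimate, 6),
                  t = signif(t, 5), p_perm = signif(p_perm, 4)),
        row.names = FALSE)
  invisible(x)
}

#' QAP correlation between two per-node vectors
#'
#' Pearson correlation with significance from random permutations of the
#' node alignment (quadratic assignment): the pairing of `x` values to `y`
#' values is shuffled to build the null.
#'
#' @param x,y numeric vectors aligned on the same node list (use names to
#'   check alignment).
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @param tail `"two_sided"` (default), `"greater"` or `"less"`.
#' @return a `perm_test` object.
#' @export
qap_correlation <- function(x, y, n_perm = 1000, seed = NULL,
                            tail = "two_sided") {
  if (length(x) != length(y))
    fsna_stop("x and y must have equal length", "focalsna_invalid_value")
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y)))
      fsna_stop("x and y must cover the same nodes",
                "focalsna_invalid_value")
    y <- y[names(x)]
  }
  observed <- stats::cor(x, y)
  null_values <- with_seed(seed,
    vapply(seq_len(n_perm),
           function(i) stats::cor(x, y[sample.int(length(y))]),
           numeric(1)))
  new_perm_test("QAP Pearson r", observed, null_values, tail, n_perm, seed)
}
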