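#' Dyadic binomial samples from association counts
#'
#' Converts a [dyadic_counts] object into the per-ordered-pair samples the
#' mixture model consumes: successes `x` = the index numerator (observed
#' association), trials `d` = the index denominator (sampling effort).
#' Because the data are directional, each dyad contributes two samples (A
#' toward B, and B toward A). Pairs never co-sampled (`d = 0`) are dropped.
#' Duration-mode counts enter as integer seconds.
#'
#' @param counts a [dyadic_counts] object.
#' @return data.frame with columns `a`, `b`, `x`, `d` (one row per ordered
#'   pair with positive denominator).
#' @export
dyad_samples <- function(counts) {
  stopifnot(inherits(counts, "dyadic_counts"))
  D <- counts_denominator(counts)
  off <- which(row(D) != col(D) & D > 0)
  data.frame(a = counts$ids[row(D)[off]],
             b = counts$ids[col(D)[off]],
             x = round(counts$X[off]),
             d = round(D[off]),
             stringsAsFactors = FALSE)
}

# One EM run from a given start; returns list(q, p, z, loglik, n_iter,
# converged). All likelihood terms in log space (duration-mode trials are
# large). Duplicate (x, d) patterns are collapsed with multiplicity
# weights `w` (sum(w) = n of the original samples): the likelihood,
# responsibilities and M-step are exactly those of the expanded sample.
binmix_em <- function(x, d, w, n, q0, p0, tol, max_iter) {
  m_pat <- length(x)
  K <- length(p0)
  lch <- lchoose(d, x)
  q <- q0
  p <- p0
  loglik <- -Inf
  converged <- FALSE
  z <- matrix(1 / K, m_pat, K)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lp <- matrix(0, m_pat, K)
    for (k in seq_len(K))
      lp[, k] <- log(q[k]) + lch + xlogy(x, p[k]) + xlogy(d - x, 1 - p[k])
    mx <- lp[cbind(seq_len(m_pat), max.col(lp, ties.method = "first"))]
    ll_i <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(w * ll_i)
    trace <- c(trace, ll)
    z <- exp(lp - ll_i)
    # M step (weighted by pattern multiplicity)
    cz <- colSums(w * z)
    q <- cz / n
    zd <- colSums(w * z * d)
    p_new <- ifelse(zd > 0, colSums(w * z * x) / zd, p)
    p <- p_new
    if (is.finite(loglik) &&
        (ll - loglik) <= tol * (abs(ll) + tol)) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  list(q = q, p = p, z = z, loglik = loglik, n_iter = it,
       converged = converged, trace = trace)
}

#' Fit a K-class binomial mixture to dyadic association samples
#'
#' Models each sample's successes as `x_i ~ Binomial(d_i, p_k)` with latent
#' class `k` drawn with frequency `q_k`: the classes are discrete
#' relationship types, `p_k` the mean association strength of type `k` and
#' `q_k` its frequency in the network. Fitted by EM (best of `n_starts`
#' starts by log-likelihood); the first start is a deterministic quantile
#' split of the empirical `x/d` ratios, the rest random perturbations.
#' Classes are reported sorted by increasing `p`.
#'
#' @param x integer successes per sample (or a data.frame from
#'   [dyad_samples()], in which case `d` is taken from it).
#' @param d integer trials per sample (positive).
#' @param K number of classes (>= 1).
#' @param n_starts number of EM starts.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per start.
#' @param seed optional RNG seed for the random starts.
#' @return an object of class `binmix` with components `K`, `q`, `p`,
#'   `loglik`, `z` (posterior class responsibilities), `converged`,
#'   `n_iter`, `n`, `x`, `d`, `degenerate`.
#' @export
fit_binmix <- function(x, d = NULL, K, n_starts = 5, tol = 1e-8,
                       max_iter = 1000, seed = NULL) {
  if (is.data.frame(x)) {
    d <- x$d
    x <- x$x
  }
  stopifnot(length(x) == length(d), all(d > 0), all(x >= 0), all(x <= d))
  n <- length(x)
  if (K < 1) fsna_stop("K must be >= 1", "focalsna_invalid_value")
  if (K > n)
    fsna_stop(sprintf("K = %d exceeds the number of samples (%d)", K, n),
              "focalsna_invalid_value")
  if (K == 1) {
    p <- sum(x) / sum(d)
    ll <- sum(lchoose(d, x) + xlogy(x, p) + xlogy(d - x, 1 - p))
    fit <- list(q = 1, p = p, z = matrix(1, n, 1), loglik = ll,
                n_iter = 1L, converged = TRUE, trace = ll)
  } else {
    r <- x / d
    grp <- cut(rank(r, ties.method = "first"), breaks = K, labels = FALSE)
    p0 <- as.numeric(tapply(x, grp, sum) / tapply(d, grp, sum))
    q0 <- as.numeric(table(factor(grp, levels = seq_len(K)))) / n
    # collapse duplicate (x, d) patterns; EM is exactly equivalent on the
    # weighted patterns and much faster when trials repeat
    pat <- match(paste(x, d), unique(paste(x, d)))
    keep <- !duplicated(pat)
    xu <- x[keep]
    du <- d[keep]
    wu <- as.numeric(tabulate(pat, max(pat)))
    starts <- list(list(q0 = q0, p0 = p0))
    fit <- with_seed(seed, {
      if (n_starts > 1) {
        for (s in seq_len(n_starts - 1)) {
          pr <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
          p0r <- stats::plogis(stats::qlogis(pr) + stats::rnorm(K, 0, 1))
          q0r <- stats::rgamma(K, 1)
          starts[[s + 1]] <- list(q0 = q0r / sum(q0r), p0 = sort(p0r))
        }
      }
      runs <- lapply(starts, function(st)
        binmix_em(xu, du, wu, n, st$q0, st$p0, tol, max_iter))
      runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
    })
    fit$z <- fit$z[pat, , drop = FALSE]  # expand to the original samples
  }
  ord <- order(fit$p)
  fit$p <- fit$p[ord]
  fit$q <- fit$q[ord]
  fit$z <- fit$z[, ord, drop = FALSE]
  degenerate <- (K > 1 && (any(diff(fit$p) < 1e-8) || any(fit$q < 1 / n)))
  if (!fit$converged)
    warning("EM did not converge within max_iter; best iterate returned",
            call. = FALSE)
  structure(list(K = K, q = fit$q, p = fit$p, loglik = fit$loglik,
                 loglik_trace = fit$trace, z = fit$z,
                 converged = fit$converged, n_iter = fit$n_iter,
                 n = n, x = x, d = d, degenerate = degenerate),
            class = "binmix")
}

#' @export
print.binmix <- function(x, ...) {
  cat(sprintf("Binomial mixture fit: K = %d, logLik = %.4f%s\n", x$K,
              x$loglik, if (x$degenerate) " (degenerate classes)" else ""))
  print(round(rbind(`mean strength (p)` = x$p, `frequency (q)` = x$q), 4))
  invisible(x)
}

#' @export
coef.binmix <- function(object, ...) {
  list(q = object$q, p = object$p)
}

#' @export
logLik.binmix <- function(object, ...) {
  structure(object$loglik, df = 2 * object$K - 1, nobs = object$n,
            class = "logLik")
}

#' @export
summary.binmix <- function(object, ...) {
  sc <- icl_score(object)
  cat(sprintf(
    "Binomial mixture: K = %d classes over %d dyadic samples\n",
    object$K, object$n))
  print(data.frame(class = seq_len(object$K),
                   mean_strength = round(object$p, 5),
                   frequency = round(object$q, 5)), row.names = FALSE)
  cat(sprintf("logLik %.3f  BIC %.3f  entropy %.3f  ICL %.3f\n",
              object$loglik, sc["BIC"], sc["E"], sc["ICL"]))
  invisible(object)
}

#' Simulate dyadic samples from a fitted binomial mixture
#'
#' Draws new success counts at the fit's own trial sizes: each sample's
#' class from `q`, then `x ~ Binomial(d, p_k)`.
#'
#' @param object a `binmix` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param d trial sizes (defaults to the fit's training trials).
#' @param ... unused.
#' @return a list of `nsim` data.frames with columns `x`, `d`, `class`.
#' @export
simulate.binmix <- function(object, nsim = 1, seed = NULL,
                            d = object$d, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    k <- sample.int(object$K, length(d), replace = TRUE, prob = object$q)
    data.frame(x = stats::rbinom(length(d), d, object$p[k]), d = d,
               class = k)
  }))
}

#' Posterior class responsibilities for new samples
#'
#' @param object a `binmix` fit.
#' @param newdata data.frame with columns `x` and `d` (default: training
#'   samples).
#' @param ... unused.
#' @return matrix (samples x classes) of posterior probabilities.
#' @export
predict.binmix <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$z)
  x <- newdata$x
  d <- newdata$d
  lp <- vapply(seq_len(object$K), function(k)
    log(object$q[k]) + lchoose(d, x) + xlogy(x, object$p[k]) +
      xlogy(d - x, 1 - object$p[k]), numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1, max)
  z <- exp(lp - m)
  z / rowSums(z)
}

#' BIC, classification entropy and ICL of a mixture fit
#'
#' `BIC = -2 logLik + (2K - 1) log(n)` (free parameters: K strengths plus
#' K - 1 frequencies); `E = -sum z log z` over the posterior classification
#' matrix (0 log 0 := 0); `ICL = BIC + 2E`, so the selected model is the one
#' with least classification uncertainty in addition to fit.
#'
#' @param fit a `binmix` fit.
#' @param n_samples number of samples (defaults to the fit's).
#' @return named numeric vector `c(BIC, E, ICL)`.
#' @export
icl_score <- function(fit, n_samples = fit$n) {
  z <- fit$z
  E <- -sum(xlogy(z, z))
  BIC <- -2 * fit$loglik + (2 * fit$K - 1) * log(n_samples)
  c(BIC = BIC, E = E, ICL = BIC + 2 * E)
}

#' Select the number of relationship classes by ICL
#'
#' Fits binomial mixtures for `K = 1..Kmax` and selects the minimal-ICL
#' model (ties within 1e-6 broken toward smaller K). The Shannon entropy of
#' the selected model's class frequencies summarises social complexity.
#'
#' @inheritParams fit_binmix
#' @param Kmax largest number of classes to consider.
#' @return an object of class `binmix_select` with `fits` (list of `binmix`
#'   by K), `table` (K, loglik, converged, BIC, E, ICL), `selected_K`,
#'   `fit` (the selected `binmix`), and `H`.
#' @export
select_binmix <- function(x, d = NULL, Kmax = 6, n_starts = 5, tol = 1e-8,
                          max_iter = 1000, seed = NULL) {
  if (is.data.frame(x)) {
    d <- x$d
    x <- x$x
  }
  if (Kmax < 1) fsna_stop("Kmax must be >= 1", "focalsna_invalid_value")
  seeds <- if (is.null(seed)) vector("list", Kmax) else
    with_seed(seed, as.list(sample.int(.Machine$integer.max, Kmax)))
  fits <- lapply(seq_len(Kmax), function(K)
    fit_binmix(x, d, K = K, n_starts = n_starts, tol = tol,
               max_iter = max_iter, seed = seeds[[K]]))
  scores <- t(vapply(fits, icl_score, numeric(3)))
  icl <- scores[, "ICL"]
  selected_K <- which(icl <= min(icl) + 1e-6)[1]
  structure(
    list(fits = fits,
         table = data.frame(K = seq_len(Kmax),
                            loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                            converged = vapply(fits, `[[`, logical(1),
                                               "converged"),
                            BIC = scores[, "BIC"], E = scores[, "E"],
                            ICL = scores[, "ICL"]),
         selected_K = selected_K,
         fit = fits[[selected_K]],
         H = shannon_entropy(fits[[selected_K]]$q),
         seed = seed),
    class = "binmix_select")
}

#' @export
print.binmix_select <- function(x, ...) {
  cat(sprintf(
    "Binomial mixture selection (ICL): selected K = %d, Shannon H = %.4f\n",
    x$selected_K, x$H))
  print(transform(x$table, loglik = round(loglik, 2), BIC = round(BIC, 2),
                  E = round(E, 3), ICL = round(ICL, 2)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.binmix_select <- function(object, ...) {
  print(object)
  cat("\nSelected model:\n")
  summary(object$fit)
  invisible(object)
}

#' @export
coef.binmix_select <- function(object, ...) coef(object$fit)

#' Shannon entropy of class frequencies
#'
#' `H = -sum q_k ln q_k` (0 ln 0 := 0): the richness-and-evenness summary of
#' the relationship-class distribution; larger H means a more diverse, and
#' in this framework more complex, social structure. Bounded by `ln K`.
#'
#' @param q non-negative class frequencies summing to 1 (tolerance 1e-8).
#' @return entropy in nats.
#' @export
shannon_entropy <- function(q) {
  if (any(q < 0) || abs(sum(q) - 1) > 1e-8)
    fsna_stop("q must be a probability vector summing to 1",
              "focalsna_invalid_value")
  -sum(xlogy(q, q))
}

#' Table of selected relationship classes across networks
#'
#' Flattens one or more [select_binmix()] results into the standard
#' complexity report: one row per class of the selected model with its mean
#' strength and frequency, plus the network's Shannon H, and (as
#' `aic_style = FALSE` columns) the per-K BIC/E/ICL audit trail.
#'
#' @param selections named list of `binmix_select` objects; names are taken
#'   as `network` labels.
#' @param period_label period to stamp on the rows.
#' @return list with `classes` and `criteria` data.frames.
#' @export
complexity_report <- function(selections, period_label = "unlabelled") {
  classes <- do.call(rbind, lapply(names(selections), function(nm) {
    s <- selections[[nm]]
    data.frame(network = nm, period = period_label, K = s$selected_K,
               class = seq_len(s$selected_K),
               mean_strength = s$fit$p, frequency = s$fit$q, H = s$H,
               stringsAsFactors = FALSE)
  }))
  criteria <- do.call(rbind, lapply(names(selections), function(nm) {
    cbind(network = nm, period = period_label, selections[[nm]]$table)
  }))
  list(classes = classes, criteria = criteria)
}
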