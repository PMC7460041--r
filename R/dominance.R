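#' Win-loss matrix from aggressive interactions
#'
#' Aggregates directed aggressive events into `W(A, B)` = total "wins" of A
#' over B, with the actor of each event treated as its winner (the only
#' outcome signal the recording protocol provides). Wins are measured in
#' interaction seconds by default, consistent with duration-weighted
#' matrices elsewhere; `measure = "count"` uses event counts instead.
#'
#' @param ds an [obs_dataset()].
#' @param measure `"duration"` (seconds) or `"count"` (events).
#' @return square numeric matrix with zero diagonal, class `win_loss`.
#' @export
win_loss_from_aggression <- function(ds, measure = c("duration", "count")) {
  measure <- match.arg(measure)
  ids <- ds$individuals$id
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ev <- ds$interactions
  ev <- ev[ev$category == "aggressive", , drop = FALSE]
  if (nrow(ev)) {
    val <- if (measure == "duration") ev$duration_s else rep(1, nrow(ev))
    agg <- stats::aggregate(val,
                            by = list(a = ev$actor_id, r = ev$receiver_id),
                            FUN = sum)
    W[cbind(match(agg$a, ids), match(agg$r, ids))] <- agg$x
  }
  attr(W, "measure") <- measure
  class(W) <- c("win_loss", class(W))
  W
}

#' David's scores from a win-loss matrix
#'
#' A cardinal dominance index: with `P_AB` the proportion of the A-B
#' interaction total won by A (0 contribution for non-interacting dyads),
#' `DS_A = w_A + w2_A - l_A - l2_A`, where `w_A = sum_B P_AB`,
#' `w2_A = sum_B P_AB w_B` (wins weighted by the opponents' own win rates),
#' and `l`, `l2` the mirror-image loss terms. Scores sum to zero over the
#' group. The `"Dij"` variant replaces `P_AB` with the dyadic-frequency
#' correction `D_AB = P_AB - (P_AB - 0.5) / (n_AB + 1)` (with `n_AB` the
#' dyad's interaction total), shrinking sparsely observed dyads toward 0.5;
#' both variants agree as `n_AB` grows.
#'
#' @param W a `win_loss` matrix (or any non-negative square matrix with a
#'   zero diagonal).
#' @param variant `"Dij"` (default) or `"Pij"`.
#' @return named numeric vector of David's scores (attribute `"variant"`).
#' @export
davids_score <- function(W, variant = c("Dij", "Pij")) {
  variant <- match.arg(variant)
  W <- unclass(W)
  n <- nrow(W)
  if (n < 2)
    fsna_stop("David's score needs at least 2 individuals",
              "focalsna_invalid_value")
  Nt <- W + t(W)
  P <- matrix(0, n, n, dimnames = dimnames(W))
  pos <- Nt > 0
  P[pos] <- W[pos] / Nt[pos]
  if (variant == "Dij") {
    D <- P
    D[pos] <- P[pos] - (P[pos] - 0.5) / (Nt[pos] + 1)
    P <- D
  }
  diag(P) <- 0
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.numeric(P %*% w)
  l2 <- as.numeric(t(P) %*% l)
  ds <- w + w2 - l - l2
  names(ds) <- rownames(W)
  attr(ds, "variant") <- variant
  ds
}

#' Hierarchy linearity (de Vries' h')
#'
#' Builds the binary dominance digraph (A dominates B when
#' `W(A,B) > W(B,A)`), scores tied and unobserved relationships 0.5 each
#' way, and computes Landau's index
#' `h = 12/(n^3 - n) * sum_i (V_i - (n-1)/2)^2` on the dominance totals
#' `V_i`, plus de Vries' correction for the `u` unknown relationships,
#' `h' = h + 6u/(n^3 - n)`. Significance comes from a randomization test:
#' `h'` of the observed matrix is compared (right tail, add-one rule)
#' against matrices whose dyad directions are random coin flips.
#'
#' @param W a `win_loss` matrix.
#' @param n_perm randomization repeats.
#' @param seed optional RNG seed.
#' @return list of class `linearity`: `h_prime`, `h_landau`, `u` (unknown
#'   relationships), `p_value`, `n_perm`, `seed`.
#' @export
linearity_h <- function(W, n_perm = 1000, seed = NULL) {
  W <- unclass(W)
  n <- nrow(W)
  if (n < 3)
    fsna_stop("linearity needs at least 3 individuals",
              "focalsna_invalid_value")
  denom <- n^3 - n
  h_of <- function(S) {
    V <- rowSums(S)
    12 / denom * sum((V - (n - 1) / 2)^2)
  }
  S <- matrix(0.5, n, n)
  S[W < t(W)] <- 0
  S[W > t(W)] <- 1
  diag(S) <- 0
  u <- sum(W == 0 & t(W) == 0 & upper.tri(W))
  h_landau <- h_of(S)
  h_prime <- h_landau + 6 * u / denom
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    R <- matrix(0, n, n)
    up <- upper.tri(R)
    R[up] <- as.numeric(stats::runif(sum(up)) < 0.5)
    lo <- lower.tri(R)
    R[lo] <- (1 - t(R))[lo]  # complete the tournament
    h_of(R)
  }, numeric(1)))
  structure(list(h_prime = h_prime, h_landau = h_landau, u = u,
                 p_value = perm_pvalue(h_prime, null_values, "greater"),
                 null_values = null_values, n_perm = n_perm, seed = seed),
            class = "linearity")
}

#' @export
print.linearity <- function(x, ...) {
  cat(sprintf(
    "Hierarchy linearity: h' = %.4f (Landau h = %.4f, %d unknown dyads), p = %.4g\n",
    x$h_prime, x$h_landau, x$u, x$p_value))
  invisible(x)
}

#' Model dominance scores on age and sex
#'
#' Fits the four Gaussian linear models {intercept-only, sex, age,
#' sex + age} of David's score and selects the lowest-AIC model only when
#' it beats the runner-up by at least 2 AIC units and contains at least one
#' predictor; otherwise no model is deemed predictive. A Shapiro-Wilk
#' statistic on the scores is reported as a normality diagnostic.
#'
#' @param ds_scores named numeric vector of David's scores (names = IDs).
#' @param individuals individuals table (`id`, `sex`, `birth_date`).
#' @param reference_date date at which ages are computed.
#' @return object of class `dominance_model`: `aic_table`, `selected`
#'   (formula label or `"none"`), `fit` (the selected `lm`, or `NULL`),
#'   `coefficients` (estimate, SE, p for the selected model), `shapiro`.
#' @export
dominance_model <- function(ds_scores, individuals, reference_date) {
  idx <- match(names(ds_scores), individuals$id)
  if (any(is.na(idx)))
    fsna_stop("scores and individuals tables do not align",
              "focalsna_invalid_value")
  dat <- data.frame(
    DS = as.numeric(ds_scores),
    sex = factor(individuals$sex[idx], levels = c("female", "male")),
    age = age_at(individuals$birth_date[idx], reference_date))
  if (nrow(dat) < 4)
    fsna_stop("too few individuals to fit the candidate models",
              "focalsna_invalid_value")
  forms <- list(`(intercept)` = DS ~ 1, sex = DS ~ sex, age = DS ~ age,
                `sex+age` = DS ~ sex + age)
  fits <- lapply(forms, stats::lm, data = dat)
  aic <- vapply(fits, stats::AIC, numeric(1))
  n_par <- c(0L, 1L, 1L, 2L)
  aic_table <- data.frame(model = names(forms), AIC = aic, dAIC = aic -
                            min(aic[is.finite(aic)], Inf),
                          stringsAsFactors = FALSE)
  ord <- order(aic)
  pick <- aic_select(aic, n_par)
  selected <- if (pick %in% c("none", "(intercept)")) "none" else pick
  fit <- if (selected != "none") fits[[selected]] else NULL
  coefs <- if (!is.null(fit)) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               p = s[, 4], row.names = NULL, stringsAsFactors = FALSE)
  } else NULL
  sw <- tryCatch(stats::shapiro.test(dat$DS),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  structure(list(aic_table = aic_table[ord, ], selected = selected,
                 picked_model = pick, fit = fit, coefficients = coefs,
                 shapiro = c(W = unname(sw$statistic),
                             p = unname(sw$p.value)),
                 reference_date = as.Date(reference_date)),
            class = "dominance_model")
}

#' @export
print.dominance_model <- function(x, ...) {
  cat("Dominance ~ {age, sex} model selection (dAIC >= 2 rule)\n")
  print(transform(x$aic_table, AIC = round(AIC, 2), dAIC = round(dAIC, 2)),
        row.names = FALSE)
  if (x$selected == "none") {
    cat("No predictive model (no candidate clears the dAIC >= 2 rule).\n")
  } else {
    cat(sprintf("Selected: %s\n", x$selected))
    print(transform(x$coefficients, estimate = signif(estimate, 4),
                    se = signif(se, 3), p = signif(p, 3)),
          row.names = FALSE)
  }
  invisible(x)
}
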