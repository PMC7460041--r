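# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Raise a classed error so callers can distinguish validation failures.
fsna_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "focalsna_error")))
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# x * log(y) with the 0 * log(0) := 0 convention.
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

# Permutation p-value with the add-one rule; never 0.
perm_pvalue <- function(observed, null_values,
                        tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  x <- switch(tail,
    two_sided = sum(abs(null_values) >= abs(observed)),
    greater   = sum(null_values >= observed),
    less      = sum(null_values <= observed))
  (1 + x) / (1 + length(null_values))
}

new_perm_test <- function(statistic_name, observed, null_values, tail,
                          n_perm, seed = NULL) {
  structure(
    list(statistic_name = statistic_name,
         observed = observed,
         null_values = null_values,
         p_value = perm_pvalue(observed, null_values, tail),
         tail = tail,
         n_perm = n_perm,
         seed = seed),
    class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test:", x$statistic_name, "\n")
  cat(sprintf("  observed = %.6g\n", x$observed))
  cat(sprintf("  p = %.4g  (%s, %d permutations)\n",
              x$p_value, x$tail, x$n_perm))
  invisible(x)
}

# AIC model selection with the parsimony reading of the dAIC >= 2 rule:
# among candidates within 2 AIC units of the minimum, pick the one with the
# fewest parameters; an intercept-only winner means no predictive factors,
# and a tie between equally simple distinct models selects nothing.
# `aic` named vector, `n_par` parameter counts aligned with it.
aic_select <- function(aic, n_par) {
  aic[!is.finite(aic)] <- -.Machine$double.xmax / 4  # saturated fits tie
  close <- which(aic <= min(aic) + 2)
  simplest <- close[n_par[close] == min(n_par[close])]
  if (length(simplest) > 1 && length(unique(names(aic)[simplest])) > 1)
    return("none")
  names(aic)[simplest[1]]
}

# A matrix of `n_perm` random permutations of 1:n (one per row).
rand_perms <- function(n, n_perm) {
  t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
}
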