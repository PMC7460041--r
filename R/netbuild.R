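#' Directed dyadic count matrices
#'
#' A `dyadic_counts` object holds, for every ordered pair (A, B), the
#' components of the association index: `X(A,B)` (samples where A was the
#' focal and B its nearest neighbour, or seconds A-as-focal interacted with
#' B), plus the per-focal sampling totals `S` from which the "A focal,
#' partner not B" terms derive as `Y_A(A,B) = S_A - X(A,B)`. The
#' joint-absence term `Y_AB` is structurally zero under focal sampling (both
#' members of a pair cannot be jointly "observed but not neighbours" in one
#' sample) and is carried explicitly so the index mirrors its definition.
#'
#' @name dyadic_counts
NULL

new_dyadic_counts <- function(X, S, mode, layer, period_label) {
  stopifnot(is.matrix(X), nrow(X) == ncol(X), length(S) == nrow(X))
  diag(X) <- 0
  structure(
    list(ids = rownames(X), X = X, S = S,
         Y_AB = matrix(0, nrow(X), ncol(X), dimnames = dimnames(X)),
         mode = mode, layer = layer, period_label = period_label),
    class = "dyadic_counts")
}

#' @export
print.dyadic_counts <- function(x, ...) {
  cat(sprintf("Dyadic counts (%s, layer '%s', period '%s'): %d individuals\n",
              x$mode, x$layer, x$period_label, length(x$ids)))
  invisible(x)
}

# Y_A(A,B): samples with A focal and partner != B.
counts_YA <- function(counts) {
  Y <- counts$S - counts$X
  diag(Y) <- 0
  Y
}

# Denominator of the association index for every ordered pair:
# X + Y_A + Y_B + Y_AB = S_A + S_B - X(B,A).
counts_denominator <- function(counts) {
  D <- counts$X + counts_YA(counts) + t(counts_YA(counts)) + counts$Y_AB
  diag(D) <- 0
  D
}

#' Tally nearest-neighbour scans into dyadic counts
#'
#' Each scan contributes one point to `X(focal, n)` for every neighbour `n`
#' recorded in it (equidistant neighbours are separate, full data points
#' with the same time stamp), and one point to `Y(focal, m)` for every other
#' individual `m`. Individuals never sampled as focal are retained as
#' isolates with a warning.
#'
#' @param ds an [obs_dataset()].
#' @return a `dyadic_counts` object with `mode = "scan_count"`.
#' @export
count_nearest_neighbour <- function(ds) {
  ids <- ds$individuals$id
  n <- length(ids)
  X <- matrix(0, n, n, dimnames = list(ids, ids))
  nb <- neighbour_sets(ds)
  if (length(nb)) {
    focal <- rep(as.character(ds$scans$focal_id), lengths(nb))
    tab <- table(factor(focal, levels = ids),
                 factor(unlist(nb), levels = ids))
    X <- X + unclass(tab)
  }
  S <- as.numeric(table(factor(ds$scans$focal_id, levels = ids)))
  names(S) <- ids
  if (any(S == 0))
    warning(sprintf("%d individual(s) with no focal scans retained as isolates",
                    sum(S == 0)), call. = FALSE)
  new_dyadic_counts(X, S, mode = "scan_count", layer = "association",
                    period_label = ds$period_label)
}

#' Tally interaction durations into dyadic counts
#'
#' `X(A,B)` totals the seconds, within focals of A, that A interacted with B
#' in the given category. By default only events where the focal was the
#' actor are attributed (`X(A,B)` = A focal and actor toward B), preserving
#' directionality; set `include_received = TRUE` to also count the focal's
#' time as receiver toward that partner.
#'
#' @param ds an [obs_dataset()].
#' @param category `"affiliative"` or `"aggressive"`.
#' @param include_received also count events where the focal was the
#'   receiver (directionality then reflects the focal's total interaction
#'   time with the partner).
#' @return a `dyadic_counts` object with `mode = "duration_s"`.
#' @export
count_interaction_durations <- function(ds,
                                        category = c("affiliative",
                                                     "aggressive"),
                                        include_received = FALSE) {
  category <- match.arg(category)
  ids <- ds$individuals$id
  n <- length(ids)
  X <- matrix(0, n, n, dimnames = list(ids, ids))
  ev <- ds$interactions
  ev <- ev[ev$category == category, , drop = FALSE]
  if (nrow(ev)) {
    as_actor <- ev[ev$focal_id == ev$actor_id, , drop = FALSE]
    if (nrow(as_actor)) {
      agg <- stats::aggregate(duration_s ~ actor_id + receiver_id,
                              data = as_actor, FUN = sum)
      X[cbind(match(agg$actor_id, ids), match(agg$receiver_id, ids))] <-
        X[cbind(match(agg$actor_id, ids), match(agg$receiver_id, ids))] +
        agg$duration_s
    }
    if (include_received) {
      as_rec <- ev[ev$focal_id == ev$receiver_id, , drop = FALSE]
      if (nrow(as_rec)) {
        agg <- stats::aggregate(duration_s ~ receiver_id + actor_id,
                                data = as_rec, FUN = sum)
        X[cbind(match(agg$receiver_id, ids), match(agg$actor_id, ids))] <-
          X[cbind(match(agg$receiver_id, ids), match(agg$actor_id, ids))] +
          agg$duration_s
      }
    }
  }
  S <- rowSums(X)
  layer <- if (category == "affiliative") "affiliation" else "aggression"
  new_dyadic_counts(X, S, mode = "duration_s", layer = layer,
                    period_label = ds$period_label)
}

#' Directed weighted network from an association index
#'
#' Computes the Simple Ratio Index for every ordered pair:
#' `w(A,B) = X / (Y_AB + Y_A + Y_B + X)`, where `Y_AB` is structurally zero.
#' The index controls for inter-individual differences in how often each
#' partner was sampled. Pairs never co-sampled (zero denominator) get weight
#' 0 (with a warning) so downstream matrix methods receive complete
#' matrices.
#'
#' @param counts a `dyadic_counts` object.
#' @return a `weighted_network`.
#' @export
simple_ratio_index <- function(counts) {
  stopifnot(inherits(counts, "dyadic_counts"))
  D <- counts_denominator(counts)
  W <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  pos <- D > 0
  W[pos] <- counts$X[pos] / D[pos]
  diag(W) <- 0
  off <- row(D) != col(D)
  if (any(D[off] == 0))
    warning(sprintf("%d ordered pair(s) never co-sampled; weight set to 0",
                    sum(D[off] == 0)), call. = FALSE)
  weighted_network(W, layer = counts$layer,
                   period_label = counts$period_label)
}

#' Directed weighted social network
#'
#' @param w square numeric matrix of weights in `[0, 1]` with individual IDs
#'   as dimnames; the diagonal is forced to zero.
#' @param layer one of `"association"`, `"affiliation"`, `"aggression"` (or
#'   any label).
#' @param period_label collection-period label.
#' @return an object of class `weighted_network` with fields `ids`, `w`,
#'   `layer`, `period_label`.
#' @export
weighted_network <- function(w, layer = "association",
                             period_label = "unlabelled") {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (is.null(rownames(w)))
    dimnames(w) <- list(paste0("N", seq_len(nrow(w))),
                        paste0("N", seq_len(nrow(w))))
  if (any(w < 0) || any(w > 1 + 1e-12))
    fsna_stop("network weights must lie in [0, 1]", "focalsna_invalid_value")
  diag(w) <- 0
  structure(list(ids = rownames(w), w = w, layer = layer,
                 period_label = period_label),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  off <- x$w[row(x$w) != col(x$w)]
  cat(sprintf(
    "Weighted directed network (layer '%s', period '%s'): %d nodes, %d non-zero edges, mean weight %.4g\n",
    x$layer, x$period_label, length(x$ids), sum(off > 0),
    if (any(off > 0)) mean(off[off > 0]) else 0))
  invisible(x)
}

net_igraph <- function(net, directed = TRUE) {
  igraph::graph_from_adjacency_matrix(net$w, mode = if (directed) "directed"
                                      else "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Write / read a weighted network
#'
#' GraphML (via igraph), a 3-column weighted edge list
#' (`source,target,weight`) or a full CSV matrix dump with an ID header row
#' and column. Edge-list and matrix weights are written with 17 significant
#' digits so a write/read round trip preserves them exactly.
#'
#' @param net a [weighted_network()].
#' @param path output/input file path.
#' @param format `"graphml"`, `"edgelist"` or `"matrix"`; default guessed
#'   from the file extension (`.graphml` / `.csv` = matrix / `.edges` =
#'   edge list).
#' @param layer,period_label metadata to attach on read (edge list and
#'   matrix formats do not store them).
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a `weighted_network`.
#' @export
write_network <- function(net, path, format = guess_format(path)) {
  format <- match.arg(format, c("graphml", "edgelist", "matrix"))
  if (format == "graphml") {
    g <- net_igraph(net)
    igraph::graph_attr(g, "layer") <- net$layer
    igraph::graph_attr(g, "period_label") <- net$period_label
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    idx <- which(net$w > 0, arr.ind = TRUE)
    df <- data.frame(source = net$ids[idx[, 1]],
                     target = net$ids[idx[, 2]],
                     weight = format(net$w[idx], digits = 17,
                                     scientific = TRUE, trim = TRUE),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    m <- net$w
    df <- data.frame(id = rownames(m),
                     apply(m, 2, base::format, digits = 17,
                           scientific = TRUE, trim = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         graphml = "graphml", edges = "edgelist", csv = "matrix",
         "graphml")
}

#' @rdname write_network
#' @param ids for `format = "edgelist"`, the complete node set (isolates are
#'   absent from an edge list); defaults to the IDs seen in the file.
#' @export
read_network <- function(path, format = guess_format(path),
                         layer = "association", period_label = "unlabelled",
                         ids = NULL) {
  format <- match.arg(format, c("graphml", "edgelist", "matrix"))
  if (format == "graphml") {
    g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                  error = function(e)
                    fsna_stop(paste("malformed GraphML file:",
                                    conditionMessage(e)),
                              "focalsna_parse_error"))
    w <- igraph::as_adjacency_matrix(g, attr = if ("weight" %in%
      igraph::edge_attr_names(g)) "weight" else NULL, sparse = FALSE)
    if (is.null(rownames(w)) && "name" %in% igraph::vertex_attr_names(g))
      dimnames(w) <- list(igraph::V(g)$name, igraph::V(g)$name)
    la <- igraph::graph_attr(g, "layer") %||% layer
    pe <- igraph::graph_attr(g, "period_label") %||% period_label
    return(weighted_network(w, layer = la, period_label = pe))
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE),
                 error = function(e)
                   fsna_stop(paste("malformed network file:",
                                   conditionMessage(e)),
                             "focalsna_parse_error"))
  if (format == "edgelist") {
    if (!all(c("source", "target", "weight") %in% names(df)))
      fsna_stop("edge list must have columns source,target,weight",
                "focalsna_parse_error")
    ids <- ids %||% sort(unique(c(df$source, df$target)))
    w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    w[cbind(match(df$source, ids), match(df$target, ids))] <-
      as.numeric(df$weight)
  } else {
    ids <- df[[1]]
    w <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(w) <- "double"
    dimnames(w) <- list(ids, colnames(df)[-1])
    if (!identical(rownames(w), colnames(w)))
      fsna_stop("matrix dump rows and columns disagree",
                "focalsna_parse_error")
  }
  weighted_network(w, layer = layer, period_label = period_label)
}
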