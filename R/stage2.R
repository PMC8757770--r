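# Stage 2: pairwise k-NN refinement on quadrant statistical-moment features.
#
# Each map is summarized by 32 features: for each quadrant Q1..Q4 and each
# channel (magnitude, then angle) the mean, variance, kurtosis and skewness
# of the node values. Binary k-NN between the two candidate classes uses a
# per-pair distance metric and neighbor count from a packaged registry.

.METRICS <- c("cityblock", "euclidean", "chebyshev")

# Metric spelling normalization: the literature uses Manhattan/Cityblock
# interchangeably and misc spellings of Euclidean/Chebyshev.
.normalize_metric <- function(x) {
  v <- tolower(trimws(x))
  v[v %in% c("manhattan", "cityblock", "city block", "l1")] <- "cityblock"
  v[v %in% c("euclidean", "eucledian", "l2")] <- "euclidean"
  v[v %in% c("chebyshev", "chebychev", "linf", "linfinity")] <- "chebyshev"
  bad <- setdiff(unique(v), .METRICS)
  if (length(bad) > 0)
    stop("unknown metric(s): ", paste(bad, collapse = ", "), call. = FALSE)
  v
}

# Population moments of a sample: mean, variance (divisor N), non-excess
# kurtosis (normal -> 3) and skewness (standardized third moment). A constant
# sample has zero variance; its skewness and kurtosis are set to 0 rather
# than dividing by zero.
.moments <- function(x) {
  m <- mean(x)
  d <- x - m
  v <- mean(d^2)
  if (v == 0) return(c(mean = m, variance = 0, kurtosis = 0, skewness = 0))
  c(mean = m, variance = v,
    kurtosis = mean(d^4) / v^2,
    skewness = mean(d^3) / v^(3 / 2))
}

#' Extract the 32 quadrant-moment features of a CDDM
#'
#' For each quadrant (Q1 top-left, Q2 top-right, Q3 bottom-left, Q4
#' bottom-right) and each channel (magnitude then angle): mean, variance
#' (population, divisor N), kurtosis (non-excess; normal is approximately 3)
#' and skewness. The layout order is frozen; the per-pair k-NN models depend
#' on it.
#'
#' @param map A `cddm` with even grid dimensions.
#' @return Named numeric vector of length 32
#'   (`Q1_mag_mean`, `Q1_mag_variance`, ..., `Q4_ang_skewness`).
#' @export
extract_features <- function(map) {
  q <- split_quadrants(map)
  out <- numeric(0)
  for (qi in names(q)) {
    for (ch in c("mag", "ang")) {
      x <- if (ch == "mag") q[[qi]]$magnitude else q[[qi]]$angle
      mm <- .moments(as.vector(x))
      names(mm) <- paste(qi, ch, names(mm), sep = "_")
      out <- c(out, mm)
    }
  }
  out
}

#' Distance between two feature vectors
#'
#' The three Minkowski-family metrics used by the pairwise classifiers:
#' cityblock (Manhattan, L1), euclidean (L2) and chebyshev (L-infinity,
#' maximum absolute coordinate difference). Euclidean is returned as the
#' root, which is ordering-equivalent to the squared form for k-NN.
#'
#' @param x,y Numeric vectors of equal length (32 in the pipeline; any
#'   length is accepted).
#' @param metric One of `"cityblock"`, `"euclidean"`, `"chebyshev"` (aliases
#'   such as `"Manhattan"` are normalized).
#' @return A single non-negative number.
#' @export
#' @examples
#' feature_distance(c(1, 2, 3), c(2, 4, 0), "cityblock")  # 6
feature_distance <- function(x, y, metric) {
  if (length(x) != length(y))
    stop("feature length mismatch: ", length(x), " vs ", length(y),
         call. = FALSE)
  metric <- .normalize_metric(metric)
  d <- abs(x - y)
  switch(metric,
         cityblock = sum(d),
         euclidean = sqrt(sum(d^2)),
         chebyshev = max(d))
}

# Internal: distances from one query vector to the rows of a feature matrix.
.distances_to <- function(query, train_mat, metric) {
  d <- abs(sweep(train_mat, 2, query))
  switch(metric,
         cityblock = rowSums(d),
         euclidean = sqrt(rowSums(d^2)),
         chebyshev = apply(d, 1, max))
}

#' Majority vote among the k nearest neighbors
#'
#' Sorts the training set by distance to the query (ties broken by stable
#' input order), takes the first `k` and returns the majority label. If the
#' k votes split evenly, the label of the single nearest neighbor wins —
#' a deterministic tie rule needed because even k occurs in the per-pair
#' parameter registry.
#'
#' @param query Numeric feature vector.
#' @param train_features Matrix, one row per training map.
#' @param train_labels Labels of the training rows; exactly 2 distinct values.
#' @param k Number of neighbors, `1 <= k <= nrow(train_features)`.
#' @param metric Distance metric name.
#' @return The winning label.
#' @export
knn_vote <- function(query, train_features, train_labels, k, metric) {
  train_features <- as.matrix(train_features)
  n <- nrow(train_features)
  if (n == 0) stop("empty training set", call. = FALSE)
  if (length(train_labels) != n)
    stop("labels/features size mismatch", call. = FALSE)
  if (length(unique(train_labels)) != 2)
    stop("knn_vote is a binary classifier; got ",
         length(unique(train_labels)), " distinct label(s)", call. = FALSE)
  if (k < 1 || k > n)
    stop("k must be in [1, ", n, "]; got ", k, call. = FALSE)
  if (ncol(train_features) != length(query))
    stop("feature length mismatch", call. = FALSE)
  metric <- .normalize_metric(metric)
  dists <- .distances_to(query, train_features, metric)
  ord <- order(dists)                       # stable on ties
  top <- train_labels[ord[seq_len(k)]]
  tab <- table(top)
  if (length(tab) == 2 && tab[1] == tab[2]) return(top[1])  # nearest wins
  names(tab)[which.max(tab)]
}

#' Per-pair k-NN parameter registry
#'
#' Loads the table of best-performing (metric, k) per unordered class pair —
#' the parameters selected by the metric-by-k sweep on the original clinical
#' cohort — plus the default row applied to all unlisted pairs (cityblock,
#' k = 1). The packaged file can be replaced by a user-supplied one with
#' columns `group1`, `group2`, `metric`, `k` (`group1 = OTHER` marks the
#' default row).
#'
#' @param path Optional path to a registry file; default: the packaged one.
#' @return Object of class `pair_registry`: data.frame with canonical labels
#'   and normalized metric names, plus a `default` attribute.
#' @export
pair_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pair_params.tsv",
                        package = "cddmcascade", mustWork = TRUE)
  reg <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("group1", "group2", "metric", "k")
  if (!all(need %in% names(reg)))
    stop("pair registry must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  reg$metric <- .normalize_metric(reg$metric)
  reg$k <- as.integer(reg$k)
  if (any(is.na(reg$k)) || any(reg$k < 1) || any(reg$k > 15))
    stop("registry k values must be integers in [1, 15]", call. = FALSE)
  isdef <- toupper(reg$group1) %in% c("OTHER", "OTHER PAIRS", "DEFAULT")
  if (sum(isdef) != 1)
    stop("registry must contain exactly one default (OTHER) row",
         call. = FALSE)
  default <- list(metric = reg$metric[isdef], k = reg$k[isdef])
  reg <- reg[!isdef, , drop = FALSE]
  reg$group1 <- as_heart_state(reg$group1)
  reg$group2 <- as_heart_state(reg$group2)
  key <- apply(cbind(reg$group1, reg$group2), 1,
               function(p) paste(sort(p), collapse = "|"))
  if (anyDuplicated(key))
    stop("duplicate pair in registry: ", key[duplicated(key)][1],
         call. = FALSE)
  rownames(reg) <- key
  attr(reg, "default") <- default
  class(reg) <- c("pair_registry", "data.frame")
  reg
}

#' Look up the k-NN parameters for a class pair
#'
#' Symmetric in the pair order. Pairs absent from the registry fall back to
#' the default row (cityblock, k = 1 in the packaged registry).
#'
#' @param a,b Heart-state labels (codes or aliases).
#' @param registry A [pair_registry()].
#' @return List with `pair` (sorted canonical labels), `metric` and `k`.
#' @export
#' @examples
#' lookup_pair_params("CAD2", "LVH3", pair_registry())  # cityblock, k = 3
lookup_pair_params <- function(a, b, registry = pair_registry()) {
  stopifnot(inherits(registry, "pair_registry"))
  pair <- sort(c(as_heart_state(a), as_heart_state(b)))
  if (pair[1] == pair[2])
    stop("a pair needs two distinct labels", call. = FALSE)
  key <- paste(pair, collapse = "|")
  if (key %in% rownames(registry)) {
    row <- registry[key, ]
    list(pair = pair, metric = row$metric, k = row$k)
  } else {
    def <- attr(registry, "default")
    list(pair = pair, metric = def$metric, k = def$k)
  }
}

#' Binary k-NN classification between two classes
#'
#' Builds feature vectors for every reference map of the two classes and
#' runs [knn_vote()] with the pair's parameters.
#'
#' @param query A `cddm`.
#' @param reference A `cddm_cohort` containing maps of both classes.
#' @param pair Character vector of the two labels.
#' @param params Optional list with `metric` and `k`; default: registry
#'   lookup for the pair.
#' @param registry Registry used when `params` is NULL.
#' @return One of the two labels.
#' @export
classify_pair <- function(query, reference, pair, params = NULL,
                          registry = pair_registry()) {
  stopifnot(inherits(reference, "cddm_cohort"), length(pair) == 2)
  pair <- as_heart_state(pair)
  if (is.null(params))
    params <- lookup_pair_params(pair[1], pair[2], registry)
  ids <- unlist(reference$groups[pair], use.names = FALSE)
  if (length(ids) < params$k)
    stop("insufficient training maps (", length(ids), ") for k = ",
         params$k, call. = FALSE)
  train <- t(vapply(reference$maps[ids], extract_features, numeric(32)))
  labels <- vapply(reference$maps[ids], function(m) m$label, "")
  knn_vote(extract_features(query), train, labels, params$k, params$metric)
}
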