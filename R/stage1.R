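# Stage 1: multiclass classification by the resulting correlation
# coefficient. A query map is compared with every reference map by Pearson
# correlation of the flattened magnitude vectors and of the flattened angle
# vectors; the product of the two ("resulting correlation") scores the pair.
# Per class, the mean of the m largest resulting correlations is the group
# score; classes are ranked by descending score.

#' Pearson correlation with a zero-variance convention
#'
#' Standard product-moment correlation of two equal-length vectors. If either
#' vector is constant the coefficient is undefined; this implementation
#' returns 0 there — "no variation" is read as "no evidence of similarity" —
#' so the classification pipeline stays total on degenerate maps.
#'
#' @param x,y Numeric vectors of equal length n >= 2.
#' @return A single value in \[-1, 1\].
#' @export
#' @examples
#' pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))   # 0.6
pearson <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("pearson expects numeric vectors", call. = FALSE)
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y), call. = FALSE)
  if (length(x) < 2)
    stop("pearson needs n >= 2", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("pearson inputs must be NA-free", call. = FALSE)
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) return(0)
  r <- stats::cor(x, y)
  # clamp float spill just outside [-1, 1]
  max(-1, min(1, r))
}

#' Resulting correlation between two CDDMs
#'
#' Pearson correlation of the flattened magnitude vectors, Pearson
#' correlation of the flattened angle vectors, and their product — a single
#' similarity score that accounts for both the current density moduli and
#' the directions. Symmetric in its arguments.
#'
#' @param a,b `cddm` objects of the same grid shape.
#' @return List with `r_magnitude`, `r_angle`, `r_resulting`
#'   (= `r_magnitude * r_angle`) and `against_map_id` (`b`'s id).
#' @export
resulting_correlation <- function(a, b) {
  stopifnot(inherits(a, "cddm"), inherits(b, "cddm"))
  if (!identical(dim(a$magnitude), dim(b$magnitude)))
    stop("shape mismatch: ", paste(dim(a$magnitude), collapse = "x"),
         " vs ", paste(dim(b$magnitude), collapse = "x"), call. = FALSE)
  rm_ <- pearson(as.vector(t(a$magnitude)), as.vector(t(b$magnitude)))
  ra_ <- pearson(as.vector(t(a$angle)), as.vector(t(b$angle)))
  list(r_magnitude = rm_, r_angle = ra_, r_resulting = rm_ * ra_,
       against_map_id = b$map_id)
}

# Internal: flattened magnitude/angle matrices for a list of maps.
# Returns n x N matrices (one column per map, row-major flattening).
.flatten_matrix <- function(maps) {
  n <- length(maps)
  stopifnot(n >= 1)
  mag <- vapply(maps, function(m) as.vector(t(m$magnitude)),
                numeric(length(maps[[1]]$magnitude)))
  ang <- vapply(maps, function(m) as.vector(t(m$angle)),
                numeric(length(maps[[1]]$angle)))
  list(mag = as.matrix(mag), ang = as.matrix(ang))
}

# Internal batch scorer: resulting-correlation matrix between query columns
# and reference columns. Zero-variance columns yield r = 0 by convention.
.resulting_matrix <- function(qmag, qang, rmag, rang) {
  cm <- suppressWarnings(stats::cor(qmag, rmag))
  ca <- suppressWarnings(stats::cor(qang, rang))
  cm[is.na(cm)] <- 0
  ca[is.na(ca)] <- 0
  cm[cm > 1] <- 1; cm[cm < -1] <- -1
  ca[ca > 1] <- 1; ca[ca < -1] <- -1
  cm * ca                                  # queries x references
}

# Internal: mean of the top min(m, length(v)) values.
.top_m_mean <- function(v, m) mean(sort(v, decreasing = TRUE)[seq_len(min(m, length(v)))])

#' Group score of a query against one reference group
#'
#' Computes the resulting correlation of the query with every reference map
#' of the group, keeps the `min(m, group size)` largest values and returns
#' their arithmetic mean.
#'
#' @param query A `cddm`.
#' @param group_refs Non-empty list of reference `cddm`s (one class).
#' @param m Number of top correlations averaged (default 3).
#' @return A single numeric score.
#' @export
group_score <- function(query, group_refs, m = 3L) {
  if (length(group_refs) == 0)
    stop("empty reference group", call. = FALSE)
  stopifnot(m >= 1)
  r <- vapply(group_refs,
              function(ref) resulting_correlation(query, ref)$r_resulting,
              0)
  .top_m_mean(r, m)
}

#' Rank all 14 groups for a query map
#'
#' One [group_score()] per class, sorted by descending score. Ties are broken
#' by the canonical label order of [heart_state_labels()] so the ranking is
#' deterministic.
#'
#' @param query A `cddm`.
#' @param reference A `cddm_cohort` containing at least one map per label.
#' @param m Top-m averaging parameter (default 3).
#' @return Object of class `ranked_groups`: data.frame with columns `label`
#'   and `score` (14 rows, non-increasing score), attribute `m_used`.
#' @export
rank_groups <- function(query, reference, m = 3L) {
  stopifnot(inherits(reference, "cddm_cohort"))
  missing <- setdiff(heart_state_labels(), names(reference$groups))
  if (length(missing) > 0)
    stop("reference cohort is missing label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  scores <- vapply(heart_state_labels(), function(lb)
    group_score(query, reference$maps[reference$groups[[lb]]], m = m), 0)
  .ranked_from_scores(scores, m)
}

# scores: named vector over all 14 labels in canonical order
.ranked_from_scores <- function(scores, m) {
  ord <- order(-scores)                    # stable: canonical order on ties
  out <- data.frame(label = heart_state_labels()[ord],
                    score = unname(scores[ord]), stringsAsFactors = FALSE)
  attr(out, "m_used") <- as.integer(m)
  class(out) <- c("ranked_groups", "data.frame")
  out
}

#' Stage-1 label of a query map
#'
#' The label of the top-ranked group: the class whose top-m mean resulting
#' correlation with the query is highest.
#'
#' @inheritParams rank_groups
#' @return A canonical heart-state label.
#' @export
classify_stage1 <- function(query, reference, m = 3L) {
  rank_groups(query, reference, m = m)$label[1]
}
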