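# Shared fixtures and independent oracles for the test suite.

# Random valid CDDM on an even grid.
random_cddm <- function(h = 10, w = 10, label = NULL, map_id = "t") {
  mag <- matrix(runif(h * w), h, w)
  ang <- matrix(runif(h * w, -pi, pi), h, w)
  cddm(mag, ang, label = label, map_id = map_id)
}

# Tiny labelled cohort: n_per maps per class, moderate noise, fast.
tiny_cohort <- function(n_per = 4, seed = 7L, separation = 1,
                        mag_noise = 0.05, ang_noise = 0.2) {
  cfg <- generator_config(per_group_count = n_per,
                          magnitude_noise_sd = mag_noise,
                          angle_noise_sd = ang_noise,
                          separation = separation, seed = seed)
  simulate_cohort(cfg)
}

# --- Independent oracles (kept deliberately naive) ---

# Direct sum-formula Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  num <- sum((x - xb) * (y - yb))
  den <- sqrt(sum((x - xb)^2)) * sqrt(sum((y - yb)^2))
  num / den
}

# Direct per-coordinate Minkowski distances.
oracle_distance <- function(x, y, metric) {
  s <- 0
  if (metric == "cityblock") {
    for (j in seq_along(x)) s <- s + abs(x[j] - y[j])
  } else if (metric == "euclidean") {
    for (j in seq_along(x)) s <- s + (x[j] - y[j])^2
    s <- sqrt(s)
  } else {
    for (j in seq_along(x)) s <- max(s, abs(x[j] - y[j]))
  }
  s
}

# Brute-force k-NN: full distance vector, stable sort, count votes,
# even split -> nearest neighbor's label.
oracle_knn <- function(query, train, labels, k, metric) {
  d <- apply(train, 1, function(r) oracle_distance(query, r, metric))
  ord <- order(d)
  top <- labels[ord[1:k]]
  counts <- table(top)
  if (length(counts) == 2 && counts[[1]] == counts[[2]]) return(top[1])
  names(counts)[which.max(counts)]
}

# Brute-force population moments.
oracle_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  if (m2 == 0) c(m, 0, 0, 0) else c(m, m2, m4 / m2^2, m3 / m2^1.5)
}

# Independent re-reading of the escalation tables for the truth-table test.
oracle_tables <- list(
  low_precision = list(
    LVH1  = c("MDAM", "LVH2", "MVD_M", "NORM2"),
    LVH2  = c("NORM1", "LVH1", "MVD_F"),
    LVH3  = c("CAD2", "MVD_M", "CAD3", "NORM2"),
    CAD3  = c("NONCOR", "CAD2", "MVD_M", "MVD_F"),
    NORM1 = c("CAD1", "LVH2", "NORM2", "NONCOR")
  ),
  low_sensitivity = list(
    NORM2  = c("LVH1", "LVH3", "NORM1"),
    MVD_F  = c("CAD4", "LVH2"),
    MVD_M  = c("CAD1", "CAD3", "NORM2"),
    NONCOR = c("CAD1", "CAD3", "NORM1"),
    LVH2   = c("LVH1", "NORM1"),
    CAD2   = c("LVH2", "LVH3", "CAD3", "CAD5")
  )
)

# Naive escalation decision from a top-3 label triple.
oracle_escalation <- function(g1, g2, g3) {
  for (rule in c("low_precision", "low_sensitivity")) {
    tb <- oracle_tables[[rule]]
    if (g1 %in% names(tb)) {
      if (g2 %in% tb[[g1]])
        return(list(escalate = TRUE, rule = rule, partner = g2, rank = 2L))
      if (g3 %in% tb[[g1]])
        return(list(escalate = TRUE, rule = rule, partner = g3, rank = 3L))
    }
  }
  list(escalate = FALSE, rule = "none", partner = NA_character_,
       rank = NA_integer_)
}

# Ranking data.frame from an ordered label vector (scores descending).
fake_ranking <- function(labels_in_order) {
  out <- data.frame(label = labels_in_order,
                    score = seq(1, 0, length.out = length(labels_in_order)),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_groups", "data.frame")
  out
}
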