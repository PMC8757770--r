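# End-to-end two-stage classification with a full decision trace.
#
# Every classification records its evidence chain: the full stage-1 ranking,
# the escalation decision (which rule fired, against which rank), the k-NN
# parameters used, and both stage labels. The method is defined by which
# rule fired, so the trace is the primary audit surface.

# Internal: cached per-cohort matrices (stage-1 vectors, features, labels).
.cohort_cache <- function(cohort) {
  maps <- cohort$maps
  fl <- .flatten_matrix(maps)
  list(mag = fl$mag, ang = fl$ang,
       features = t(vapply(maps, extract_features, numeric(32))),
       labels = vapply(maps, function(m) m$label, ""),
       map_ids = names(maps))
}

# Internal workhorse: classify the query columns of (qmag, qang, qfeat)
# against a cached reference. Returns a list of traces.
.classify_core <- function(qids, qlabels, qmag, qang, qfeat,
                           ref, tables, registry, m) {
  rmat <- .resulting_matrix(qmag, qang, ref$mag, ref$ang)
  ref_groups <- split(seq_along(ref$labels), ref$labels)
  missing <- setdiff(heart_state_labels(), names(ref_groups))
  if (length(missing) > 0)
    stop("reference cohort is missing label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lapply(seq_along(qids), function(qi) {
    rr <- rmat[qi, ]
    scores <- vapply(heart_state_labels(),
                     function(lb) .top_m_mean(rr[ref_groups[[lb]]], m), 0)
    ranked <- .ranked_from_scores(scores, m)
    decision <- decide_escalation(ranked, tables)
    stage1 <- ranked$label[1]
    params <- NULL; stage2 <- NA_character_
    final <- stage1
    if (decision$escalate) {
      params <- lookup_pair_params(decision$pair[1], decision$pair[2],
                                   registry)
      tr_idx <- unlist(ref_groups[sort(decision$pair)], use.names = FALSE)
      k <- min(params$k, length(tr_idx))
      stage2 <- knn_vote(qfeat[qi, ], ref$features[tr_idx, , drop = FALSE],
                         ref$labels[tr_idx], k, params$metric)
      final <- stage2
    }
    structure(list(map_id = qids[qi], true_label = qlabels[qi],
                   ranked = ranked, decision = decision,
                   pair_params_used = params, stage1_label = stage1,
                   stage2_label = stage2, final_label = final),
              class = "cddm_trace")
  })
}

#' Two-stage classification of a single query map
#'
#' Runs the full cascade: stage-1 group ranking by resulting correlation,
#' the escalation decision, and — when a rule fires — the pairwise k-NN duel
#' between the top-ranked group and the matched 2nd/3rd-ranked group, whose
#' winner becomes the final label. Non-escalated queries keep the stage-1
#' label.
#'
#' @param query A `cddm`.
#' @param reference A `cddm_cohort` covering all 14 labels; it serves both
#'   stages (correlation references and k-NN training set).
#' @param tables [escalation_tables()].
#' @param registry [pair_registry()].
#' @param m Stage-1 top-m averaging parameter (default 3).
#' @return A `cddm_trace`: list with `map_id`, `true_label`, `ranked`,
#'   `decision`, `pair_params_used`, `stage1_label`, `stage2_label`,
#'   `final_label`.
#' @export
classify_two_stage <- function(query, reference,
                               tables = escalation_tables(),
                               registry = pair_registry(), m = 3L) {
  stopifnot(inherits(query, "cddm"), inherits(reference, "cddm_cohort"))
  ref <- .cohort_cache(reference)
  fl <- flatten_for_stage1(query, grid_config(nrow(query$magnitude),
                                              ncol(query$magnitude)))
  .classify_core(query$map_id, query$label,
                 matrix(fl$magnitude, ncol = 1),
                 matrix(fl$angle, ncol = 1),
                 matrix(extract_features(query), nrow = 1),
                 ref, tables, registry, m)[[1]]
}

#' @export
print.cddm_trace <- function(x, ...) {
  cat(sprintf("<trace '%s'> stage1=%s", x$map_id, x$stage1_label))
  if (x$decision$escalate)
    cat(sprintf(" -> %s duel (%s, rank %d) -> %s",
                paste(x$decision$pair, collapse = " vs "),
                x$decision$rule_fired, x$decision$matched_rank,
                x$stage2_label))
  cat(sprintf(" | final=%s\n", x$final_label))
  invisible(x)
}

#' Classify every map of a query cohort
#'
#' Batch equivalent of [classify_two_stage()]: output order equals the
#' input map order and each trace equals the corresponding single call.
#'
#' @param queries A `cddm_cohort` of maps to classify.
#' @param reference The reference `cddm_cohort`.
#' @inheritParams classify_two_stage
#' @return List of `cddm_trace` objects (class `cddm_trace_list`).
#' @export
classify_batch <- function(queries, reference,
                           tables = escalation_tables(),
                           registry = pair_registry(), m = 3L) {
  stopifnot(inherits(queries, "cddm_cohort"),
            inherits(reference, "cddm_cohort"))
  if (length(queries$maps) == 0)
    return(structure(list(), class = c("cddm_trace_list", "list")))
  ref <- .cohort_cache(reference)
  q <- .cohort_cache(queries)
  traces <- .classify_core(q$map_ids, q$labels, q$mag, q$ang, q$features,
                           ref, tables, registry, m)
  structure(traces, class = c("cddm_trace_list", "list"))
}

#' Predictions table from a list of traces
#'
#' @param traces List of `cddm_trace` objects.
#' @return data.frame with columns `map_id`, `true_label`, `stage1_label`,
#'   `escalated` (0/1), `rule_fired`, `pair`, `stage2_label`, `final_label`.
#' @export
predictions_table <- function(traces) {
  rows <- lapply(traces, function(tr) {
    data.frame(map_id = tr$map_id,
               true_label = tr$true_label,
               stage1_label = tr$stage1_label,
               escalated = as.integer(tr$decision$escalate),
               rule_fired = tr$decision$rule_fired,
               pair = if (tr$decision$escalate)
                        paste(tr$decision$pair, collapse = ",") else "",
               stage2_label = tr$stage2_label,
               final_label = tr$final_label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(map_id = character(0), true_label = character(0),
                      stage1_label = character(0), escalated = integer(0),
                      rule_fired = character(0), pair = character(0),
                      stage2_label = character(0), final_label = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
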