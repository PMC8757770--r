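# Escalation rule engine.
#
# The one-stage correlation classifier shows low precision for five classes
# (many false positives) and low sensitivity for six classes (many false
# negatives). The escalation tables list, for each such class, the classes
# it is most often confused with. A stage-1 result is escalated to a k-NN
# duel when the top-ranked class is one of these keys and the 2nd- or
# 3rd-ranked class is in its confusable set.

#' Load the escalation tables
#'
#' Two maps: `low_precision` (classes the one-stage classifier over-predicts,
#' keyed LVH1, LVH2, LVH3, CAD3, NORM1, each with the classes most often
#' misclassified *to* it) and `low_sensitivity` (classes it under-predicts,
#' keyed NORM2, MVD_F, MVD_M, NONCOR, LVH2, CAD2, each with the classes they
#' are most often misclassified *as*). The packaged fixture is validated on
#' load: the key sets must be exactly these, and every candidate label must
#' be canonical.
#'
#' @param path Optional path to a rules file with columns `rule_type`
#'   (`low_precision` / `low_sensitivity`), `key_label`, `candidate_label`;
#'   default: the packaged tables.
#' @return Object of class `escalation_tables`: list of two named lists of
#'   character vectors.
#' @export
escalation_tables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "escalation_rules.tsv",
                        package = "cddmcascade", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("rule_type", "key_label", "candidate_label")
  if (!all(need %in% names(tab)))
    stop("rules file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tab$rule_type %in% c("low_precision", "low_sensitivity")))
    stop("rule_type must be low_precision or low_sensitivity", call. = FALSE)
  tab$key_label <- as_heart_state(tab$key_label)
  tab$candidate_label <- as_heart_state(tab$candidate_label)
  build <- function(type) {
    sub <- tab[tab$rule_type == type, ]
    lapply(split(sub$candidate_label, sub$key_label), unique)
  }
  out <- structure(list(low_precision = build("low_precision"),
                        low_sensitivity = build("low_sensitivity")),
                   class = "escalation_tables")
  # structural validation: the key sets are fixed by the method
  if (!setequal(names(out$low_precision),
                c("LVH1", "LVH2", "LVH3", "CAD3", "NORM1")))
    stop("low_precision keys must be exactly LVH1, LVH2, LVH3, CAD3, NORM1",
         call. = FALSE)
  if (!setequal(names(out$low_sensitivity),
                c("NORM2", "MVD_F", "MVD_M", "NONCOR", "LVH2", "CAD2")))
    stop("low_sensitivity keys must be exactly NORM2, MVD_F, MVD_M, NONCOR, ",
         "LVH2, CAD2", call. = FALSE)
  out
}

#' Decide whether a stage-1 ranking escalates to stage 2
#'
#' Let g1, g2, g3 be the top three ranked labels. Rules are checked in fixed
#' precedence: first the low-precision condition (g1 is a low-precision key
#' and g2 — else g3 — is in its confusable set), then the low-sensitivity
#' condition in the same pattern. A rank-2 match takes precedence over a
#' rank-3 match within a rule. At most one duel is scheduled; when no rule
#' fires the stage-1 label stands. The decision depends only on the top
#' three labels.
#'
#' @param ranked A `ranked_groups` object (14 rows) from [rank_groups()].
#' @param tables An [escalation_tables()] object.
#' @return List with `escalate` (logical), `rule_fired` (`"none"`,
#'   `"low_precision"` or `"low_sensitivity"`), `pair` (the top label and the
#'   matched candidate, or NULL) and `matched_rank` (2, 3 or NA).
#' @export
decide_escalation <- function(ranked, tables = escalation_tables()) {
  stopifnot(inherits(tables, "escalation_tables"))
  if (!is.data.frame(ranked) || nrow(ranked) != 14 ||
      !all(c("label", "score") %in% names(ranked)))
    stop("ranked must be a 14-row ranking with columns label, score",
         call. = FALSE)
  g <- ranked$label[1:3]
  for (rule in c("low_precision", "low_sensitivity")) {
    tb <- tables[[rule]]
    if (g[1] %in% names(tb)) {
      cand <- tb[[g[1]]]
      for (r in 2:3) {
        if (g[r] %in% cand)
          return(list(escalate = TRUE, rule_fired = rule,
                      pair = c(g[1], g[r]), matched_rank = r))
      }
    }
  }
  list(escalate = FALSE, rule_fired = "none", pair = NULL,
       matched_rank = NA_integer_)
}
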