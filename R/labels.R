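# Heart-state label set: 14 closed classes covering normal states, myocardial
# damage, non-coronarogenic disease, microvascular disease by sex, five grades
# of coronary artery disease and three grades of left ventricular hypertrophy.

.LABELS <- c("NORM1", "NORM2", "MDAM", "NONCOR", "MVD_M", "MVD_F",
             "CAD1", "CAD2", "CAD3", "CAD4", "CAD5",
             "LVH1", "LVH2", "LVH3")

.LABEL_DISPLAY <- c(
  NORM1  = "Healthy volunteers",
  NORM2  = "Sportsmen",
  MDAM   = "Myocardial damage",
  NONCOR = "Non-coronarogenic diseases",
  MVD_M  = "Microvascular disease (M)",
  MVD_F  = "Microvascular disease (F)",
  CAD1   = "Coronary artery disease, grade 1",
  CAD2   = "Coronary artery disease, grade 2",
  CAD3   = "Coronary artery disease, grade 3",
  CAD4   = "Coronary artery disease, grade 4",
  CAD5   = "Coronary artery disease, grade 5",
  LVH1   = "Left ventricular hypertrophy, grade 1",
  LVH2   = "Left ventricular hypertrophy, grade 2",
  LVH3   = "Left ventricular hypertrophy, grade 3"
)

# Aliases seen across the literature for the same groups. IHDn and CADn are
# used interchangeably; DIFFm/DIFFf denote diffuse (microvascular) disease by
# sex; REUMO denotes non-coronarogenic disease.
.LABEL_ALIASES <- c(
  IHD1 = "CAD1", IHD2 = "CAD2", IHD3 = "CAD3", IHD4 = "CAD4", IHD5 = "CAD5",
  DIFFM = "MVD_M", DIFFF = "MVD_F",
  REUMO = "NONCOR",
  NORMAL = "NORM1",
  `MYOCARDIAL DAMAGE` = "MDAM",
  `MICROVASCULAR DISEASE (M)` = "MVD_M",
  `MICROVASCULAR DISEASE (F)` = "MVD_F",
  `NON-CORONAROGENIC DISEASES` = "NONCOR",
  `NON-CORONAROGENIC DISEASE` = "NONCOR"
)

#' Canonical heart-state labels
#'
#' Returns the closed set of 14 heart-state class codes in canonical order.
#' This order is also the deterministic tie-break order used when ranking
#' groups by correlation score.
#'
#' @return Character vector of length 14.
#' @export
#' @examples
#' heart_state_labels()
heart_state_labels <- function() .LABELS

#' Display names for heart-state labels
#'
#' @param labels Character vector of canonical codes (default: all 14).
#' @return Named character vector of human-readable group names.
#' @export
heart_state_display <- function(labels = heart_state_labels()) {
  labels <- as_heart_state(labels)
  .LABEL_DISPLAY[labels]
}

#' Resolve heart-state labels to canonical codes
#'
#' Accepts canonical codes and common aliases (\code{IHDn} for \code{CADn},
#' \code{DIFFm}/\code{DIFFf} for \code{MVD_M}/\code{MVD_F}, \code{REUMO} for
#' \code{NONCOR}, and spelled-out group names). Matching ignores case and
#' surrounding whitespace; internal spaces in codes collapse (e.g.
#' \code{"LVH 1"}). Unknown codes are an error: the label set is closed.
#'
#' @param x Character vector of labels or aliases.
#' @return Character vector of canonical codes, same length as \code{x}.
#' @export
#' @examples
#' as_heart_state(c("IHD3", "DIFFm", "REUMO", "lvh 2"))
as_heart_state <- function(x) {
  if (length(x) == 0) return(character(0))
  raw <- toupper(trimws(as.character(x)))
  out <- character(length(raw))
  for (i in seq_along(raw)) {
    v <- raw[i]
    if (!(v %in% .LABELS) && !(v %in% names(.LABEL_ALIASES))) {
      v2 <- gsub(" ", "", v)   # "LVH 1" -> "LVH1"
      if (v2 %in% .LABELS || v2 %in% names(.LABEL_ALIASES)) v <- v2
    }
    if (v %in% .LABELS) {
      out[i] <- v
    } else if (v %in% names(.LABEL_ALIASES)) {
      out[i] <- .LABEL_ALIASES[[v]]
    } else {
      stop("Unknown heart-state label: '", x[i],
           "'. The label set is closed; see heart_state_labels().",
           call. = FALSE)
    }
  }
  out
}
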