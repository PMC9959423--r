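#' Staging thresholds
#'
#' Thresholds of the rule-based fluorosis classifier: `theta1` < `theta2`
#' < `theta3` partition the opaque fraction, `delta` bounds the brown
#' fraction considered negligible.  Defaults (0.05, 0.1, 0.3, 0.007)
#' reflect clinical practice: up to 5% opaque enamel is normal
#' regardless of apparent brown (small brown readings at low opacity are
#' almost always shadow artifacts), up to 10% opaque with <= 0.7% brown
#' is still normal, up to 30% opaque is Stage 1, more is Stage 2, and
#' any appreciable brown staining alongside opacity is Stage 3.
#'
#' @param theta1,theta2,theta3 Opaque-fraction thresholds with
#'   `0 <= theta1 < theta2 < theta3 <= 1`.
#' @param delta Brown-fraction threshold in [0, 1].
#' @return List of class `stage_thresholds`.
#' @export
stage_thresholds <- function(theta1 = 0.05, theta2 = 0.1, theta3 = 0.3,
                             delta = 0.007) {
  stopifnot(theta1 >= 0, theta1 < theta2, theta2 < theta3, theta3 <= 1,
            delta >= 0, delta <= 1)
  structure(list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 delta = delta),
            class = "stage_thresholds")
}

#' Rule-based fluorosis staging
#'
#' Grades an image from its opaque and brown pixel fractions, evaluated
#' strictly in order: Normal if `r_opaque <= theta1`; Normal if
#' `r_opaque <= theta2` and `r_brown <= delta`; Stage 1 if
#' `r_opaque <= theta3` and `r_brown <= delta`; Stage 2 if
#' `r_brown <= delta`; otherwise Stage 3.  The first branch makes tiny
#' opaque areas unconditionally normal, so spurious brown pixels (e.g.
#' from shadows) cannot escalate an otherwise healthy tooth to Stage 3.
#'
#' @param r_opaque,r_brown Fractions in [0, 1] (vectorized).
#' @param thresholds A [stage_thresholds()].
#' @return Character vector of stages (see [stage_labels()]).
#' @export
classify_fluorosis <- function(r_opaque, r_brown,
                               thresholds = stage_thresholds()) {
  check_ratios(r_opaque, r_brown)
  th <- thresholds
  ifelse(r_opaque <= th$theta1, "Normal",
  ifelse(r_opaque <= th$theta2 & r_brown <= th$delta, "Normal",
  ifelse(r_opaque <= th$theta3 & r_brown <= th$delta, "Stage 1",
  ifelse(r_brown <= th$delta, "Stage 2", "Stage 3"))))
}

#' Staging rule without the low-opacity shortcut
#'
#' Variant of [classify_fluorosis()] with the first branch removed, as
#' used by earlier rule-based systems: a healthy tooth with a few
#' shadow-induced brown pixels can then be escalated to Stage 3.  Kept
#' for ablation comparisons.
#'
#' @inheritParams classify_fluorosis
#' @return Character vector of stages.
#' @export
classify_fluorosis_ablated <- function(r_opaque, r_brown,
                                       thresholds = stage_thresholds()) {
  check_ratios(r_opaque, r_brown)
  th <- thresholds
  ifelse(r_opaque <= th$theta2 & r_brown <= th$delta, "Normal",
  ifelse(r_opaque <= th$theta3 & r_brown <= th$delta, "Stage 1",
  ifelse(r_brown <= th$delta, "Stage 2", "Stage 3")))
}

check_ratios <- function(r_opaque, r_brown) {
  if (any(!is.finite(r_opaque)) || any(!is.finite(r_brown)) ||
      any(r_opaque < 0 | r_opaque > 1) || any(r_brown < 0 | r_brown > 1))
    stop("r_opaque and r_brown must lie in [0, 1]")
  invisible(NULL)
}
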