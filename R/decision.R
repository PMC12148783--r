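#' Default decision-rule configuration
#'
#' Numeric thresholds of the clinic's documented bladder and rectum setup
#' rules: the bladder at treatment should hold at least two-thirds of its
#' planning volume; a rectum distended anteriorly past the expanded (5 mm)
#' planning rectum on at least three axial slices is flagged for review; an
#' anterior/posterior couch shift to spare the rectum is capped at 4 mm.
#' Only the textually documented rules ship as defaults — clinics can extend
#' the chart via this configuration rather than the package inventing
#' branches.
#'
#' @param bladder_min_ratio minimum acceptable bladder volume ratio
#'   (fraction of the planning volume; default 2/3).
#' @param distension_min_slices slice-count trigger for the rectum flag
#'   (default 3).
#' @param ap_shift_cap_mm maximum anterior/posterior couch shift, mm
#'   (default 4).
#' @param actions named character vector of recommended-action strings for
#'   categories \code{B2}, \code{B1N}, \code{B1Y}, \code{no-flag},
#'   \code{flagged-for-review}.
#' @return A list of class \code{decision_rules}.
#' @export
decision_rules <- function(bladder_min_ratio = 2 / 3,
                           distension_min_slices = 3L,
                           ap_shift_cap_mm = 4,
                           actions = NULL) {
  default_actions <- c(
    "B2" = "proceed with treatment",
    "B1N" = "proceed; review small-bowel dose before treatment",
    # B1Y semantics inferred from the documented action list; see vignette
    "B1Y" = "task radiation oncologist for review",
    "no-flag" = "proceed with treatment",
    "flagged-for-review" = paste0(
      "candidate for anterior couch shift (cap ", ap_shift_cap_mm,
      " mm); otherwise task radiation oncologist for review"))
  if (!is.null(actions)) default_actions[names(actions)] <- actions
  structure(list(bladder_min_ratio = bladder_min_ratio,
                 distension_min_slices = as.integer(distension_min_slices),
                 ap_shift_cap_mm = ap_shift_cap_mm,
                 actions = default_actions),
            class = "decision_rules")
}

#' Observations feeding the setup decision rules
#'
#' @param bladder_comparison a \code{\link{compare_volumes}} result for the
#'   bladder, or NULL.
#' @param small_bowel_in_80pct_isodose_increased operator-supplied flag:
#'   has small-bowel volume inside the 80\% isodose increased versus
#'   planning? (Small bowel is not auto-contoured; the CBCT field of view
#'   often excludes it, so this stays a human input.)
#' @param distension_slices anterior rectal distension slice count
#'   (\code{\link{anterior_distension_slices}}), or NA.
#' @param applied_ap_shift_mm anterior/posterior couch shift applied, mm.
#' @param rules a \code{\link{decision_rules}} (for the shift-cap check).
#' @return A list of class \code{setup_observation}.
#' @export
setup_observation <- function(bladder_comparison = NULL,
                              small_bowel_in_80pct_isodose_increased = FALSE,
                              distension_slices = NA_integer_,
                              applied_ap_shift_mm = 0,
                              rules = decision_rules()) {
  if (abs(applied_ap_shift_mm) > rules$ap_shift_cap_mm + 1e-9)
    stop(sprintf("applied A/P shift %.1f mm exceeds the %.1f mm cap",
                 applied_ap_shift_mm, rules$ap_shift_cap_mm))
  structure(list(bladder_comparison = bladder_comparison,
                 small_bowel_flag = isTRUE(small_bowel_in_80pct_isodose_increased),
                 distension_slices = distension_slices,
                 applied_ap_shift_mm = applied_ap_shift_mm),
            class = "setup_observation")
}

#' Bladder setup rule
#'
#' Volume ratio at least the configured minimum (default 2/3 of the planning
#' volume) gives category B2 (proceed). Below the minimum, the category is
#' B1N when small-bowel dose has not increased (proceed after the bowel-dose
#' review) and B1Y when it has (oncologist review).
#'
#' @param obs a \code{\link{setup_observation}} with a bladder comparison.
#' @param rules a \code{\link{decision_rules}}.
#' @return list(category, action, trace).
#' @export
bladder_rule <- function(obs, rules = decision_rules()) {
  stopifnot(inherits(obs, "setup_observation"))
  if (is.null(obs$bladder_comparison))
    stop("bladder volume comparison is required for the bladder rule")
  ratio <- obs$bladder_comparison$ratio_pct / 100
  # small tolerance so that an exact two-thirds filling classifies as B2
  # despite floating-point noise in the percent conversion
  if (ratio >= rules$bladder_min_ratio - 1e-9) {
    cat_ <- "B2"
    trace <- sprintf("bladder ratio %.1f%% >= %.1f%% -> B2",
                     100 * ratio, 100 * rules$bladder_min_ratio)
  } else if (!obs$small_bowel_flag) {
    cat_ <- "B1N"
    trace <- sprintf("bladder ratio %.1f%% < %.1f%%, small bowel not increased -> B1N",
                     100 * ratio, 100 * rules$bladder_min_ratio)
  } else {
    cat_ <- "B1Y"
    trace <- sprintf("bladder ratio %.1f%% < %.1f%%, small bowel increased -> B1Y",
                     100 * ratio, 100 * rules$bladder_min_ratio)
  }
  list(category = cat_, action = unname(rules$actions[cat_]), trace = trace)
}

#' Rectum setup rule
#'
#' Flags the setup for review when the daily rectum distends anteriorly past
#' the expanded planning rectum on at least the configured number of axial
#' slices (default 3).
#'
#' @param obs a \code{\link{setup_observation}} with a distension count.
#' @param rules a \code{\link{decision_rules}}.
#' @return list(flagged, category, action, trace).
#' @export
rectum_rule <- function(obs, rules = decision_rules()) {
  stopifnot(inherits(obs, "setup_observation"))
  if (is.na(obs$distension_slices))
    stop("anterior distension slice count is required for the rectum rule")
  flagged <- obs$distension_slices >= rules$distension_min_slices
  cat_ <- if (flagged) "flagged-for-review" else "no-flag"
  list(flagged = flagged, category = cat_,
       action = unname(rules$actions[cat_]),
       trace = sprintf("anterior distension on %d slice(s) (trigger >= %d) -> %s",
                       obs$distension_slices, rules$distension_min_slices, cat_))
}

#' Run both setup rules on one observation
#'
#' @param obs a \code{\link{setup_observation}}.
#' @param rules a \code{\link{decision_rules}}.
#' @return An object of class \code{decision_outcome}: bladder category,
#'   rectum flag, recommended actions and the ordered rule trace.
#' @export
evaluate_decision <- function(obs, rules = decision_rules()) {
  trace <- character(0)
  bladder <- if (!is.null(obs$bladder_comparison)) {
    b <- bladder_rule(obs, rules)
    trace <- c(trace, b$trace)
    b
  } else NULL
  rectum <- if (!is.na(obs$distension_slices)) {
    r <- rectum_rule(obs, rules)
    trace <- c(trace, r$trace)
    r
  } else NULL
  structure(list(
    bladder_category = if (is.null(bladder)) NA_character_ else bladder$category,
    bladder_action = if (is.null(bladder)) NA_character_ else bladder$action,
    rectum_flagged = if (is.null(rectum)) NA else rectum$flagged,
    rectum_category = if (is.null(rectum)) NA_character_ else rectum$category,
    rectum_action = if (is.null(rectum)) NA_character_ else rectum$action,
    trace = trace), class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat("decision_outcome:\n")
  for (t in x$trace) cat("  ", t, "\n", sep = "")
  invisible(x)
}

#' Cross-tabulate decision-rule categories against metric violations
#'
#' The audit the workflow automates: for each goal metric, how often did the
#' relevant setup rule fire on fractions with minor/major violations? Returns
#' the contingency counts and each rule's sensitivity for major violations
#' per metric (proportion of major-violation fractions the rule flagged;
#' \code{NaN} when a metric had no majors).
#'
#' @param decisions list of \code{\link{decision_outcome}}, one per fraction.
#' @param assessments list of \code{\link{assess_fraction}} results, aligned
#'   with \code{decisions}.
#' @return A list with \code{bladder} and \code{rectum} data.frames (metric,
#'   n_major, n_major_flagged, sensitivity_major, n_minor, n_optimal) and
#'   \code{overall_concordance} (proportion of fractions where "any rule
#'   fired" agrees with "any violation present").
#' @export
audit_concordance <- function(decisions, assessments) {
  if (length(decisions) != length(assessments))
    stop("decisions and assessments must be aligned by fraction")
  n <- length(decisions)
  bladder_fired <- vapply(decisions, function(d)
    isTRUE(d$bladder_category %in% c("B1N", "B1Y")), logical(1))
  rectum_fired <- vapply(decisions, function(d)
    isTRUE(d$rectum_flagged), logical(1))

  tab_for <- function(structure, fired) {
    metrics <- unique(unlist(lapply(assessments, function(a)
      a$metrics$metric[a$metrics$structure == structure])))
    rows <- lapply(metrics, function(m) {
      cls <- vapply(assessments, function(a) {
        sel <- a$metrics$structure == structure & a$metrics$metric == m
        if (any(sel)) a$metrics$class[sel][1] else NA_character_
      }, character(1))
      major <- !is.na(cls) & cls == "major"
      data.frame(metric = m,
                 n_major = sum(major),
                 n_major_flagged = sum(major & fired),
                 sensitivity_major = if (sum(major)) sum(major & fired) / sum(major) else NaN,
                 n_minor = sum(!is.na(cls) & cls == "minor"),
                 n_optimal = sum(!is.na(cls) & cls == "optimal"),
                 stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(metric = character(0), n_major = integer(0),
                 n_major_flagged = integer(0), sensitivity_major = numeric(0),
                 n_minor = integer(0), n_optimal = integer(0))
  }

  any_fired <- bladder_fired | rectum_fired
  any_violation <- vapply(assessments, function(a)
    !is.na(a$fraction_class) && a$fraction_class != "optimal", logical(1))
  list(bladder = tab_for("Bladder", bladder_fired),
       rectum = tab_for("Rectum", rectum_fired),
       overall_concordance = if (n) mean(any_fired == any_violation) else NaN)
}
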