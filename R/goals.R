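.CLASS_LEVELS <- c("optimal", "minor", "major")

#' The default two-tier planning-goal table (40 Gy / 5 fractions)
#'
#' Prostate SABR planning goals for a 40 Gy in 5 fractions prescription, as a
#' data frame with one row per (structure, metric). Each goal has a primary
#' (preferred) limit and, where the protocol defines one, a looser secondary
#' (mandatory) limit; meeting the primary is optimal, failing the primary but
#' meeting the secondary is a minor violation, failing the secondary (or
#' failing a primary that has no secondary) is a major violation. The CTV
#' coverage goal relaxes the dose level rather than the limit
#' (V40Gy >= 95\% preferred, V39.2Gy >= 95\% mandatory), encoded via
#' \code{secondary_dose_level_gy}. Target (CTV/PTV) rows are marked
#' \code{target = TRUE} and are excluded from the default assessment profile:
#' with implanted fiducial alignment, target coverage is not the online
#' decision driver; organ-at-risk sparing is.
#'
#' @param prescription_gy prescription dose (default 40).
#' @param fractions number of fractions (default 5).
#' @return A \code{goal_table}: a data.frame with columns \code{structure},
#'   \code{metric}, \code{kind}, \code{dose_level_gy}, \code{units},
#'   \code{direction}, \code{primary}, \code{secondary},
#'   \code{secondary_dose_level_gy}, \code{target}, and attributes
#'   \code{prescription_gy}, \code{fractions}.
#' @export
default_goal_table <- function(prescription_gy = 40, fractions = 5) {
  g <- function(structure, metric, kind, level, units, direction, primary,
                secondary = NA_real_, sec_level = NA_real_, target = FALSE) {
    data.frame(structure = structure, metric = metric, kind = kind,
               dose_level_gy = level, units = units, direction = direction,
               primary = primary, secondary = secondary,
               secondary_dose_level_gy = sec_level, target = target,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    g("CTV", "V40Gy", "V", 40, "pct", "ge", 95, 95, 39.2, TRUE),
    g("PTV", "V36.25Gy", "V", 36.25, "pct", "ge", 95, target = TRUE),
    g("Rectum + 5 mm", "Dmax", "Dmax", NA, "pct_rx", "le", 105, 107),
    g("Rectum", "V36Gy", "V", 36, "cm3", "le", 1, 2),
    g("Rectum", "V33Gy", "V", 33, "pct", "le", 10, 12.5),
    g("Rectum", "V29Gy", "V", 29, "pct", "le", 20, 22.5),
    g("Rectum", "V18Gy", "V", 18, "pct", "le", 40, 50),
    g("Sigmoid", "V30Gy", "V", 30, "cm3", "le", 1),
    g("Sigmoid", "V18Gy", "V", 18, "cm3", "le", 5),
    g("Bladder", "V37Gy", "V", 37, "cm3", "le", 5, 10),
    g("Bladder", "V36Gy", "V", 36, "pct", "le", 5, 10),
    g("Bladder", "V33Gy", "V", 33, "pct", "le", 10, 20),
    g("Bladder", "V18Gy", "V", 18, "pct", "le", 30, 45),
    g("Penile Bulb", "V30Gy", "V", 30, "pct", "le", 50),
    g("Femoral Head L", "V14Gy", "V", 14, "pct", "le", 5),
    g("Femoral Head R", "V14Gy", "V", 14, "pct", "le", 5)
  )
  as_goal_table(tab, prescription_gy = prescription_gy, fractions = fractions)
}

#' Validate and class a data frame as a goal table
#'
#' @param tab data.frame with the columns of \code{\link{default_goal_table}}.
#' @param prescription_gy prescription dose in Gy.
#' @param fractions number of fractions.
#' @return A validated \code{goal_table}.
#' @export
as_goal_table <- function(tab, prescription_gy = 40, fractions = 5) {
  needed <- c("structure", "metric", "kind", "dose_level_gy", "units",
              "direction", "primary", "secondary")
  if (!all(needed %in% names(tab)))
    stop("goal table missing columns: ",
         paste(setdiff(needed, names(tab)), collapse = ", "))
  if (is.null(tab$secondary_dose_level_gy))
    tab$secondary_dose_level_gy <- NA_real_
  if (is.null(tab$target)) tab$target <- FALSE
  if (anyDuplicated(tab[, c("structure", "metric")]))
    stop("duplicate (structure, metric) pair in goal table")
  if (!all(tab$direction %in% c("le", "ge")))
    stop("direction must be 'le' or 'ge'")
  if (!all(tab$kind %in% c("V", "Dmax", "D")))
    stop("kind must be 'V', 'D' or 'Dmax'")
  has_sec <- !is.na(tab$secondary)
  same_level <- has_sec & is.na(tab$secondary_dose_level_gy)
  bad <- same_level &
    ifelse(tab$direction == "le", tab$secondary <= tab$primary,
           tab$secondary >= tab$primary)
  if (any(bad))
    stop("secondary limit must be strictly looser than primary for: ",
         paste(tab$metric[bad], collapse = ", "))
  relaxed <- has_sec & !is.na(tab$secondary_dose_level_gy)
  bad2 <- relaxed &
    ifelse(tab$direction == "ge",
           tab$secondary_dose_level_gy >= tab$dose_level_gy,
           tab$secondary_dose_level_gy <= tab$dose_level_gy)
  if (any(bad2))
    stop("secondary dose level must relax the primary level for: ",
         paste(tab$metric[bad2], collapse = ", "))
  structure(tab, class = c("goal_table", "data.frame"),
            prescription_gy = prescription_gy, fractions = fractions)
}

#' Read / write a goal table as CSV
#'
#' The file is a plain CSV of the goal-table columns; prescription and
#' fraction number ride along as commented header lines.
#'
#' @param gt a \code{goal_table}.
#' @param path file path.
#' @return \code{read_goal_table} returns a \code{goal_table};
#'   \code{write_goal_table} returns \code{path} invisibly.
#' @export
write_goal_table <- function(gt, path) {
  stopifnot(inherits(gt, "goal_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# prescription_gy=%g", attr(gt, "prescription_gy")), con)
  writeLines(sprintf("# fractions=%d", attr(gt, "fractions")), con)
  utils::write.csv(as.data.frame(gt), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_goal_table
#' @export
read_goal_table <- function(path) {
  hdr <- readLines(path, n = 2L)
  rx <- as.numeric(sub("# prescription_gy=", "", hdr[1], fixed = TRUE))
  fx <- as.integer(sub("# fractions=", "", hdr[2], fixed = TRUE))
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_goal_table(tab, prescription_gy = rx, fractions = fx)
}

#' Classify a metric value against a two-tier goal
#'
#' Comparison is inclusive at the printed limit: a value exactly equal to the
#' primary limit is optimal. Failing a primary that has no secondary is a
#' major violation (those rows are mandatory). For goals whose secondary tier
#' relaxes the dose level (CTV coverage), supply the metric recomputed at the
#' secondary level via \code{secondary_value}.
#'
#' @param value the metric value, in the goal's units.
#' @param goal one row of a \code{goal_table} (data.frame row or list).
#' @param secondary_value metric value at the secondary dose level; defaults
#'   to \code{value}.
#' @return \code{"optimal"}, \code{"minor"} or \code{"major"}.
#' @export
classify_metric <- function(value, goal, secondary_value = value) {
  if (!is.finite(value)) stop("metric value must be finite")
  meets <- function(v, lim) {
    if (goal$direction == "le") v <= lim else v >= lim
  }
  if (meets(value, goal$primary)) return("optimal")
  if (!is.na(goal$secondary) && meets(secondary_value, goal$secondary))
    return("minor")
  "major"
}

worst_class <- function(classes) {
  if (length(classes) == 0L) return(NA_character_)
  .CLASS_LEVELS[max(match(classes, .CLASS_LEVELS))]
}

#' Evaluate one metric of a goal row from raw voxel doses
#'
#' @param goal one goal-table row.
#' @param doses per-voxel doses, Gy.
#' @param voxel_volume_cm3 voxel volume.
#' @param prescription_gy prescription for percent-of-prescription outputs.
#' @return list(value, secondary_value).
#' @keywords internal
evaluate_goal_metric <- function(goal, doses, voxel_volume_cm3,
                                 prescription_gy = 40) {
  if (goal$kind == "V") {
    value <- metric_V(doses, voxel_volume_cm3, goal$dose_level_gy,
                      units = if (goal$units == "cm3") "cm3" else "pct")
    sec_value <- if (!is.na(goal$secondary_dose_level_gy))
      metric_V(doses, voxel_volume_cm3, goal$secondary_dose_level_gy,
               units = if (goal$units == "cm3") "cm3" else "pct")
    else value
  } else if (goal$kind == "Dmax") {
    value <- metric_Dmax(doses,
                         output = if (goal$units == "pct_rx") "pct_rx" else "gy",
                         prescription_gy = prescription_gy)
    sec_value <- value
  } else {
    stop("unsupported goal kind: ", goal$kind)
  }
  list(value = value, secondary_value = sec_value)
}

#' Assess one treatment fraction against the goal table
#'
#' Computes every applicable goal metric from the per-structure voxel doses,
#' classifies each as optimal / minor / major, and rolls the classes up per
#' structure and for the whole fraction (the worst constituent class wins).
#' Per-fraction doses are compared against the full-course limits without
#' scaling — the conservative worst-case reading that assumes the observed
#' daily dose pattern repeats every fraction. Goals for structures not
#' supplied are skipped with a warning; target (CTV/PTV) goals are skipped
#' unless \code{include_targets = TRUE}. The derived "Rectum + 5 mm" goal is
#' evaluated when doses are supplied under that name.
#'
#' @param doses_by_structure named list; each element a list with
#'   \code{doses} (Gy vector) and \code{voxel_volume_cm3} (as returned by
#'   \code{\link{structure_doses}}), optionally \code{out_of_grid_fraction}.
#' @param goal_table a \code{goal_table} (default
#'   \code{\link{default_goal_table}()}).
#' @param volume_comparisons optional named list of
#'   \code{\link{compare_volumes}} results per OAR.
#' @param decision optional \code{\link{decision_outcome}} to attach.
#' @param include_targets evaluate CTV/PTV goals too (default FALSE).
#' @return An object of class \code{fraction_assessment}: list with
#'   \code{metrics} (data.frame: structure, metric, value, units, primary,
#'   secondary, class), \code{structure_worst}, \code{fraction_class},
#'   \code{volume_comparisons}, \code{decision}, \code{out_of_grid}.
#' @export
assess_fraction <- function(doses_by_structure,
                            goal_table = default_goal_table(),
                            volume_comparisons = list(),
                            decision = NULL,
                            include_targets = FALSE) {
  stopifnot(inherits(goal_table, "goal_table"))
  rx <- attr(goal_table, "prescription_gy")
  rows <- list()
  skipped <- character(0)
  for (r in seq_len(nrow(goal_table))) {
    goal <- as.list(goal_table[r, ])
    if (goal$target && !include_targets) next
    sd <- doses_by_structure[[goal$structure]]
    if (is.null(sd)) {
      skipped <- c(skipped, goal$structure)
      next
    }
    ev <- evaluate_goal_metric(goal, sd$doses, sd$voxel_volume_cm3, rx)
    cls <- classify_metric(ev$value, goal, ev$secondary_value)
    rows[[length(rows) + 1L]] <- data.frame(
      structure = goal$structure, metric = goal$metric, value = ev$value,
      units = goal$units, primary = goal$primary, secondary = goal$secondary,
      class = cls, stringsAsFactors = FALSE)
  }
  skipped <- setdiff(unique(skipped), names(doses_by_structure))
  if (length(skipped))
    warning("no doses supplied for: ", paste(skipped, collapse = ", "),
            " (goals skipped)")
  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(0), metric = character(0),
               value = numeric(0), units = character(0),
               primary = numeric(0), secondary = numeric(0),
               class = character(0), stringsAsFactors = FALSE)
  structure_worst <- if (nrow(metrics))
    vapply(split(metrics$class, metrics$structure), worst_class, character(1))
  else stats::setNames(character(0), character(0))
  oog <- vapply(doses_by_structure, function(sd) {
    f <- sd$out_of_grid_fraction
    if (is.null(f)) NA_real_ else f
  }, numeric(1))
  structure(list(metrics = metrics,
                 structure_worst = structure_worst,
                 fraction_class = worst_class(metrics$class),
                 volume_comparisons = volume_comparisons,
                 decision = decision,
                 out_of_grid = oog,
                 config_hash = goal_table_hash(goal_table)),
            class = "fraction_assessment")
}

#' @export
print.fraction_assessment <- function(x, ...) {
  cat("fraction_assessment: ",
      if (is.na(x$fraction_class)) "no metrics" else x$fraction_class, "\n",
      sep = "")
  if (nrow(x$metrics)) {
    df <- x$metrics
    df$value <- signif(df$value, 4)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$decision))
    cat("decision: bladder ", x$decision$bladder_category,
        if (isTRUE(x$decision$rectum_flagged)) ", rectum flagged" else "",
        "\n", sep = "")
  invisible(x)
}
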