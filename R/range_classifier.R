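#' Axis-aligned On.Ar x H.Ar range rectangle
#'
#' @param onar_interval,har_interval Length-2 numeric `[min, max]` in
#'   square micrometres; degenerate (point) intervals are allowed for
#'   single-member groups.
#' @param label Rectangle label (group, taxon or fragment ID).
#' @param basis `"group_member_means"` or `"fragment_shrinkage_bounds"`.
#' @return Object of class `range_rectangle`.
#' @export
range_rectangle <- function(onar_interval, har_interval, label,
                            basis = c("group_member_means",
                                      "fragment_shrinkage_bounds")) {
  basis <- match.arg(basis)
  for (iv in list(onar_interval, har_interval)) {
    if (length(iv) != 2 || anyNA(iv) || iv[1] > iv[2]) {
      abort_stage("range_rectangle", "intervals must be [min, max] with min <= max")
    }
  }
  structure(
    list(onar_interval = as.numeric(onar_interval),
         har_interval = as.numeric(har_interval),
         label = label, basis = basis),
    class = "range_rectangle"
  )
}

#' @export
print.range_rectangle <- function(x, ...) {
  cat(sprintf("Rectangle '%s' (%s)\n  On.Ar [%s, %s] um^2\n  H.Ar  [%s, %s] um^2\n",
              x$label, x$basis,
              format(round_report(x$onar_interval[1])),
              format(round_report(x$onar_interval[2])),
              format(round_report(x$har_interval[1])),
              format(round_report(x$har_interval[2]))))
  invisible(x)
}

#' Range rectangle of a taxon group
#'
#' The group's rectangle spans the minimum-to-maximum of member specimen
#' mean On.Ar (x axis) and mean H.Ar (y axis). Members lacking either
#' metric (plexiform-only rows) are dropped; at least one member with both
#' metrics is required.
#'
#' @param records `reference_db` rows belonging to one group (or taxon).
#' @param label Label for the rectangle (defaults to the single taxon name
#'   if unambiguous).
#' @return A `range_rectangle` with basis `"group_member_means"` and an
#'   attribute `members` listing the specimen IDs used.
#' @examples
#' groups <- group_records(load_reference())
#' group_rectangle(groups$proboscideans, "proboscideans")$onar_interval
#' @export
group_rectangle <- function(records, label = NULL) {
  keep <- !is.na(records$mean_onar) & !is.na(records$mean_har)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) {
    abort_stage("group_rectangle", "no member has both On.Ar and H.Ar means")
  }
  if (is.null(label)) {
    taxa <- unique(records$taxon)
    label <- if (length(taxa) == 1) taxa else paste(taxa, collapse = "+")
  }
  rect <- range_rectangle(
    onar_interval = range(records$mean_onar),
    har_interval = range(records$mean_har),
    label = label, basis = "group_member_means"
  )
  attr(rect, "members") <- records$specimen_id
  rect
}

#' Range rectangle of a fragment's shrinkage interval
#'
#' The fragment's rectangle runs from the lower-bound means (no shrinkage,
#' 500-600 degrees C; lower-left corner) to the upper-bound means
#' (shrinkage at ~700 degrees C; upper-right corner) on both axes.
#'
#' @param interval An `interval_summary` from [apply_shrinkage_bounds()].
#' @return A `range_rectangle` with basis `"fragment_shrinkage_bounds"`.
#' @export
fragment_rectangle <- function(interval) {
  if (!inherits(interval, "interval_summary")) {
    abort_stage("fragment_rectangle", "interval must be an interval_summary")
  }
  range_rectangle(
    onar_interval = c(interval$lower$mean_onar, interval$upper$mean_onar),
    har_interval = c(interval$lower$mean_har, interval$upper$mean_har),
    label = interval$specimen_id, basis = "fragment_shrinkage_bounds"
  )
}

#' Do two range rectangles overlap?
#'
#' Closed-interval overlap: rectangles sharing only an edge or corner still
#' count as overlapping. TRUE iff the intervals intersect on both axes.
#'
#' @param a,b `range_rectangle` objects.
#' @return Logical scalar. Symmetric and reflexive.
#' @export
rectangles_overlap <- function(a, b) {
  if (!inherits(a, "range_rectangle") || !inherits(b, "range_rectangle")) {
    abort_stage("rectangles_overlap", "arguments must be range_rectangle objects")
  }
  iv_overlap <- function(u, v) u[1] <= v[2] && v[1] <= u[2]
  iv_overlap(a$onar_interval, b$onar_interval) &&
    iv_overlap(a$har_interval, b$har_interval)
}

#' Classify a fragment against taxon-group rectangles and statistics
#'
#' Combines the geometric and statistical evidence per group:
#' \itemize{
#'   \item \strong{candidate}: the fragment rectangle overlaps the group
#'     rectangle;
#'   \item \strong{excluded}: no overlap AND every member specimen with
#'     data is significantly different from the fragment on at least one
#'     metric under BOTH shrinkage scenarios;
#'   \item \strong{indeterminate}: no overlap but the statistical
#'     criterion is not met for every member.
#' }
#' With `criterion = "either"` a group is excluded by no-overlap alone or
#' by the statistical criterion alone.
#'
#' @param frag_rect Fragment `range_rectangle` (from
#'   [fragment_rectangle()]).
#' @param group_rects Named list of group `range_rectangle`s, each carrying
#'   a `members` attribute (from [group_rectangle()]).
#' @param tables Named list with both scenarios' comparison tables:
#'   `no_shrinkage` and `shrinkage_700` (from [build_comparison_table()]).
#' @param criterion `"both"` (default) or `"either"`; see above.
#' @param qualitative_flags Optional character vector of notes carried into
#'   the report (e.g. a plexiform-bone observation).
#' @return Object of class `classification_report`: list with
#'   `fragment_id`, `candidates`, `excluded` (named list of reason
#'   strings), `indeterminate`, `qualitative_flags`.
#' @export
classify_fragment <- function(frag_rect, group_rects, tables,
                              criterion = c("both", "either"),
                              qualitative_flags = character(0)) {
  criterion <- match.arg(criterion)
  needed <- c("no_shrinkage", "shrinkage_700")
  if (!all(needed %in% names(tables))) {
    abort_stage("classify_fragment",
                paste0("missing scenario table(s): ",
                       paste(setdiff(needed, names(tables)), collapse = ", ")))
  }
  frag_id <- frag_rect$label
  candidates <- character(0)
  excluded <- list()
  indeterminate <- character(0)

  for (gname in names(group_rects)) {
    grect <- group_rects[[gname]]
    if (rectangles_overlap(frag_rect, grect)) {
      candidates <- c(candidates, gname)
      next
    }
    members <- attr(grect, "members")
    sig_all <- all_members_distinguished(frag_id, members, tables)
    if (is.na(sig_all)) {
      indeterminate <- c(indeterminate, gname)
    } else if (sig_all) {
      if (criterion == "both" || criterion == "either") {
        excluded[[gname]] <- paste0(
          "no rectangle overlap; every member specimen significantly ",
          "different on >= 1 metric under both shrinkage scenarios")
      }
    } else if (criterion == "either") {
      excluded[[gname]] <- "no rectangle overlap"
    } else {
      indeterminate <- c(indeterminate, gname)
    }
  }
  structure(
    list(fragment_id = frag_id,
         candidates = candidates,
         excluded = excluded,
         indeterminate = indeterminate,
         qualitative_flags = qualitative_flags),
    class = "classification_report"
  )
}

# TRUE iff every member specimen with any usable cell is significant on
# >= 1 metric vs this fragment in BOTH scenario tables; NA when no member
# has usable cells.
all_members_distinguished <- function(frag_id, members, tables) {
  any_data <- FALSE
  for (spec in members) {
    per_scenario <- vapply(tables, function(tb) {
      cells <- tb[tb$fragment == frag_id & tb$reference_specimen == spec, ]
      if (nrow(cells) == 0 || all(is.na(cells$significant))) return(NA)
      any(cells$significant, na.rm = TRUE)
    }, logical(1))
    if (all(is.na(per_scenario))) next
    any_data <- TRUE
    if (!all(per_scenario, na.rm = TRUE)) return(FALSE)
  }
  if (!any_data) return(NA)
  TRUE
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Fragment %s\n", x$fragment_id))
  cat("  candidates   : ",
      if (length(x$candidates)) paste(x$candidates, collapse = ", ") else "(none)",
      "\n", sep = "")
  cat("  excluded     : ",
      if (length(x$excluded)) paste(names(x$excluded), collapse = ", ") else "(none)",
      "\n", sep = "")
  cat("  indeterminate: ",
      if (length(x$indeterminate)) paste(x$indeterminate, collapse = ", ") else "(none)",
      "\n", sep = "")
  for (flag in x$qualitative_flags) cat("  note: ", flag, "\n", sep = "")
  invisible(x)
}

# Taxa in which plexiform bone is commonly developed; used for the
# qualitative note attached to plexiform-bearing fragments.
PLEXIFORM_TAXA_NOTE <- paste(
  "plexiform bone present: consistent with artiodactyls (e.g. wild boar,",
  "deer, cattle), perissodactyls (e.g. horse) and some carnivores (e.g.",
  "dog, bear); not reported in adult human bone")

#' Build rectangles for every taxon group (or taxon)
#'
#' Convenience wrapper producing the named list of rectangles that
#' [classify_fragment()] consumes. Per the packaged analysis design the
#' rectangle basis uses ALL reference rows (including external-literature
#' rows), while the statistical stage uses the filtered set; pass a
#' filtered `reference_db` to change that.
#'
#' @param records A `reference_db`.
#' @param level `"group"` (order-level/body-size labels) or `"taxon"`.
#' @param taxon_groups Taxon-to-group table (used for `level = "group"`).
#' @return Named list of `range_rectangle`s with `members` attributes.
#' @export
build_group_rectangles <- function(records, level = c("group", "taxon"),
                                   taxon_groups = load_taxon_groups()) {
  level <- match.arg(level)
  parts <- if (level == "group") {
    group_records(records, taxon_groups)
  } else {
    split(records, records$taxon)
  }
  # drop partitions with no quantitative member (e.g. a plexiform-only taxon)
  parts <- Filter(function(df) any(!is.na(df$mean_onar) & !is.na(df$mean_har)),
                  parts)
  out <- lapply(names(parts), function(nm) group_rectangle(parts[[nm]], nm))
  stats::setNames(out, names(parts))
}

#' Plot fragment and group range rectangles
#'
#' Bivariate On.Ar x H.Ar plot in which each taxon group is an axis-aligned
#' rectangle spanning its member specimen means and each fragment is a
#' rectangle from its no-shrinkage (lower-left) to 700-degree
#' (upper-right) bounds.
#'
#' @param group_rects Named list of group rectangles.
#' @param frag_rects List of fragment rectangles.
#' @param log_axes Use log10 axes (default TRUE; the group means span two
#'   orders of magnitude).
#' @return A ggplot object.
#' @export
plot_range_rectangles <- function(group_rects, frag_rects, log_axes = TRUE) {
  rect_df <- function(rects, kind) {
    do.call(rbind, lapply(rects, function(r) {
      data.frame(label = r$label,
                 xmin = r$onar_interval[1], xmax = r$onar_interval[2],
                 ymin = r$har_interval[1], ymax = r$har_interval[2],
                 kind = kind, stringsAsFactors = FALSE)
    }))
  }
  df <- rbind(rect_df(group_rects, "reference group"),
              rect_df(frag_rects, "fragment"))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    xmin = .data$xmin, xmax = .data$xmax,
    ymin = .data$ymin, ymax = .data$ymax,
    colour = .data$label, linetype = .data$kind)) +
    ggplot2::geom_rect(fill = NA, linewidth = 0.6) +
    ggplot2::geom_text(ggplot2::aes(x = sqrt(.data$xmin * .data$xmax),
                                    y = .data$ymax, label = .data$label),
                       size = 2.6, vjust = -0.4, show.legend = FALSE) +
    ggplot2::labs(x = expression(On.Ar ~ (mu * m^2)),
                  y = expression(H.Ar ~ (mu * m^2)),
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  if (log_axes) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}
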