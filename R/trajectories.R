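#' Mean group trajectories through pattern space
#'
#' Mean coordinates per (group, timepoint) over the available samples along
#' two chosen pattern axes, plus the healthy-donor centroid. Timepoints with
#' no samples are omitted, never zero-filled; each cell records how many
#' samples contributed.
#'
#' Groups are `healthy`, `survived`, `died` (and `unknown` if present):
#' sepsis samples are grouped by 28-day outcome, healthy donors form their
#' own group.
#'
#' @param P pattern matrix (patterns x samples).
#' @param meta cohort metadata.
#' @param axes two pattern row indices (or names).
#' @param groups groups to summarize; default all present.
#' @return a `TrajectorySummary`: `axes`, `table` (data.frame group,
#'   timepoint, hours, mean_x, mean_y, n), `healthy_centroid`.
#' @export
group_mean_trajectory <- function(P, meta, axes, groups = NULL) {
  if (length(axes) != 2L) stop("axes must name exactly two patterns")
  if (is.character(axes)) {
    if (!all(axes %in% rownames(P))) stop("unknown pattern axis")
  } else if (any(axes < 1) || any(axes > nrow(P))) {
    stop("pattern axis index out of range")
  }
  m <- meta[meta$sample_id %in% colnames(P), , drop = FALSE]
  grp <- ifelse(m$group == "healthy", "healthy", m$outcome)
  if (is.null(groups)) groups <- unique(grp)
  absent <- setdiff(groups, grp)
  if (length(absent))
    stop("no samples for group(s): ", paste(absent, collapse = ", "))
  X <- P[axes[1], m$sample_id]
  Y <- P[axes[2], m$sample_id]
  tp <- canonical_timepoints()
  rows <- list()
  for (g in groups) {
    for (t in names(tp)) {
      sel <- grp == g & m$timepoint == t
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, timepoint = t, hours = unname(tp[t]),
        mean_x = mean(X[sel]), mean_y = mean(Y[sel]), n = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  table <- table[order(match(table$group, groups), table$hours), , drop = FALSE]
  rownames(table) <- NULL
  healthy_centroid <- if (any(grp == "healthy")) {
    c(x = mean(X[grp == "healthy"]), y = mean(Y[grp == "healthy"]))
  } else c(x = NA_real_, y = NA_real_)
  structure(list(axes = axes, table = table,
                 healthy_centroid = healthy_centroid),
            class = "TrajectorySummary")
}

#' Net displacement of a group through pattern space
#'
#' Euclidean distance between a group's first and last observed mean
#' coordinates (net movement, not path length). Groups observed at a single
#' timepoint have displacement 0.
#'
#' @param traj a `TrajectorySummary` from [group_mean_trajectory()].
#' @param group group name.
#' @return a non-negative number.
#' @export
net_displacement <- function(traj, group) {
  tb <- traj$table[traj$table$group == group, , drop = FALSE]
  if (nrow(tb) == 0L) stop("group '", group, "' not in trajectory summary")
  tb <- tb[order(tb$hours), , drop = FALSE]
  first <- c(tb$mean_x[1], tb$mean_y[1])
  last <- c(tb$mean_x[nrow(tb)], tb$mean_y[nrow(tb)])
  sqrt(sum((last - first)^2))
}

#' Per-subject paths through pattern space
#'
#' Coordinates of every subject's samples along two pattern axes, ordered by
#' collection time (hours, not file order). Subjects with a single sample
#' yield length-1 paths.
#'
#' @param P pattern matrix.
#' @param meta cohort metadata.
#' @param axes two pattern row indices (or names).
#' @return named list of data.frames (`timepoint`, `hours`, `x`, `y`), one
#'   per subject.
#' @export
subject_paths <- function(P, meta, axes) {
  if (length(axes) != 2L) stop("axes must name exactly two patterns")
  m <- meta[meta$sample_id %in% colnames(P), , drop = FALSE]
  out <- lapply(split(m, m$subject_id), function(sub) {
    sub <- sub[order(sub$hours), , drop = FALSE]
    data.frame(timepoint = sub$timepoint, hours = sub$hours,
               x = unname(P[axes[1], sub$sample_id]),
               y = unname(P[axes[2], sub$sample_id]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out
}

#' Recovery index relative to the healthy reference
#'
#' For a per-sample scalar (a pattern value or PC score), computes each
#' sample's signed distance to the healthy-donor mean in units of the
#' healthy SD, then summarizes each subject by the slope of that distance
#' against `log(hours + 1)` (or plain hours). A negative slope means
#' movement toward the healthy reference.
#'
#' @param values named numeric vector (per sample), names = sample IDs.
#' @param meta cohort metadata (must include healthy samples).
#' @param time_axis `"log_hours"` (default) or `"hours"`.
#' @return list with `per_sample` (data.frame sample_id, subject_id, hours,
#'   z), `per_subject` (data.frame subject_id, group, outcome, slope, n),
#'   and `group_mean_slope` (named vector over outcome groups).
#' @export
recovery_index <- function(values, meta, time_axis = c("log_hours", "hours")) {
  time_axis <- match.arg(time_axis)
  m <- meta[meta$sample_id %in% names(values), , drop = FALSE]
  h <- m$group == "healthy"
  if (!any(h)) stop("healthy samples are required as the reference")
  mu <- mean(values[m$sample_id[h]])
  sdv <- stats::sd(values[m$sample_id[h]])
  if (is.na(sdv) || sdv == 0) stop("healthy reference has zero variance")
  z <- (values[m$sample_id] - mu) / sdv
  per_sample <- data.frame(sample_id = m$sample_id, subject_id = m$subject_id,
                           group = m$group, outcome = m$outcome,
                           hours = m$hours, z = unname(z),
                           stringsAsFactors = FALSE)
  subj <- split(per_sample, per_sample$subject_id)
  per_subject <- do.call(rbind, lapply(subj, function(s) {
    tt <- if (time_axis == "log_hours") log(s$hours + 1) else s$hours
    slope <- if (length(unique(tt)) < 2L) NA_real_
             else unname(stats::coef(stats::lm(s$z ~ tt))[2])
    data.frame(subject_id = s$subject_id[1], group = s$group[1],
               outcome = s$outcome[1], slope = slope, n = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(per_subject) <- NULL
  sep <- per_subject[per_subject$group == "sepsis" & !is.na(per_subject$slope), ]
  group_mean_slope <- tapply(sep$slope, sep$outcome, mean)
  list(per_sample = per_sample, per_subject = per_subject,
       group_mean_slope = group_mean_slope)
}
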