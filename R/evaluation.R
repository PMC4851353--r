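# Quantitative evaluation against ground truth: per-fish-frame correctness
# labels and the four summary metrics (miss/error ratio, correct tracking
# ratio, average interruption times, correct identification ratio).

#' Label every fish-frame by matching results to ground truth
#'
#' Within each frame, result rows are matched one-to-one to truth rows by
#' minimum nose distance (Kuhn-Munkres, distances beyond `tol` forbidden).
#' A matched result is correct iff its nose lies within `tol` px of the
#' truth nose, its pose passed the cover-ratio check and, when the truth
#' carries joint chains, its joints lie within `tol` px of the truth joints
#' on average. Unmatched truth rows are misses; unmatched result rows are
#' errors.
#'
#' @param results a pose table (e.g. [trajectories_table()]): columns
#'   `frame`, `id`, `N_x`, `N_y`, `cover_ratio`, and optionally joints.
#' @param truth ground-truth table: columns `frame`, `id`, `nose_x`,
#'   `nose_y`, optionally `J1_x` ... joint columns.
#' @param tol correctness tolerance in pixels.
#' @param cover_min cover-ratio threshold a pose must have passed.
#' @return A tibble of labels: one row per truth fish-frame and per
#'   unmatched result, with columns `frame`, `truth_id`, `result_id`,
#'   `dist`, `type` (`"match"`, `"miss"`, `"error"`) and `correct`.
#' @export
match_to_truth <- function(results, truth, tol = 10, cover_min = 0.8) {
  stopifnot(nrow(truth) > 0L)
  joint_cols <- intersect(paste0("J", 1:16, "_x"), colnames(truth))
  use_joints <- length(joint_cols) > 0L &&
    all(c("J1_x", "J1_y") %in% colnames(results))
  out <- list()
  for (f in sort(unique(truth$frame))) {
    tt <- truth[truth$frame == f, , drop = FALSE]
    rr <- results[results$frame == f, , drop = FALSE]
    nt <- nrow(tt)
    nr <- nrow(rr)
    if (nr > 0L) {
      D <- outer(rr$N_x, tt$nose_x, `-`)^2 + outer(rr$N_y, tt$nose_y, `-`)^2
      D <- sqrt(D)
      C <- ifelse(D < tol, D, Inf)
      asg <- associate(C)
      matched_t <- integer(0)
      if (nrow(asg$pairs)) {
        for (r in seq_len(nrow(asg$pairs))) {
          i <- asg$pairs[r, 1]
          j <- asg$pairs[r, 2]
          ok <- D[i, j] < tol && rr$cover_ratio[i] >= cover_min
          if (ok && use_joints) {
            jd <- joint_chain_dist(rr[i, ], tt[j, ])
            if (!is.na(jd) && jd > tol) ok <- FALSE
          }
          out[[length(out) + 1L]] <- tibble(
            frame = f, truth_id = tt$id[j], result_id = rr$id[i],
            dist = D[i, j], type = "match", correct = ok)
          matched_t <- c(matched_t, j)
        }
      }
      for (j in setdiff(seq_len(nt), matched_t)) {
        out[[length(out) + 1L]] <- tibble(
          frame = f, truth_id = tt$id[j], result_id = NA_real_,
          dist = NA_real_, type = "miss", correct = FALSE)
      }
      for (i in asg$unassigned_rows) {
        out[[length(out) + 1L]] <- tibble(
          frame = f, truth_id = NA_real_, result_id = rr$id[i],
          dist = NA_real_, type = "error", correct = FALSE)
      }
    } else {
      for (j in seq_len(nt)) {
        out[[length(out) + 1L]] <- tibble(
          frame = f, truth_id = tt$id[j], result_id = NA_real_,
          dist = NA_real_, type = "miss", correct = FALSE)
      }
    }
  }
  dplyr::bind_rows(out)
}

# Mean distance between result joints and truth joints for one row pair.
joint_chain_dist <- function(rrow, trow) {
  ds <- c()
  for (i in 1:16) {
    cx <- paste0("J", i, "_x")
    cy <- paste0("J", i, "_y")
    if (!(cx %in% colnames(rrow)) || !(cx %in% colnames(trow))) break
    ds <- c(ds, sqrt((rrow[[cx]] - trow[[cx]])^2 +
                     (rrow[[cy]] - trow[[cy]])^2))
  }
  if (length(ds)) mean(ds) else NA_real_
}

#' Miss and error ratio
#'
#' Miss ratio is the number of undetected truth fish-frames over
#' `n_fish * n_frames`; error ratio is the number of spurious results over
#' the same denominator.
#'
#' @param labels label table from [match_to_truth()].
#' @param n_fish,n_frames denominators; inferred from the labels if NULL.
#' @return `list(miss_ratio, error_ratio)`.
#' @export
miss_error_ratio <- function(labels, n_fish = NULL, n_frames = NULL) {
  if (is.null(n_fish)) n_fish <- length(unique(stats::na.omit(labels$truth_id)))
  if (is.null(n_frames)) n_frames <- length(unique(labels$frame))
  denom <- n_fish * n_frames
  if (denom == 0) stop("empty evaluation: no fish-frames")
  list(miss_ratio = sum(labels$type == "miss") / denom,
       error_ratio = sum(labels$type == "error") / denom)
}

#' Correct tracking ratio
#'
#' Fraction of fish-frames tracked correctly (nose within tolerance and
#' cover check passed).
#'
#' @inheritParams miss_error_ratio
#' @return Fraction in \[0, 1\].
#' @export
ctr <- function(labels, n_fish = NULL, n_frames = NULL) {
  if (is.null(n_fish)) n_fish <- length(unique(stats::na.omit(labels$truth_id)))
  if (is.null(n_frames)) n_frames <- length(unique(labels$frame))
  sum(labels$correct) / (n_fish * n_frames)
}

# Assign each result trajectory to the truth fish it follows (majority of
# its per-frame matches); returns a tibble id, truth_id, st, ed.
assign_trajectories <- function(labels) {
  m <- labels[labels$type == "match", , drop = FALSE]
  if (!nrow(m)) {
    return(tibble(id = numeric(0), truth_id = numeric(0),
                  st = numeric(0), ed = numeric(0)))
  }
  sp <- split(m, m$result_id)
  dplyr::bind_rows(lapply(sp, function(g) {
    tibble(id = g$result_id[1],
           truth_id = as.numeric(names(which.max(table(g$truth_id)))),
           st = min(g$frame), ed = max(g$frame))
  }))
}

#' Average interruption times per fish per 100 frames
#'
#' An interruption is a frame at which a fish's trajectory ends while the
#' fish is still visible later in the sequence. The rate is the total
#' interruption count divided by `n_fish * n_frames / 100`.
#'
#' @param labels label table from [match_to_truth()].
#' @param truth ground-truth table (for each fish's last visible frame).
#' @param n_fish,n_frames denominators; inferred if NULL.
#' @return Interruptions per fish per 100 frames.
#' @export
ait <- function(labels, truth, n_fish = NULL, n_frames = NULL) {
  if (is.null(n_fish)) n_fish <- length(unique(truth$id))
  if (is.null(n_frames)) n_frames <- length(unique(truth$frame))
  traj <- assign_trajectories(labels)
  if (!nrow(traj)) return(0)
  last_seen <- vapply(split(truth$frame, truth$id), max, 0)
  interruptions <- sum(vapply(seq_len(nrow(traj)), function(r) {
    traj$ed[r] < last_seen[[as.character(traj$truth_id[r])]]
  }, logical(1)))
  interruptions / (n_fish * n_frames / 100)
}

#' Correct identification ratio after occlusion events
#'
#' For each occlusion event, the identity mapping between truth fish and
#' result trajectories is read off immediately before the event and at the
#' first frame after it where every involved fish is matched again; the
#' event counts as correct iff every involved fish carries the same
#' trajectory id on both sides.
#'
#' @param labels label table from [match_to_truth()].
#' @param events occlusion log: tibble with `start_frame`, `end_frame` and
#'   `ids` (list-column or comma-separated string of involved truth ids).
#' @return Fraction of events after which all involved fish keep their
#'   identity, or `NA` if there are no events.
#' @export
cir <- function(labels, events) {
  if (is.null(events) || nrow(events) == 0L) return(NA_real_)
  m <- labels[labels$type == "match", , drop = FALSE]
  ok <- logical(nrow(events))
  for (e in seq_len(nrow(events))) {
    ids <- event_ids(events, e)
    before <- mapping_at(m, ids, events$start_frame[e] - 1L, "before")
    after <- mapping_at(m, ids, events$end_frame[e] + 1L, "after")
    ok[e] <- !is.null(before) && !is.null(after) &&
      all(!is.na(before)) && all(!is.na(after)) &&
      identical(before, after)
  }
  mean(ok)
}

event_ids <- function(events, e) {
  v <- events$ids[[e]]
  if (is.character(v)) v <- as.numeric(strsplit(v, "[,;]")[[1]])
  as.numeric(v)
}

# Identity mapping truth_id -> result_id for the given fish at the nearest
# frame at-or-before ("before") / at-or-after ("after") `frame` where all
# of them are matched.
mapping_at <- function(m, ids, frame, direction) {
  frames <- sort(unique(m$frame))
  frames <- if (direction == "before") rev(frames[frames <= frame])
            else frames[frames >= frame]
  for (f in frames) {
    g <- m[m$frame == f & m$truth_id %in% ids, , drop = FALSE]
    if (length(unique(g$truth_id)) == length(ids)) {
      g <- g[match(ids, g$truth_id), ]
      return(setNames(g$result_id, as.character(ids)))
    }
  }
  NULL
}

#' Evaluate tracked trajectories against ground truth
#'
#' Convenience wrapper computing all metrics at once.
#'
#' @param results a pose/trajectory table.
#' @param truth ground-truth table (`frame`, `id`, `nose_x`, `nose_y`,
#'   optional joints).
#' @param events optional occlusion-event log for [cir()].
#' @param tol correctness tolerance, px.
#' @return A `fish_metrics` object: list with `miss_ratio`, `error_ratio`,
#'   `ctr`, `ait`, `cir`, `n_fish`, `n_frames` and the `labels` table.
#' @export
evaluate_tracking <- function(results, truth, events = NULL, tol = 10) {
  labels <- match_to_truth(results, truth, tol)
  n_fish <- length(unique(truth$id))
  n_frames <- length(unique(truth$frame))
  me <- miss_error_ratio(labels, n_fish, n_frames)
  structure(list(
    miss_ratio = me$miss_ratio,
    error_ratio = me$error_ratio,
    ctr = ctr(labels, n_fish, n_frames),
    ait = ait(labels, truth, n_fish, n_frames),
    cir = if (is.null(events)) NA_real_ else cir(labels, events),
    n_fish = n_fish, n_frames = n_frames,
    labels = labels
  ), class = "fish_metrics")
}

#' @export
print.fish_metrics <- function(x, ...) {
  cat("<fish_metrics> ", x$n_fish, " fish x ", x$n_frames, " frames\n", sep = "")
  cat(sprintf("  miss ratio : %.4f\n", x$miss_ratio))
  cat(sprintf("  error ratio: %.4f\n", x$error_ratio))
  cat(sprintf("  CTR        : %.4f\n", x$ctr))
  cat(sprintf("  AIT        : %.4f per fish per 100 frames\n", x$ait))
  if (is.na(x$cir)) cat("  CIR        : n/a (no occlusion events)\n")
  else cat(sprintf("  CIR        : %.4f\n", x$cir))
  invisible(x)
}

#' Tidy per-fish-frame labels of a metrics object
#'
#' @param x a `fish_metrics` object.
#' @param ... unused.
#' @return The label tibble.
#' @export
tidy.fish_metrics <- function(x, ...) x$labels

#' One-row summary of a metrics object
#'
#' @param x a `fish_metrics` object.
#' @param ... unused.
#' @return A one-row tibble with all summary metrics.
#' @export
glance.fish_metrics <- function(x, ...) {
  tibble(miss_ratio = x$miss_ratio, error_ratio = x$error_ratio,
         ctr = x$ctr, ait = x$ait, cir = x$cir,
         n_fish = x$n_fish, n_frames = x$n_frames)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
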