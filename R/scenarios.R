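# Canned study scenarios: reproducible simulation configurations used by
# the examples, the test suite and the acceptance script.

#' Schooling scenario: freely swimming fish, no occlusions
#'
#' A school of fish cruising in a square arena at a density low enough for
#' the collision-avoidance behavior to keep silhouettes from ever
#' intersecting, so every trajectory should be tracked without
#' interruption.
#'
#' @param seed simulation seed.
#' @param n_fish number of fish.
#' @param n_frames number of frames.
#' @return A [sim_config()].
#' @export
demo_schooling <- function(seed = 1L, n_fish = 5L, n_frames = 200L) {
  sim_config(n_fish = n_fish, arena = c(1400L, 1400L), n_frames = n_frames,
             seed = seed)
}

#' Crossing scenario: staged pairwise occlusions
#'
#' Ten fish in five spatially separated territories; each pair is steered
#' through one brief scripted crossing (plus one later re-crossing of the
#' last pair), producing short occlusions that terminate the involved
#' trackers and exercise the tracklet-relinking stage. The spawn layout
#' keeps the staged crossings from interfering with one another.
#'
#' @param seed simulation seed.
#' @return A [sim_config()] for a 10-fish, 370-frame sequence with six
#'   scripted pairwise crossings.
#' @export
demo_crossings <- function(seed = 2L) {
  spawn <- rbind(
    c(300, 720, 0),      c(720, 300, -pi / 2),
    c(1700, 720, pi),    c(1280, 300, -pi / 2),
    c(580, 1000, 0),     c(1000, 580, -pi / 2),
    c(300, 1280, 0),     c(720, 1700, pi / 2),
    c(1700, 1280, pi),   c(1280, 1700, pi / 2))
  crossings <- data.frame(frame = c(1, 1, 1, 1, 1, 200),
                          id1 = c(1, 3, 5, 7, 9, 9),
                          id2 = c(2, 4, 6, 8, 10, 10))
  sim_config(n_fish = 10L, arena = c(2000L, 2000L), n_frames = 370L,
             seed = seed, crossings = crossings, spawn = spawn)
}

#' Audit relinking decisions against ground truth
#'
#' Labels each chosen link with the true fish identity at both endpoints
#' (nearest ground-truth head joint), so incorrect links (joining
#' fragments of different fish) can be counted.
#'
#' @param tracklets the tracklet list that was relinked.
#' @param links the link tibble from [relink()].
#' @param truth ground-truth table with `frame`, `id`, `J1_x`, `J1_y`.
#' @param tol maximum distance (px) for endpoint-to-truth attribution.
#' @return A tibble with one row per link: `i`, `j`, `gap`, `D`,
#'   `fish_out`, `fish_in`, `correct`. `correct` is `NA` when either
#'   endpoint cannot be attributed to a fish within `tol` (for instance
#'   a coasted endpoint that drifted): such links are indeterminate, not
#'   known-wrong.
#' @export
audit_links <- function(tracklets, links, truth, tol = 60) {
  fish_at <- function(frame, pt) {
    frame <- max(min(frame, max(truth$frame)), min(truth$frame))
    g <- truth[truth$frame == frame, ]
    d <- sqrt((g$J1_x - pt[1])^2 + (g$J1_y - pt[2])^2)
    if (min(d) <= tol) g$id[which.min(d)] else NA_real_
  }
  if (nrow(links) == 0L) {
    return(tibble(i = integer(0), j = integer(0), gap = numeric(0),
                  D = numeric(0), fish_out = numeric(0),
                  fish_in = numeric(0), correct = logical(0)))
  }
  rows <- lapply(seq_len(nrow(links)), function(r) {
    i <- links$i[r]
    j <- links$j[r]
    fo <- fish_at(tracklets[[i]]$ed, tracklets[[i]]$head_out[1:2])
    fi <- fish_at(tracklets[[j]]$st, tracklets[[j]]$head_in[1:2])
    tibble(i = i, j = j, gap = links$gap[r], D = links$D[r],
           fish_out = fo, fish_in = fi,
           correct = if (is.na(fo) || is.na(fi)) NA else fo == fi)
  })
  dplyr::bind_rows(rows)
}
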