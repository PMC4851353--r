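# Plotting helpers built on ggplot2.

#' Plot trajectories
#'
#' Nose paths of all fish over time, colored by identity, in image
#' coordinates (y axis reversed so the plot matches the video frames).
#'
#' @param object a `fish_trajectories` tibble (see [trajectories_table()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fish_trajectories <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$N_x, y = .data$N_y,
                               group = factor(.data$id),
                               color = factor(.data$id))) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "fish") +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Overlay fitted poses on a frame
#'
#' Draws the frame as a raster with the rectangle-chain skeleton (joints
#' and nose) of each pose on top.
#'
#' @param frame grayscale matrix.
#' @param poses list of [fish_pose()] objects (or a pose table plus `spec`).
#' @param spec a [rect_spec()]; required when `poses` is a table.
#' @return A ggplot object.
#' @export
plot_frame_poses <- function(frame, poses, spec = rect_spec()) {
  if (is.data.frame(poses)) poses <- table_to_poses(poses, spec)
  h <- nrow(frame)
  w <- ncol(frame)
  rast <- tibble(
    x = rep(seq_len(w) - 1L, each = h),
    y = rep(seq_len(h) - 1L, times = w),
    v = as.vector(frame)
  )
  sk <- dplyr::bind_rows(lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    pts <- rbind(p$N, p$G, p$J, p$O)
    tibble(x = pts[, 1], y = pts[, 2],
           id = if (is.na(p$id)) i else p$id,
           point = c("N", "G", paste0("J", seq_len(nrow(p$J))), "O"))
  }))
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = rast,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$v)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_path(data = sk,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = factor(.data$id),
                                    color = factor(.data$id))) +
    ggplot2::geom_point(data = sk[sk$point == "N", ],
                        ggplot2::aes(x = .data$x, y = .data$y),
                        color = "red", size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, color = "fish") +
    ggplot2::theme_void()
}
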