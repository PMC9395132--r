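#' Moving-window average along a score axis
#'
#' Quantifies the gradient of a response variable along an axis: a window
#' covering `window_frac` of the axis range starts at the axis minimum and
#' is shifted in steps of `step_frac` of the range until its right edge
#' reaches the maximum. In each window position the mean response over the
#' samples whose axis value falls in the closed interval is recorded;
#' windows containing no samples are dropped. The gradient is the ordinary
#' least-squares slope of the window means on the window centers.
#'
#' @param axis numeric vector (the axis score), >= 2 distinct values.
#' @param response numeric vector of equal length.
#' @param window_frac window width as a fraction of the axis range (0.60).
#' @param step_frac shift per step as a fraction of the axis range (0.01).
#' @return list of class `window_profile`: `centers`, `means`, `counts`,
#'   `slope`, plus the window parameters.
#' @export
moving_window <- function(axis, response, window_frac = 0.60,
                          step_frac = 0.01) {
  if (length(axis) != length(response)) stop("axis and response lengths differ")
  if (any(!is.finite(axis)) || any(!is.finite(response)))
    stop("non-finite values")
  if (window_frac <= 0 || window_frac > 1) stop("window_frac must be in (0, 1]")
  if (step_frac <= 0) stop("step_frac must be > 0")
  rng <- range(axis)
  span <- diff(rng)
  if (span == 0) stop("all axis values identical: gradient undefined")
  width <- window_frac * span
  step <- step_frac * span
  k_max <- floor((span - width) / step + 1e-9)
  lefts <- rng[1] + step * (0:k_max)

  centers <- means <- numeric(0)
  counts <- integer(0)
  for (left in lefts) {
    right <- left + width
    inside <- axis >= left - 1e-12 & axis <= right + 1e-12
    if (!any(inside)) next
    centers <- c(centers, left + width / 2)
    means <- c(means, mean(response[inside]))
    counts <- c(counts, sum(inside))
  }
  slope <- if (length(centers) >= 2 && stats::sd(centers) > 0)
    unname(stats::coef(stats::lm(means ~ centers))[2]) else NA_real_
  structure(list(centers = centers, means = means, counts = counts,
                 slope = slope, window_frac = window_frac,
                 step_frac = step_frac),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat("<window_profile> ", length(x$centers), " windows, slope = ",
      format(x$slope, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Export the two-dimensional EMT plane for a score table
#'
#' Tidy per-sample table of the E and M score coordinates plus an overlay
#' variable (proliferative or invasive score, or a phenotype label),
#' consumed by [moving_window()] along each axis and by plotting.
#'
#' @param scores score table from [score_panel()] (or any data.frame with
#'   the named columns).
#' @param overlay column name of the overlay variable.
#' @param e_col,m_col column names of the E and M axes.
#' @return data.frame with columns `sample_id`, `E`, `M`, `overlay`.
#' @export
emt_plane <- function(scores, overlay = "proliferative",
                      e_col = "epithelial", m_col = "mesenchymal") {
  missing <- setdiff(c(e_col, m_col, overlay), colnames(scores))
  if (length(missing))
    stop("score table lacks column(s): ", paste(missing, collapse = ", "))
  data.frame(sample_id = rownames(scores),
             E = scores[[e_col]], M = scores[[m_col]],
             overlay = scores[[overlay]],
             stringsAsFactors = FALSE)
}

#' Overlay gradients along the E and M axes of the plane
#'
#' Runs [moving_window()] of the overlay variable along each of the two
#' EMT-plane axes and returns both profiles with their slopes.
#'
#' @param plane output of [emt_plane()].
#' @inheritParams moving_window
#' @return list with `along_E` and `along_M` window profiles.
#' @export
plane_gradients <- function(plane, window_frac = 0.60, step_frac = 0.01) {
  list(along_E = moving_window(plane$E, plane$overlay, window_frac, step_frac),
       along_M = moving_window(plane$M, plane$overlay, window_frac, step_frac))
}
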