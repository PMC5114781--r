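#' Build the chord for one side of the density peak
#'
#' A straight line is drawn from the anchor peak of the density to the point
#' on the density one sample standard deviation to the left (lower side) or
#' right (upper side) of that peak.  The endpoint abscissa is snapped to the
#' nearest grid point and clipped to the grid range.  Anchoring the chords
#' at one standard deviation rather than the tails keeps high-intensity
#' outliers from inflating the upper threshold.
#'
#' When the selected peak differs from the global maximum, each side is
#' anchored at the maximum nearer to its own chord: the lower chord at the
#' leftmost of \{selected, global\} and the upper chord at the rightmost.
#' With the default selection both chords are anchored at the global
#' maximum.
#'
#' @param pdf An `intensity_pdf`.
#' @param peaks A `peak_set` (see [find_peaks()], [select_peak()]).
#' @param side `"lower"` or `"upper"`.
#' @param endpoint `"sigma"` for the one-standard-deviation endpoints (the
#'   method's definition); `"tail"` anchors the chord at the grid end
#'   instead, provided only for comparison experiments.
#' @return An object of class `chord_spec`: grid indices and coordinates of
#'   the peak point and endpoint, the side, and the chord slope.
#' @export
build_chord <- function(pdf, peaks, side = c("lower", "upper"),
                        endpoint = c("sigma", "tail")) {
  side <- match.arg(side)
  endpoint <- match.arg(endpoint)
  g <- pdf$grid; d <- pdf$density
  apexes <- sort(c(peaks$selected_index, peaks$global_index))
  ip <- if (side == "lower") apexes[1L] else apexes[2L]
  if (endpoint == "sigma") {
    target <- g[ip] + if (side == "lower") -pdf$sample$sd else pdf$sample$sd
    ie <- which.min(abs(g - target))
  } else {
    ie <- if (side == "lower") 1L else length(g)
  }
  if (abs(ie - ip) < 2L)
    err("unithresh_degenerate_chord_error",
        "%s chord is degenerate: endpoint within one grid step of the peak (sd smaller than the grid resolution?)",
        side)
  slope <- (d[ie] - d[ip]) / (g[ie] - g[ip])
  structure(list(side = side, peak_index = ip, end_index = ie,
                 peak_point = c(x = g[ip], y = d[ip]),
                 endpoint = c(x = g[ie], y = d[ie]),
                 slope = slope),
            class = "chord_spec")
}

#' Locate the corner threshold under a chord
#'
#' Over the grid points strictly between the chord's peak and endpoint, and
#' strictly below the chord, returns the abscissa maximising the
#' perpendicular distance from the density curve to the chord line.  This
#' is the point where the right triangle with hypotenuse on the chord and
#' right-angle vertex on the density has maximal area.  For a fixed chord
#' the argmax of perpendicular distance equals the argmax of vertical
#' deviation `chord(x) - density(x)`, because perpendicular distance is the
#' vertical deviation scaled by `cos(theta)` with `theta` the (constant)
#' chord inclination; the vertical form is what is computed, the
#' perpendicular distance is reported in the diagnostics.  Exact ties are
#' broken toward the candidate farthest from the peak (the more
#' conservative removal boundary).
#'
#' @param pdf An `intensity_pdf`.
#' @param chord A `chord_spec` from [build_chord()].
#' @return A list: `threshold` (grid value), `index`, `deviation` (vertical),
#'   `perp_distance`, `side`, `chord`, `fallback = FALSE`.
#' @export
corner_threshold <- function(pdf, chord) {
  g <- pdf$grid; d <- pdf$density
  ip <- chord$peak_index; ie <- chord$end_index
  idx <- if (ie < ip) (ie + 1L):(ip - 1L) else (ip + 1L):(ie - 1L)
  chord_y <- chord$peak_point[["y"]] + chord$slope * (g[idx] - chord$peak_point[["x"]])
  dev <- chord_y - d[idx]
  below <- dev > 0
  if (!any(below))
    err("unithresh_corner_error",
        "%s side: no grid point lies below the chord (density is concave under the whole chord); consider the endpoint fallback",
        chord$side)
  idx <- idx[below]; dev <- dev[below]
  best <- dev == max(dev)
  pick <- which(best)[which.max(abs(idx[best] - ip))]
  i <- idx[pick]
  list(threshold = g[i], index = i, deviation = dev[pick],
       perp_distance = dev[pick] / sqrt(1 + chord$slope^2),
       side = chord$side, chord = chord, fallback = FALSE)
}

#' Compute the lower and upper unimodal thresholds
#'
#' Applies [build_chord()] and [corner_threshold()] on both sides of the
#' anchor peak(s) and assembles a `threshold_pair`.  If a side has no point
#' below its chord the error is propagated with the side label, unless
#' `fallback = TRUE`, in which case the clipped chord endpoint itself is
#' used as the threshold for that side and flagged in the diagnostics.
#'
#' @inheritParams build_chord
#' @param fallback Use the chord endpoint as the threshold when no corner
#'   exists on a side (logged in the diagnostics), instead of erroring.
#' @return An object of class `threshold_pair`: `lower`, `upper`,
#'   `lower_diag`, `upper_diag`, `peak_intensity` (selected peak),
#'   `selected_ordinal`, `n_peaks`.
#' @export
compute_thresholds <- function(pdf, peaks, endpoint = c("sigma", "tail"),
                               fallback = FALSE) {
  endpoint <- match.arg(endpoint)
  one_side <- function(side) {
    ch <- build_chord(pdf, peaks, side, endpoint)
    tryCatch(corner_threshold(pdf, ch),
             unithresh_corner_error = function(e) {
               if (!fallback) stop(e)
               list(threshold = ch$endpoint[["x"]], index = ch$end_index,
                    deviation = NA_real_, perp_distance = NA_real_,
                    side = side, chord = ch, fallback = TRUE)
             })
  }
  lo <- one_side("lower")
  up <- one_side("upper")
  sel_x <- pdf$grid[peaks$selected_index]
  if (!(lo$threshold < sel_x && sel_x < up$threshold))
    err("unithresh_corner_error",
        "thresholds (%.4g, %.4g) do not bracket the selected peak %.4g",
        lo$threshold, up$threshold, sel_x)
  structure(list(lower = lo$threshold, upper = up$threshold,
                 lower_diag = lo, upper_diag = up,
                 peak_intensity = sel_x,
                 selected_ordinal = match(peaks$selected_index, peaks$peak_indices),
                 n_peaks = length(peaks$peak_indices)),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  fb <- c(if (isTRUE(x$lower_diag$fallback)) "lower",
          if (isTRUE(x$upper_diag$fallback)) "upper")
  cat(sprintf("<threshold_pair> [%.4g, %.4g] around peak %.4g (peak %d of %d)%s\n",
              x$lower, x$upper, x$peak_intensity, x$selected_ordinal,
              x$n_peaks,
              if (length(fb)) paste0("; endpoint fallback on: ",
                                     paste(fb, collapse = ", ")) else ""))
  invisible(x)
}
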