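# Shared fixtures and independent oracles for the test suite.

# A small image volume built from an array, for unit tests.
make_volume <- function(data, spacing = c(1, 1, 1)) {
  image_volume(data, spacing)
}

# Intensity sample object without going through a volume (for closed-form
# bandwidth/KDE checks where n and sd are set directly).
make_sample <- function(values, sd_override = NULL, n_override = NULL) {
  s <- if (is.null(sd_override)) stats::sd(values) else sd_override
  n <- if (is.null(n_override)) length(values) else n_override
  structure(list(values = values, n = n, mean = mean(values), sd = s),
            class = "intensity_sample")
}

# A hand-built gridded density with a given sample sd attached, bypassing
# the KDE, for geometric threshold tests.
make_pdf <- function(grid, density, sd) {
  structure(list(grid = grid, density = density, bandwidth = NA_real_,
                 sample = make_sample(grid, sd_override = sd,
                                      n_override = length(grid))),
            class = "intensity_pdf")
}

make_peaks <- function(pdf, peak_index) {
  structure(list(peak_indices = as.integer(peak_index),
                 global_index = as.integer(peak_index[1]),
                 selected_index = as.integer(peak_index[1]),
                 pdf = pdf),
            class = "peak_set")
}

# Mixture sample emulating a kidney ROI: dominant Gaussian mode plus a low
# and a high contaminant cluster.  Used by the corner-oracle tests.
mixture_sample <- function(seed, n = 3000) {
  set.seed(seed)
  w <- c(0.8, 0.12, 0.08)
  mu <- c(300, 120 + stats::runif(1, -30, 30), 520 + stats::runif(1, -40, 40))
  sd <- c(30, 20, 30)
  k <- sample(1:3, n, replace = TRUE, prob = w)
  pmax(stats::rnorm(n, mu[k], sd[k]), 0)
}

# Exhaustive point-to-chord perpendicular-distance corner search: for every
# grid point strictly between peak and endpoint and strictly below the
# chord, compute the perpendicular distance to the infinite line through
# the chord's two points, and return the index of the maximum.
corner_oracle <- function(pdf, chord) {
  g <- pdf$grid; d <- pdf$density
  ip <- chord$peak_index; ie <- chord$end_index
  idx <- if (ie < ip) (ie + 1):(ip - 1) else (ip + 1):(ie - 1)
  x1 <- g[ip]; y1 <- d[ip]; x2 <- g[ie]; y2 <- d[ie]
  # line: (y2-y1) x - (x2-x1) y + (x2 y1 - x1 y2) = 0
  a <- y2 - y1; b <- -(x2 - x1); cc <- x2 * y1 - x1 * y2
  below <- (y1 + (y2 - y1) / (x2 - x1) * (g[idx] - x1)) - d[idx] > 0
  idx <- idx[below]
  if (!length(idx)) return(NA_integer_)
  perp <- abs(a * g[idx] + b * d[idx] + cc) / sqrt(a^2 + b^2)
  idx[which.max(perp)]
}

# Direct per-point kernel-sum oracle for the KDE, written as an explicit
# loop over the sample.
kernel_sum_oracle <- function(x, values, h) {
  acc <- 0
  for (v in values) acc <- acc + stats::dnorm((x - v) / h)
  acc / (length(values) * h)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# The 20-phantom recovery study at the default study conditions, computed
# once per test run and shared between the recovery and unimodality checks.
phantom_study <- local({
  cache <- NULL
  function(n_phantoms = 20) {
    if (!is.null(cache) && nrow(cache) >= n_phantoms)
      return(cache[seq_len(n_phantoms), ])
    rows <- lapply(seq_len(n_phantoms), function(seed) {
      ph <- generate_phantom(phantom_spec(seed = seed))
      fit <- unithresh(ph$volume, ph$roi)
      data.frame(
        seed = seed,
        n_peaks = length(fit$peaks$peak_indices),
        removed_fraction = fit$segmentation$removed_fraction,
        true_fraction = ph$truth$true_contaminant_fraction,
        dice = dice_coef(fit$segmentation$kept_mask,
                         ph$truth$parenchyma_mask),
        kept_n = fit$segmentation$kept_n,
        below_n = fit$segmentation$below_n,
        above_n = fit$segmentation$above_n,
        roi_n = fit$segmentation$roi_n)
    })
    cache <<- do.call(rbind, rows)
    cache
  }
})
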