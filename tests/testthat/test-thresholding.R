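# A deterministic triangular density: peak at x = 300, linear flanks.
triangle_pdf <- function(sd = 40) {
  g <- seq(100, 500, by = 1)
  d <- pmax(0, 1 - abs(g - 300) / 150)
  make_pdf(g, d, sd = sd)
}

test_that("chord endpoints sit one sample SD from the peak, snapped to grid", {
  p <- triangle_pdf(sd = 40)
  pk <- make_peaks(p, which(p$grid == 300))
  lo <- build_chord(p, pk, "lower")
  up <- build_chord(p, pk, "upper")
  expect_equal(lo$endpoint[["x"]], 260)
  expect_equal(up$endpoint[["x"]], 340)
  expect_equal(lo$peak_point[["x"]], 300)
  # symmetric density -> mirror-image chords
  expect_equal(abs(lo$slope), abs(up$slope))
})

test_that("endpoints clip to the grid range; sub-grid SDs are degenerate", {
  g <- seq(0, 100, by = 1)
  d <- pmax(0, 1 - abs(g - 10) / 60)
  p <- make_pdf(g, d, sd = 50)           # peak at 10, sd reaches past 0
  pk <- make_peaks(p, which(g == 10))
  lo <- build_chord(p, pk, "lower")
  expect_equal(lo$end_index, 1L)

  p2 <- make_pdf(g, d, sd = 0.4)         # sd below one grid step
  expect_error(build_chord(p2, make_peaks(p2, which(g == 10)), "lower"),
               class = "unithresh_degenerate_chord_error")
})

test_that("a single dip below an otherwise straight flank is the corner", {
  g <- seq(0, 100, by = 1)
  d <- 1 - abs(g - 50) / 100             # linear flanks from peak at 50
  d[30] <- d[30] - 0.1                   # one point dips below the chord
  p <- make_pdf(g, d, sd = 40)
  pk <- make_peaks(p, 51L)
  res <- corner_threshold(p, build_chord(p, pk, "lower"))
  expect_equal(res$index, 30L)
  expect_equal(res$threshold, g[30])
  expect_equal(res$deviation, 0.1, tolerance = 1e-9)
  # perpendicular distance = vertical deviation * cos(chord inclination)
  ch <- build_chord(p, pk, "lower")
  expect_equal(res$perp_distance, 0.1 / sqrt(1 + ch$slope^2))
})

test_that("equal maximal deviations resolve to the candidate farthest from the peak", {
  g <- seq(0, 100, by = 1)
  d <- 1 - abs(g - 50) / 100
  d[c(25, 40)] <- d[c(25, 40)] - 0.1     # exact tie, two dips
  p <- make_pdf(g, d, sd = 40)
  res <- corner_threshold(p, build_chord(p, make_peaks(p, 51L), "lower"))
  expect_equal(res$index, 25L)           # the dip at x = 24, farther out
})

test_that("production corner matches the exhaustive perpendicular-distance search", {
  for (seed in 1:12) {
    p <- estimate_pdf(make_sample(mixture_sample(seed, n = 2500)))
    pk <- find_peaks(p)
    for (side in c("lower", "upper")) {
      ch <- build_chord(p, pk, side)
      expect_identical(corner_threshold(p, ch)$index, corner_oracle(p, ch),
                       label = sprintf("seed %d, %s side", seed, side))
    }
  }
})

test_that("a left shoulder pulls the lower corner between the two modes", {
  set.seed(42)
  x <- c(rnorm(45000, 300, 30), rnorm(5000, 150, 20))
  p <- estimate_pdf(make_sample(x))
  pk <- find_peaks(p)
  res <- corner_threshold(p, build_chord(p, pk, "lower"))
  expect_gt(res$threshold, 150)
  expect_lt(res$threshold, 300)
})

test_that("thresholds bracket the peak and are symmetric for symmetric mixtures", {
  set.seed(12)
  x <- c(rnorm(20000, 300, 25), rnorm(3000, 150, 15), rnorm(3000, 450, 15))
  p <- estimate_pdf(make_sample(x))
  pk <- find_peaks(p)
  th <- compute_thresholds(p, pk)
  peak_x <- p$grid[pk$selected_index]
  expect_lt(th$lower, peak_x)
  expect_gt(th$upper, peak_x)
  step <- diff(p$grid[1:2])
  expect_lt(abs((th$upper - peak_x) - (peak_x - th$lower)), 6 * step)
})

test_that("the full threshold pipeline is affine-equivariant", {
  x <- mixture_sample(99, n = 4000)
  base <- compute_thresholds(p <- estimate_pdf(make_sample(x)),
                             find_peaks(p))
  step <- diff(p$grid[1:2])
  for (ab in list(c(0.5, -100), c(3, 250))) {
    a <- ab[1]; b <- ab[2]
    pt <- estimate_pdf(make_sample(a * x + b))
    tht <- compute_thresholds(pt, find_peaks(pt))
    expect_lt(abs(tht$lower - (a * base$lower + b)), a * step + 1e-9)
    expect_lt(abs(tht$upper - (a * base$upper + b)), a * step + 1e-9)
  }
})

test_that("a pure Gaussian has no corner inside the sigma chord; the fallback uses the endpoints", {
  # within one SD of its mode a Gaussian is concave, so every candidate lies
  # above the chord and the corner search must fail per side
  set.seed(21)
  x <- rnorm(50000, 300, 30)
  p <- estimate_pdf(make_sample(x))
  pk <- find_peaks(p)
  expect_error(compute_thresholds(p, pk), class = "unithresh_corner_error")

  th <- compute_thresholds(p, pk, fallback = TRUE)
  expect_true(th$lower_diag$fallback && th$upper_diag$fallback)
  peak_x <- p$grid[pk$selected_index]
  s <- p$sample$sd
  step <- diff(p$grid[1:2])
  expect_lt(abs(th$lower - (peak_x - s)), step)
  expect_lt(abs(th$upper - (peak_x + s)), step)
  expect_lt(th$lower, peak_x); expect_gt(th$upper, peak_x)

  # a small far contaminant inflates the sample SD past the inflection:
  # the corner exists again and removal stays modest
  x2 <- c(rnorm(47000, 300, 30), rnorm(3000, 80, 20))
  p2 <- estimate_pdf(make_sample(x2))
  th2 <- compute_thresholds(p2, find_peaks(p2))
  removed <- mean(x2 < th2$lower | x2 > th2$upper)
  expect_lt(removed, 0.25)
})

test_that("widening the contaminant separation never crosses the parenchyma peak", {
  # monotone sensibility: as the low mode moves away, the lower threshold
  # stays below the parenchyma peak and above the contaminant floor
  for (mu_v in c(120, 90, 60, 30)) {
    set.seed(31)
    x <- c(rnorm(8500, 300, 30), rnorm(1500, mu_v, 20))
    p <- estimate_pdf(make_sample(x))
    pk <- find_peaks(p)
    th <- compute_thresholds(p, pk)
    expect_lt(th$lower, p$grid[pk$global_index])
    expect_gt(th$lower, mu_v - 80)
  }
})

test_that("tail endpoints are available as an explicit non-default policy", {
  x <- mixture_sample(55, n = 4000)
  p <- estimate_pdf(make_sample(x))
  pk <- find_peaks(p)
  ch <- build_chord(p, pk, "lower", endpoint = "tail")
  expect_equal(ch$end_index, 1L)
  th <- compute_thresholds(p, pk, endpoint = "tail")
  expect_lt(th$lower, p$grid[pk$selected_index])
  expect_gt(th$upper, p$grid[pk$selected_index])
})
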