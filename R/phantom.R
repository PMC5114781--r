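#' Specification for a synthetic kidney phantom
#'
#' Defines the geometry, population intensity laws and contamination levels
#' of a synthetic kidney-like volume.  The defaults emulate the data regime
#' the method is designed for: a T2-weighted abdominal acquisition at
#' 1.0 x 1.0 mm in plane and 4.4 mm slices, a kidney of roughly 140 ml
#' whose parenchyma is the dominant tissue in the ROI, dark intrarenal
#' vessels (flow voids), fluid-bright calyces, and a coarse manual tracing
#' that slightly overshoots the organ.
#'
#' Contaminant voxels are partial-volume mixed: each draws a mixing weight
#' `t ~ U(0, partial_volume)` and its intensity from
#' `N((1-t) m_c + t m_p, (1-t) s_c + t s_p)` with `(m_c, s_c)` the pure
#' contaminant law and `(m_p, s_p)` the parenchyma law.  At 4.4 mm slices
#' essentially every voxel of a 1-2 voxel-radius vessel is a partial-volume
#' voxel, and this smearing is what keeps the ROI density unimodal in
#' practice: the contaminants appear as shoulders, not separate modes.
#' `partial_volume = 0` gives pure, well-separated contaminant modes.
#'
#' @param shape Grid dimensions (voxels).
#' @param spacing Voxel edge lengths in mm.
#' @param semiaxes Ellipsoid semi-axes of the kidney body, in voxels;
#'   the default gives a body of about 138 ml at the default spacing.
#' @param parenchyma `(mean, sd)` of the parenchyma intensity law.
#' @param vessels `(mean, sd, fraction)` of the pure vessel law and the
#'   fraction of ROI voxels that are vessel; mean must be below the
#'   parenchyma mean (flow voids are dark).
#' @param calyces `(mean, sd, fraction)` of the pure calyx/fluid law;
#'   mean must be above the parenchyma mean (fluid is bright on T2).
#' @param background `(mean, sd)` of the surrounding-tissue law.
#' @param secondary `(mean, sd, fraction)`: an optional second parenchymal
#'   intensity population (kept tissue with a distinct mode, as in the
#'   occasional bimodal kidney); fraction 0 disables it.
#' @param roi_margin In-plane dilation radius (voxels) for the coarse ROI.
#' @param overshoot Probability that a dilation-ring voxel is included in
#'   the ROI, emulating a tracing that overshoots in patches.
#' @param partial_volume Upper bound of the contaminant mixing weight.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 28),
                         spacing = c(1.0, 1.0, 4.4),
                         semiaxes = c(34, 20, 11),
                         parenchyma = c(300, 30),
                         vessels = c(20, 15, 0.08),
                         calyces = c(750, 60, 0.05),
                         background = c(80, 40),
                         secondary = c(350, 8, 0),
                         roi_margin = 1,
                         overshoot = 0.2,
                         partial_volume = 1,
                         seed = 1L) {
  if (!(vessels[1] < parenchyma[1] && parenchyma[1] < calyces[1]))
    err("unithresh_spec_error",
        "need vessel mean < parenchyma mean < calyx mean (got %g, %g, %g)",
        vessels[1], parenchyma[1], calyces[1])
  fr <- c(vessels[3], calyces[3], secondary[3])
  if (any(fr < 0) || sum(fr) >= 0.5)
    err("unithresh_spec_error",
        "contaminant/secondary fractions must be >= 0 and sum to < 0.5 (parenchyma must dominate)")
  if (partial_volume < 0 || partial_volume > 1)
    err("unithresh_spec_error", "partial_volume must be in [0, 1]")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 semiaxes = as.numeric(semiaxes),
                 parenchyma = parenchyma, vessels = vessels,
                 calyces = calyces, background = background,
                 secondary = secondary,
                 roi_margin = as.integer(roi_margin),
                 overshoot = overshoot,
                 partial_volume = partial_volume,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# intensity draw: partial-volume mix of a pure law toward the parenchyma law
pv_mix <- function(n, pure, par, pv_max) {
  t <- if (pv_max > 0) stats::runif(n, 0, pv_max) else numeric(n)
  stats::rnorm(n, (1 - t) * pure[1] + t * par[1],
               (1 - t) * pure[2] + t * par[2])
}

# in-plane dilation of a logical 3-D mask by a disc of radius r
dilate_inplane <- function(m, r) {
  if (r < 1) return(m)
  out <- m
  for (dx in -r:r) for (dy in -r:r) {
    if ((dx == 0 && dy == 0) || dx^2 + dy^2 > r^2) next
    sh <- array(FALSE, dim = dim(m))
    xs <- max(1, 1 + dx):min(nrow(m), nrow(m) + dx)
    ys <- max(1, 1 + dy):min(ncol(m), ncol(m) + dy)
    sh[xs, ys, ] <- m[xs - dx, ys - dy, , drop = FALSE]
    out <- out | sh
  }
  out
}

# random-walk tubes: walk through the body marking an in-plane disc of
# radius 1-2 voxels until `budget` distinct voxels are collected
grow_vessels <- function(body, budget, coords) {
  dims <- dim(body)
  marked <- array(FALSE, dim = dims)
  n_marked <- 0L
  inside <- function(p) all(p >= 1L) && all(p <= dims) && body[p[1], p[2], p[3]]
  body_idx <- which(body)
  guard <- 0L
  while (n_marked < budget && guard < 200L) {
    guard <- guard + 1L
    p <- coords[sample(length(body_idx), 1L), ]
    radius <- sample(1:2, 1L)
    for (step in seq_len(400L)) {
      if (n_marked >= budget) break
      # mark the in-plane disc around p
      for (dx in -radius:radius) for (dy in -radius:radius) {
        if (dx^2 + dy^2 > radius^2) next
        q <- c(p[1] + dx, p[2] + dy, p[3])
        if (all(q >= 1L) && all(q <= dims) && body[q[1], q[2], q[3]] &&
            !marked[q[1], q[2], q[3]]) {
          marked[q[1], q[2], q[3]] <- TRUE
          n_marked <- n_marked + 1L
          if (n_marked >= budget) break
        }
      }
      # biased in-plane step, occasional slice change
      d <- c(sample(-1:1, 2L, replace = TRUE),
             if (stats::runif(1) < 0.15) sample(c(-1L, 1L), 1L) else 0L)
      p2 <- p + d
      if (!inside(p2)) break
      p <- p2
    }
  }
  marked
}

#' Generate a synthetic kidney phantom with ground truth
#'
#' Places an ellipsoidal kidney body in the grid, grows random-walk vessel
#' tubes and central calyx blobs inside it to the requested ROI fractions,
#' draws per-region intensities (clipped at zero), and produces the coarse
#' ROI by a patchy in-plane dilation of the body.  Fully reproducible from
#' `spec$seed` (the function seeds the RNG).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `kidney_phantom`: `volume` (an
#'   [image_volume()]), `roi` (an `roi_mask`), `truth` (masks
#'   `parenchyma_mask`, `vessel_mask`, `calyx_mask`, scalar
#'   `true_parenchyma_ml` and `true_contaminant_fraction`, the fraction of
#'   ROI voxels that are not true parenchyma), and the `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 42))
#' ph$truth$true_contaminant_fraction
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  dims <- spec$shape
  ctr <- (dims + 1) / 2
  ax <- seq_len(dims[1]); ay <- seq_len(dims[2]); az <- seq_len(dims[3])
  ex <- ((ax - ctr[1]) / spec$semiaxes[1])^2
  ey <- ((ay - ctr[2]) / spec$semiaxes[2])^2
  ez <- ((az - ctr[3]) / spec$semiaxes[3])^2
  body <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
  n_body <- sum(body)
  if (n_body < 100L)
    err("unithresh_spec_error", "kidney body too small for this grid")

  # coarse ROI: patchy in-plane dilation
  ring_cand <- dilate_inplane(body, spec$roi_margin) & !body
  keep <- stats::runif(sum(ring_cand)) < spec$overshoot
  roi <- body
  roi[which(ring_cand)[keep]] <- TRUE
  n_roi <- sum(roi)

  n_v <- round(spec$vessels[3] * n_roi)
  n_c <- round(spec$calyces[3] * n_roi)
  n_2 <- round(spec$secondary[3] * n_roi)
  if (n_v + n_c + n_2 > 0.6 * n_body)
    err("unithresh_spec_error",
        "requested fractions exceed the available interior volume")

  coords <- which(body, arr.ind = TRUE)
  vessel <- if (n_v > 0) grow_vessels(body, n_v, coords)
            else array(FALSE, dim = dims)

  # calyces: blobs around a few centres near the body centre, nearest-first
  calyx <- array(FALSE, dim = dims)
  if (n_c > 0) {
    n_blob <- 3L
    centres <- matrix(ctr, n_blob, 3, byrow = TRUE) +
      cbind(stats::rnorm(n_blob, 0, spec$semiaxes[1] / 6),
            stats::rnorm(n_blob, 0, spec$semiaxes[2] / 6),
            stats::rnorm(n_blob, 0, spec$semiaxes[3] / 6))
    free <- which(body & !vessel)
    fc <- which(body & !vessel, arr.ind = TRUE)
    zscale <- spec$spacing[3] / spec$spacing[1]
    dmin <- rep(Inf, nrow(fc))
    for (b in seq_len(n_blob)) {
      db <- sqrt((fc[, 1] - centres[b, 1])^2 + (fc[, 2] - centres[b, 2])^2 +
                 ((fc[, 3] - centres[b, 3]) * zscale)^2)
      dmin <- pmin(dmin, db)
    }
    calyx[free[order(dmin)[seq_len(min(n_c, length(free)))]]] <- TRUE
  }

  secondary <- array(FALSE, dim = dims)
  if (n_2 > 0) {
    free <- which(body & !vessel & !calyx)
    secondary[sample(free, min(n_2, length(free)))] <- TRUE
  }

  parenchyma <- body & !vessel & !calyx           # secondary is parenchyma
  plain_par <- parenchyma & !secondary
  ring <- roi & !body

  x <- array(stats::rnorm(prod(dims), spec$background[1], spec$background[2]),
             dim = dims)
  x[plain_par] <- stats::rnorm(sum(plain_par), spec$parenchyma[1],
                               spec$parenchyma[2])
  if (any(secondary))
    x[secondary] <- stats::rnorm(sum(secondary), spec$secondary[1],
                                 spec$secondary[2])
  if (any(vessel))
    x[vessel] <- pv_mix(sum(vessel), spec$vessels, spec$parenchyma,
                        spec$partial_volume)
  if (any(calyx))
    x[calyx] <- pv_mix(sum(calyx), spec$calyces, spec$parenchyma,
                       spec$partial_volume)
  if (any(ring))
    x[ring] <- pv_mix(sum(ring), spec$background, spec$parenchyma,
                      spec$partial_volume)
  x <- pmax(x, 0)

  vol <- image_volume(x, spec$spacing, source_path = "<phantom>")
  vox <- voxel_volume_ml(vol)
  truth <- list(parenchyma_mask = parenchyma, vessel_mask = vessel,
                calyx_mask = calyx,
                true_parenchyma_ml = sum(parenchyma) * vox,
                true_contaminant_fraction = 1 - sum(parenchyma) / n_roi)
  structure(list(volume = vol, roi = roi_mask(roi, dims), truth = truth,
                 spec = spec),
            class = "kidney_phantom")
}

#' @export
print.kidney_phantom <- function(x, ...) {
  cat(sprintf(paste0("<kidney_phantom> seed %d: body %.1f ml parenchyma, ",
                     "ROI %d voxels, contaminant fraction %.3f\n"),
              x$spec$seed, x$truth$true_parenchyma_ml,
              sum(x$roi$data), x$truth$true_contaminant_fraction))
  invisible(x)
}

#' Write a phantom set to disk
#'
#' Writes the phantom volume, ROI and truth masks as NIfTI files plus a
#' JSON manifest of the spec and truth scalars.
#'
#' @param phantom A `kidney_phantom`.
#' @param dir Output directory (created if needed).
#' @param stem Filename stem.
#' @return The manifest path, invisibly.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$spec$spacing
  write_volume(phantom$volume, file.path(dir, paste0(stem, ".nii.gz")))
  write_mask(phantom$roi, file.path(dir, paste0(stem, "_roi.nii.gz")), sp)
  dims <- dim(phantom$volume$data)
  for (m in c("parenchyma_mask", "vessel_mask", "calyx_mask"))
    write_mask(roi_mask_or_empty(phantom$truth[[m]], dims),
               file.path(dir, paste0(stem, "_", sub("_mask", "", m), ".nii.gz")),
               sp)
  manifest <- c(phantom$spec[setdiff(names(phantom$spec), "shape")],
                list(shape = phantom$spec$shape,
                     true_parenchyma_ml = phantom$truth$true_parenchyma_ml,
                     true_contaminant_fraction =
                       phantom$truth$true_contaminant_fraction))
  mp <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

# tolerate an all-FALSE truth mask (e.g. contaminant-free spec) on export
roi_mask_or_empty <- function(m, dims) {
  if (!any(m)) {
    structure(list(data = array(FALSE, dims), reference_shape = as.integer(dims)),
              class = "roi_mask")
  } else roi_mask(m, dims)
}
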