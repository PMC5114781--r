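test_that("the fitted object carries the full pipeline and is deterministic", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  f1 <- unithresh(ph$volume, ph$roi)
  f2 <- unithresh(ph$volume, ph$roi)
  expect_s3_class(f1, "unithresh")
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$segmentation$kept_mask, f2$segmentation$kept_mask)
  expect_lt(coef(f1)[["lower"]], coef(f1)[["upper"]])
  expect_equal(f1$segmentation$kept_ml,
               f1$segmentation$kept_n * 0.0044)

  out <- capture.output(print(f1))
  expect_true(any(grepl("ml", out)))
  s <- summary(f1)
  expect_s3_class(s, "summary.unithresh")
  expect_equal(s$kept_ml + s$removed_ml, s$roi_ml)

  # the delineation plot renders without error
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf, 600, 400)
  plot(f1)
  grDevices::dev.off()
  expect_true(file.size(tf) > 0)
})

test_that("file-path inputs and in-memory inputs give identical fits", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 14),
                                      semiaxes = c(16, 10, 5), seed = 9))
  dir <- tempfile(); dir.create(dir)
  write_volume(ph$volume, file.path(dir, "img.nii.gz"))
  write_mask(ph$roi, file.path(dir, "roi.nii.gz"), ph$spec$spacing)
  f1 <- unithresh(ph$volume, ph$roi)
  f2 <- unithresh(file.path(dir, "img.nii.gz"), file.path(dir, "roi.nii.gz"))
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$segmentation$kept_n, f2$segmentation$kept_n)
})

test_that("requesting a nonexistent peak is a selection error", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 14),
                                      semiaxes = c(16, 10, 5), seed = 10))
  expect_error(unithresh(ph$volume, ph$roi, peak = 9),
               class = "unithresh_selection_error")
})

test_that("the segment subcommand runs end to end and logs its provenance", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 14),
                                      semiaxes = c(16, 10, 5), seed = 20))
  dir <- tempfile(); dir.create(dir)
  write_volume(ph$volume, file.path(dir, "img.nii.gz"))
  write_mask(ph$roi, file.path(dir, "roi.nii.gz"), ph$spec$spacing)
  out <- file.path(dir, "out")
  logs <- capture.output(
    status <- unithresh_cli(c("segment",
                              "--image", file.path(dir, "img.nii.gz"),
                              "--roi", file.path(dir, "roi.nii.gz"),
                              "--out", out,
                              "--label", "subject=s1,kidney=L,observer=o1")),
    type = "message")
  expect_identical(status, 0L)
  expect_true(any(grepl("bandwidth", logs)))
  expect_true(any(grepl("thresholds", logs)))
  expect_true(file.exists(file.path(out, "overlay.nii.gz")))
  expect_true(file.exists(file.path(out, "delineation.png")))
  res <- read_results(file.path(out, "results.csv"))
  expect_equal(nrow(res), 1)
  expect_identical(res$subject, "s1")
  expect_identical(res$kidney, "L")
  # overlay labels partition the ROI
  lab <- as.array(RNifti::readNifti(file.path(out, "overlay.nii.gz")))
  expect_equal(sum(lab > 0), sum(ph$roi$data))

  # rerun with identical config: same volumes, idempotent results table
  capture.output(
    status2 <- unithresh_cli(c("segment",
                               "--image", file.path(dir, "img.nii.gz"),
                               "--roi", file.path(dir, "roi.nii.gz"),
                               "--out", out,
                               "--label", "subject=s1,kidney=L,observer=o1")),
    type = "message")
  expect_identical(status2, 0L)
  expect_equal(nrow(read_results(file.path(out, "results.csv"))), 1)
})

test_that("CLI errors surface as nonzero status with a labelled message", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 14),
                                      semiaxes = c(16, 10, 5), seed = 21))
  dir <- tempfile(); dir.create(dir)
  write_volume(ph$volume, file.path(dir, "img.nii.gz"))
  write_mask(ph$roi, file.path(dir, "roi.nii.gz"), ph$spec$spacing)
  logs <- capture.output(
    status <- unithresh_cli(c("segment",
                              "--image", file.path(dir, "img.nii.gz"),
                              "--roi", file.path(dir, "roi.nii.gz"),
                              "--out", file.path(dir, "out2"),
                              "--peak", "9")),
    type = "message")
  expect_identical(status, 1L)
  expect_true(any(grepl("unithresh_selection_error", logs)))

  expect_identical(suppressMessages(unithresh_cli(character())), 1L)
  expect_identical(suppressMessages(unithresh_cli("frobnicate")), 1L)
})

test_that("the phantom subcommand writes a manifest per phantom", {
  dir <- tempfile()
  spec_file <- tempfile(fileext = ".json")
  jsonlite::write_json(list(shape = c(48, 48, 14), semiaxes = c(16, 10, 5)),
                       spec_file, auto_unbox = TRUE)
  logs <- capture.output(
    status <- unithresh_cli(c("phantom", "--spec", spec_file,
                              "--seed", "5", "--n", "2", "--out", dir)),
    type = "message")
  expect_identical(status, 0L)
  manifests <- list.files(dir, pattern = "manifest\\.json$")
  expect_length(manifests, 2)
  man <- jsonlite::read_json(file.path(dir, manifests[1]),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 5)
})

test_that("the agree subcommand pairs observers from the results table", {
  a <- array(rnorm(4^3, 100, 10), dim = c(4, 4, 4))
  seg <- apply_thresholds(make_volume(a),
                          roi_mask(array(TRUE, dim(a)), dim(a)),
                          list(lower = 80, upper = 120))
  set.seed(30)
  recs <- do.call(rbind, lapply(1:10, function(i) {
    r1 <- summarize_result(seg, sprintf("s%02d", i), "L", "o1")
    r2 <- summarize_result(seg, sprintf("s%02d", i), "L", "o2")
    r1$kept_ml <- 140 + rnorm(1, 0, 10)
    r2$kept_ml <- r1$kept_ml + rnorm(1, 2, 3)
    rbind(r1, r2)
  }))
  f <- tempfile(fileext = ".csv")
  export_results(recs, f)
  out <- capture.output(
    status <- unithresh_cli(c("agree", "--results", f,
                              "--group-a", "o1", "--group-b", "o2")))
  expect_identical(status, 0L)
  expect_true(any(grepl("Bland-Altman", out)))
  expect_true(any(grepl("10 kidney pairs", out)))
})
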