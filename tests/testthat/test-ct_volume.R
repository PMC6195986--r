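test_that("NRRD round trip preserves data bit-exactly and spacing to full precision", {
  arr <- array(stats::rnorm(10 * 10 * 10, sd = 500), c(10, 10, 10))
  vol <- ct_volume(arr, spacing = c(0.5, 0.62, 0.71), origin = c(-1, 2, 3.5))
  for (enc in c("raw", "gzip")) {
    path <- withr::local_tempfile(fileext = ".nrrd")
    write_volume(vol, path, encoding = enc)
    back <- read_volume(path)
    expect_identical(back$data, vol$data)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-12)
    expect_equal(back$origin, vol$origin, tolerance = 1e-12)
  }
})

test_that("NIfTI round trip preserves data and spacing", {
  arr <- array(seq_len(4 * 5 * 6) * 1.5 - 800, c(4, 5, 6))
  vol <- ct_volume(arr, spacing = c(0.5, 0.5, 0.8))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path, format = "nifti")
  back <- read_volume(path, format = "nifti")
  expect_equal(back$data, vol$data, ignore_attr = TRUE)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
})

test_that("an NRRD file written here parses identically under an independent reader", {
  skip_if(Sys.which("python") == "", "python not available")
  arr <- array(round(stats::rnorm(6 * 7 * 8, sd = 300)), c(6, 7, 8))
  vol <- ct_volume(arr, spacing = c(0.5, 0.6, 0.7))
  path <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(vol, path)
  out <- suppressWarnings(system2("python", c("-c", shQuote(sprintf(
    "import SimpleITK as sitk; im = sitk.ReadImage(%s); print(im.GetSize(), im.GetSpacing(), sum(sitk.GetArrayFromImage(im).ravel()))",
    dQuote(path, q = FALSE)))), stdout = TRUE, stderr = TRUE))
  skip_if(!is.null(attr(out, "status")), "SimpleITK unavailable")
  # sizes are reported fastest-axis-first = our (z, y, x)
  expect_match(paste(out, collapse = " "), "\\(6, 7, 8\\)")
  expect_match(paste(out, collapse = " "), sprintf("%.1f", sum(arr)), fixed = TRUE)
})

test_that("invalid volume metadata is rejected", {
  expect_error(ct_volume(array(0, c(3, 3, 3)), spacing = c(0, 1, 1)),
               class = "cleftmorph_metadata_error")
  expect_error(ct_volume(array(c(NA, rep(0, 26)), c(3, 3, 3)), spacing = rep(1, 3)),
               class = "cleftmorph_metadata_error")
  expect_error(ct_volume(matrix(0, 3, 3), spacing = rep(1, 3)),
               class = "cleftmorph_metadata_error")
  expect_error(read_volume(tempfile(fileext = ".nrrd")),
               class = "cleftmorph_io_error")
})

test_that("display windowing maps level to mid-gray and clamps at half-width edges", {
  mk <- function(hu) ct_volume(array(hu, c(2, 2, 2)), spacing = rep(1, 3))
  bw <- bone_window()
  expect_equal(window_transform(mk(300), bw)[1], 0.5)
  expect_equal(window_transform(mk(-450), bw)[1], 0)
  expect_equal(window_transform(mk(1050), bw)[1], 1)
  expect_equal(window_transform(mk(40), soft_tissue_window())[1], 0.5)
  expect_error(window_setting(100, 0), class = "cleftmorph_parameter_error")
})

test_that("windowing is monotone in HU and bounded in [0, 1]", {
  hus <- sort(stats::runif(200, -2000, 3000))
  vol <- ct_volume(array(rep(hus, length.out = 216), c(6, 6, 6)), spacing = rep(1, 3))
  for (win in list(bone_window(), soft_tissue_window(), window_setting(-200, 70))) {
    ordered <- ct_volume(array(hus[1:8], c(2, 2, 2)), spacing = rep(1, 3))
    w <- as.vector(window_transform(ordered, win))
    expect_true(all(diff(w) >= 0))
    wv <- window_transform(vol, win)
    expect_true(all(wv >= 0 & wv <= 1))
  }
})

test_that("QC slice export writes a readable grayscale PNG", {
  skip_if_not_installed("png")
  ph <- cached_phantom("intact_control_sutures")
  path <- withr::local_tempfile(fileext = ".png")
  write_qc_slice(ph$volume, path, window = bone_window())
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], dim(ph$volume$data)[2:3])
})
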