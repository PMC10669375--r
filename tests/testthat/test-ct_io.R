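test_that("DICOM round trip preserves HU within stored-integer quantization", {
  b <- make_phantom(tiny_spec(noise_sd = 5, spacing = c(1.2, 1.2, 2.5)))
  d <- withr::local_tempdir()
  write_dicom_series(b$volume, d, patient_id = "P1", exam_date = "20210304")
  rd <- read_dicom_series(d)
  expect_equal(rd$volume$voxels, round(b$volume$voxels), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lte(max(abs(rd$volume$voxels - b$volume$voxels)), 0.5)
  expect_equal(rd$volume$spacing, c(1.2, 1.2, 2.5))
  expect_identical(rd$volume$kernel, "SYNTHETIC")
  expect_identical(rd$metadata$patient_id, "P1")
  expect_equal(rd$metadata$exam_date, as.Date("2021-03-04"))
})

test_that("slice rescale follows slope and intercept", {
  # stored value 24 with slope 1, intercept -1024 must read back as -1000 HU
  v <- ct_volume(array(-1000, c(8, 8, 3)), c(1, 1, 2))
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  rd <- read_dicom_series(d)
  expect_true(all(rd$volume$voxels == -1000))
})

test_that("file order on disk does not affect the canonical volume", {
  b <- make_phantom(tiny_spec(noise_sd = 5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  paths <- write_dicom_series(b$volume, d1)
  # re-store in inferior->superior order under shuffled names
  n <- length(paths)
  for (i in seq_len(n))
    file.copy(paths[n - i + 1], file.path(d2, sprintf("x_%03d.dcm", i)))
  r1 <- read_dicom_series(d1)
  r2 <- read_dicom_series(d2)
  expect_identical(r1$volume$voxels, r2$volume$voxels)
  expect_identical(r1$volume$slice_z, r2$volume$slice_z)
})

test_that("mixed series and missing mandatory tags are rejected", {
  b <- make_phantom(tiny_spec(noise_sd = 0))
  d <- withr::local_tempdir()
  write_dicom_series(b$volume, d, patient_id = "A", exam_date = "20200101")
  write_dicom_series(b$volume, file.path(d, "sub"), patient_id = "B",
                     exam_date = "20200202")
  file.copy(list.files(file.path(d, "sub"), full.names = TRUE)[1],
            file.path(d, "other.dcm"))
  unlink(file.path(d, "sub"), recursive = TRUE)
  expect_error(read_dicom_series(d), "mixes multiple DICOM series")

  # hand-built file without RescaleIntercept must name the missing tag
  el <- function(...) lamcyst:::.element(...)
  px <- writeBin(rep(0L, 16), raw(), size = 2, endian = "little")
  meta <- c(el(0x0002, 0x0010, "UI", lamcyst:::EXPLICIT_LE))
  meta <- c(el(0x0002, 0x0000, "UL", length(meta)), meta)
  ds <- c(el(0x0020, 0x000E, "UI", "1.2.3.4"),
          el(0x0020, 0x0032, "DS", c("0", "0", "0")),
          el(0x0028, 0x0010, "US", 4L), el(0x0028, 0x0011, "US", 4L),
          el(0x0028, 0x0030, "DS", c("1", "1")),
          el(0x0028, 0x0100, "US", 16L), el(0x0028, 0x0103, "US", 0L),
          el(0x0028, 0x1053, "DS", "1"),
          el(0x7FE0, 0x0010, "OW", px))
  d2 <- withr::local_tempdir()
  for (f in c("a.dcm", "b.dcm")) {
    con <- file(file.path(d2, f), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  # both files share one z position -> patch the second one
  expect_error(read_dicom_series(d2), "0028,1052")
})

test_that("our DICOM output agrees with an independent reader (pydicom)", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  b <- make_phantom(tiny_spec(noise_sd = 5))
  d <- withr::local_tempdir()
  paths <- write_dicom_series(b$volume, d, patient_id = "XCHK")
  script <- sprintf(
    "import pydicom; d = pydicom.dcmread(r'%s'); print(float(d.pixel_array.astype('float64').mean()*float(d.RescaleSlope)+float(d.RescaleIntercept)), d.PatientID, float(d.PixelSpacing[0]))",
    paths[5])
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  parts <- strsplit(out, " ")[[1]]
  expect_equal(as.numeric(parts[1]), mean(round(b$volume$voxels[, , 5])),
               tolerance = 1e-6)
  expect_identical(parts[2], "XCHK")
  expect_equal(as.numeric(parts[3]), 1)
})

test_that("NIfTI mask round trip is voxelwise exact and counts match", {
  b <- make_phantom(tiny_spec(noise_sd = 0))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(b$truth_cyst, f, reference = b$volume)
  back <- read_mask(f, b$volume, "truth_cyst")
  expect_identical(back$voxels, b$truth_cyst$voxels)
  expect_identical(sum(back$voxels), sum(b$truth_cyst$voxels))

  empty <- mask_volume(array(FALSE, dim(b$volume$voxels)), b$volume, "cyst")
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(empty, f2)
  expect_identical(sum(read_mask(f2, b$volume, "cyst")$voxels), 0L)

  other <- ct_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_error(write_mask(b$truth_cyst, f, reference = other), "grid")
})

test_that("configuration loading merges, warns and validates", {
  cfg <- load_config(NULL)
  expect_identical(cfg, default_config())

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("schema_version: 1", "lung_threshold_hu: -300",
               "nonsense_key: 5"), f)
  expect_warning(cfg2 <- load_config(f), "nonsense_key")
  expect_equal(cfg2$lung_threshold_hu, -300)
  expect_equal(cfg2$hist_upper_hu, default_config()$hist_upper_hu)

  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("schema_version: 1", "kernel_widths:", "  BAD: -1"), f2)
  expect_error(load_config(f2), "non-negative")
})

test_that("kernel width 0 makes harmonization the identity", {
  b <- make_phantom(tiny_spec(noise_sd = 5, kernel = "STANDARD"))
  cfg <- default_config()
  cfg$kernel_widths$STANDARD <- 0
  h <- harmonize_resolution(b$volume, cfg)
  expect_identical(h$voxels, b$volume$voxels)
})
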