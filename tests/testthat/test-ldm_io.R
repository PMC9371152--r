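test_that("row-wise and column-wise dialects parse to the same trace", {
  rw <- parse_ldm_text("0.00 0.01 0.02\n7.300 7.302 7.301")
  expect_s3_class(rw, "ldm_trace")
  expect_length(rw$t, 3L)
  expect_equal(rw$nominal_rate, 100)
  expect_equal(rw$d, c(7.300, 7.302, 7.301))

  cw <- parse_ldm_text("0.00 7.300\n0.01 7.302\n0.02 7.301", dialect = "auto")
  expect_equal(cw$t, rw$t)
  expect_equal(cw$d, rw$d)

  # semicolon separators and decimal commas are device-software variants
  dirty <- parse_ldm_text("0,00;0,01;0,02\n7,300;7,302;7,301")
  expect_equal(dirty$d, rw$d)

  mm <- parse_ldm_text("0.00 0.01 0.02\n7300 7302 7301", units = "mm")
  expect_equal(mm$d, rw$d)
})

test_that("malformed traces raise parse errors", {
  expect_error(parse_ldm_text("0.00 0.02 0.01\n1 2 3"),
               class = "ldm_parse_error")            # non-monotone time
  expect_error(parse_ldm_text("0.00 0.01\n1 2 3"),
               class = "ldm_parse_error")            # unequal counts
  expect_error(parse_ldm_text(""), class = "ldm_parse_error")
  expect_error(parse_ldm_text("0 0.01 0.02\nabc 2 3"),
               class = "ldm_parse_error")            # garbage token
  # a 5x off-nominal sampling interval is rejected
  expect_error(ldm_trace(c(0, 0.05, 0.10), c(1, 2, 3), nominal_rate = 100),
               class = "ldm_parse_error")
})

test_that("parse -> serialize -> parse round-trips bit-exactly", {
  set.seed(11)
  t <- seq(0, 2, by = 0.01)
  d <- 7.3 + cumsum(runif(length(t), 0, 0.12))
  d[sample(length(d), 5)] <- NaN                      # dropouts survive too
  tr <- ldm_trace(t, d)
  for (dialect in c("row-wise", "column-wise")) {
    back <- parse_ldm_text(write_ldm_text(tr, dialect), dialect = dialect)
    expect_identical(back$t, tr$t)
    expect_identical(back$d, tr$d)
  }
})

test_that("calibration subtracts L1 and is invertible", {
  tr <- ldm_trace(c(0, 0.01, 0.02), c(7.30, 7.31, 7.35))
  cal <- apply_calibration(tr, 7.30)
  expect_equal(cal$x, c(0, 0.01, 0.05))
  expect_identical(cal$x[1], 0)                       # L1 equal to d_0
  expect_identical(cal$x + cal$L1, tr$d)              # invertible

  # the measuring distance is the raw distance minus the calibration
  # distance (L2 = L3 - L1)
  one <- apply_calibration(ldm_trace(0, 57.3, nominal_rate = 100), 7.3)
  expect_equal(one$x, 50)

  expect_error(apply_calibration(tr, 0), class = "ldm_calibration_error")
  expect_error(apply_calibration(tr, -1), class = "ldm_calibration_error")
})

test_that("metadata validates and round-trips through the flat file", {
  expect_error(measurement_meta(calibration_distance_L1 = -1),
               class = "ldm_calibration_error")
  expect_error(measurement_meta(7.3, max_speed_tolerance = 0.7),
               class = "ldm_config_error")

  meta <- measurement_meta(7.3, wind = 1.2, first_leg_on_start = "L",
                           official_time = 10.39,
                           athlete = list(name = "test", height_cm = "177.6"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_meta(meta, path)
  back <- read_meta(path)
  expect_equal(back$calibration_distance_L1, 7.3)
  expect_equal(back$max_speed_tolerance, 0.02)
  expect_equal(back$first_leg_on_start, "L")
  expect_equal(back$wind, 1.2)
  expect_equal(back$official_time, 10.39)
  expect_equal(back$athlete$name, "test")
})

test_that("trace CSV export writes t and x", {
  cal <- apply_calibration(ldm_trace(c(0, 0.01), c(7.3, 7.4)), 7.3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(cal, path)
  back <- utils::read.csv(path)
  expect_equal(back$t, cal$t)
  expect_equal(back$x, cal$x, tolerance = 1e-12)
})

test_that("beam spot growth over the measuring range matches the device sheet", {
  specs <- ldm_device_specs()
  expect_equal(beam_spread_factor(specs$spot_area_mm2[["10m"]],
                                  specs$spot_area_mm2[["100m"]]), 12.9)
})
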