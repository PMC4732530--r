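make_mini_survey <- function(path) {
  writeLines(c(
    "location_id,lon,lat,sample_date,i131,cs137,te129m",
    "A,140.70,37.55,2011-06-14,17,7900,920",
    "B,140.80,37.50,2011-06-14,ND,1300,220",
    "C,140.90,37.60,2011-06-14,2.8,1300,"), path)
  path
}

test_that("survey files parse with typed records and missing tokens", {
  path <- withr::local_tempfile(fileext = ".csv")
  make_mini_survey(path)
  rec <- read_survey(path)
  expect_equal(nrow(rec), 3)
  expect_true(is.na(rec$i131[2]))
  expect_true(is.na(rec$te129m[3]))
  expect_s3_class(rec$sample_date, "Date")
  # malformed numeric is rejected with its row number
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("location_id,lon,lat,sample_date,i131,cs137,te129m",
               "A,140.7,37.5,2011-06-14,x17,7900,920"), bad)
  expect_error(read_survey(bad), "row 1.*i131")
  # unknown columns warn, required columns are enforced
  extra <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("location_id,lon,lat,sample_date,i131,cs137,te129m,foo",
               "A,140.7,37.5,2011-06-14,1,2,3,4"), extra)
  expect_warning(read_survey(extra), "unknown survey column")
  hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines("location_id,lon,lat", hdr)
  expect_error(read_survey(hdr), "required column")
})

test_that("the bundled 72-location fixture loads with no rejects", {
  rec <- read_survey(extdata("dose_table_72_locations.csv"))
  expect_equal(nrow(rec), 72)
  expect_equal(sum(is.na(rec$cs137)), 0)
  expect_equal(sum(!is.na(rec$te129m)), 46)  # 26 rows lack Te-129m
})

test_that("the pipeline reproduces the highest published dose from printed ratios", {
  rec <- data.frame(location_id = "Akogi-Teshichiro",
                    lon = 140.7541, lat = 37.59606,
                    sample_date = as.Date("2011-06-14"),
                    i131 = NA_real_, cs137 = 7900, te129m = NA_real_,
                    r_i = 5.6, r_t = 1.1)
  res <- run_pipeline(rec, beta_dose_model(paper_param()))
  expect_equal(res$table$d_a, 710, tolerance = 0.01)
  # both dose paths agree after calibration
  res2 <- run_pipeline(rec, beta_dose_model(paper_param()),
                       method = "integral")
  expect_equal(res$table$d_a, res2$table$d_a, tolerance = 1e-6)
})

test_that("pipeline keeps every record, excludes doses only with a reason", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- read_survey(make_mini_survey(path))
  res <- run_pipeline(rec)
  expect_equal(nrow(res$table), 3)
  expect_equal(res$n_excluded, 1)         # record B lacks I-131
  expect_true(is.na(res$table$d_a[res$table$location_id == "B"]))
  expect_false(anyNA(res$table$r_t))      # C's r_t filled by interpolation
  expect_equal(res$table$r_t_origin[res$table$location_id == "C"],
               "interpolated")
  # zero deposition gives a zero dose
  rec0 <- data.frame(location_id = "Z", lon = 140, lat = 37,
                     sample_date = as.Date("2011-06-14"),
                     i131 = NA_real_, cs137 = 0, te129m = NA_real_,
                     r_i = 9.2, r_t = 1)
  expect_equal(run_pipeline(rec0)$table$d_a, 0)
  # interpolating r_i is off by default, on by request
  res_ri <- run_pipeline(rec, interpolate_r_i = TRUE)
  expect_equal(res_ri$n_excluded, 0)
  expect_equal(res_ri$table$r_i_origin[res_ri$table$location_id == "B"],
               "interpolated")
})

test_that("dose tables are written deterministically and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- read_survey(make_mini_survey(path))
  res <- run_pipeline(rec)
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_dose_table(res, out1)
  write_dose_table(res$table[c(3, 1, 2), ], out2)  # permuted input
  expect_identical(readLines(out1), readLines(out2))
  back <- read_survey(out1)
  expect_equal(back$cs137, res$table$cs137[order(res$table$location_id)])
  # empty table: header only
  empty <- withr::local_tempfile(fileext = ".csv")
  write_dose_table(res$table[0, ], empty)
  expect_equal(length(readLines(empty)), 1)
  # fixture: 72 data lines
  full <- withr::local_tempfile(fileext = ".csv")
  rec72 <- read_survey(extdata("dose_table_72_locations.csv"))
  res72 <- run_pipeline(rec72, beta_dose_model(paper_param()))
  write_dose_table(res72, full)
  expect_equal(length(readLines(full)), 73)
})

test_that("report rounding follows the table convention", {
  expect_equal(format_dose(c(710.21, 476.52, 99.96, 5.23)),
               c(710, 477, 100.0, 5.2))
})

test_that("model configurations round-trip through the key-value dialect", {
  m <- beta_dose_model(paper_param(), te_split = 0.3, cs_split = 0.7)
  path <- withr::local_tempfile(fileext = ".dcf")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$nuclides$d0, m$nuclides$d0, tolerance = 1e-10)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(attr(m2$nuclides, "reference_date"),
               attr(m$nuclides, "reference_date"))
  expect_equal(m2$te_split, 0.3)
  # invalid record type is refused
  bad <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c("type: banana", "a: 1"), bad)
  expect_error(read_model_config(bad), "unknown record type")
})

test_that("the command-line interface drives the pipeline end to end", {
  out_dir <- withr::local_tempdir()
  path <- withr::local_tempfile(fileext = ".csv")
  make_mini_survey(path)
  # fit-table writes the six-row intercept table
  expect_equal(betadose_cli(c("fit-table", "--out-dir", out_dir, "--quiet")),
               0L)
  tab <- utils::read.csv(file.path(out_dir, "fit_table.csv"))
  expect_equal(nrow(tab), 6)
  # dose on the bundled fixture emits 72 rows
  expect_equal(betadose_cli(c("dose", "--survey",
                              extdata("dose_table_72_locations.csv"),
                              "--out-dir", out_dir, "--quiet")), 0L)
  dt <- utils::read.csv(file.path(out_dir, "dose_table.csv"))
  expect_equal(nrow(dt), 72)
  # map writes rasters
  expect_equal(betadose_cli(c("map", "--survey", path,
                              "--out-dir", out_dir, "--quiet",
                              "--ncols", "30")), 0L)
  expect_true(file.exists(file.path(out_dir, "dose_map.asc")))
  # curve and calibrate
  expect_equal(betadose_cli(c("curve", "--out-dir", out_dir, "--quiet")), 0L)
  expect_true(file.exists(file.path(out_dir, "dose_rate_curve.csv")))
  # failures exit non-zero with a usage message
  quiet_cli <- function(args) {
    status <- NULL
    utils::capture.output(
      status <- suppressMessages(betadose_cli(args)), type = "message")
    status
  }
  expect_equal(quiet_cli("frobnicate"), 1L)
  expect_equal(quiet_cli(c("dose", "--quiet")), 1L)
  expect_equal(quiet_cli(c("dose", "--survey", "missing.csv", "--quiet")), 1L)
})
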