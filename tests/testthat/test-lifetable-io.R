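test_that("generated tables pass validation; seeded corruptions are caught", {
  lt <- make_lifetable(siler_preset("modern"))
  expect_s3_class(lt, "abridged_lifetable")
  expect_equal(nrow(validate_lifetable(lt)), 0)

  # a exceeding the interval width
  bad <- lt
  bad$intervals$a[3] <- 7
  rep <- validate_lifetable(bad)
  expect_true("a_within_width" %in% rep$invariant)
  expect_equal(rep$interval[rep$invariant == "a_within_width"], 3L)

  # negative deaths
  bad <- lt
  bad$intervals$d[2] <- -1
  expect_true("d_nonnegative" %in% validate_lifetable(bad)$invariant)

  # radix mismatch (sum d = 0.9 radix)
  bad <- lt
  bad$intervals$d <- bad$intervals$d * 0.9
  bad$intervals$l <- NULL
  expect_true("radix_conservation" %in% validate_lifetable(bad)$invariant)

  # gap in the age layout
  iv <- lt$intervals[-4, ]  # drop the 10-14 row
  gap <- abridged_lifetable(x = iv$x, n = iv$n, d = iv$d, a = iv$a,
                            radix = sum(iv$d))
  rep <- validate_lifetable(gap)
  expect_true("contiguity" %in% rep$invariant)
  expect_match(rep$message[rep$invariant == "contiguity"], "10")
  expect_match(rep$message[rep$invariant == "contiguity"], "15")

  # no open-ended terminal interval
  iv <- lt$intervals
  iv$n[nrow(iv)] <- 10
  closed <- abridged_lifetable(x = iv$x, n = iv$n, d = iv$d, a = iv$a,
                               radix = sum(iv$d))
  expect_true("terminal_open" %in% validate_lifetable(closed)$invariant)
})

test_that("WPP-dialect reader builds one valid table per location-year-sex", {
  t1 <- make_lifetable(siler_preset("modern"),
                       meta = list(country = "Alpha", year = 2000, sex = "both"))
  t2 <- make_lifetable(siler_preset("historical"),
                       meta = list(country = "Alpha", year = 1950, sex = "both"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_wpp_fixture(list(t1, t2), path)
  tabs <- read_unwpp_csv(path)
  expect_length(tabs, 2)
  for (tt in tabs) {
    expect_equal(nrow(validate_lifetable(tt)), 0)
    expect_equal(nrow(tt$intervals), 22)
  }
  years <- sort(unname(vapply(tabs, function(t) as.numeric(t$meta$year),
                              numeric(1))))
  expect_equal(years, c(1950, 2000))
})

test_that("reader errors name missing columns and non-contiguous ages", {
  t1 <- make_lifetable(siler_preset("modern"),
                       meta = list(country = "A", year = 2000, sex = "both"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_wpp_fixture(list(t1), path)

  raw <- utils::read.csv(path)
  raw$dx <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path2, row.names = FALSE)
  expect_error(read_unwpp_csv(path2), "dx|\\bd\\b")

  raw <- utils::read.csv(path)
  raw <- raw[raw$AgeGrpStart != 10, ]  # gap between ages 10 and 15
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path3, row.names = FALSE)
  err <- tryCatch(read_unwpp_csv(path3), error = conditionMessage)
  expect_match(err, "10")
  expect_match(err, "15")
})

test_that("generic reader honours the column map and matches the WPP reader", {
  lt <- make_lifetable(siler_preset("modern"),
                       meta = list(country = "A", year = 2000, sex = "both"))
  iv <- lt$intervals
  toy <- data.frame(age = iv$x, width = ifelse(is.na(iv$n), -1, iv$n),
                    dx = iv$d, ax = iv$a)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(format(toy, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  tabs <- read_generic(path, c(x = "age", n = "width", d = "dx", a = "ax"))
  expect_length(tabs, 1)
  expect_equal(nrow(validate_lifetable(tabs[[1]])), 0)
  expect_equal(tabs[[1]]$intervals$d, iv$d, tolerance = 1e-12)

  expect_error(read_generic(path, c(x = "age", n = "width", a = "ax")), "d")

  # UN-dialect headers read through both readers give identical tables
  wpp <- withr::local_tempfile(fileext = ".csv")
  write_wpp_fixture(list(lt), wpp)
  via_unwpp <- read_unwpp_csv(wpp)[[1]]
  via_generic <- read_generic(
    wpp, c(location = "Location", year = "Time", sex = "Sex",
           x = "AgeGrpStart", n = "AgeGrpSpan", d = "dx", a = "ax",
           l = "lx", e = "ex"))[[1]]
  expect_equal(via_generic$intervals, via_unwpp$intervals, tolerance = 1e-12)
})

test_that("write/read round trip preserves d, a, l, e to 1e-12 relative", {
  tabs <- random_tables(3, seed = 11)
  for (i in seq_along(tabs)) {
    tabs[[i]]$meta <- list(country = paste0("C", i), year = 2000 + i,
                           sex = "both")
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_generic(tabs, path)
  back <- read_generic(path, c(location = "location", year = "year",
                               sex = "sex", x = "x", n = "n", d = "d",
                               a = "a", l = "l", e = "e"))
  expect_length(back, 3)
  back <- back[order(vapply(back, function(t) t$meta$country, character(1)))]
  for (i in seq_along(tabs)) {
    for (col in c("d", "a", "l", "e")) {
      expect_equal(back[[i]]$intervals[[col]], tabs[[i]]$intervals[[col]],
                   tolerance = 1e-12)
    }
  }
})

test_that("dataset writer emits six files with the exact schema header", {
  lt1 <- make_lifetable(siler_preset("modern"),
                        meta = list(country = "A", ISO3 = "AAA", year = 2000,
                                    sex = "both"))
  recs <- rbind(compute_measures(lt1, "total"), compute_measures(lt1, "15"))
  dir <- withr::local_tempdir()
  paths <- write_dataset(recs, "TEST", dir)
  expect_length(paths, 6)
  expect_setequal(basename(paths),
                  paste0("TEST_", rep(c("both", "female", "male"), each = 2),
                         "_", rep(c("total", "15"), 3), ".csv"))
  for (p in paths) {
    header <- strsplit(readLines(p, n = 1), ",")[[1]]
    expect_equal(gsub('"', "", header), dataset_columns())
  }
  filled <- utils::read.csv(file.path(dir, "TEST_both_total.csv"))
  expect_equal(nrow(filled), 1)
  empty <- utils::read.csv(file.path(dir, "TEST_female_total.csv"))
  expect_equal(nrow(empty), 0)

  # empty record set still produces six header-only files
  dir2 <- withr::local_tempdir()
  paths2 <- write_dataset(NULL, "EMPTY", dir2)
  expect_length(paths2, 6)
  expect_true(all(vapply(paths2, function(p) length(readLines(p)) == 1,
                         logical(1))))

  # unknown scope is rejected with the record's identifier
  bad <- recs
  bad$scope[1] <- "adult"
  expect_error(write_dataset(bad, "X", withr::local_tempdir()), "AAA2000")
})
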