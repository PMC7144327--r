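test_that("reading a hand-written table preserves records and channels", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,channel,frame,x_nm,y_nm,z_nm,photons,bg,sigma_xy_nm,sigma_z_nm",
    "0,bassoon,0,100.5,200.25,-50.0,1200,4.5,9.8,24.0",
    "1,bassoon,1,110.0,210.0,-45.0,900,5.0,10.1,26.0",
    "2,Homer1,0,230.0,205.0,70.0,1500,5.2,9.5,25.5"), f)
  tb <- readLocalizations(f)
  expect_s4_class(tb, "LocalizationTable")
  expect_equal(nLocs(tb), 3L)
  expect_equal(channels(tb), c("bassoon", "Homer1"))
  expect_equal(locData(tb)$x_nm, c(100.5, 110, 230))
  expect_equal(locData(tb)$id, 0:2)
})

test_that("a header-only file yields an empty table without error", {
  f <- tempfile(fileext = ".csv")
  writeLines("id,channel,frame,x_nm,y_nm,z_nm,photons,bg,sigma_xy_nm,sigma_z_nm",
             f)
  tb <- readLocalizations(f)
  expect_equal(nLocs(tb), 0L)
})

test_that("write -> read -> write is byte-identical on canonical files", {
  tb <- makeFixtureTable(7)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeLocalizations(tb, f1)
  writeLocalizations(readLocalizations(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  tb2 <- readLocalizations(f2)
  expect_equal(locData(tb2)$x_nm, locData(tb)$x_nm, tolerance = 1e-6)
  expect_equal(locData(tb2)$z_nm, locData(tb)$z_nm, tolerance = 1e-6)
})

test_that("format errors name the offending column and row", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,channel,frame,x_nm,y_nm,photons,bg,sigma_xy_nm,sigma_z_nm",
               "0,bassoon,0,1,2,3,4,5,6"), f)
  expect_error(readLocalizations(f), "z_nm")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("id,channel,frame,x_nm,y_nm,z_nm,photons,bg,sigma_xy_nm,sigma_z_nm",
               "0,bassoon,0,1.0,2.0,3.0,1000,5,10,25",
               "1,bassoon,0,oops,2.0,3.0,1000,5,10,25"), f2)
  expect_error(readLocalizations(f2), "row 2")
})

test_that("cluster assignment column is written only when set", {
  tb <- makeFixtureTable(4)
  f <- tempfile(fileext = ".csv")
  writeLocalizations(tb, f)
  expect_false(grepl("cluster_id", readLines(f)[5]))
  d <- locData(tb); d$cluster_id <- c(0L, 0L, -1L, 1L)
  writeLocalizations(localizationTable(d, locMeta(tb)), f)
  expect_true(grepl("cluster_id", readLines(f)[5]))
  tb2 <- readLocalizations(f)
  expect_equal(locData(tb2)$cluster_id, c(0L, 0L, -1L, 1L))
})

test_that("a zero-record table writes a header-only file", {
  tb <- localizationTable(
    data.frame(channel = character(0), frame = integer(0),
               x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
               photons = numeric(0), bg = numeric(0),
               sigma_xy_nm = numeric(0), sigma_z_nm = numeric(0)),
    list(channels = "GLT1"))
  f <- tempfile(fileext = ".csv")
  writeLocalizations(tb, f)
  lines <- readLines(f)
  expect_equal(length(lines), 5L)  # 4 meta lines + header
  expect_match(lines[5], "^id,channel,frame")
})

test_that("channel filtering partitions the table and keeps provenance", {
  tb <- makeFixtureTable(9, channels = c("GLT1", "bassoon", "Homer1"))
  subs <- lapply(channels(tb), function(ch) filterByChannel(tb, ch))
  expect_equal(sum(vapply(subs, nLocs, integer(1))), nLocs(tb))
  recovered <- sort(unlist(lapply(subs, function(s) locData(s)$orig_id)))
  expect_equal(recovered, locData(tb)$id)
  expect_equal(locMeta(subs[[1]])$channels, channels(tb))
  # filtering on a channel with no records gives an empty table
  d <- locData(tb); d <- d[d$channel != "GLT1", ]
  tb2 <- localizationTable(d, locMeta(tb))
  expect_equal(nLocs(filterByChannel(tb2, "GLT1")), 0L)
  expect_error(filterByChannel(tb, "psd95"), "GLT1")
})
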