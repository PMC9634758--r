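test_that("vcg_record validates its invariants", {
  expect_error(vcg_record(matrix(1, 5, 2)), "3 leads")
  expect_error(vcg_record(matrix(NA_real_, 5, 3)), "non-finite")
  expect_error(vcg_record(matrix(1, 5, 3), fs = 0), "fs")
  r <- vcg_record(matrix(1:15, 5, 3), fs = 1000, record_id = "r1")
  expect_equal(n_samples(r), 5)
  expect_equal(colnames(r$leads), c("X", "Y", "Z"))
})

test_that("CSV records round-trip with channel selection rules", {
  d <- data.frame(x = rnorm(100), y = rnorm(100), z = rnorm(100))
  p <- tempfile(fileext = ".csv")
  utils::write.csv(d, p, row.names = FALSE)
  r <- read_vcg(p, fs = 1000)
  expect_equal(n_samples(r), 100)
  expect_equal(unname(r$leads[, 2]), d$y)

  # >3 channels: Frank leads picked automatically, mapping honoured
  d15 <- as.data.frame(matrix(rnorm(100 * 15), ncol = 15))
  names(d15) <- c(paste0("ch", 1:12), "vx", "vy", "vz")
  p15 <- tempfile(fileext = ".csv")
  utils::write.csv(d15, p15, row.names = FALSE)
  r15 <- read_vcg(p15, fs = 1000)
  expect_equal(unname(r15$leads[, 1]), d15$vx)
  rmap <- read_vcg(p15, fs = 1000, channels = c("ch2", "ch4", "ch6"))
  expect_equal(unname(rmap$leads[, 3]), d15$ch6)
  expect_error(read_vcg(p15, fs = 1000, channels = c("a", "b", "c")),
               "missing lead")

  # 2 channels: missing lead
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(d[, 1:2], p2, row.names = FALSE)
  expect_error(read_vcg(p2, fs = 1000), "missing lead")

  # mV units are scaled to GAIN.mV
  rmv <- read_vcg(p, fs = 1000, units = "mv")
  expect_equal(unname(rmv$leads[, 1]), 2000 * d$x)
})

test_that("WFDB-style format-16 records are read with gain scaling", {
  dir <- tempfile(); dir.create(dir)
  n <- 400
  sig <- matrix(as.integer(round(2000 * sin(outer(seq_len(n) / 50, 1:3)))),
                ncol = 3)
  writeBin(as.integer(t(sig)), file.path(dir, "rec01.dat"), size = 2,
           endian = "little")
  writeLines(c(
    "rec01 3 1000 400",
    "rec01.dat 16 2000 16 0 0 0 0 vx",
    "rec01.dat 16 2000 16 0 0 0 0 vy",
    "rec01.dat 16 2000 16 0 0 0 0 vz"
  ), file.path(dir, "rec01.hea"))
  r <- read_vcg(file.path(dir, "rec01.hea"))
  expect_equal(r$fs, 1000)
  # gain 2000 ADC/mV -> stored units are already GAIN.mV
  expect_equal(unname(r$leads), unname(sig * 1.0))
  expect_error(read_vcg(file.path(dir, "missing.hea")), "unreadable header")
})

test_that("non-1000 Hz records are resampled on ingestion", {
  t5 <- seq_len(2000) / 500  # 4 s at 500 Hz
  d <- data.frame(x = sin(2 * pi * 5 * t5), y = cos(2 * pi * 5 * t5),
                  z = sin(2 * pi * 2 * t5))
  p <- tempfile(fileext = ".csv")
  utils::write.csv(d, p, row.names = FALSE)
  r <- read_vcg(p, fs = 500)
  expect_equal(r$fs, 1000)
  expect_equal(n_samples(r), 4000)
  t1 <- seq_len(4000) / 1000
  mid <- 500:3500
  expect_equal(r$leads[mid, 1], sin(2 * pi * 5 * t1)[mid], tolerance = 0.05)
})

test_that("fiducial tables round-trip through CSV and JSON", {
  tab <- structure(list(
    R = matrix(c(500L, 505L, 498L, 1400L, 1402L, 1399L), 3, 2),
    Q = matrix(c(460L, 462L, 459L, 1360L, 1361L, 1358L), 3, 2),
    S = matrix(c(540L, 544L, 541L, 1442L, 1444L, 1440L), 3, 2),
    PQ_begin = matrix(c(420L, 421L, 419L, 1320L, 1322L, 1318L), 3, 2),
    PQ_end = matrix(c(439L, 440L, 438L, 1339L, 1341L, 1337L), 3, 2)),
    class = "fiducial_table")
  summ <- structure(list(boundL = 90L, boundR = 60L,
                         ISO = matrix(rnorm(6), 3, 2)),
                    class = "loop_summary")
  for (fmt in c("csv", "json")) {
    p <- tempfile(fileext = paste0(".", fmt))
    write_fiducials(tab, summ, p, format = fmt)
    back <- read_fiducials(p, format = fmt)
    expect_equal(back$table$R, tab$R)
    expect_equal(back$table$PQ_begin, tab$PQ_begin)
    expect_equal(back$summary$boundL, summ$boundL)
    expect_equal(back$summary$ISO, summ$ISO, tolerance = 1e-12)
    # second round trip is the identity
    p2 <- tempfile(fileext = paste0(".", fmt))
    write_fiducials(back$table, back$summary, p2, format = fmt)
    expect_equal(read_fiducials(p2, format = fmt)$table, back$table)
  }
  # millisecond columns are index * (1000/fs)
  p <- tempfile(fileext = ".csv")
  write_fiducials(tab, summ, p, fs = 1000, format = "csv")
  df <- utils::read.csv(p)
  expect_equal(df$r_ms, df$r * 1)
  expect_equal(df$q0, df$q - 1)
})

test_that("an empty fiducial table writes a header-only file with warning", {
  empty <- structure(list(R = matrix(integer(), 3, 0),
                          Q = matrix(integer(), 3, 0),
                          S = matrix(integer(), 3, 0),
                          PQ_begin = matrix(integer(), 3, 0),
                          PQ_end = matrix(integer(), 3, 0)),
                     class = "fiducial_table")
  p <- tempfile(fileext = ".csv")
  expect_warning(write_fiducials(empty, NULL, p), "empty")
  df <- utils::read.csv(p)
  expect_equal(nrow(df), 0)
})
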