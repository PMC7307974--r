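test_that("counts CSV round-trips through the long format", {
  set.seed(50)
  sc <- surveillanceCounts(matrix(rpois(12, 20), 3, 4),
                           matrix(runif(12, 10, 30), 3, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  writeCountsCSV(sc, path)
  back <- readCountsCSV(path)
  expect_equal(counts(back), counts(sc))
  expect_equal(expectedCounts(back), expectedCounts(sc))
  expect_identical(rownames(back), rownames(sc))
})

test_that("counts CSV validation names the offending cells", {
  df <- data.frame(area = rep(c("a", "b"), each = 2),
                   time = rep(1:2, 2), count = c(1, 2, 3, 4),
                   expected = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[-2, ], path, row.names = FALSE)
  expect_error(readCountsCSV(path), "missing cell \\(area=a, time=2\\)")

  bad <- df; bad$count[3] <- -1
  write.csv(bad, path, row.names = FALSE)
  expect_error(readCountsCSV(path), "negative counts.*3")

  bad <- df; bad$expected[2] <- 0
  write.csv(bad, path, row.names = FALSE)
  expect_error(readCountsCSV(path), "non-positive expected.*2")

  write.csv(df[, 1:3], path, row.names = FALSE)
  expect_error(readCountsCSV(path), "columns")
})

test_that("surveillance counts enforce their invariants", {
  expect_error(surveillanceCounts(matrix(-1, 2, 2), matrix(1, 2, 2)),
               "non-negative")
  expect_error(surveillanceCounts(matrix(1.5, 2, 2), matrix(1, 2, 2)),
               "non-negative integers")
  expect_error(surveillanceCounts(matrix(1, 2, 2), matrix(0, 2, 2)),
               "strictly positive")
  expect_error(surveillanceCounts(matrix(1, 2, 2), matrix(1, 3, 2)),
               "identical dimensions")
})

test_that("district traffic volume sums length times AADF over segments", {
  one <- data.frame(district_id = "D1", length = c(2, 3), aadf = c(100, 50))
  expect_equal(aggregateExposure(one), c(D1 = 350))

  set.seed(51)
  seg <- data.frame(district_id = sample(c("A", "B"), 30, replace = TRUE),
                    length = runif(30, 0.1, 5), aadf = runif(30, 100, 5000))
  tv <- aggregateExposure(seg)
  loop <- c(A = 0, B = 0)
  for (r in seq_len(30)) {
    loop[seg$district_id[r]] <- loop[seg$district_id[r]] +
      seg$length[r] * seg$aadf[r]
  }
  expect_equal(tv[c("A", "B")], loop)
  # a district with no segments is absent
  expect_false("C" %in% names(tv))

  expect_error(aggregateExposure(data.frame(district_id = "A", length = 0,
                                            aadf = 1)), "positive")
  expect_error(aggregateExposure(data.frame()), "non-empty")
})

test_that("the CLI pipeline simulates, fits, detects and evaluates", {
  dir <- withr::local_tempdir()
  pre <- file.path(dir, "s2")
  status <- runCLI(c("simulate", "--scenario", "S2", "--rows", "3",
                     "--cols", "3", "--seed", "5", "--nunusual", "2",
                     "--timepoints", "8", "--out", pre))
  expect_identical(status, 0L)
  expect_true(file.exists(paste0(pre, "_counts.csv")))
  expect_true(file.exists(paste0(pre, "_truth.csv")))
  meta <- read.csv(paste0(pre, "_meta.csv"))
  expect_true("seed" %in% meta$key)

  status <- runCLI(c("fit", "--counts", paste0(pre, "_counts.csv"),
                     "--rows", "3", "--cols", "3", "--model", "proposed",
                     "--iters", "400", "--burnin", "200", "--chains", "1",
                     "--seed", "2", "--out", pre))
  expect_identical(status, 0L)
  expect_true(file.exists(paste0(pre, "_f.csv")))

  status <- runCLI(c("detect", "--f", paste0(pre, "_f.csv"),
                     "--rule", "fixed", "--level", "0.5",
                     "--out", file.path(dir, "det.csv")))
  expect_identical(status, 0L)

  status <- runCLI(c("evaluate", "--truth", paste0(pre, "_truth.csv"),
                     "--detections", file.path(dir, "det.csv"),
                     "--out", file.path(dir, "metrics.csv")))
  expect_identical(status, 0L)
  metrics <- read.csv(file.path(dir, "metrics.csv"))
  expect_true(all(c("sensitivity", "fpProportion") %in% names(metrics)))

  # identical seeds reproduce the simulation bit for bit
  pre2 <- file.path(dir, "again")
  runCLI(c("simulate", "--scenario", "S2", "--rows", "3", "--cols", "3",
           "--seed", "5", "--nunusual", "2", "--timepoints", "8",
           "--out", pre2))
  expect_identical(readLines(paste0(pre, "_counts.csv")),
                   readLines(paste0(pre2, "_counts.csv")))
})

test_that("the CLI rejects unknown scenarios and subcommands", {
  expect_identical(suppressMessages(runCLI(c("simulate", "--scenario", "S99",
                                             "--rows", "2", "--cols", "2",
                                             "--out", tempfile()))), 2L)
  expect_identical(suppressMessages(runCLI("frobnicate")), 2L)
  expect_identical(suppressMessages(runCLI(character())), 2L)
})
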