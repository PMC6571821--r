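test_that("long_table enforces the complete-design invariants", {
  tbl <- toy_table(S_per_group = 1, J = 3, times = c(0, 2, 4, 24))
  expect_s3_class(tbl, "long_table")
  d <- table_dims(tbl)
  expect_equal(d$n_units, 2)
  expect_equal(d$n_times, 4)
  expect_equal(d$n_samples, 8)

  # duplicate (unit, time)
  X <- matrix(1:12, 4, 3)
  expect_error(
    long_table(X, subject = c("a", "a", "b", "b"), group = rep("g1", 4),
               time = c(0, 0, 0, 2)),
    "duplicate sample")
  # incomplete design: unit b misses time 24
  expect_error(
    long_table(rbind(X, X[1:2, ]), subject = c("a", "a", "a", "a", "b", "b"),
               group = rep("g1", 6), time = c(0, 2, 4, 24, 0, 2)),
    "full")
  # group varying within a unit
  expect_error(
    long_table(X, subject = rep("a", 4), group = c("g1", "g1", "g2", "g2"),
               time = c(0, 2, 4, 24)),
    "group label varies")
})

test_that("CSV round trip is the identity on values and metadata", {
  tbl <- toy_table(S_per_group = 2, J = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(tbl, path)
  back <- read_long_csv(path)
  expect_equal(back$X, tbl$X, ignore_attr = TRUE)
  expect_equal(back$samples$unit, tbl$samples$unit)
  expect_equal(back$samples$time, tbl$samples$time)
  expect_equal(as.character(back$samples$group), as.character(tbl$samples$group))
})

test_that("read_long_csv validates the schema and flags constant variables", {
  df <- data.frame(subject = rep(c("a", "b"), each = 2), group = "g1",
                   time = rep(c(0, 2), 2), V1 = c(1, 2, 3, 4), V2 = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_message(tbl <- read_long_csv(path), "constant")
  expect_equal(ncol(tbl$X), 2)
  expect_error(read_long_csv(path, schema = list(subject = "nope",
                                                 group = "group", time = "time")),
               "schema error")
  expect_error(read_long_csv(file.path(tempdir(), "no-such-file.csv")),
               "not found")
})

test_that("to_cube indexes correctly and round-trips with from_cube", {
  tbl <- toy_table(S_per_group = 1, J = 3, seed = 5)
  cube <- to_cube(tbl)
  expect_equal(dim(cube$X3), c(2, 3, 4))
  # indexing identity: entry (unit, variable, time) matches the long table
  s <- tbl$samples
  for (r in c(1L, 4L, 6L)) {
    si <- match(s$unit[r], cube$unit_ids)
    ti <- match(s$time[r], cube$times)
    expect_equal(cube$X3[si, , ti], tbl$X[r, ], ignore_attr = TRUE)
  }
  back <- from_cube(cube)
  bk <- back$X[order(back$samples$unit, back$samples$time), ]
  fw <- tbl$X[order(s$unit, s$time), ]
  expect_equal(bk, fw, ignore_attr = TRUE)
})

test_that("the cube is invariant to the row order of the long table", {
  tbl <- toy_table(S_per_group = 2, J = 3, seed = 7)
  set.seed(99)
  perm <- sample(nrow(tbl$X))
  shuffled <- long_table(tbl$X[perm, ], subject = tbl$samples$subject[perm],
                         group = tbl$samples$group[perm],
                         time = tbl$samples$time[perm],
                         unit = tbl$samples$unit[perm],
                         variable_ids = tbl$variable_ids)
  expect_equal(to_cube(shuffled)$X3, to_cube(tbl)$X3)
})

test_that("filter_features applies the detection and QC-CV rules", {
  tbl <- toy_table(S_per_group = 5, J = 4, times = c(0, 2), seed = 11)
  tbl$X <- abs(tbl$X) + 1
  # V1: detected in only 5/10 control samples at time 0 (floor 0.7 -> removed)
  ctrl0 <- which(tbl$samples$group == "control" & tbl$samples$time == 0)
  tbl$X[ctrl0, 1] <- 0
  tbl$X[ctrl0[1:2], 1] <- 1  # 2/5 detected in that subgroup
  # QC: V2 with CV 0.8 removed, V3 with CV 0.5 kept
  qc <- cbind(rep(10, 50), rnorm(50, 10, 8), rnorm(50, 10, 5), rep(10, 50))
  qc2 <- qc; qc2[, 2] <- 10 + 8 * scale(qc[, 2])[, 1]  # exact sd 8, mean 10
  qc2[, 3] <- 10 + 5 * scale(qc[, 3])[, 1]
  res <- filter_features(tbl, qc = qc2)
  expect_setequal(res$removed$variable_id, c("V1", "V2"))
  expect_equal(res$removed$reason[res$removed$variable_id == "V1"],
               "low_detection")
  expect_equal(res$removed$reason[res$removed$variable_id == "V2"], "qc_cv")
  # idempotence on the surviving table, and sample rows untouched
  keep_cols <- match(res$table$variable_ids, tbl$variable_ids)
  again <- filter_features(res$table, qc = qc2[, keep_cols, drop = FALSE])
  expect_equal(again$table$X, res$table$X)
  expect_equal(nrow(again$removed), 0)
  expect_equal(nrow(res$table$X), nrow(tbl$X))

  # no-op case
  clean <- toy_table(S_per_group = 2, J = 3, seed = 13)
  clean$X <- abs(clean$X) + 1
  res2 <- filter_features(clean)
  expect_equal(res2$table$X, clean$X)
  expect_equal(nrow(res2$removed), 0)

  # mismatched qc dimension
  expect_error(filter_features(clean, qc = qc2[, 1:2]), "dimension error")

  # pre-supplied exclusion list
  res3 <- filter_features(clean, exclude = "V2")
  expect_equal(res3$removed$reason, "excluded")
  expect_false("V2" %in% res3$table$variable_ids)
})
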