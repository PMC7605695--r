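test_that("roster CSV parsing validates schema, genders and AUDIT ranges", {
  df <- make_roster_df(c("a", "b", "c"), c("F", "F", "M"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  ros <- read_roster(path)
  expect_equal(nrow(ros), 3)
  expect_equal(ros$id, c("a", "b", "c"))
  expect_equal(sum(ros$gender == "female"), 2)

  # missing required column is a schema error naming the column
  df2 <- df[, setdiff(names(df), "setting")]
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_roster(path), "setting", class = "schema_error")

  # AUDIT item 9 takes only {0,2,4}
  df3 <- df
  df3$audit_9[2] <- 3
  write.csv(df3, path, row.names = FALSE)
  err <- expect_error(read_roster(path), class = "validation_error")
  expect_match(conditionMessage(err), "item 9")
  expect_match(conditionMessage(err), "\\bb\\b")
})

test_that("roster invariants: duplicate ids, age window, mixed-setting classroom", {
  df <- make_roster_df(c("a", "a"), c("F", "M"))
  expect_error(roster(df), "duplicate", class = "validation_error")

  df <- make_roster_df(c("a", "b"), c("F", "M"))
  df$age[1] <- 30
  expect_error(roster(df), "plausibility", class = "validation_error")
  expect_s3_class(roster(df, age_range = c(10, 35)), "roster")

  df <- make_roster_df(c("a", "b"), c("F", "M"))
  df$setting <- c("rural", "urban")  # same classroom, two settings
  expect_error(roster(df), "constant", class = "validation_error")
})

test_that("roster record content is invariant to file row order", {
  df <- make_roster_df(sprintf("s%02d", 1:12), rep(c("F", "M"), 6))
  df$age <- c(16, 17, 18, 19)[(1:12) %% 4 + 1]
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p1, row.names = FALSE)
  write.csv(df[sample(12), ], p2, row.names = FALSE)
  r1 <- read_roster(p1)
  r2 <- read_roster(p2)
  expect_equal(r1[order(r1$id), ], r2[order(r2$id), ], ignore_attr = TRUE)
})

test_that("a roster emulating the study reproduces its gender proportion", {
  # 195 actors of whom 105 women -> 53.85% (two-decimal precision)
  df <- make_roster_df(sprintf("s%03d", 1:195),
                       rep(c("F", "M"), c(105, 90)))
  ros <- roster(df)
  expect_equal(round(100 * mean(ros$gender == "female"), 2), 53.85)
})

test_that("contact matrix readers validate shape and range across dialects", {
  vals <- matrix(1L, 4, 4)
  ids <- letters[1:4]
  cm <- contact_matrix(vals, ids, classroom = "c1")
  expect_true(all(cm$values == 1L))

  p <- withr::local_tempfile(fileext = ".csv")
  expect_error(contact_matrix(matrix(1L, 3, 4)), class = "shape_error")
  bad <- vals; bad[1, 2] <- 7L
  expect_error(contact_matrix(bad, ids), "range", class = "validation_error")

  # DL fullmatrix and CSV dialects read back the same matrix
  vals2 <- rand_contact_values(3)
  cm2 <- contact_matrix(vals2, c("x", "y", "z"), "c2")
  pc <- withr::local_tempfile(fileext = ".csv")
  pd <- withr::local_tempfile(fileext = ".dl")
  write_contact_matrix(cm2, pc, "csv")
  write_contact_matrix(cm2, pd, "ucinet_dl")
  from_csv <- read_contact_matrix(pc, "csv", classroom = "c2")
  from_dl <- read_contact_matrix(pd, "ucinet_dl", classroom = "c2")
  expect_equal(from_csv$values, from_dl$values)
  expect_equal(from_csv$actor_order, from_dl$actor_order)
})

test_that("contact matrix round-trips and handles missing ratings per policy", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    cm <- contact_matrix(rand_contact_values(n), sprintf("a%02d", 1:n), "rt")
    for (dialect in c("csv", "ucinet_dl")) {
      p <- withr::local_tempfile()
      write_contact_matrix(cm, p, dialect)
      back <- read_contact_matrix(p, dialect, classroom = "rt")
      expect_identical(back$values, cm$values)
      expect_identical(back$actor_order, cm$actor_order)
    }
  }

  vals <- rand_contact_values(4)
  vals[2, ] <- NA; vals[2, 2] <- 1L  # actor b never responded
  ids <- letters[1:4]
  p <- withr::local_tempfile()
  write.csv(as.data.frame(matrix(vals, 4, dimnames = list(ids, ids))), p)
  as_never <- read_contact_matrix(p, "csv", missing = "as_never")
  expect_equal(unname(as_never$values[2, c(1, 3, 4)]), c(1L, 1L, 1L))
  dropped <- read_contact_matrix(p, "csv", missing = "drop_actor")
  expect_equal(dropped$actor_order, c("a", "c", "d"))
  kept <- read_contact_matrix(p, "csv", missing = "keep")
  expect_true(anyNA(kept$values))
})

test_that("network writing is deterministic and round-trips in all dialects", {
  empty <- binary_network(matrix(0L, 3, 3), c("a", "b", "c"), "c1", "minimum")
  p <- withr::local_tempfile()
  write_network(empty, p, "edge_list")
  body <- readLines(p)
  expect_equal(sum(!startsWith(body, "#")), 1)  # header only, 0 edge rows

  adj <- matrix(0L, 3, 3, dimnames = rep(list(c("b", "a", "c")), 2))
  adj["a", "b"] <- 1L; adj["b", "a"] <- 1L
  net <- binary_network(adj, c("b", "a", "c"), "c1", "minimum")
  write_network(net, p, "edge_list")
  rows <- readLines(p)
  rows <- rows[!startsWith(rows, "#")][-1]
  expect_equal(rows, c("a,b", "b,a"))  # sorted by (source, target)

  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    net <- rand_network(n, 0.35, classroom = "rt", layer = "consumption")
    for (dialect in c("csv", "ucinet_dl", "edge_list")) {
      p2 <- withr::local_tempfile()
      write_network(net, p2, dialect)
      back <- read_network(p2, dialect,
                           classroom = if (dialect == "ucinet_dl") "rt" else NULL,
                           layer = if (dialect == "ucinet_dl") "consumption" else NULL)
      expect_identical(back$adjacency, net$adjacency)
      expect_identical(back$actor_order, net$actor_order)
      expect_identical(back$layer, net$layer)
      expect_identical(back$classroom, net$classroom)
    }
  }
})

test_that("DL parser accepts edgelist1, rejects other variants and bad files", {
  p <- withr::local_tempfile()
  writeLines(c("dl n=3 format=edgelist1", "labels:", "a,b,c", "data:",
               "a b", "b c"), p)
  net <- read_network(p, "ucinet_dl", classroom = "c", layer = "minimum")
  expect_equal(tie_set(net), c("a->b", "b->c"))

  writeLines(c("dl n=3 format=nodelist1", "data:", "1 2 3"), p)
  expect_error(read_network(p, "ucinet_dl"), "nodelist1", class = "io_error")
  writeLines(c("not a dl file"), p)
  expect_error(read_network(p, "ucinet_dl"), class = "io_error")
  writeLines(c("dl n=3 format=fullmatrix", "data:", "0 1", "0 0"), p)
  expect_error(read_network(p, "ucinet_dl"), "cells", class = "io_error")
})

test_that("unwritable paths raise an I/O error", {
  net <- rand_network(3)
  expect_error(write_network(net, "/nonexistent-dir/x/net.csv", "csv"),
               class = "io_error")
})
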