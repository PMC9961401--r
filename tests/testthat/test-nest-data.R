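# Nest table ingest, validation, windows and round-tripping.

test_that("windows validate geometry and measure area", {
  w <- rectangle_window(0, 65, 0, 65)
  expect_equal(window_area(w), 4225)
  expect_error(study_window(cbind(c(0, 1), c(0, 0))), "degenerate")
  expect_error(study_window(cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
  # asymmetric bow-tie: non-zero shoelace area but crossing edges
  expect_error(study_window(cbind(c(0, 4, 4, 0), c(0, 4, 0, 3))),
               "self-intersecting")
  # irregular pentagon, shoelace by hand: 2 * area of unit right triangles etc.
  ring <- cbind(c(0, 4, 6, 3, 0), c(0, 0, 3, 6, 4))
  w2 <- study_window(ring)
  expect_equal(window_area(w2), 25.5)  # hand shoelace
  expect_true(all(points_in_window(w2, cbind(c(1, 3), c(1, 2)))))
  expect_false(points_in_window(w2, cbind(10, 10)))
  # boundary point counts as inside
  expect_true(points_in_window(w, cbind(0, 10)))
})

test_that("reading a toy CSV defaults the window to the buffered bounding box", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  rec <- toy_records(n = 3)
  write.csv(rec, f, row.names = FALSE)
  pats <- read_nest_table(f)
  expect_length(pats, 1)
  p <- pats[[1]]
  expect_equal(n_nests(p), 3)
  bb <- rbind(range(rec$x), range(rec$y))
  expect_equal(window_area(p$window),
               (diff(bb[1, ]) + 4) * (diff(bb[2, ]) + 4))
})

test_that("schema and invariant violations are rejected by name", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  rec <- toy_records(n = 3)
  write.csv(rec[, setdiff(names(rec), "size_class")], f, row.names = FALSE)
  expect_error(read_nest_table(f), "size_class")

  rec2 <- toy_records(n = 3)
  rec2$larvae_teleius[2] <- -1L
  write.csv(rec2, f, row.names = FALSE)
  expect_error(read_nest_table(f), "larvae_teleius")

  rec3 <- toy_records(n = 3)
  rec3$nest_id <- "N01"
  write.csv(rec3, f, row.names = FALSE)
  expect_error(read_nest_table(f), "nest_id|duplicated")

  # point outside a supplied window names the offending nest
  rec4 <- toy_records(n = 3)
  rec4$x[1] <- 999
  expect_error(marked_point_pattern(rec4, rectangle_window(0, 20, 0, 20)),
               "N01")
})

test_that("write/read round-trips records field-for-field", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  write.csv(toy_records(n = 8), f1, row.names = FALSE)
  pats <- read_nest_table(f1)
  write_nest_table(pats, f2)
  pats2 <- read_nest_table(f2)
  expect_equal(pats2[[1]]$records, pats[[1]]$records)
})

test_that("packaged synthetic site fixture splits into its two seasons", {
  csv <- system.file("extdata", "kosyn_synthetic_nests.csv", package = "myrmspat")
  gj <- system.file("extdata", "kosyn_synthetic_window.geojson", package = "myrmspat")
  pats <- read_nest_table(csv, window = gj)
  expect_named(pats, c("Kosyn:autumn", "Kosyn:spring"))
  expect_equal(n_nests(pats[["Kosyn:autumn"]]), 57)
  expect_equal(n_nests(pats[["Kosyn:spring"]]), 60)
  # window is the surveyed polygon, ~0.42 ha
  expect_equal(window_area(pats[[1]]$window) / 1e4, 0.42, tolerance = 0.02)
})

test_that("infestation is a derived predicate over arbitrary taxon sets", {
  rec <- toy_records(n = 5)
  rec$larvae_teleius <- c(2L, 0L, 0L, 1L, 0L)
  rec$larvae_microdon <- c(1L, 0L, 3L, 0L, 0L)
  expect_equal(is_infested(rec, "teleius"), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(is_infested(rec, c("teleius", "microdon")),
               c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(is_infested(rec, character(0)), rep(FALSE, 5))
  expect_error(is_infested(rec, "nosuchtaxon"), "unknown")
})
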