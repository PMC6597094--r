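test_that("entity tables read from CSV preserve order and validate", {
  f <- write_tmp_csv(c("id,supply", "c1,1", "c2,3", "c3,2"))
  tab <- read_entities(f, "facilities")
  expect_equal(tab$id, c("c1", "c2", "c3"))
  expect_equal(tab$size, c(1, 3, 2))

  g <- write_tmp_csv(c("id,population",
                       paste0("c", 1:9, ",",
                              c(250, 250, 500, 500, 1000, 500, 1000, 250,
                                250))))
  ctr <- read_entities(g, "centers")
  expect_equal(sum(ctr$size), 4500)

  expect_error(read_entities(write_tmp_csv("id,population"), "centers"),
               "no entities")
  expect_error(read_entities(write_tmp_csv(c("id,population", "a,10",
                                             "a,20")), "centers"),
               "duplicate id at row 2")
  expect_error(read_entities(write_tmp_csv(c("id,population", "a,-5")),
                             "centers"),
               "bad row 1")
  expect_error(read_entities(write_tmp_csv(c("name,population", "a,5")),
                             "centers"),
               "missing required column 'id'")
})

test_that("wide and long cost layouts yield the identical aligned matrix", {
  # long file enumerating 3 origins x 2 destinations completely
  long <- write_tmp_csv(c("origin,destination,cost",
                          "c1,f1,5", "c1,f2,20", "c2,f1,10", "c2,f2,10",
                          "c3,f1,25", "c3,f2,5"))
  m_long <- read_cost_matrix(long, "long", c("c1", "c2", "c3"),
                             c("f1", "f2"))
  expect_equal(dim(m_long), c(3L, 2L))
  expect_true(all(is.finite(m_long)))

  # same data in wide layout with permuted facility columns
  wide <- write_tmp_csv(c("origin,f2,f1", "c1,20,5", "c2,10,10",
                          "c3,5,25"))
  m_wide <- read_cost_matrix(wide, "wide", c("c1", "c2", "c3"),
                             c("f1", "f2"))
  expect_equal(m_wide, m_long)
})

test_that("missing long pairs are unreachable: weight 0 under any impedance", {
  long <- write_tmp_csv(c("origin,destination,cost",
                          "c1,f1,5", "c2,f1,10", "c2,f2,10"))
  m <- read_cost_matrix(long, "long", c("c1", "c2"), c("f1", "f2"))
  expect_identical(m["c1", "f2"], Inf)
  for (spec in list(impedance_binary(1e6), impedance_gaussian(1e6)))
    expect_equal(impedance_weights(spec, m)["c1", "f2"], 0)
})

test_that("cost files with bad ids, duplicates or bad costs are rejected", {
  expect_error(
    read_cost_matrix(write_tmp_csv(c("origin,destination,cost", "cX,f1,5")),
                     "long", "c1", "f1"),
    "unknown origin")
  expect_error(
    read_cost_matrix(write_tmp_csv(c("origin,destination,cost",
                                     "c1,f1,5", "c1,f1,7")),
                     "long", "c1", "f1"),
    "duplicate pair")
  expect_error(
    read_cost_matrix(write_tmp_csv(c("origin,destination,cost",
                                     "c1,f1,-3")),
                     "long", "c1", "f1"),
    "negative")
  expect_error(
    read_cost_matrix(write_tmp_csv(c("origin,f1", "c1,abc")),
                     "wide", "c1", "f1"),
    "non-numeric")
})

test_that("euclidean costs come from plane geometry", {
  ctr <- data.frame(id = "c1", size = 1, x = 0, y = 0)
  fac <- data.frame(id = "f1", size = 1, x = 3, y = 4)
  expect_equal(euclidean_costs(ctr, fac)[1, 1], 5)
  expect_equal(euclidean_costs(ctr, transform(ctr, id = "f1"))[1, 1], 0)

  sq_c <- data.frame(id = c("a", "b"), size = 1, x = c(0, 1), y = c(0, 0))
  sq_f <- data.frame(id = c("p", "q"), size = 1, x = c(0, 1), y = c(1, 1))
  expect_equal(unname(euclidean_costs(sq_c, sq_f)),
               matrix(c(1, sqrt(2), sqrt(2), 1), 2))
  expect_error(euclidean_costs(data.frame(id = "c", size = 1), fac),
               "coordinates")
})

test_that("scenario assembly aligns the cost matrix to the entity tables", {
  ctr <- data.frame(id = c("c1", "c2"), size = c(10, 20))
  fac <- data.frame(id = c("f1", "f2"), size = c(1, 1))
  costs <- matrix(c(1, 2, 3, 4), 2, 2,
                  dimnames = list(c("c2", "c1"), c("f2", "f1")))
  sc <- fca_scenario(ctr, fac, costs)
  expect_equal(sc$costs["c1", "f1"], 4)
  expect_equal(sc$costs["c2", "f2"], 1)
  expect_error(fca_scenario(ctr, fac, matrix(1, 2, 2,
               dimnames = list(c("c1", "cX"), c("f1", "f2")))),
               "do not match")
})

test_that("result files round-trip and carry the printed per-facility demand", {
  fx <- simulated_nine_centers()
  r <- fca_run_weights(fx$centers$size, fx$facilities$size,
                       fx$weights$binary, method = "balanced")
  dir <- tempfile()
  write_results(r, dir, disparity = disparity(r), allocation = TRUE)
  fac <- read.csv(file.path(dir, "facilities.csv"))
  expect_equal(fac$demand[1], 708.333, tolerance = 1e-6)
  expect_equal(fac$level_of_service, c(1.412, 1.532, 1.091),
               tolerance = 1e-3)
  # round-trip: rewriting what was read back reproduces the file verbatim
  f2 <- tempfile(fileext = ".csv")
  write.csv(fac, f2, row.names = FALSE)
  expect_identical(readLines(f2), readLines(file.path(dir, "facilities.csv")))
  ctr <- read.csv(file.path(dir, "centers.csv"))
  expect_named(ctr, c("id", "population", "accessibility", "disparity"))
  al <- read.csv(file.path(dir, "allocation.csv"))
  expect_equal(nrow(al), 27L)
})

test_that("GeoJSON is written from coordinates and skipped without them", {
  sc <- random_scenario(4, 2, seed = 7)
  r <- suppressWarnings(fca_run(sc, impedance_binary(40), method = "2sfca"))
  dir <- tempfile()
  write_results(r, dir, geojson = TRUE)
  gj <- jsonlite::read_json(file.path(dir, "centers.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 4L)
  expect_equal(gj$features[[1]]$geometry$type, "Point")

  fx <- toy_two_clinics()  # no coordinates
  r2 <- fca_run_weights(fx$centers$size, fx$facilities$size,
                        fx$weights$binary, method = "2sfca")
  expect_warning(write_results(r2, tempfile(), geojson = TRUE),
                 "GeoJSON skipped")
})
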