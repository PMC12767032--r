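test_that("percent outcomes convert to proportions and boundaries reject", {
  path <- write_tmp_csv(data.frame(area_id = c("A", "B"),
                                   y = c(68.2, 54.6), sed = c(25, 19)))
  tab <- read_county_table(path, outcome_unit = "percent")
  expect_equal(tab$y, c(0.682, 0.546))
  expect_equal(tab$n_areas, 2L)
  expect_equal(colnames(tab$X), "sed")

  bad <- write_tmp_csv(data.frame(area_id = c("A", "B"),
                                  y = c(100, 54.6), sed = c(25, 19)))
  expect_error(read_county_table(bad, outcome_unit = "percent"),
               "domain error.*A")
  badp <- write_tmp_csv(data.frame(area_id = "A", y = 1.0, sed = 25))
  expect_error(read_county_table(badp, outcome_unit = "proportion"),
               "domain error")
})

test_that("a 67-county supplementary-style layout loads with all covariates", {
  set.seed(1)
  n <- 67
  df <- data.frame(
    county = paste0("county_", seq_len(n)),
    pct_black = runif(n, 2, 55), unemployment = runif(n, 2, 9),
    below_hs = runif(n, 5, 25), hs_diploma = runif(n, 25, 40),
    associate = runif(n, 5, 15), bachelor_plus = runif(n, 10, 45),
    poverty = runif(n, 9, 30), insured = runif(n, 70, 92),
    sedentary = runif(n, 18, 35),
    observed_prev = runif(n, 54.6, 78.5))
  path <- write_tmp_csv(df)
  tab <- read_county_table(path, id_col = "county",
                           outcome_col = "observed_prev",
                           outcome_unit = "percent")
  expect_equal(tab$n_areas, 67L)
  expect_equal(ncol(tab$X), 9L)
  expect_true(all(tab$y > 0 & tab$y < 1))
})

test_that("schema, duplicate-id and missing-cell violations are caught", {
  path <- write_tmp_csv(data.frame(area_id = c("A", "B"), y = c(50, 60)))
  expect_error(read_county_table(path, outcome_col = "prevalence"),
               "schema error.*prevalence")
  dup <- write_tmp_csv(data.frame(area_id = c("A", "A"), y = c(50, 60)))
  expect_error(read_county_table(dup, outcome_unit = "percent"),
               "duplicate area_id.*A")
  expect_error(county_table(c("A", "B"), c(0.5, 0.6),
                            matrix(c(1, NA), 2, 1,
                                   dimnames = list(NULL, "sed"))),
               "missing covariate.*sed")
})

test_that("validation report lists violations without raising", {
  tab <- county_table(paste0("c", 1:67), runif(67, 0.5, 0.8),
                      matrix(runif(67 * 2), 67, 2))
  rep <- validate_county_table(tab)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$status, "pass")
  expect_equal(nrow(rep$issues), 0L)

  broken <- list(area_id = c("A", "A", "B"), y = c(0.5, 1.2, 0.6),
                 X = matrix(c(1, 1, 1), 3, 1, dimnames = list(NULL, "k")))
  rep2 <- validate_county_table(broken)
  expect_equal(rep2$status, "fail")
  expect_true(any(rep2$issues$severity == "error" &
                    grepl("duplicate", rep2$issues$message)))
  expect_true(any(rep2$issues$severity == "error" &
                    grepl("\\(0,1\\)", rep2$issues$message)))
  expect_true(any(rep2$issues$severity == "warning" &
                    grepl("zero variance", rep2$issues$message)))
})

test_that("CSV round trip preserves y to full precision and area order", {
  set.seed(7)
  tab <- county_table(sample(paste0("c", 1:12)), runif(12, 0.4, 0.9),
                      matrix(rnorm(12), 12, 1, dimnames = list(NULL, "x1")))
  path <- tempfile(fileext = ".csv")
  write_county_table(tab, path)
  back <- read_county_table(path, outcome_col = "y",
                            name_col = "area_name",
                            outcome_unit = "proportion")
  expect_identical(back$area_id, tab$area_id)
  expect_identical(back$y, tab$y)
  # idempotence: write/read again is a fixed point
  path2 <- tempfile(fileext = ".csv")
  write_county_table(back, path2)
  again <- read_county_table(path2, outcome_col = "y",
                             name_col = "area_name",
                             outcome_unit = "proportion")
  expect_identical(again$y, back$y)
})

test_that("GeoJSON polygons round trip; id integrity enforced", {
  polys <- grid_polygons(2, 2)
  path <- tempfile(fileext = ".geojson")
  write_polygons(polys, path)
  back <- read_polygons(path)
  expect_equal(back$n_areas, 4L)
  expect_identical(back$area_id, polys$area_id)
  expect_equal(back$geometry[[1]][[1]], polys$geometry[[1]][[1]])

  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  gj$features[[2]]$properties$area_id <- gj$features[[1]]$properties$area_id
  dup_path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, dup_path, auto_unbox = TRUE, digits = NA)
  expect_error(read_polygons(dup_path), "duplicate feature id")

  gj$features[[1]]$properties <- list(other = 1)
  miss_path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, miss_path, auto_unbox = TRUE, digits = NA)
  expect_error(read_polygons(miss_path), "feature 1 has no property")

  expect_error(read_polygons(tempfile(fileext = ".shp")), "not found")
  shp <- tempfile(fileext = ".shp"); file.create(shp)
  expect_error(read_polygons(shp), "Shapefile")
})
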