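test_that("CSV descriptors load with percent/proportion autodetection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"male",50.0', '"female",50.0'), path)
  d <- read_descriptor(path, "gender", level = "person")
  expect_equal(d$shares, c(0.5, 0.5))
  expect_equal(d$categories, c("male", "female"))

  # header row is skipped automatically
  writeLines(c("category,share", '"1",14.5', '"2-3",40.0', '"4-5",30.0', '"6+",15.5'),
             path)
  d2 <- read_descriptor(path, "household_size", ordered = TRUE, level = "household")
  expect_equal(sum(d2$shares), 1, tolerance = 1e-12)
  expect_equal(d2$shares[1], 0.145)
  expect_true(d2$ordered)

  # proportions accepted too
  writeLines(c('"a",0.25', '"b",0.75'), path)
  expect_equal(read_descriptor(path, "x")$shares, c(0.25, 0.75))
})

test_that("descriptor parse errors name the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"a",40', '"b",-3'), path)
  expect_error(read_descriptor(path, "x"), "row 2.*negative", class = "hhsynth_parse_error")

  writeLines(c('"a",40', '"a",60'), path)
  expect_error(read_descriptor(path, "x"), "duplicate category",
               class = "hhsynth_parse_error")

  writeLines(c('"a",0', '"b",0'), path)
  expect_error(read_descriptor(path, "x"), "all zero", class = "hhsynth_parse_error")

  writeLines(c('"a",40,1', '"b",60,2'), path)
  expect_error(read_descriptor(path, "x"), "two columns", class = "hhsynth_parse_error")

  # a sum far from both 1 and 100 is a unit error, not silently rescaled
  writeLines(c('"a",4', '"b",6'), path)
  expect_error(read_descriptor(path, "x"), "expected", class = "hhsynth_parse_error")
})

test_that("descriptors round-trip through the CSV dialect", {
  d <- fixture_targets()$descriptors$age
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor(d, path)
  d2 <- read_descriptor(path, "age", ordered = TRUE, level = "person")
  expect_equal(d2$categories, d$categories)
  expect_equal(d2$shares, d$shares, tolerance = 1e-9)
})

test_that("empirical tallies conserve counts and match hand tallies", {
  empty <- population(list())
  spec <- target_descriptor("gender", c("male", "female"), c(1, 1), level = "person")
  e0 <- empirical_descriptor(empty, spec)
  expect_equal(e0$counts, c(0L, 0L))
  expect_equal(e0$total, 0L)
  expect_equal(e0$shares, c(0, 0))

  pop <- population(list(
    hh(person(30, "male", "head"), id = "a"),
    hh(person(31, "male", "head"), id = "b"),
    hh(person(32, "female", "head"), id = "c"),
    hh(person(33, "female", "head"), id = "d")))
  e <- empirical_descriptor(pop, spec)
  expect_equal(e$shares, c(0.5, 0.5))
  expect_equal(sum(e$counts), n_persons(pop))

  # 10 households: 6 of size 3, 4 of size 4 -> bins {1, 2, 3-5}
  hhs <- c(lapply(1:6, function(i) hh(person(40, "male", "head"),
                                      person(39, "female", "partner"),
                                      person(10, "male", "child"),
                                      id = paste0("s3_", i))),
           lapply(1:4, function(i) hh(person(40, "male", "head"),
                                      person(39, "female", "partner"),
                                      person(10, "male", "child"),
                                      person(8, "female", "child"),
                                      id = paste0("s4_", i))))
  size_spec <- target_descriptor("household_size", c("1", "2", "3-5"), c(1, 1, 1),
                                 ordered = TRUE, level = "household")
  es <- empirical_descriptor(population(hhs), size_spec)
  expect_equal(es$shares, c(0, 0, 1))
  expect_equal(es$total, 10L)

  # a unit outside every category is an error, not an extra bin
  bad_spec <- target_descriptor("gender", c("x", "y"), c(1, 1), level = "person")
  expect_error(empirical_descriptor(pop, bad_spec),
               class = "hhsynth_consistency_error")
})

test_that("alignment zero-fills and preserves share mass", {
  t1 <- target_descriptor("x", c("a", "b", "c"), c(0.2, 0.3, 0.5))
  e <- structure(
    list(name = "x", categories = c("a", "b"), shares = c(0.4, 0.6),
         ordered = FALSE, level = "person", counts = c(2L, 3L), total = 5L),
    class = c("empirical_descriptor", "target_descriptor"))
  al <- align_descriptors(t1, e)
  expect_equal(al$categories, c("a", "b", "c"))
  expect_equal(al$empirical, c(0.4, 0.6, 0))
  expect_equal(sum(al$target), sum(t1$shares))
  expect_equal(sum(al$empirical), 1)

  # permuted unordered categories are reindexed with shares preserved
  e2 <- structure(
    list(name = "x", categories = c("b", "a"), shares = c(0.6, 0.4),
         ordered = FALSE, level = "person", counts = c(3L, 2L), total = 5L),
    class = c("empirical_descriptor", "target_descriptor"))
  al2 <- align_descriptors(t1, e2)
  expect_equal(al2$empirical[match(c("a", "b"), al2$categories)], c(0.4, 0.6))

  # conflicting orderings of shared ordered categories are an error
  t_ord <- target_descriptor("x", c("a", "b"), c(0.5, 0.5), ordered = TRUE)
  e3 <- structure(
    list(name = "x", categories = c("b", "a"), shares = c(0.6, 0.4),
         ordered = TRUE, level = "person", counts = c(3L, 2L), total = 5L),
    class = c("empirical_descriptor", "target_descriptor"))
  expect_error(align_descriptors(t_ord, e3), class = "hhsynth_align_error")
})

test_that("descriptor sets enforce unique names and record weights", {
  a <- target_descriptor("a", c("x", "y"), c(1, 1))
  b <- target_descriptor("b", c("x", "y"), c(1, 3))
  ds <- descriptor_set(a, b, weights = c(a = 2, b = 1))
  expect_equal(names(ds$descriptors), c("a", "b"))
  expect_equal(unname(ds$weights), c(2, 1))
  expect_error(descriptor_set(a, a), class = "hhsynth_descriptor_error")
})
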