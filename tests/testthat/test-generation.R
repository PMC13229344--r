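test_that("prompts contain the four elements in order, with feedback switchable", {
  targets <- fixture_targets()
  schema <- default_schema()
  current <- lapply(targets$descriptors, function(d) {
    structure(c(unclass(d), list(counts = rep(0L, length(d$categories)), total = 0L)),
              class = c("empirical_descriptor", "target_descriptor"))
  })
  p <- build_prompt(targets, current, schema, B = 7, feedback = TRUE)
  pos <- vapply(c("# TASK", "# SCHEMA", "# TARGET DISTRIBUTIONS",
                  "# CURRENT DISTRIBUTIONS"),
                function(s) regexpr(s, p, fixed = TRUE)[1], numeric(1))
  expect_true(all(pos > 0))
  expect_true(all(diff(pos) > 0))
  expect_match(p, "households-requested: 7")
  # every target category label appears verbatim
  for (d in targets$descriptors) {
    for (lab in d$categories) expect_match(p, lab, fixed = TRUE)
  }
  p0 <- build_prompt(targets, current, schema, B = 7, feedback = FALSE)
  expect_false(grepl("# CURRENT DISTRIBUTIONS", p0, fixed = TRUE))
})

test_that("response parsing separates malformed JSON from structural faults", {
  schema <- default_schema()
  ok <- parse_households(valid_response_1(), 1L, schema)
  expect_true(ok$ok)
  expect_length(ok$households, 1L)
  expect_equal(ok$households[[1]]$members[[1]]$age, 40L)

  trunc <- parse_households('{"households": [{"members": [{"age": 4', 1L, schema)
  expect_false(trunc$ok)
  expect_equal(trunc$class, "parse")

  wrong_count <- parse_households(valid_response_1(), 2L, schema)
  expect_false(wrong_count$ok)
  expect_equal(wrong_count$class, "structure")
  expect_match(wrong_count$message, "expected exactly 2")

  missing_field <- parse_households(
    '{"households": [{"members": [{"age": 30, "gender": "male"}]}]}', 1L, schema)
  expect_false(missing_field$ok)
  expect_equal(missing_field$class, "structure")
  expect_match(missing_field$message, "relationship")

  no_array <- parse_households('{"people": []}', 1L, schema)
  expect_equal(no_array$class, "structure")
})

test_that("a clean scripted run accepts everything with no errors", {
  targets <- fixture_targets()
  backend <- scripted_backend(list(valid_response_1()))
  res <- generate_population(generation_config(5, batch_size = 1, seed = 1),
                             targets, default_schema(), default_rules(), backend)
  expect_equal(n_households(res$population), 5L)
  expect_equal(res$trace$success_rate, 100)
  expect_equal(unname(res$trace$error_counts), c(0L, 0L, 0L, 0L))
  expect_equal(res$trace$accepted + res$trace$failed, res$trace$attempted)
})

test_that("fault injection produces exactly the planned error accounting", {
  targets <- fixture_targets()
  s <- default_schema()
  r <- default_rules()
  cfg <- function(n) generation_config(n, batch_size = 1, retry_limit = 3, seed = 1)

  # one malformed response, then recovery: 1 parse error, full population
  b1 <- scripted_backend(list("not json {", valid_response_1()))
  r1 <- generate_population(cfg(3), targets, s, r, b1)
  expect_equal(n_households(r1$population), 3L)
  expect_equal(r1$trace$error_counts[["parse"]], 1L)
  expect_equal(r1$trace$success_rate, 100)

  # an invalid household corrected on retry: 1 rule error, full population
  minor_alone <- format_households_response(list(hh(person(12, "male", "head"))))
  b2 <- scripted_backend(list(minor_alone, valid_response_1()))
  r2 <- generate_population(cfg(3), targets, s, r, b2)
  expect_equal(n_households(r2$population), 3L)
  expect_equal(r2$trace$error_counts[["rule"]], 1L)

  # a backend raising once: 1 api error, then recovery
  b3 <- scripted_backend(list(function(prompt) stop("socket timeout"),
                              valid_response_1()))
  r3 <- generate_population(cfg(3), targets, s, r, b3)
  expect_equal(r3$trace$error_counts[["api"]], 1L)
  expect_equal(r3$trace$success_rate, 100)

  # wrong household count is a schema-class error
  two <- format_households_response(list(hh(person(40, "male", "head")),
                                         hh(person(41, "male", "head"))))
  b4 <- scripted_backend(list(two, valid_response_1()))
  r4 <- generate_population(cfg(3), targets, s, r, b4)
  expect_equal(r4$trace$error_counts[["schema"]], 1L)

  # always-malformed: nothing accepted, errors = N x retry_limit
  b5 <- scripted_backend(list("garbage"))
  r5 <- generate_population(cfg(20), targets, s, r, b5)
  expect_equal(n_households(r5$population), 0L)
  expect_equal(r5$trace$success_rate, 0)
  expect_equal(r5$trace$error_counts[["parse"]], 20L * 3L)
  expect_equal(r5$trace$failed, 20L)
})

test_that("llm backend adapters pass text through and surface failures as api errors", {
  targets <- fixture_targets()
  ok_transport <- function(prompt, config) list(text = valid_response_1(), tokens = 12)
  b <- llm_backend(ok_transport, name = "mock")
  res <- generate_population(generation_config(2, batch_size = 1, seed = 1),
                             targets, default_schema(), default_rules(), b)
  expect_equal(n_households(res$population), 2L)
  expect_equal(b$usage$tokens, 24)

  fail_transport <- function(prompt, config) stop("HTTP 500")
  b2 <- llm_backend(fail_transport)
  res2 <- generate_population(generation_config(2, batch_size = 1, retry_limit = 2,
                                                seed = 1),
                              targets, default_schema(), default_rules(), b2)
  expect_equal(n_households(res2$population), 0L)
  expect_equal(res2$trace$error_counts[["api"]], 4L)
})

test_that("the reference sampler fits consistent targets and improves with feedback", {
  targets <- fixture_targets()
  s <- default_schema()
  r <- default_rules()
  backend <- reference_sampler_backend(targets, s, r, seed = 5)
  res <- generate_population(generation_config(300, batch_size = 10, seed = 5),
                             targets, s, r, backend)
  expect_equal(n_households(res$population), 300L)
  fr <- fit_report(res$population, targets, s, r)
  expect_equal(fr$feasibility, 1)
  expect_lt(fr$mean_srmse, 0.1)

  # uniform two-gender target is met by symmetry
  emp <- empirical_descriptor(res$population, targets$descriptors$gender)
  expect_equal(emp$shares[1], 0.5, tolerance = 0.05)
})

test_that("a pure one-person target forces singleton adults", {
  single <- descriptor_set(
    target_descriptor("household_size", c("1", "2-3"), c(1, 0),
                      ordered = TRUE, level = "household"),
    target_descriptor("household_composition",
                      c("One-person", "Couple"), c(1, 0), level = "household"),
    target_descriptor("age", decade_age_bands(), c(0, 0, 1, 1, 1, 1, 1, 1, 1),
                      ordered = TRUE, level = "person"),
    target_descriptor("gender", c("male", "female"), c(1, 1), level = "person"))
  backend <- reference_sampler_backend(single, default_schema(), seed = 2)
  res <- generate_population(generation_config(10, batch_size = 5, seed = 2),
                             single, default_schema(), default_rules(), backend)
  sizes <- vapply(res$population$households, household_size, integer(1))
  ages <- vapply(res$population$households, function(h) h$members[[1]]$age, integer(1))
  expect_true(all(sizes == 1L))
  expect_true(all(ages >= 18L))
})

test_that("unconstructible size bins are rejected at backend construction", {
  bad <- descriptor_set(
    target_descriptor("household_size", c("1", "40+"), c(0.5, 0.5),
                      ordered = TRUE, level = "household"),
    target_descriptor("gender", c("male", "female"), c(1, 1), level = "person"))
  expect_error(reference_sampler_backend(bad, default_schema(), seed = 1),
               class = "hhsynth_backend_error")
})

test_that("identical seeds give bit-identical populations and traces", {
  targets <- fixture_targets()
  run <- function() {
    backend <- reference_sampler_backend(targets, default_schema(), seed = 31)
    generate_population(generation_config(80, batch_size = 10, seed = 31),
                        targets, default_schema(), default_rules(), backend)
  }
  a <- run()
  b <- run()
  expect_identical(a$population$households, b$population$households)
  expect_identical(a$trace$batches, b$trace$batches)
})
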