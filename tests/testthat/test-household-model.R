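test_that("size bins and age bands partition their domains", {
  global_bins <- target_descriptor("household_size", c("1", "2-3", "4-5", "6+"),
                                   rep(1, 4), ordered = TRUE, level = "household")
  sizes <- c(1, 2, 3, 4, 5, 6, 9, 12)
  labs <- vapply(sizes, function(s) {
    members <- lapply(seq_len(s), function(i) person(30 + i, "male",
                                                     if (i == 1) "head" else "housemate"))
    household_size_category(household(members, id = "t"), global_bins)
  }, character(1))
  expect_equal(labs, c("1", "2-3", "2-3", "4-5", "4-5", "6+", "6+", "6+"))

  uk_bins <- target_descriptor("household_size", c(as.character(1:7), "8+"),
                               rep(1, 8), ordered = TRUE, level = "household")
  nine <- household(lapply(1:9, function(i) person(30 + i, "male",
                                                   if (i == 1) "head" else "housemate")),
                    id = "n")
  expect_equal(household_size_category(nine, uk_bins), "8+")

  bands <- decade_age_bands()
  expect_equal(age_band(0, bands), "0-9")
  expect_equal(age_band(79, bands), "70-79")
  expect_equal(age_band(80, bands), "80+")
  expect_equal(age_band(120, bands), "80+")
  # every age maps to exactly one band
  for (a in 0:120) expect_length(age_band(a, bands), 1L)
})

test_that("bin labels outside the k / a-b / k+ grammar are rejected", {
  expect_error(parse_bins("under 5"), class = "hhsynth_bin_error")
  expect_error(parse_bins("5-3"), class = "hhsynth_bin_error")
  b <- parse_bins(c("1", "2-3", "6+"))
  expect_equal(b$lo, c(1, 2, 6))
  expect_equal(b$hi, c(1, 3, Inf))
})

test_that("every composition mapping row yields the printed labels", {
  uk <- classification_scheme("UK")
  gl <- classification_scheme("GLOBAL")
  fx <- mapping_fixtures()
  expected <- list(
    head_young    = c("One person aged <66", "One-person"),
    head_old      = c("One-person aged 66+", "One-person"),
    couple        = c("Couple", "Couple"),
    lone_parent   = c("Lone parent", "Lone parent"),
    couple_dep    = c("Couple with dependent children", "Couple with children"),
    couple_nondep = c("Couple with non-dependent children", "Couple with children"),
    relatives     = c("Other", "Extended family"),
    housemates    = c("Other", "Non-relatives"),
    catch_all     = c("Other", "Non-relatives")
  )
  for (nm in names(expected)) {
    expect_identical(derive_household_type(fx[[nm]], uk), expected[[nm]][1],
                     label = paste0("UK:", nm))
    expect_identical(derive_household_type(fx[[nm]], gl), expected[[nm]][2],
                     label = paste0("GLOBAL:", nm))
  }
})

test_that("composition edge cases: age-66 boundary and headless households", {
  uk <- classification_scheme("UK")
  expect_equal(derive_household_type(hh(person(66, "male", "head")), uk),
               "One-person aged 66+")
  expect_equal(derive_household_type(hh(person(65, "male", "head")), uk),
               "One person aged <66")
  # dependent-child boundary: any child under 18
  dep <- hh(person(50, "male", "head"), person(49, "female", "partner"),
            person(17, "male", "child"))
  nondep <- hh(person(50, "male", "head"), person(49, "female", "partner"),
               person(18, "male", "child"))
  expect_match(derive_household_type(dep, uk), "dependent")
  expect_match(derive_household_type(nondep, uk), "non-dependent")

  no_head <- hh(person(30, "male", "housemate"), person(29, "male", "housemate"))
  expect_error(derive_household_type(no_head), class = "hhsynth_consistency_error")
})

test_that("composition mapping is total on schema-valid households", {
  pop <- latent_fixture()
  for (scheme in list(classification_scheme("UK"), classification_scheme("GLOBAL"))) {
    labs <- vapply(pop$households[1:200], derive_household_type, character(1),
                   scheme = scheme)
    expect_true(all(nzchar(labs)))
    expect_true(all(labs %in% scheme$labels))
  }
})

test_that("populations round-trip through JSONL and flatten to tables", {
  pop <- population(latent_fixture()$households[1:25])
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_population_jsonl(pop, path)
  back <- read_population_jsonl(path)
  expect_equal(n_households(back), 25)
  expect_equal(n_persons(back), n_persons(pop))
  expect_equal(back$households[[3]]$members, pop$households[[3]]$members)
  expect_equal(vapply(back$households, `[[`, character(1), "id"),
               vapply(pop$households, `[[`, character(1), "id"))

  size_spec <- fixture_targets()$descriptors$household_size
  tabs <- population_tables(pop, size_spec = size_spec,
                            scheme = classification_scheme("GLOBAL"))
  expect_equal(nrow(tabs$persons), n_persons(pop))
  expect_equal(nrow(tabs$households), 25)
  expect_true(all(c("size_category", "composition") %in% names(tabs$households)))
  expect_equal(sum(tabs$households$size), n_persons(pop))
})

test_that("duplicate household ids are rejected", {
  expect_error(population(list(hh(person(30, "male", "head"), id = "a"),
                               hh(person(31, "male", "head"), id = "a"))),
               class = "hhsynth_model_error")
})
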