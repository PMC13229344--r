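# Hierarchical population data model: persons nested in households, plus the
# derived attributes (size bins, age bands, household composition) that the
# marginal descriptors are expressed in.

#' Construct a person
#'
#' A person is a flat attribute map. `age` (integer years), `gender` and
#' `relationship` (role label relative to the household head) are required by
#' the default schema; arbitrary extra attributes are allowed.
#'
#' @param age Integer age in years.
#' @param gender Category label, e.g. `"male"` / `"female"`.
#' @param relationship Role relative to the head: `"head"`, `"partner"`,
#'   `"child"`, `"grandparent"`, `"aunt"`, `"cousin"`, `"housemate"`,
#'   `"other-relative"`.
#' @param ... Further named attributes.
#' @return A named list of attributes.
#' @export
person <- function(age, gender, relationship, ...) {
  c(list(age = as.integer(age), gender = gender, relationship = relationship),
    list(...))
}

#' Construct a household
#'
#' @param members List of [person()] attribute maps (at least one).
#' @param id Stable identifier; autogenerated when omitted.
#' @return An object of class `household`.
#' @export
household <- function(members, id = NULL) {
  if (!is.null(names(members)) && all(c("age", "gender", "relationship") %in% names(members))) {
    members <- list(members)  # single person passed bare
  }
  if (length(members) < 1L) {
    hh_abort("a household must have at least one member", "hhsynth_model_error")
  }
  structure(list(id = id %||% next_household_id(), members = members),
            class = "household")
}

# Sequential fallback ids; deterministic and RNG-free.
.hh_counter <- new.env(parent = emptyenv())
.hh_counter$n <- 0L
next_household_id <- function() {
  .hh_counter$n <- .hh_counter$n + 1L
  sprintf("h%06d", .hh_counter$n)
}

#' Household size
#' @param h A [household()].
#' @return Integer member count.
#' @export
household_size <- function(h) length(h$members)

#' Construct a population
#'
#' @param households List of [household()] objects with unique ids.
#' @param provenance Optional list recording how the population was produced
#'   (seed, backend, batch size, ...).
#' @return An object of class `population`.
#' @export
population <- function(households, provenance = list()) {
  ids <- vapply(households, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    hh_abort(sprintf("duplicate household id '%s'", ids[duplicated(ids)][1]),
             "hhsynth_model_error")
  }
  structure(list(households = households, provenance = provenance),
            class = "population")
}

#' Number of households in a population
#' @param p A [population()].
#' @export
n_households <- function(p) length(p$households)

#' Number of persons in a population
#' @param p A [population()].
#' @export
n_persons <- function(p) {
  sum(vapply(p$households, function(h) length(h$members), integer(1)))
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d households, %d persons\n",
              n_households(x), n_persons(x)))
  invisible(x)
}

# --- derived categorical attributes -----------------------------------------

#' Assign a household to a size category
#'
#' @param h A [household()].
#' @param spec An ordered household-level [target_descriptor()] whose labels
#'   parse as size bins (`"k"`, `"a-b"`, `"k+"`).
#' @return The covering bin label.
#' @export
household_size_category <- function(h, spec) {
  bins <- parse_bins(spec$categories)
  lab <- bin_assign(household_size(h), bins)
  if (is.na(lab)) {
    hh_abort(sprintf("household size %d outside all bins of '%s'",
                     household_size(h), spec$name), "hhsynth_consistency_error")
  }
  lab
}

#' Assign an age to its band
#'
#' @param age Integer age in years (non-negative).
#' @param banding Ordered band labels, e.g. `c("0-9", "10-19", ..., "80+")`.
#' @return The unique covering band label.
#' @export
age_band <- function(age, banding) {
  bins <- parse_bins(banding)
  lab <- bin_assign(age, bins)
  if (is.na(lab)) {
    hh_abort(sprintf("age %s outside all bands", age), "hhsynth_consistency_error")
  }
  lab
}

#' Ten-year age bands with an open top bin
#' @param top Lower edge of the open-ended band (default 80).
#' @return Character vector `"0-9"`, `"10-19"`, ..., `"80+"`.
#' @export
decade_age_bands <- function(top = 80) {
  c(paste0(seq(0, top - 10, 10), "-", seq(9, top - 1, 10)), paste0(top, "+"))
}

# Relationship role groups used by the composition mapping.
REL_RELATIVE <- c("grandparent", "aunt", "cousin", "other-relative")

#' Household-composition classification schemes
#'
#' The mapping from household relationship structure (member roles and ages)
#' to a categorical household type, under either the UK census classification
#' or the harmonised global classification. Rows are matched in priority
#' order; a final catch-all guarantees every household gets a label.
#'
#' @param name `"UK"` or `"GLOBAL"`.
#' @return An object of class `classification_scheme`.
#' @export
classification_scheme <- function(name = c("GLOBAL", "UK")) {
  name <- match.arg(toupper(name), c("GLOBAL", "UK"))
  labels <- if (name == "UK") {
    c(head_only_young   = "One person aged <66",
      head_only_old     = "One-person aged 66+",
      couple            = "Couple",
      lone_parent       = "Lone parent",
      couple_dep_child  = "Couple with dependent children",
      couple_nondep     = "Couple with non-dependent children",
      relatives         = "Other",
      housemates        = "Other",
      other             = "Other")
  } else {
    c(head_only_young   = "One-person",
      head_only_old     = "One-person",
      couple            = "Couple",
      lone_parent       = "Lone parent",
      couple_dep_child  = "Couple with children",
      couple_nondep     = "Couple with children",
      relatives         = "Extended family",
      housemates        = "Non-relatives",
      other             = "Non-relatives")
  }
  structure(list(name = name, labels = labels,
                 senior_age = 66, dependent_age = 18),
            class = "classification_scheme")
}

#' Derive a household's composition type
#'
#' Classifies a household by its relationship structure: a lone head (split at
#' head age 66), head and partner, head with children only (lone parent),
#' head, partner and children (split by whether any child is under 18), head
#' with other relatives, head with housemates, and a catch-all for any other
#' combination.
#'
#' @param h A schema-valid [household()] containing exactly one head.
#' @param scheme A [classification_scheme()].
#' @return A composition label from the scheme.
#' @export
derive_household_type <- function(h, scheme = classification_scheme("GLOBAL")) {
  roles <- vapply(h$members, function(p) trimws2(p$relationship), character(1))
  ages <- vapply(h$members, function(p) as.numeric(p$age), numeric(1))
  head_idx <- which(roles == "head")
  if (length(head_idx) != 1L) {
    hh_abort(sprintf("household %s has %d heads; composition is undefined",
                     h$id %||% "?", length(head_idx)), "hhsynth_consistency_error")
  }
  others <- roles[-head_idx]
  lab <- function(key) unname(scheme$labels[key])
  n_partner <- sum(others == "partner")
  n_child <- sum(others == "child")
  child_ages <- ages[-head_idx][others == "child"]
  n_relative <- sum(others %in% REL_RELATIVE)
  n_housemate <- sum(others == "housemate")
  accounted <- n_partner + n_child + n_relative + n_housemate

  if (length(others) == 0L) {
    return(lab(if (ages[head_idx] >= scheme$senior_age) "head_only_old" else "head_only_young"))
  }
  if (accounted != length(others)) return(lab("other"))
  if (n_partner == 1L && n_child == 0L && n_relative == 0L && n_housemate == 0L) {
    return(lab("couple"))
  }
  if (n_partner == 0L && n_child >= 1L && n_relative == 0L && n_housemate == 0L) {
    return(lab("lone_parent"))
  }
  if (n_partner == 1L && n_child >= 1L && n_relative == 0L && n_housemate == 0L) {
    return(lab(if (any(child_ages < scheme$dependent_age)) "couple_dep_child" else "couple_nondep"))
  }
  if (n_relative >= 1L && n_housemate == 0L) {
    return(lab("relatives"))
  }
  if (n_housemate >= 1L && n_partner == 0L && n_child == 0L && n_relative == 0L) {
    return(lab("housemates"))
  }
  lab("other")
}

# --- serialisation -----------------------------------------------------------

#' Write a population as JSON lines
#'
#' One household object per line: `{"id": ..., "members": [...]}`.
#'
#' @param p A [population()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_jsonl <- function(p, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (h in p$households) {
    line <- jsonlite::toJSON(list(id = h$id, members = h$members),
                             auto_unbox = TRUE, digits = NA)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a population from JSON lines
#'
#' @param path Path to a file written by [write_population_jsonl()].
#' @param provenance Optional provenance list to attach.
#' @return A [population()].
#' @export
read_population_jsonl <- function(path, provenance = list()) {
  if (!file.exists(path)) {
    hh_abort(sprintf("population file not found: %s", path), "hhsynth_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  households <- lapply(lines, function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    members <- lapply(obj$members, function(m) {
      m$age <- as.integer(m$age)
      m
    })
    household(members, id = obj$id)
  })
  population(households, provenance = provenance)
}

#' Flatten a population to person and household tables
#'
#' @param p A [population()].
#' @param size_spec Optional ordered household-level descriptor used to add a
#'   `size_category` column.
#' @param scheme Optional [classification_scheme()] used to add a
#'   `composition` column.
#' @return A list with data frames `persons` (one row per person, with
#'   `household_id`) and `households` (one row per household with derived
#'   size and, when requested, type).
#' @export
population_tables <- function(p, size_spec = NULL, scheme = NULL) {
  persons <- do.call(rbind, lapply(p$households, function(h) {
    do.call(rbind, lapply(seq_along(h$members), function(i) {
      m <- h$members[[i]]
      data.frame(household_id = h$id, member = i,
                 age = as.integer(m$age), gender = m$gender,
                 relationship = m$relationship, stringsAsFactors = FALSE)
    }))
  }))
  households <- data.frame(
    household_id = vapply(p$households, `[[`, character(1), "id"),
    size = vapply(p$households, function(h) length(h$members), integer(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(size_spec)) {
    households$size_category <- vapply(p$households, household_size_category,
                                       character(1), spec = size_spec)
  }
  if (!is.null(scheme)) {
    households$composition <- vapply(p$households, derive_household_type,
                                     character(1), scheme = scheme)
  }
  list(persons = persons, households = households)
}
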