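# The feasible set: an attribute schema (value domains) plus structural rules,
# yielding the per-household validity indicator and the population feasibility
# rate.

#' Construct a population schema
#'
#' The schema fixes each attribute's kind and value domain. Invariants:
#' exactly one integer attribute named `"age"` with a bounded range, a
#' relationship vocabulary containing `"head"`, and at least two categories
#' per categorical attribute.
#'
#' @param attributes List of attribute definitions; each a list with `name`,
#'   `kind` (`"integer"` or `"categorical"`), `level` (`"person"` or
#'   `"household"`), and either `min`/`max` (integer kind) or `categories`.
#' @param relationships Character vector of allowed role labels.
#' @return An object of class `population_schema`.
#' @export
population_schema <- function(attributes, relationships) {
  for (a in attributes) {
    if (is.null(a$name) || is.null(a$kind)) {
      hh_abort("every schema attribute needs a name and a kind", "hhsynth_schema_error")
    }
    if (!a$kind %in% c("integer", "categorical")) {
      hh_abort(sprintf("attribute '%s': unknown kind '%s'", a$name, a$kind),
               "hhsynth_schema_error")
    }
    if (a$kind == "integer") {
      if (!is_scalar_number(a$min) || !is_scalar_number(a$max) || a$max < a$min) {
        hh_abort(sprintf("attribute '%s': integer domain must be a bounded range",
                         a$name), "hhsynth_schema_error")
      }
    } else {
      if (length(a$categories) < 2L) {
        hh_abort(sprintf("attribute '%s': categorical domain needs at least 2 categories",
                         a$name), "hhsynth_schema_error")
      }
    }
  }
  nms <- vapply(attributes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    hh_abort(sprintf("duplicate attribute '%s'", nms[duplicated(nms)][1]),
             "hhsynth_schema_error")
  }
  age <- attributes[nms == "age"]
  if (length(age) != 1L || age[[1]]$kind != "integer") {
    hh_abort("schema must contain exactly one integer attribute named 'age'",
             "hhsynth_schema_error")
  }
  if (!"head" %in% relationships) {
    hh_abort("relationship vocabulary must contain 'head'", "hhsynth_schema_error")
  }
  names(attributes) <- nms
  structure(list(attributes = attributes, relationships = relationships),
            class = "population_schema")
}

#' The default person schema
#'
#' Age as an integer between 0 and `age_max` years, a binary gender, and a
#' relationship role drawn from the standard vocabulary.
#'
#' @param age_max Upper bound of the age range (default 120).
#' @return A [population_schema()].
#' @export
default_schema <- function(age_max = 120) {
  rel <- c("head", "partner", "child", "grandparent", "aunt", "cousin",
           "housemate", "other-relative")
  population_schema(
    attributes = list(
      list(name = "age", kind = "integer", level = "person", min = 0, max = age_max),
      list(name = "gender", kind = "categorical", level = "person",
           categories = c("male", "female")),
      list(name = "relationship", kind = "categorical", level = "person",
           categories = rel)
    ),
    relationships = rel
  )
}

#' Read a population schema from JSON
#'
#' The file format mirrors [population_schema()]:
#' `{"attributes": [{"name", "kind", "level", "min"/"max" or "categories"}],
#' "relationships": [...]}`. A machine-readable description of this
#' schema-of-schemas ships in `inst/extdata/schema-format.json`.
#'
#' @param path Path to the JSON file.
#' @return A [population_schema()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) {
    hh_abort(sprintf("schema file not found: %s", path), "hhsynth_io_error")
  }
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    hh_abort(sprintf("%s: malformed JSON (%s)", path, conditionMessage(e)),
                             "hhsynth_schema_error")
                  })
  if (is.null(obj$attributes)) {
    hh_abort(sprintf("%s: $.attributes missing", path), "hhsynth_schema_error")
  }
  attrs <- lapply(obj$attributes, function(a) {
    if (!is.null(a$categories)) a$categories <- unlist(a$categories)
    a
  })
  population_schema(attrs, unlist(obj$relationships))
}

#' Write a population schema to JSON
#' @param schema A [population_schema()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(
    list(attributes = unname(schema$attributes),
         relationships = schema$relationships),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# --- structural rules --------------------------------------------------------

#' Built-in structural rules
#'
#' Construct a rule set from the built-in registry. Available rules:
#' \describe{
#'   \item{exactly-one-head}{each household contains exactly one member with
#'     relationship `"head"`.}
#'   \item{no-minor-alone}{a one-person household's member must be at least
#'     `minor_age` (default 18) years old.}
#'   \item{parent-older-than-child}{every member with relationship `"child"`
#'     is strictly younger than the head and (when present) the partner.}
#'   \item{min-head-age}{the head is at least `min_head_age` (default 16).}
#'   \item{parent-child-gap}{optional stricter plausibility rule: parents are
#'     at least `gap` (default 15) years older than every child. Not in the
#'     default set.}
#' }
#'
#' @param rules Character vector of rule identifiers to enable.
#' @param minor_age Age below which a person counts as a minor.
#' @param min_head_age Minimum age for a household head.
#' @param gap Minimum parent-child age gap for `parent-child-gap`.
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(rules = c("exactly-one-head", "no-minor-alone",
                               "parent-older-than-child", "min-head-age"),
                     minor_age = 18, min_head_age = 16, gap = 15) {
  registry <- list(
    "exactly-one-head" = function(h) {
      n <- sum(vapply(h$members, function(p) identical(trimws2(p$relationship), "head"),
                      logical(1)))
      if (n != 1L) sprintf("household must contain exactly one head, found %d", n)
    },
    "no-minor-alone" = function(h) {
      if (length(h$members) == 1L && as.numeric(h$members[[1]]$age) < minor_age) {
        sprintf("member 1 (age %s) is a minor living alone", h$members[[1]]$age)
      }
    },
    "parent-older-than-child" = function(h) {
      roles <- vapply(h$members, function(p) trimws2(p$relationship), character(1))
      ages <- vapply(h$members, function(p) as.numeric(p$age), numeric(1))
      parents <- ages[roles %in% c("head", "partner")]
      kids <- which(roles == "child")
      if (length(parents) == 0L || length(kids) == 0L) return(NULL)
      bad <- kids[ages[kids] >= min(parents)]
      if (length(bad)) {
        sprintf("member %d (child, age %d) is not younger than the parents (youngest parent age %d)",
                bad[1], as.integer(ages[bad[1]]), as.integer(min(parents)))
      }
    },
    "min-head-age" = function(h) {
      roles <- vapply(h$members, function(p) trimws2(p$relationship), character(1))
      i <- which(roles == "head")
      if (length(i) != 1L) return(NULL)  # exactly-one-head reports this
      if (as.numeric(h$members[[i]]$age) < min_head_age) {
        sprintf("member %d (head) is aged %s; heads must be at least %d",
                i, h$members[[i]]$age, min_head_age)
      }
    },
    "parent-child-gap" = function(h) {
      roles <- vapply(h$members, function(p) trimws2(p$relationship), character(1))
      ages <- vapply(h$members, function(p) as.numeric(p$age), numeric(1))
      parents <- ages[roles %in% c("head", "partner")]
      kids <- which(roles == "child")
      if (length(parents) == 0L || length(kids) == 0L) return(NULL)
      bad <- kids[ages[kids] > min(parents) - gap]
      if (length(bad)) {
        sprintf("member %d (child, age %d) is within %d years of the youngest parent",
                bad[1], as.integer(ages[bad[1]]), gap)
      }
    }
  )
  unknown <- setdiff(rules, names(registry))
  if (length(unknown)) {
    hh_abort(sprintf("unknown rule identifier '%s'", unknown[1]), "hhsynth_rule_error")
  }
  if (anyDuplicated(rules)) {
    hh_abort("rule identifiers must be unique", "hhsynth_rule_error")
  }
  structure(list(rules = registry[rules],
                 params = list(minor_age = minor_age, min_head_age = min_head_age,
                               gap = gap)),
            class = "rule_set")
}

#' The default structural rule set
#'
#' Exactly one head, no minors living alone, parents strictly older than
#' children, and a minimum head age.
#'
#' @inheritParams rule_set
#' @return A [rule_set()].
#' @export
default_rules <- function(minor_age = 18, min_head_age = 16) {
  rule_set(minor_age = minor_age, min_head_age = min_head_age)
}

#' Read a rule configuration from JSON
#'
#' Format: `{"rules": [{"id": "exactly-one-head"}, {"id": "no-minor-alone",
#' "minor_age": 18}, ...]}` with optional parameter overrides per rule.
#'
#' @param path Path to the JSON file.
#' @return A [rule_set()].
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) {
    hh_abort(sprintf("rules file not found: %s", path), "hhsynth_io_error")
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ids <- vapply(obj$rules, `[[`, character(1), "id")
  pars <- list(minor_age = 18, min_head_age = 16, gap = 15)
  for (r in obj$rules) {
    if (!is.null(r$minor_age)) pars$minor_age <- r$minor_age
    if (!is.null(r$min_age)) pars$min_head_age <- r$min_age
    if (!is.null(r$min_head_age)) pars$min_head_age <- r$min_head_age
    if (!is.null(r$gap)) pars$gap <- r$gap
  }
  rule_set(rules = ids, minor_age = pars$minor_age,
           min_head_age = pars$min_head_age, gap = pars$gap)
}

# --- validation --------------------------------------------------------------

#' Validate one household against a schema and rule set
#'
#' Schema checks (every person-level attribute present and in-domain, roles in
#' the vocabulary) run first; structural rules run when the household is
#' schema-valid. All failures are collected, not just the first, and each
#' diagnostic names the offending member or rule so it can be fed back to a
#' generator verbatim.
#'
#' @param h A [household()] (structurally a list of persons).
#' @param schema A [population_schema()].
#' @param rules A [rule_set()].
#' @return A list of class `validation_report` with `valid` (logical) and
#'   `failures` (data frame with columns `check` and `message`).
#' @export
validate_household <- function(h, schema, rules = default_rules()) {
  failures <- list()
  add <- function(check, message) {
    failures[[length(failures) + 1L]] <<- data.frame(
      check = check, message = message, stringsAsFactors = FALSE)
  }
  person_attrs <- Filter(function(a) identical(a$level %||% "person", "person"),
                         schema$attributes)
  for (i in seq_along(h$members)) {
    m <- h$members[[i]]
    for (a in person_attrs) {
      v <- m[[a$name]]
      if (is.null(v) || length(v) != 1L || is.na(v)) {
        add(paste0("schema:", a$name),
            sprintf("member %d: attribute '%s' is missing", i, a$name))
        next
      }
      if (a$kind == "integer") {
        vn <- suppressWarnings(as.numeric(v))
        if (is.na(vn) || vn != floor(vn)) {
          add(paste0("schema:", a$name),
              sprintf("member %d: '%s' must be an integer, got '%s'", i, a$name, v))
        } else if (vn < a$min || vn > a$max) {
          add(paste0("schema:", a$name),
              sprintf("member %d: %s %s outside the allowed range [%s, %s]",
                      i, a$name, v, a$min, a$max))
        }
      } else {
        if (!trimws2(v) %in% a$categories) {
          add(paste0("schema:", a$name),
              sprintf("member %d: %s '%s' is not one of: %s",
                      i, a$name, v, paste(a$categories, collapse = ", ")))
        }
      }
    }
    rel <- m$relationship
    if (!is.null(rel) && !trimws2(rel) %in% schema$relationships) {
      add("schema:relationship",
          sprintf("member %d: relationship '%s' is outside the vocabulary", i, rel))
    }
  }
  if (length(failures) == 0L) {
    for (rid in names(rules$rules)) {
      msg <- rules$rules[[rid]](h)
      if (!is.null(msg)) add(paste0("rule:", rid), msg)
    }
  }
  failures <- if (length(failures)) {
    do.call(rbind, failures)
  } else {
    data.frame(check = character(0), message = character(0), stringsAsFactors = FALSE)
  }
  structure(list(valid = nrow(failures) == 0L, failures = failures),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("<validation_report> valid\n")
  } else {
    cat(sprintf("<validation_report> INVALID (%d failures)\n", nrow(x$failures)))
    for (i in seq_len(nrow(x$failures))) {
      cat(sprintf("  [%s] %s\n", x$failures$check[i], x$failures$message[i]))
    }
  }
  invisible(x)
}

#' Proportion of valid households in a population
#'
#' The mean of the per-household validity indicator over the population.
#'
#' @param p A non-empty [population()].
#' @param schema A [population_schema()].
#' @param rules A [rule_set()].
#' @return A proportion in `[0, 1]`.
#' @export
feasibility_rate <- function(p, schema, rules = default_rules()) {
  if (n_households(p) == 0L) {
    hh_abort("feasibility rate is undefined for an empty population",
             "hhsynth_consistency_error")
  }
  ok <- vapply(p$households,
               function(h) validate_household(h, schema, rules)$valid,
               logical(1))
  sum(ok) / length(ok)
}
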