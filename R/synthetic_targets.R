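# Fixture machinery: a latent ground-truth population with known household
# structure, the internally consistent target descriptors derived from it,
# and controlled conflict injection. Everything other modules need for
# offline testing, with no external data.

#' Specification of a latent ground-truth population
#'
#' The latent population stands in for census ground truth: a seeded mixture
#' of structural household patterns with role-conditional age profiles. Every
#' generated household satisfies the default schema and structural rules by
#' construction.
#'
#' @param n_households Number of households (default 883, a typical small-area
#'   census zone size).
#' @param mixture Named shares over the structural patterns
#'   `one_person_young`, `one_person_old`, `couple`, `couple_dep_children`,
#'   `couple_nondep_children`, `lone_parent`, `extended`, `nonrelatives`;
#'   must sum to 1.
#' @param gender_balance Probability that a drawn gender is female.
#' @param seed Integer seed.
#' @return A list of class `latent_population_spec`.
#' @export
latent_population_spec <- function(n_households = 883,
                                   mixture = c(one_person_young = 0.17,
                                               one_person_old = 0.13,
                                               couple = 0.18,
                                               couple_dep_children = 0.20,
                                               couple_nondep_children = 0.05,
                                               lone_parent = 0.11,
                                               extended = 0.08,
                                               nonrelatives = 0.08),
                                   gender_balance = 0.5,
                                   seed = 1) {
  required <- c("one_person_young", "one_person_old", "couple",
                "couple_dep_children", "couple_nondep_children",
                "lone_parent", "extended", "nonrelatives")
  if (!setequal(names(mixture), required)) {
    hh_abort(sprintf("mixture must name exactly: %s", paste(required, collapse = ", ")),
             "hhsynth_config_error")
  }
  if (abs(sum(mixture) - 1) > 1e-9 || any(mixture < 0)) {
    hh_abort("mixture shares must be non-negative and sum to 1", "hhsynth_config_error")
  }
  if (n_households < 1) hh_abort("n_households must be >= 1", "hhsynth_config_error")
  structure(list(n_households = as.integer(n_households),
                 mixture = mixture[required],
                 gender_balance = gender_balance, seed = as.integer(seed)),
            class = "latent_population_spec")
}

runif_int <- function(lo, hi) {
  if (hi <= lo) return(as.integer(lo))
  as.integer(sample.int(hi - lo + 1L, 1L) + lo - 1L)
}

#' Build the latent ground-truth population
#'
#' @param spec A [latent_population_spec()].
#' @param schema A [population_schema()] (used only for the age upper bound).
#' @return A [population()]; seeded and reproducible.
#' @export
make_latent_population <- function(spec, schema = default_schema()) {
  stopifnot(inherits(spec, "latent_population_spec"))
  gap <- 15  # generator-side parent-child gap, stricter than the rule
  rng <- make_rng(spec$seed)
  pfem <- spec$gender_balance
  gender <- function() if (stats::runif(1) < pfem) "female" else "male"
  other <- function(g) if (g == "female") "male" else "female"
  mk <- function(age, g, rel) person(age = age, gender = g, relationship = rel)

  build_one <- function(kind) {
    switch(kind,
      one_person_young = list(mk(runif_int(18, 65), gender(), "head")),
      one_person_old = list(mk(runif_int(66, 92), gender(), "head")),
      couple = {
        a <- runif_int(21, 88)
        g <- gender()
        list(mk(a, g, "head"),
             mk(max(18L, runif_int(a - 8L, a + 8L)), other(g), "partner"))
      },
      couple_dep_children = {
        a <- runif_int(28, 55)
        g <- gender()
        p <- max(18L + gap + 1L, runif_int(a - 6L, a + 6L))
        n_kids <- runif_int(1, 4)
        kids <- lapply(seq_len(n_kids), function(i) {
          hi <- min(17L, min(a, p) - gap)
          mk(runif_int(0, max(0L, hi)), gender(), "child")
        })
        c(list(mk(a, g, "head"), mk(p, other(g), "partner")), kids)
      },
      couple_nondep_children = {
        a <- runif_int(45, 75)
        g <- gender()
        p <- max(18L + gap + 1L, runif_int(a - 6L, a + 6L))
        n_kids <- runif_int(1, 2)
        kids <- lapply(seq_len(n_kids), function(i) {
          mk(runif_int(18, min(a, p) - gap), gender(), "child")
        })
        c(list(mk(a, g, "head"), mk(p, other(g), "partner")), kids)
      },
      lone_parent = {
        a <- runif_int(22, 60)
        n_kids <- runif_int(1, 3)
        kids <- lapply(seq_len(n_kids), function(i) {
          mk(runif_int(0, max(0L, min(17L, a - gap))), gender(), "child")
        })
        c(list(mk(a, gender(), "head")), kids)
      },
      extended = {
        a <- runif_int(25, 70)
        n_rel <- runif_int(1, 5)
        rels <- lapply(seq_len(n_rel), function(i) {
          role <- sample_one(c("grandparent", "aunt", "cousin", "other-relative"),
                             prob = c(0.25, 0.25, 0.3, 0.2))
          age <- switch(role,
                        grandparent = runif_int(min(a + 20L, 90L), 92),
                        aunt = runif_int(30, 80),
                        cousin = runif_int(5, 60),
                        `other-relative` = runif_int(0, 85))
          mk(age, gender(), role)
        })
        c(list(mk(a, gender(), "head")), rels)
      },
      nonrelatives = {
        n_mates <- runif_int(1, 3)
        mates <- lapply(seq_len(n_mates), function(i) {
          mk(runif_int(18, 45), gender(), "housemate")
        })
        c(list(mk(runif_int(18, 45), gender(), "head")), mates)
      })
  }

  households <- with_rng(rng, {
    kinds <- sample(names(spec$mixture), spec$n_households, replace = TRUE,
                    prob = spec$mixture)
    lapply(seq_along(kinds), function(i) {
      household(build_one(kinds[i]), id = sprintf("L%06d", i))
    })
  })
  population(households,
             provenance = list(source = "latent", seed = spec$seed,
                               n_households = spec$n_households))
}

#' Derive internally consistent target descriptors from a population
#'
#' Produces the four conventional marginals — age bands, gender, household
#' size, household composition — by tallying the population itself, so the
#' resulting targets are exactly recoverable (zero discrepancy by
#' construction). Optionally writes them in the two-column CSV dialect.
#'
#' @param p A non-empty [population()].
#' @param age_bands Ordered age band labels.
#' @param size_bins Ordered household-size bin labels.
#' @param scheme A [classification_scheme()] for the composition labels.
#' @param dir Optional directory: when given, one CSV per descriptor is
#'   written there (`age.csv`, `gender.csv`, `household_size.csv`,
#'   `household_composition.csv`).
#' @return A [descriptor_set()] of empirical descriptors (they carry counts
#'   and totals as well as shares).
#' @export
marginals_from_population <- function(p,
                                      age_bands = decade_age_bands(),
                                      size_bins = c("1", "2-3", "4-5", "6+"),
                                      scheme = classification_scheme("GLOBAL"),
                                      dir = NULL) {
  if (n_households(p) == 0L) {
    hh_abort("cannot derive marginals from an empty population", "hhsynth_config_error")
  }
  comp_labels <- unique(unname(scheme$labels))
  specs <- list(
    age = target_descriptor("age", age_bands, rep(1, length(age_bands)),
                            ordered = TRUE, level = "person"),
    gender = target_descriptor("gender", c("male", "female"), c(1, 1),
                               level = "person"),
    household_size = target_descriptor("household_size", size_bins,
                                       rep(1, length(size_bins)),
                                       ordered = TRUE, level = "household"),
    household_composition = target_descriptor("household_composition", comp_labels,
                                              rep(1, length(comp_labels)),
                                              level = "household")
  )
  descs <- lapply(specs, function(sp) empirical_descriptor(p, sp, scheme = scheme))
  out <- descriptor_set(descs)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out$descriptors)) {
      write_descriptor(out$descriptors[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  out
}

#' Inject a controlled conflict between two descriptors
#'
#' Overwrites one category's share with a different value in each of two
#' descriptors (e.g. the one-person share in the size and composition
#' marginals), rescaling the remaining categories proportionally so each
#' descriptor still sums to 1.
#'
#' @param targets A [descriptor_set()].
#' @param descriptor_names Character vector of two descriptor names.
#' @param categories The affected category label in each descriptor (recycled
#'   if one label applies to both).
#' @param shares The two inconsistent shares to impose (both in `[0, 1]`,
#'   unequal).
#' @return A new [descriptor_set()] with the conflict in place.
#' @export
inject_conflict <- function(targets, descriptor_names, categories, shares) {
  stopifnot(length(descriptor_names) == 2L, length(shares) == 2L)
  if (length(categories) == 1L) categories <- rep(categories, 2L)
  if (any(shares < 0 | shares > 1)) {
    hh_abort("imposed shares must lie in [0, 1]", "hhsynth_config_error")
  }
  if (shares[1] == shares[2]) {
    hh_abort("the two imposed shares must differ (no conflict otherwise)",
             "hhsynth_config_error")
  }
  descs <- targets$descriptors
  for (i in 1:2) {
    nm <- descriptor_names[i]
    if (!nm %in% names(descs)) {
      hh_abort(sprintf("descriptor '%s' not in the set", nm), "hhsynth_config_error")
    }
    d <- descs[[nm]]
    j <- match(categories[i], d$categories)
    if (is.na(j)) {
      hh_abort(sprintf("category '%s' not in descriptor '%s'", categories[i], nm),
               "hhsynth_config_error")
    }
    rest <- d$shares[-j]
    if (sum(rest) <= 0) {
      hh_abort(sprintf("descriptor '%s' has no remaining mass to rescale", nm),
               "hhsynth_config_error")
    }
    new_shares <- d$shares
    new_shares[j] <- shares[i]
    new_shares[-j] <- rest / sum(rest) * (1 - shares[i])
    descs[[nm]] <- target_descriptor(d$name, d$categories, new_shares,
                                     ordered = d$ordered, level = d$level)
  }
  descriptor_set(descs, weights = targets$weights)
}
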