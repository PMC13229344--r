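# Deficit-proportional reference sampler: a seeded, offline generator backend
# that embodies the feedback principle of the framework. It reads the target
# and current tables out of the prompt text (exactly as an external model
# would), computes per-category deficits, and samples households that steer
# every marginal towards its target while respecting the structural rules.

MAX_HOUSEHOLD_SIZE <- 12L

# Interpret a household-composition category label as a constructive pattern.
comp_pattern <- function(label) {
  l <- tolower(label)
  has <- function(rx) grepl(rx, l)
  if (has("one[- ]person") || has("one person")) {
    head_range <- if (has("66\\+") || has(">=\\s*66") || has("66 or over")) {
      c(66, Inf)
    } else if (has("<\\s*66") || has("under 66")) {
      c(18, 65)
    } else {
      c(18, Inf)
    }
    return(list(kind = "single", sizes = c(1, 1), head_range = head_range))
  }
  if (has("lone parent")) return(list(kind = "lone_parent", sizes = c(2, Inf)))
  if (has("couple")) {
    if (!has("child")) return(list(kind = "couple", sizes = c(2, 2)))
    kids <- if (has("non[- ]dependent")) "nondep" else if (has("dependent")) "dep" else "any"
    return(list(kind = "couple_children", sizes = c(3, Inf), kids = kids))
  }
  if (has("extended") || has("relative") && !has("non-relative")) {
    return(list(kind = "extended", sizes = c(2, Inf)))
  }
  if (has("non-relative") || has("housemate") || has("other") || has("unknown")) {
    return(list(kind = "housemates", sizes = c(2, Inf)))
  }
  list(kind = "housemates", sizes = c(2, Inf))
}

# IPF reconciliation of the size and composition marginals into one joint
# target over (composition category, size bin), supported on the structural
# compatibility mask. With consistent marginals IPF converges and the joint
# reproduces both; with conflicting marginals the row- and column-scaled
# iterates disagree and their average splits the difference, which is what
# yields the intermediate-compromise behaviour on conflicting inputs.
reconcile_structure <- function(comp, size_bins, t_comp, t_size, iters = 60L) {
  K <- length(comp$patterns)
  Bn <- nrow(size_bins)
  mask <- matrix(0, K, Bn)
  for (k in seq_len(K)) {
    pr <- comp$patterns[[k]]$sizes
    pr[2] <- min(pr[2], MAX_HOUSEHOLD_SIZE)
    for (b in seq_len(Bn)) {
      lo <- size_bins$lo[b]
      hi <- min(size_bins$hi[b], MAX_HOUSEHOLD_SIZE)
      if (hi >= pr[1] && lo <= pr[2]) mask[k, b] <- 1
    }
  }
  M <- mask * outer(rep(1, K), t_size)
  rs <- rowSums(M)
  bad <- which(rs == 0 & t_comp > 0)
  if (length(bad)) {
    # category has no positive-share compatible bin; fall back to the mask
    M[bad, ] <- mask[bad, ]
    rs <- rowSums(M)
  }
  M <- M / ifelse(rs > 0, rs, 1) * t_comp
  A <- M
  for (i in seq_len(iters)) {
    rs <- rowSums(M)
    A <- M / ifelse(rs > 0, rs, 1) * t_comp          # rows match composition
    cs <- colSums(A)
    M <- t(t(A) / ifelse(cs > 0, cs, 1) * t_size)    # columns match size
  }
  tau <- (A + M) / 2
  tau / sum(tau)
}

# Deficit-proportional sampling weights: desired count at (n + 1) units minus
# the current count, floored to keep every category reachable.
deficit_weights <- function(target_shares, counts, n, floor_eps) {
  w <- target_shares * (n + 1) - counts
  pmax(w, floor_eps)
}

#' Seeded deficit-proportional reference backend
#'
#' An offline generator backend that parses the prompt's target and current
#' tables, reconciles the household-level marginals (size and composition)
#' into a single joint target, computes per-category deficits against the
#' current distributions, and samples households from the deficit-weighted
#' distributions: a size/composition pattern first, then the head, then
#' further members with ages and genders steered by the person-level
#' deficits, with roles chosen to realise the composition pattern. All output
#' respects the structural rules by construction. Reproducible: the backend
#' carries its own RNG stream derived from `seed`.
#'
#' @param targets [descriptor_set()] the loop will fit (used to pre-check
#'   satisfiability; generation itself reads the prompt).
#' @param schema A [population_schema()].
#' @param rules A [rule_set()] (the minor and head-age thresholds are read
#'   from it).
#' @param seed Integer seed.
#' @param epsilon Deficit floor; keeps every category reachable.
#' @return A `generator_backend`.
#' @export
reference_sampler_backend <- function(targets, schema, rules = default_rules(),
                                      seed = 1, epsilon = 1e-6) {
  levels <- vapply(targets$descriptors, `[[`, character(1), "level")
  ordered <- vapply(targets$descriptors, `[[`, logical(1), "ordered")
  if (!any(levels == "household" & ordered)) {
    hh_abort("reference sampler needs an ordered household-size descriptor",
             "hhsynth_backend_error")
  }
  if (!any(levels == "person")) {
    hh_abort("reference sampler needs at least one person-level descriptor",
             "hhsynth_backend_error")
  }
  size_spec <- targets$descriptors[[which(levels == "household" & ordered)[1]]]
  size_bins_check <- parse_bins(size_spec$categories)
  if (any(size_bins_check$lo > MAX_HOUSEHOLD_SIZE)) {
    hh_abort(sprintf("size bin '%s' exceeds the largest constructible household (%d)",
                     size_bins_check$label[size_bins_check$lo > MAX_HOUSEHOLD_SIZE][1],
                     MAX_HOUSEHOLD_SIZE), "hhsynth_backend_error")
  }
  rng <- make_rng(seed)
  minor_age <- rules$params$minor_age %||% 18
  cache <- new.env(parent = emptyenv())

  gen <- function(prompt) {
    with_rng(rng, sampler_generate(prompt, minor_age, epsilon, cache))
  }
  new_backend("reference-sampler", gen, deterministic = TRUE)
}

sampler_generate <- function(prompt, minor_age, eps, cache) {
  pp <- parse_prompt(prompt)
  tg <- pp$targets
  cur <- pp$current
  age_max <- 120
  for (a in pp$schema$attributes) {
    if (identical(a$name, "age")) age_max <- a$max
  }
  real_max <- min(age_max, 95)  # ages drawn in a demographically plausible range

  levels <- vapply(tg, `[[`, character(1), "level")
  ord <- vapply(tg, `[[`, logical(1), "ordered")
  size_d <- tg[[which(levels == "household" & ord)[1]]]
  comp_i <- which(levels == "household" & !ord)
  comp_d <- if (length(comp_i)) tg[[comp_i[1]]] else NULL
  age_i <- which(levels == "person" & ord)
  age_d <- if (length(age_i)) tg[[age_i[1]]] else NULL
  gender_i <- which(levels == "person" & !ord)
  gender_d <- if (length(gender_i)) tg[[gender_i[1]]] else NULL

  size_bins <- parse_bins(size_d$categories)
  age_bins <- if (!is.null(age_d)) parse_bins(age_d$categories) else NULL

  # reconciled joint household-structure target (cached per target table)
  key <- paste(size_d$name, paste(size_d$shares, collapse = ","),
               if (!is.null(comp_d)) paste(comp_d$shares, collapse = ","), sep = "|")
  if (is.null(comp_d)) {
    patterns <- default_patterns_for_sizes(size_bins)
    comp <- list(patterns = patterns)
    t_comp <- rep(1 / length(patterns), length(patterns))
  } else {
    comp <- list(patterns = lapply(comp_d$categories, comp_pattern))
    t_comp <- comp_d$shares
  }
  if (!is.null(cache$key) && identical(cache$key, key)) {
    tau <- cache$tau
  } else {
    tau <- reconcile_structure(comp, size_bins, t_comp, size_d$shares)
    cache$key <- key
    cache$tau <- tau
  }
  t_comp_star <- rowSums(tau)
  t_size_star <- colSums(tau)

  # current tallies (approximate counts reconstructed from shares x units);
  # absent current block means no feedback: pure draws from the targets
  counts_of <- function(target, nm) {
    if (is.null(cur) || is.null(cur[[nm]])) {
      list(n = 0, counts = rep(0, length(target$categories)))
    } else {
      cc <- cur[[nm]]
      n <- cc$total %||% 0L
      counts <- stats::setNames(rep(0, length(target$categories)), target$categories)
      m <- match(cc$categories, target$categories)
      counts[m[!is.na(m)]] <- cc$shares[!is.na(m)] * n
      list(n = n, counts = unname(counts))
    }
  }
  st_size <- counts_of(size_d, size_d$name)
  st_comp <- if (!is.null(comp_d)) counts_of(comp_d, comp_d$name) else list(n = st_size$n, counts = t_comp * st_size$n)
  st_age <- if (!is.null(age_d)) counts_of(age_d, age_d$name) else NULL
  st_gender <- if (!is.null(gender_d)) counts_of(gender_d, gender_d$name) else NULL
  feedback_on <- !is.null(cur)

  draw_person_age <- function(lo, hi) {
    lo <- max(0, floor(lo)); hi <- min(real_max, floor(hi))
    if (hi < lo) hi <- lo
    if (is.null(age_d)) {
      age <- if (hi > lo) sample.int(hi - lo + 1L, 1L) + lo - 1L else lo
    } else {
      ok <- which(pmin(age_bins$hi, real_max) >= lo & age_bins$lo <= hi)
      if (length(ok) == 0L) ok <- which.min(abs(age_bins$lo - lo))
      w <- if (feedback_on) {
        deficit_weights(age_d$shares[ok], st_age$counts[ok], st_age$n, eps)
      } else {
        pmax(age_d$shares[ok], eps)
      }
      b <- ok[if (length(ok) > 1L) sample.int(length(ok), 1L, prob = w) else 1L]
      blo <- max(age_bins$lo[b], lo)
      bhi <- min(age_bins$hi[b], real_max, hi)
      age <- if (bhi > blo) sample.int(bhi - blo + 1L, 1L) + blo - 1L else blo
      if (feedback_on) {
        st_age$counts[b] <<- st_age$counts[b] + 1
        st_age$n <<- st_age$n + 1
      }
    }
    as.integer(age)
  }
  draw_gender <- function() {
    if (is.null(gender_d)) return("female")
    w <- if (feedback_on) {
      deficit_weights(gender_d$shares, st_gender$counts, st_gender$n, eps)
    } else {
      pmax(gender_d$shares, eps)
    }
    g <- gender_d$categories[sample.int(length(w), 1L, prob = w)]
    if (feedback_on) {
      i <- match(g, gender_d$categories)
      st_gender$counts[i] <<- st_gender$counts[i] + 1
      st_gender$n <<- st_gender$n + 1
    }
    g
  }
  opposite_gender <- function(g) {
    if (is.null(gender_d) || length(gender_d$categories) != 2L) return(draw_gender())
    out <- setdiff(gender_d$categories, g)[1]
    if (feedback_on) {
      i <- match(out, gender_d$categories)
      st_gender$counts[i] <<- st_gender$counts[i] + 1
      st_gender$n <<- st_gender$n + 1
    }
    out
  }

  draw_size_in_bin <- function(b, lo_req, hi_req) {
    lo <- max(size_bins$lo[b], lo_req, 1)
    hi <- min(size_bins$hi[b], MAX_HOUSEHOLD_SIZE, hi_req)
    if (hi < lo) return(NA_integer_)
    sizes <- lo:hi
    w <- 0.55^(seq_along(sizes) - 1)  # favour smaller households within a bin
    as.integer(sample_one(sizes, prob = w))
  }

  households <- vector("list", pp$B)
  for (hh_i in seq_len(pp$B)) {
    # joint structure draw, tilted by the two household-level deficits
    w_comp <- if (feedback_on) {
      deficit_weights(t_comp_star, st_comp$counts, st_comp$n, eps)
    } else {
      pmax(t_comp_star, eps)
    }
    w_size <- if (feedback_on) {
      deficit_weights(t_size_star, st_size$counts, st_size$n, eps)
    } else {
      pmax(t_size_star, eps)
    }
    tilt <- tau * outer(w_comp / pmax(t_comp_star, eps),
                        w_size / pmax(t_size_star, eps))
    tilt[tau <= 0] <- 0
    if (sum(tilt) <= 0) tilt <- tau
    cell <- sample.int(length(tilt), 1L, prob = as.vector(tilt))
    k <- (cell - 1L) %% nrow(tau) + 1L
    b <- (cell - 1L) %/% nrow(tau) + 1L
    pat <- comp$patterns[[k]]
    s <- draw_size_in_bin(b, pat$sizes[1], pat$sizes[2])
    if (is.na(s)) s <- max(1L, min(pat$sizes[1], MAX_HOUSEHOLD_SIZE))

    members <- build_household_members(pat, s, minor_age, real_max,
                                       draw_person_age, draw_gender,
                                       opposite_gender)
    households[[hh_i]] <- household(members, id = sprintf("pending%03d", hh_i))
    if (feedback_on) {
      st_size$counts[b] <- st_size$counts[b] + 1
      st_size$n <- st_size$n + 1
      st_comp$counts[k] <- st_comp$counts[k] + 1
      st_comp$n <- st_comp$n + 1
    }
  }
  format_households_response(households)
}

# When no composition descriptor is supplied, realise sizes with a plain
# repertoire of structures.
default_patterns_for_sizes <- function(size_bins) {
  list(list(kind = "single", sizes = c(1, 1), head_range = c(18, Inf)),
       list(kind = "couple", sizes = c(2, 2)),
       list(kind = "couple_children", sizes = c(3, Inf), kids = "any"),
       list(kind = "housemates", sizes = c(2, Inf)))
}

build_household_members <- function(pat, s, minor_age, real_max,
                                    draw_age, draw_gender, opposite_gender) {
  mk <- function(age, gender, relationship) {
    person(age = age, gender = gender, relationship = relationship)
  }
  gap <- 16  # generator-side parent-child age gap; stricter than the rule
  members <- list()
  if (pat$kind == "single") {
    hr <- pat$head_range %||% c(minor_age, Inf)
    age <- draw_age(max(hr[1], minor_age), hr[2])
    return(list(mk(age, draw_gender(), "head")))
  }
  if (pat$kind == "couple") {
    h_age <- draw_age(18, real_max)
    g <- draw_gender()
    p_age <- draw_age(max(18, h_age - 15), min(real_max, h_age + 15))
    return(list(mk(h_age, g, "head"), mk(p_age, opposite_gender(g), "partner")))
  }
  if (pat$kind %in% c("couple_children", "lone_parent")) {
    n_kids <- s - if (pat$kind == "couple_children") 2L else 1L
    n_kids <- max(1L, n_kids)
    kids_mode <- pat$kids %||% "any"
    # parents old enough to be `gap` years above every child
    min_parent <- if (kids_mode == "nondep") 18 + gap else gap
    h_age <- draw_age(max(22, min_parent), real_max)
    g <- draw_gender()
    members <- list(mk(h_age, g, "head"))
    pmin_age <- h_age
    if (pat$kind == "couple_children") {
      p_age <- draw_age(max(max(18, min_parent), h_age - 15), min(real_max, h_age + 15))
      members[[2]] <- mk(p_age, opposite_gender(g), "partner")
      pmin_age <- min(h_age, p_age)
    }
    for (ki in seq_len(n_kids)) {
      k_hi <- pmin_age - gap
      k_lo <- 0
      if (kids_mode == "dep" && ki == 1L) k_hi <- min(k_hi, minor_age - 1)
      if (kids_mode == "nondep") k_lo <- minor_age
      if (k_hi < k_lo) k_hi <- k_lo  # degenerate; still strictly younger below
      age <- draw_age(k_lo, k_hi)
      if (age >= pmin_age) age <- max(0L, pmin_age - 1L)
      members[[length(members) + 1L]] <- mk(age, draw_gender(), "child")
    }
    return(members)
  }
  if (pat$kind == "extended") {
    h_age <- draw_age(25, real_max)
    members <- list(mk(h_age, draw_gender(), "head"))
    for (ri in seq_len(s - 1L)) {
      role <- sample_one(c("grandparent", "aunt", "cousin", "other-relative"),
                         prob = c(0.2, 0.25, 0.3, 0.25))
      rng_lo <- switch(role, grandparent = min(h_age + 20, real_max - 1),
                       aunt = 18, cousin = 0, `other-relative` = 0)
      members[[length(members) + 1L]] <- mk(draw_age(rng_lo, real_max),
                                            draw_gender(), role)
    }
    return(members)
  }
  # housemates / catch-all: unrelated adults sharing
  h_age <- draw_age(18, real_max)
  members <- list(mk(h_age, draw_gender(), "head"))
  for (ri in seq_len(s - 1L)) {
    members[[length(members) + 1L]] <- mk(draw_age(18, real_max),
                                          draw_gender(), "housemate")
  }
  members
}
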