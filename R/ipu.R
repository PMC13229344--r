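# Iterative Proportional Updating baseline: reweight a household microdata
# sample to satisfy person- and household-level marginal constraints jointly,
# then realise an integer population by weighted draws.

#' Build a weighted sample with constraint incidence
#'
#' Computes, for every sample household, its contribution to each constraint
#' category: indicator columns for the household-level categories (size bin,
#' composition) and member counts for the person-level categories (age bands,
#' gender). The incidence matrix is fixed at construction; only the weights
#' change during fitting.
#'
#' @param p A [population()] serving as the microdata sample.
#' @param person_targets [descriptor_set()] of person-level descriptors.
#' @param household_targets [descriptor_set()] of household-level descriptors.
#' @param scheme [classification_scheme()] for composition incidence.
#' @return A list of class `weighted_sample` with `households`, `incidence`
#'   (matrix households x constraint categories), `constraints` (data frame
#'   with `descriptor`, `category`, `level`), and unit `weights` (initial 1).
#' @export
weighted_sample <- function(p, person_targets, household_targets,
                            scheme = classification_scheme("GLOBAL")) {
  all_desc <- c(household_targets$descriptors, person_targets$descriptors)
  cons <- do.call(rbind, lapply(all_desc, function(d) {
    data.frame(descriptor = d$name, category = d$categories,
               level = d$level, stringsAsFactors = FALSE)
  }))
  rownames(cons) <- NULL
  banders <- lapply(all_desc, default_bander, scheme = scheme)
  m <- n_households(p)
  inc <- matrix(0L, nrow = m, ncol = nrow(cons),
                dimnames = list(NULL, paste(cons$descriptor, cons$category, sep = ":")))
  for (i in seq_len(m)) {
    h <- p$households[[i]]
    for (d in all_desc) {
      if (d$level == "household") {
        lab <- banders[[d$name]](h)
        col <- paste(d$name, lab, sep = ":")
        if (col %in% colnames(inc)) inc[i, col] <- 1L
      } else {
        for (mem in h$members) {
          lab <- banders[[d$name]](mem)
          col <- paste(d$name, lab, sep = ":")
          if (col %in% colnames(inc)) inc[i, col] <- inc[i, col] + 1L
        }
      }
    }
  }
  structure(list(households = p$households, incidence = inc, constraints = cons,
                 weights = rep(1, m)),
            class = "weighted_sample")
}

#' IPU configuration
#'
#' @param max_iterations Maximum full sweeps over all constraints (default
#'   1000).
#' @param tolerance Convergence tolerance on the maximum relative change of
#'   constraint-weighted totals between sweeps.
#' @param seed Seed for the integerising draw.
#' @return A list of class `ipu_config`.
#' @export
ipu_config <- function(max_iterations = 1000, tolerance = 1e-8, seed = 1) {
  if (max_iterations < 1 || tolerance <= 0) {
    hh_abort("max_iterations must be >= 1 and tolerance > 0", "hhsynth_config_error")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "ipu_config")
}

# Resolve constraint target totals from descriptor shares. Empirical
# descriptors carry exact unit totals; plain targets fall back to
# `n_households` for the household level and a size-marginal estimate of the
# person count for the person level.
constraint_targets <- function(sample, person_targets, household_targets,
                               n_households_target) {
  totals <- numeric(nrow(sample$constraints))
  hh_total <- n_households_target
  person_total <- NULL
  for (d in person_targets$descriptors) {
    if (!is.null(d$total) && d$total > 0) person_total <- d$total
  }
  for (d in household_targets$descriptors) {
    if (is.null(hh_total) && !is.null(d$total) && d$total > 0) hh_total <- d$total
  }
  if (is.null(hh_total)) {
    hh_abort("household total unavailable: supply n_households or empirical targets",
             "hhsynth_config_error")
  }
  if (is.null(person_total)) {
    size_d <- Filter(function(d) d$ordered, household_targets$descriptors)
    if (length(size_d)) {
      bins <- parse_bins(size_d[[1]]$categories)
      mid <- ifelse(is.finite(bins$hi), (bins$lo + bins$hi) / 2, bins$lo + 1)
      person_total <- hh_total * sum(size_d[[1]]$shares * mid)
    } else {
      person_total <- hh_total * 2.4
    }
  }
  all_desc <- c(household_targets$descriptors, person_targets$descriptors)
  k <- 0L
  for (d in all_desc) {
    lvl_total <- if (d$level == "household") hh_total else person_total
    for (j in seq_along(d$categories)) {
      k <- k + 1L
      totals[k] <- d$shares[j] * lvl_total
    }
  }
  totals
}

#' Fit household weights by Iterative Proportional Updating
#'
#' Sweeps repeatedly over all constraint categories — household-level first,
#' then person-level, in declared order — multiplying each contributing
#' household's weight by the ratio of the category's target total to its
#' current weighted total. Stops when the weighted totals change by less than
#' the tolerance between sweeps, or at the iteration cap.
#'
#' @param sample A [weighted_sample()].
#' @param person_targets,household_targets The constraint
#'   [descriptor_set()]s used to build the sample.
#' @param cfg An [ipu_config()].
#' @param n_households Target household count; optional when the targets are
#'   empirical descriptors carrying totals.
#' @return A list of class `ipu_fit` with `weights`, `iterations`,
#'   `converged`, and `diagnostics` (per constraint: target and fitted
#'   weighted shares within level, and their relative deviation).
#' @export
ipu_fit <- function(sample, person_targets, household_targets,
                    cfg = ipu_config(), n_households = NULL) {
  stopifnot(inherits(sample, "weighted_sample"))
  A <- sample$incidence
  targets <- constraint_targets(sample, person_targets, household_targets,
                                n_households)
  pos <- targets > 0
  infeasible <- pos & (colSums(A) == 0)
  if (any(infeasible)) {
    hh_abort(sprintf("no sample household contributes to constraint '%s'",
                     colnames(A)[infeasible][1]), "hhsynth_infeasible_error")
  }
  w <- sample$weights
  contrib <- lapply(seq_len(ncol(A)), function(j) which(A[, j] > 0))
  prev_totals <- rep(Inf, ncol(A))
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(cfg$max_iterations)) {
    iterations <- it
    for (j in seq_len(ncol(A))) {
      if (!pos[j]) next
      idx <- contrib[[j]]
      s <- sum(w[idx] * A[idx, j])
      if (s > 0) w[idx] <- w[idx] * (targets[j] / s)
    }
    totals <- as.vector(crossprod(A, w))
    delta <- max(abs(totals - prev_totals) / pmax(targets, 1e-12))
    prev_totals <- totals
    if (delta < cfg$tolerance) {
      converged <- TRUE
      break
    }
  }
  totals <- as.vector(crossprod(A, w))
  cons <- sample$constraints
  diag_rows <- cons
  diag_rows$target_total <- targets
  diag_rows$fitted_total <- totals
  # within-level shares are scale-free, which is what fit quality means here
  for (lvl in unique(cons$level)) {
    for (ds in unique(cons$descriptor[cons$level == lvl])) {
      sel <- cons$descriptor == ds
      tsum <- sum(targets[sel])
      fsum <- sum(totals[sel])
      diag_rows$target_share[sel] <- if (tsum > 0) targets[sel] / tsum else 0
      diag_rows$fitted_share[sel] <- if (fsum > 0) totals[sel] / fsum else 0
    }
  }
  diag_rows$rel_deviation <- ifelse(
    diag_rows$target_share > 0,
    abs(diag_rows$fitted_share - diag_rows$target_share) / diag_rows$target_share,
    abs(diag_rows$fitted_share))
  structure(list(weights = w, iterations = iterations, converged = converged,
                 diagnostics = diag_rows),
            class = "ipu_fit")
}

#' @export
print.ipu_fit <- function(x, ...) {
  cat(sprintf("<ipu_fit> %d iterations (%sconverged), max relative deviation %.3g\n",
              x$iterations, if (x$converged) "" else "not ",
              max(x$diagnostics$rel_deviation)))
  invisible(x)
}

#' Draw an integer population from fitted weights
#'
#' Samples households with replacement, with probability proportional to
#' weight — the simplest unbiased integerisation.
#'
#' @param sample A [weighted_sample()].
#' @param weights Fitted weights (defaults to the sample's).
#' @param N Number of households to draw.
#' @param seed Integer seed.
#' @return A [population()].
#' @export
draw_population <- function(sample, weights = sample$weights, N, seed = 1) {
  if (N < 1) hh_abort("N must be >= 1", "hhsynth_config_error")
  if (sum(weights) <= 0) hh_abort("weights sum to zero", "hhsynth_config_error")
  rng <- make_rng(seed)
  idx <- with_rng(rng, sample.int(length(weights), N, replace = TRUE,
                                  prob = weights))
  households <- lapply(seq_along(idx), function(i) {
    household(sample$households[[idx[i]]]$members, id = sprintf("i%06d", i))
  })
  population(households, provenance = list(source = "ipu-draw", seed = seed, N = N))
}

#' Compare the feedback-loop generator with the IPU baseline
#'
#' Runs both methods repeatedly on the same targets and reports per-method,
#' per-descriptor mean SRMSE (and the ordinal Wasserstein distance for
#' ordered descriptors) with percentile-bootstrap confidence intervals.
#'
#' @param targets A [descriptor_set()] (all four conventional marginals).
#' @param sample A [weighted_sample()] for the IPU side.
#' @param schema,rules Validation context for the generator side.
#' @param N Households per run.
#' @param runs Number of independent runs per method.
#' @param seeds Integer seeds, one per run (default `seq_len(runs)`).
#' @param batch_size Generator batch size.
#' @param scheme [classification_scheme()] for tallies.
#' @return A list of class `method_comparison` with a `summary` data frame
#'   (`method`, `descriptor`, `metric`, `mean`, `lower`, `upper`) and the raw
#'   per-run values.
#' @export
compare_methods <- function(targets, sample, schema = default_schema(),
                            rules = default_rules(), N = 883, runs = 20,
                            seeds = seq_len(runs), batch_size = 10,
                            scheme = classification_scheme("GLOBAL")) {
  stopifnot(length(seeds) == runs)
  fitted <- ipu_fit(sample,
                    person_targets = descriptor_set(
                      Filter(function(d) d$level == "person", targets$descriptors)),
                    household_targets = descriptor_set(
                      Filter(function(d) d$level == "household", targets$descriptors)))
  per_run <- list()
  record <- function(method, run, pop) {
    for (d in targets$descriptors) {
      emp <- empirical_descriptor(pop, d, scheme = scheme)
      al <- align_descriptors(d, emp)
      per_run[[length(per_run) + 1L]] <<- data.frame(
        method = method, run = run, descriptor = d$name,
        srmse = srmse(al$target, al$empirical),
        wasserstein = if (d$ordered) wasserstein_ordinal(al$target, al$empirical) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(runs)) {
    backend <- reference_sampler_backend(targets, schema, rules, seed = seeds[r])
    cfg <- generation_config(N, batch_size = batch_size, seed = seeds[r])
    res <- generate_population(cfg, targets, schema, rules, backend, scheme = scheme)
    record("feedback-loop", r, res$population)
    pop_ipu <- draw_population(sample, fitted$weights, N, seed = seeds[r])
    record("ipu", r, pop_ipu)
  }
  raw <- do.call(rbind, per_run)
  rownames(raw) <- NULL
  summ <- list()
  for (method in unique(raw$method)) {
    for (ds in unique(raw$descriptor)) {
      for (metric in c("srmse", "wasserstein")) {
        vals <- raw[raw$method == method & raw$descriptor == ds, metric]
        vals <- vals[!is.na(vals)]
        if (length(vals) == 0L) next
        ci <- if (length(vals) >= 2L) {
          bootstrap_ci(vals, n_boot = 1000, seed = 1)
        } else {
          c(mean = vals, lower = NA_real_, upper = NA_real_)
        }
        summ[[length(summ) + 1L]] <- data.frame(
          method = method, descriptor = ds, metric = metric,
          mean = unname(ci[1]), lower = unname(ci[2]), upper = unname(ci[3]),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = do.call(rbind, summ), runs = raw),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(transform(x$summary, mean = round(mean, 4), lower = round(lower, 4),
                  upper = round(upper, 4)), row.names = FALSE)
  invisible(x)
}
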