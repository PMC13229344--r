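# Distributional-fit metrics and evaluation machinery.

check_pair <- function(p, q) {
  if (length(p) != length(q)) {
    hh_abort("share vectors must have equal length", "hhsynth_metric_error")
  }
  if (any(p < 0) || any(q < 0)) {
    hh_abort("shares must be non-negative", "hhsynth_metric_error")
  }
}

#' Standardised root mean square error between two categorical distributions
#'
#' `sqrt(n * sum((p - q)^2))` for `n` categories — the root mean square error
#' divided by the mean target share `1/n`. Zero at a perfect match; unbounded
#' above and sensitive to the number of categories.
#'
#' @param p,q Aligned share vectors of equal length, each summing to 1 (`q`
#'   may be all zero for an empty population).
#' @return A non-negative scalar.
#' @examples
#' srmse(c(0.6, 0.4), c(0.5, 0.5))  # 0.2
#' @export
srmse <- function(p, q) {
  check_pair(p, q)
  n <- length(p)
  sqrt(n * sum((p - q)^2))
}

#' Jensen-Shannon divergence (log base 2)
#'
#' Symmetric information-theoretic divergence bounded in `[0, 1]`: 0 for
#' identical distributions, 1 for disjoint supports. Terms with zero mass
#' contribute zero.
#'
#' @param p,q Aligned share vectors summing to 1.
#' @return A scalar in `[0, 1]`.
#' @export
jsd <- function(p, q) {
  check_pair(p, q)
  m <- (p + q) / 2
  term <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  val <- 0.5 * term(p) + 0.5 * term(q)
  min(max(val, 0), 1)  # clamp floating-point spill at the bounds
}

#' First Wasserstein distance over equally spaced ordinal categories
#'
#' The sum of absolute differences between the two cumulative distributions;
#' the unit is one category width, and open-ended terminal bins are assigned
#' the same width as closed bins.
#'
#' @param p,q Aligned share vectors over ordered categories, summing to 1.
#' @return A non-negative scalar (category widths).
#' @export
wasserstein_ordinal <- function(p, q) {
  check_pair(p, q)
  sum(abs(cumsum(p) - cumsum(q)))
}

#' Per-descriptor fit report for a synthetic population
#'
#' Computes SRMSE and JSD for every target descriptor (and the ordinal
#' Wasserstein distance for ordered ones), the unweighted combined mean SRMSE,
#' and the population feasibility rate.
#'
#' @param population A [population()].
#' @param targets A [descriptor_set()].
#' @param schema A [population_schema()] (for the feasibility rate).
#' @param rules A [rule_set()].
#' @param scheme Classification scheme for composition tallies.
#' @return A list of class `fit_report` with a `per_descriptor` data frame
#'   (columns `descriptor`, `n_categories`, `srmse`, `jsd`, `wasserstein`),
#'   `mean_srmse`, and `feasibility`.
#' @export
fit_report <- function(population, targets, schema = default_schema(),
                       rules = default_rules(),
                       scheme = classification_scheme("GLOBAL")) {
  rows <- lapply(targets$descriptors, function(d) {
    emp <- empirical_descriptor(population, d, scheme = scheme)
    al <- align_descriptors(d, emp)
    data.frame(
      descriptor = d$name,
      n_categories = length(al$categories),
      srmse = srmse(al$target, al$empirical),
      jsd = jsd(al$target, al$empirical),
      wasserstein = if (d$ordered) wasserstein_ordinal(al$target, al$empirical) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(
    list(per_descriptor = per,
         mean_srmse = mean(per$srmse),
         feasibility = feasibility_rate(population, schema, rules)),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report>\n")
  print(transform(x$per_descriptor,
                  srmse = round(srmse, 4), jsd = round(jsd, 4),
                  wasserstein = round(wasserstein, 4)), row.names = FALSE)
  cat(sprintf("mean SRMSE: %.4f   feasibility: %.3f\n", x$mean_srmse, x$feasibility))
  invisible(x)
}

#' Cross-tabulation goodness of fit
#'
#' Tabulates the joint distribution of an attribute tuple in the synthetic
#' population and reports the squared Pearson correlation between synthetic
#' and reference cell shares over the full category product. Units are
#' persons when any person-level variable is involved, households otherwise;
#' household-level variables are inherited by members.
#'
#' @param population A [population()].
#' @param reference Data frame with one column per variable plus a `share`
#'   column covering the full category product (zero cells allowed).
#' @param variables Character vector naming the cross-tabulated variables.
#'   Recognised household-level derived variables: `"household_size"` (needs
#'   `size_spec`) and `"household_composition"` (needs `scheme`); anything
#'   else is read from person attributes, with `"age"` banded by `age_bands`.
#' @param size_spec Ordered household-size descriptor for size binning.
#' @param scheme [classification_scheme()] for composition.
#' @param age_bands Band labels applied to `age`.
#' @return A list of class `crosstab_report` with the R-squared, the cell
#'   count, and the joined cell table. Degenerate references (all cells
#'   equal) yield `r_squared = NA` with `degenerate = TRUE`.
#' @export
crosstab_r2 <- function(population, reference, variables,
                        size_spec = NULL,
                        scheme = classification_scheme("GLOBAL"),
                        age_bands = decade_age_bands()) {
  stopifnot(is.data.frame(reference), all(variables %in% names(reference)),
            "share" %in% names(reference))
  person_level <- any(!variables %in% c("household_size", "household_composition"))
  value_of <- function(h, m, v) {
    if (v == "household_size") {
      if (is.null(size_spec)) hh_abort("size_spec required for household_size",
                                       "hhsynth_metric_error")
      household_size_category(h, size_spec)
    } else if (v == "household_composition") {
      derive_household_type(h, scheme)
    } else if (v == "age") {
      age_band(m$age, age_bands)
    } else {
      val <- m[[v]]
      if (is.null(val)) {
        hh_abort(sprintf("variable '%s' absent from population", v),
                 "hhsynth_metric_error")
      }
      trimws2(val)
    }
  }
  cells <- list()
  for (h in population$households) {
    units <- if (person_level) h$members else list(h$members[[1]])
    for (m in units) {
      key <- paste(vapply(variables, function(v) value_of(h, m, v), character(1)),
                   collapse = "\r")
      cells[[key]] <- (cells[[key]] %||% 0L) + 1L
    }
  }
  total <- sum(unlist(cells))
  ref_key <- apply(reference[, variables, drop = FALSE], 1L,
                   function(r) paste(trimws2(r), collapse = "\r"))
  if (anyDuplicated(ref_key)) {
    hh_abort("reference cross-tab has duplicate cells", "hhsynth_metric_error")
  }
  syn <- vapply(ref_key, function(k) (cells[[k]] %||% 0L) / max(total, 1L), numeric(1))
  stray <- setdiff(names(cells), ref_key)
  if (length(stray)) {
    hh_abort(sprintf("population cell '%s' missing from the reference product",
                     gsub("\r", " x ", stray[1])), "hhsynth_metric_error")
  }
  ref <- reference$share / sum(reference$share)
  degenerate <- stats::var(ref) == 0 || stats::var(syn) == 0
  r2 <- if (degenerate) NA_real_ else stats::cor(syn, ref)^2
  structure(
    list(variables = variables, n_cells = length(ref), r_squared = r2,
         degenerate = degenerate,
         cells = data.frame(reference[, variables, drop = FALSE],
                            reference_share = ref, synthetic_share = unname(syn))),
    class = "crosstab_report"
  )
}

#' @export
print.crosstab_report <- function(x, ...) {
  cat(sprintf("<crosstab_report> %s: %d cells, R^2 = %s\n",
              paste(x$variables, collapse = " x "), x$n_cells,
              if (x$degenerate) "undefined (degenerate reference)" else sprintf("%.3f", x$r_squared)))
  invisible(x)
}

#' Percentile bootstrap over repeated-run statistics
#'
#' Resamples the per-run statistics with replacement, takes the mean of each
#' resample, and reports the observed mean with the 2.5/97.5 percentile
#' interval of the bootstrap means.
#'
#' @param run_statistics Numeric vector of at least two per-run values.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Integer seed.
#' @return A named numeric vector `c(mean, lower, upper)`.
#' @export
bootstrap_ci <- function(run_statistics, n_boot = 2000, seed = 1) {
  if (length(run_statistics) < 2L) {
    hh_abort("bootstrap_ci needs at least 2 runs", "hhsynth_metric_error")
  }
  if (n_boot < 100L) {
    hh_abort("n_boot must be at least 100", "hhsynth_metric_error")
  }
  rng <- make_rng(seed)
  k <- length(run_statistics)
  means <- with_rng(rng, {
    idx <- matrix(sample.int(k, k * n_boot, replace = TRUE), nrow = n_boot)
    apply(idx, 1L, function(i) mean(run_statistics[i]))
  })
  qs <- stats::quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(run_statistics), lower = qs[1], upper = qs[2])
}

#' SRMSE convergence series from a generation trace
#'
#' One SRMSE value per batch and descriptor, computed from the per-batch
#' empirical snapshots recorded during generation, indexed by the number of
#' individuals added so far. The final point equals the fit-report SRMSE of
#' the finished population.
#'
#' @param trace A `generation_trace` from [generate_population()].
#' @param targets The [descriptor_set()] that was fitted.
#' @return A data frame with columns `descriptor`, `batch`, `households`,
#'   `individuals`, `srmse`.
#' @export
convergence_trace <- function(trace, targets) {
  if (length(trace$batches) == 0L) {
    hh_abort("empty generation trace", "hhsynth_metric_error")
  }
  rows <- list()
  for (b in trace$batches) {
    for (nm in names(targets$descriptors)) {
      d <- targets$descriptors[[nm]]
      shares <- b$snapshot[[nm]]
      if (is.null(shares)) next
      rows[[length(rows) + 1L]] <- data.frame(
        descriptor = nm, batch = b$batch, households = b$households_cum,
        individuals = b$persons_cum,
        srmse = srmse(d$shares, shares), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
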