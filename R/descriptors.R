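# Target and empirical marginal distributions (the descriptors that drive
# generation and against which fit is evaluated).

#' Construct a target descriptor
#'
#' A target descriptor is one named marginal distribution over categories,
#' with a proportion share per category. Shares are normalised to sum to 1;
#' ordered descriptors (age bands, household sizes) preserve category order.
#'
#' @param name Attribute identifier, e.g. `"age"` or `"household_size"`.
#' @param categories Character vector of unique, non-empty category labels.
#' @param shares Non-negative numeric vector, one share per category. Any
#'   positive-sum vector is accepted and rescaled to proportions.
#' @param ordered Logical; `TRUE` marks an ordinal variable whose category
#'   order is meaningful (enables the Wasserstein metric and bin parsing).
#' @param level Unit of the distribution: `"person"` or `"household"`.
#' @return An object of class `target_descriptor`.
#' @examples
#' target_descriptor("gender", c("male", "female"), c(50, 50), level = "person")
#' @export
target_descriptor <- function(name, categories, shares, ordered = FALSE,
                              level = c("person", "household")) {
  level <- match.arg(level)
  categories <- trimws2(categories)
  if (length(categories) == 0L || any(!nzchar(categories))) {
    hh_abort("descriptor categories must be non-empty strings", "hhsynth_descriptor_error")
  }
  if (anyDuplicated(categories)) {
    hh_abort(sprintf("duplicate category '%s' in descriptor '%s'",
                     categories[duplicated(categories)][1], name),
             "hhsynth_descriptor_error")
  }
  shares <- as.numeric(shares)
  if (length(shares) != length(categories)) {
    hh_abort("categories and shares must have equal length", "hhsynth_descriptor_error")
  }
  if (any(!is.finite(shares)) || any(shares < 0)) {
    hh_abort(sprintf("descriptor '%s' has negative or non-finite shares", name),
             "hhsynth_descriptor_error")
  }
  total <- sum(shares)
  if (total <= 0) {
    hh_abort(sprintf("descriptor '%s' has all-zero shares", name),
             "hhsynth_descriptor_error")
  }
  structure(
    list(name = name, categories = categories, shares = shares / total,
         ordered = isTRUE(ordered), level = level),
    class = "target_descriptor"
  )
}

#' @export
print.target_descriptor <- function(x, ...) {
  cat(sprintf("<target_descriptor> %s (%s-level%s, %d categories)\n",
              x$name, x$level, if (x$ordered) ", ordered" else "",
              length(x$categories)))
  print(stats::setNames(round(x$shares, 4), x$categories))
  invisible(x)
}

#' Read a target descriptor from a two-column CSV file
#'
#' The expected dialect is two columns — category label, percentage share —
#' with or without a header row (autodetected by whether the second field of
#' the first row parses as a number). Shares may be printed as percentages
#' (summing to about 100) or proportions (summing to about 1); anything else
#' is rejected as a probable unit error.
#'
#' @param path Path to the CSV file.
#' @param name Attribute identifier for the descriptor; defaults to the file
#'   name without extension.
#' @param ordered Logical; mark the variable as ordinal.
#' @param level `"person"` or `"household"`.
#' @return A [target_descriptor()].
#' @export
read_descriptor <- function(path, name = NULL,
                            ordered = FALSE, level = c("person", "household")) {
  level <- match.arg(level)
  if (!file.exists(path)) {
    hh_abort(sprintf("descriptor file not found: %s", path), "hhsynth_io_error")
  }
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", strip.white = TRUE,
                         colClasses = "character")
  if (ncol(raw) != 2L) {
    hh_abort(sprintf("%s: expected exactly two columns, found %d", path, ncol(raw)),
             "hhsynth_parse_error")
  }
  # header autodetect: drop the first row when its second field is not numeric
  first_num <- suppressWarnings(as.numeric(raw[1, 2]))
  if (is.na(first_num)) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) {
    hh_abort(sprintf("%s: no data rows", path), "hhsynth_parse_error")
  }
  cats <- trimws2(raw[[1]])
  shares <- suppressWarnings(as.numeric(raw[[2]]))
  for (i in seq_along(shares)) {
    if (is.na(shares[i])) {
      hh_abort(sprintf("%s row %d ('%s'): share '%s' is not a number",
                       path, i, cats[i], raw[i, 2]), "hhsynth_parse_error")
    }
    if (shares[i] < 0) {
      hh_abort(sprintf("%s row %d ('%s'): negative share %s",
                       path, i, cats[i], shares[i]), "hhsynth_parse_error")
    }
  }
  if (anyDuplicated(cats)) {
    dup <- cats[duplicated(cats)][1]
    hh_abort(sprintf("%s row %d: duplicate category '%s'",
                     path, which(cats == dup)[2], dup), "hhsynth_parse_error")
  }
  total <- sum(shares)
  if (total <= 0) {
    hh_abort(sprintf("%s: shares are all zero", path), "hhsynth_parse_error")
  }
  # percent-vs-proportion autodetect
  if (total >= 90 && total <= 110) {
    shares <- shares / 100
  } else if (total < 0.9 || total > 1.1) {
    hh_abort(sprintf(
      "%s: shares sum to %g; expected ~100 (percentages) or ~1 (proportions)",
      path, total), "hhsynth_parse_error")
  }
  target_descriptor(name, cats, shares, ordered = ordered, level = level)
}

#' Write a descriptor back to the two-column CSV dialect
#'
#' @param x A target or empirical descriptor.
#' @param path Output file path.
#' @param percent Write shares as percentages (the input convention) rather
#'   than proportions.
#' @return `path`, invisibly.
#' @export
write_descriptor <- function(x, path, percent = TRUE) {
  stopifnot(inherits(x, "target_descriptor"))
  shares <- if (percent) x$shares * 100 else x$shares
  df <- data.frame(category = x$categories,
                   share = format(shares, digits = 15, trim = TRUE, scientific = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Tally the empirical distribution of a population against a descriptor
#'
#' Counts the population's units (persons or households, per the descriptor's
#' level) into the descriptor's categories. A unit that maps to no category is
#' a consistency error: schema validation upstream is supposed to make this
#' impossible, so it is reported loudly rather than binned silently.
#'
#' @param population A [population()] object.
#' @param spec The [target_descriptor()] defining categories and level.
#' @param bander Function mapping a unit (a person's attribute list, or a
#'   household) to exactly one category label of `spec`. Defaults to
#'   [default_bander()] for the conventional descriptor names.
#' @param scheme Classification scheme passed to the default bander for
#'   household-composition descriptors.
#' @return An object of classes `empirical_descriptor` and
#'   `target_descriptor`, with `counts` and `total` fields. When the
#'   population is empty all counts are 0 and shares are all zero.
#' @export
empirical_descriptor <- function(population, spec, bander = NULL,
                                 scheme = classification_scheme("GLOBAL")) {
  stopifnot(inherits(spec, "target_descriptor"))
  bander <- bander %||% default_bander(spec, scheme = scheme)
  counts <- stats::setNames(integer(length(spec$categories)), spec$categories)
  units <- if (spec$level == "household") {
    population$households
  } else {
    unlist(lapply(population$households, function(h) h$members), recursive = FALSE)
  }
  for (u in units) {
    cat_lab <- bander(u)
    if (is.null(cat_lab) || is.na(cat_lab) || !cat_lab %in% spec$categories) {
      hh_abort(sprintf(
        "unit maps to no category of descriptor '%s' (got %s)",
        spec$name, if (is.null(cat_lab) || is.na(cat_lab)) "nothing" else paste0("'", cat_lab, "'")),
        "hhsynth_consistency_error")
    }
    counts[cat_lab] <- counts[cat_lab] + 1L
  }
  empirical_from_counts(spec, counts)
}

# Build an empirical descriptor from an already-computed tally (used by the
# generation loop, which maintains counts incrementally).
empirical_from_counts <- function(spec, counts) {
  counts <- as.integer(counts[spec$categories])
  counts[is.na(counts)] <- 0L
  total <- sum(counts)
  shares <- if (total > 0) counts / total else rep(0, length(counts))
  structure(
    list(name = spec$name, categories = spec$categories, shares = shares,
         ordered = spec$ordered, level = spec$level,
         counts = counts, total = total),
    class = c("empirical_descriptor", "target_descriptor")
  )
}

#' Align a target and an empirical descriptor onto a common category axis
#'
#' Returns paired share vectors over the union of the two category lists,
#' zero-filling categories missing from either side. For ordered descriptors
#' the target's order is canonical and the empirical categories must not
#' contradict it.
#'
#' @param target A [target_descriptor()].
#' @param empirical A second descriptor (usually an `empirical_descriptor`)
#'   with the same name.
#' @return A list with `categories`, `target` and `empirical` share vectors of
#'   equal length.
#' @export
align_descriptors <- function(target, empirical) {
  if (!identical(target$name, empirical$name)) {
    hh_abort(sprintf("cannot align descriptors '%s' and '%s'",
                     target$name, empirical$name), "hhsynth_align_error")
  }
  shared <- intersect(target$categories, empirical$categories)
  if (length(shared) > 1L && (target$ordered || empirical$ordered)) {
    o1 <- match(shared, target$categories)
    o2 <- match(shared, empirical$categories)
    if (!identical(order(o1), order(o2))) {
      hh_abort(sprintf("descriptor '%s': conflicting orderings of shared categories",
                       target$name), "hhsynth_align_error")
    }
  }
  cats <- union(target$categories, empirical$categories)
  p <- stats::setNames(rep(0, length(cats)), cats)
  q <- p
  p[target$categories] <- target$shares
  q[empirical$categories] <- empirical$shares
  list(categories = cats, target = unname(p), empirical = unname(q))
}

#' Bundle descriptors into a named set
#'
#' @param ... Target descriptors (or a single list of them).
#' @param weights Optional per-descriptor weights for combined-discrepancy
#'   summaries; default equal weights.
#' @return An object of class `descriptor_set`; elements are keyed by
#'   descriptor name.
#' @export
descriptor_set <- function(..., weights = NULL) {
  descs <- list(...)
  if (length(descs) == 1L && !inherits(descs[[1]], "target_descriptor")) {
    descs <- descs[[1]]
  }
  for (d in descs) {
    if (!inherits(d, "target_descriptor")) {
      hh_abort("descriptor_set elements must be target descriptors",
               "hhsynth_descriptor_error")
    }
  }
  nms <- vapply(descs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    hh_abort(sprintf("duplicate descriptor name '%s'", nms[duplicated(nms)][1]),
             "hhsynth_descriptor_error")
  }
  names(descs) <- nms
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(descs)), nms)
  } else {
    if (is.null(names(weights))) names(weights) <- nms
    weights <- weights[nms]
  }
  structure(list(descriptors = descs, weights = weights), class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d descriptors: %s\n",
              length(x$descriptors), paste(names(x$descriptors), collapse = ", ")))
  invisible(x)
}

#' Default category assignment for the conventional descriptors
#'
#' Builds the unit-to-category mapping used when tallying a population against
#' a descriptor: ordered person-level descriptors are treated as integer age
#' bands, unordered person-level descriptors as direct attribute lookups by
#' descriptor name, ordered household-level descriptors as household-size bins,
#' and unordered household-level descriptors as derived household composition
#' under the given classification scheme.
#'
#' @param spec A [target_descriptor()].
#' @param scheme A [classification_scheme()] used for composition descriptors.
#' @return A function mapping one unit to a category label.
#' @export
default_bander <- function(spec, scheme = classification_scheme("GLOBAL")) {
  if (spec$level == "person") {
    if (spec$ordered) {
      bins <- parse_bins(spec$categories)
      function(p) bin_assign(p$age, bins)
    } else {
      attr_name <- spec$name
      function(p) {
        v <- p[[attr_name]]
        if (is.null(v)) NA_character_ else trimws2(v)
      }
    }
  } else {
    if (spec$ordered) {
      bins <- parse_bins(spec$categories)
      function(h) bin_assign(length(h$members), bins)
    } else {
      function(h) derive_household_type(h, scheme)
    }
  }
}
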