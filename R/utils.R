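#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so callers/tests can distinguish error families.
hh_abort <- function(message, class) {
  stop(structure(
    class = c(class, "hhsynth_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

trimws2 <- function(x) trimws(as.character(x))

# --- seeded RNG streams ------------------------------------------------------
#
# Backends and samplers carry their own RNG state so that a run is a pure
# function of its seed, regardless of what the caller does with the global
# stream in between.

make_rng <- function(seed) {
  stopifnot(is_scalar_number(seed))
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  env
}

with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# sample() without the length-1 surprise
sample_one <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = prob)]
}

# --- bin-label parsing -------------------------------------------------------
#
# Ordered descriptors (age bands, household sizes) use labels of exactly three
# forms: "k" (a single value), "a-b" (a closed range), and "k+" (open-ended).

#' Parse ordinal bin labels
#'
#' Interprets category labels of an ordered descriptor as integer bins.
#' Accepted forms are `"k"` (single value), `"a-b"` (closed range) and
#' `"k+"` (open-ended top bin).
#'
#' @param labels Character vector of bin labels.
#' @return A data frame with columns `label`, `lo`, `hi` (`hi` is `Inf` for
#'   open-ended bins).
#' @examples
#' parse_bins(c("1", "2-3", "4-5", "6+"))
#' @export
parse_bins <- function(labels) {
  labels <- trimws2(labels)
  lo <- hi <- numeric(length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (grepl("^[0-9]+$", lab)) {
      lo[i] <- hi[i] <- as.numeric(lab)
    } else if (grepl("^[0-9]+-[0-9]+$", lab)) {
      parts <- as.numeric(strsplit(lab, "-", fixed = TRUE)[[1]])
      lo[i] <- parts[1]
      hi[i] <- parts[2]
      if (hi[i] < lo[i]) {
        hh_abort(sprintf("bin label '%s': upper bound below lower bound", lab),
                 "hhsynth_bin_error")
      }
    } else if (grepl("^[0-9]+\\+$", lab)) {
      lo[i] <- as.numeric(sub("\\+$", "", lab))
      hi[i] <- Inf
    } else {
      hh_abort(sprintf("bin label '%s' is not of the form 'k', 'a-b' or 'k+'", lab),
               "hhsynth_bin_error")
    }
  }
  data.frame(label = labels, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

# Assign a value to its unique covering bin; NA_character_ when uncovered.
bin_assign <- function(value, bins) {
  hit <- which(value >= bins$lo & value <= bins$hi)
  if (length(hit) != 1L) {
    if (length(hit) == 0L) return(NA_character_)
    hh_abort(sprintf("value %s falls in %d overlapping bins", value, length(hit)),
             "hhsynth_bin_error")
  }
  bins$label[hit]
}
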