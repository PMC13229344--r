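# The outer synthesis loop: request batches, validate, feed diagnostics back,
# accumulate accepted households, and keep per-batch trace records.

classify_failures <- function(vr) {
  if (any(startsWith(vr$failures$check, "schema:"))) "schema" else "rule"
}

#' Generate a synthetic population with a feedback-driven loop
#'
#' Repeats until the target number of households is reached: compute the
#' empirical descriptors of the population so far, build a prompt containing
#' targets, schema and (when feedback is enabled) the current distributions,
#' query the backend for a batch of candidate households, parse and validate
#' them, and re-request each invalid household with its diagnostics up to the
#' retry limit. Accepted households are appended immediately; slots whose
#' retries are exhausted are counted as failed, so the loop always terminates
#' with `accepted + failed` equal to the requested total.
#'
#' Error accounting: each failed attempt is recorded once, classified as
#' `parse` (malformed response), `schema` (wrong structure or out-of-domain
#' attributes), `rule` (structural-rule violation) or `api` (backend error).
#'
#' @param cfg A [generation_config()].
#' @param targets A [descriptor_set()].
#' @param schema A [population_schema()].
#' @param rules A [rule_set()].
#' @param backend A `generator_backend`.
#' @param scheme [classification_scheme()] used for composition tallies.
#' @return A list with `population` (all accepted households, provenance
#'   attached) and `trace` (a `generation_trace`: per-batch snapshots, error
#'   counts by class, retries, success rate).
#' @export
generate_population <- function(cfg, targets, schema, rules = default_rules(),
                                backend, scheme = classification_scheme("GLOBAL")) {
  stopifnot(inherits(cfg, "generation_config"),
            inherits(targets, "descriptor_set"),
            inherits(backend, "generator_backend"))
  if (length(targets$descriptors) == 0L) {
    hh_abort("at least one target descriptor is required", "hhsynth_config_error")
  }
  N <- cfg$target_households
  RL <- cfg$retry_limit
  banders <- lapply(targets$descriptors, default_bander, scheme = scheme)
  tallies <- lapply(targets$descriptors, function(d) {
    stats::setNames(integer(length(d$categories)), d$categories)
  })
  accepted <- vector("list", N)
  n_accepted <- 0L
  n_failed <- 0L
  persons_cum <- 0L
  err_total <- c(parse = 0L, schema = 0L, rule = 0L, api = 0L)
  batches <- list()
  slots_done <- 0L
  batch_no <- 0L

  tally_household <- function(h) {
    for (nm in names(targets$descriptors)) {
      d <- targets$descriptors[[nm]]
      if (d$level == "household") {
        lab <- banders[[nm]](h)
        if (lab %in% names(tallies[[nm]])) {
          tallies[[nm]][lab] <<- tallies[[nm]][lab] + 1L
        }
      } else {
        for (m in h$members) {
          lab <- banders[[nm]](m)
          if (!is.null(lab) && !is.na(lab) && lab %in% names(tallies[[nm]])) {
            tallies[[nm]][lab] <<- tallies[[nm]][lab] + 1L
          }
        }
      }
    }
  }
  snapshot <- function() {
    out <- list()
    for (nm in names(targets$descriptors)) {
      tot <- sum(tallies[[nm]])
      out[[nm]] <- if (tot > 0) unname(tallies[[nm]] / tot) else rep(0, length(tallies[[nm]]))
    }
    out
  }
  current_descriptors <- function() {
    mapply(empirical_from_counts, targets$descriptors, tallies, SIMPLIFY = FALSE)
  }

  while (slots_done < N) {
    b <- min(cfg$batch_size, N - slots_done)
    batch_no <- batch_no + 1L
    batch_err <- c(parse = 0L, schema = 0L, rule = 0L, api = 0L)
    retries_used <- 0L
    base_prompt <- build_prompt(targets, current_descriptors(), schema, b,
                                feedback = cfg$feedback_enabled)

    # obtain a structurally valid batch (batch-level retries)
    batch_attempts <- 0L
    hhs <- NULL
    prompt_now <- base_prompt
    last_raw <- NULL
    repeat {
      batch_attempts <- batch_attempts + 1L
      raw <- tryCatch(backend$generate(prompt_now), error = function(e) e)
      if (inherits(raw, "error")) {
        batch_err["api"] <- batch_err["api"] + 1L
        diag <- conditionMessage(raw)
        last_raw <- NULL
      } else {
        pr <- parse_households(raw, b, schema)
        if (pr$ok) {
          hhs <- pr$households
          break
        }
        cls <- if (pr$class == "parse") "parse" else "schema"
        batch_err[cls] <- batch_err[cls] + 1L
        diag <- pr$message
        last_raw <- raw
      }
      if (batch_attempts >= RL) break
      retries_used <- retries_used + 1L
      prompt_now <- retry_prompt(base_prompt, last_raw, diag, b)
    }

    batch_accepted <- 0L
    if (is.null(hhs)) {
      n_failed <- n_failed + b
    } else {
      for (h in hhs) {
        slot_attempts <- batch_attempts
        cur_h <- h
        fail_cls <- NULL
        diag <- NULL
        ok <- FALSE
        repeat {
          if (!is.null(cur_h)) {
            vr <- validate_household(cur_h, schema, rules)
            if (vr$valid) {
              ok <- TRUE
              break
            }
            fail_cls <- classify_failures(vr)
            diag <- paste(vr$failures$message, collapse = "; ")
          }
          batch_err[fail_cls] <- batch_err[fail_cls] + 1L
          if (slot_attempts >= RL) break
          slot_attempts <- slot_attempts + 1L
          retries_used <- retries_used + 1L
          cprompt <- retry_prompt(
            build_prompt(targets, current_descriptors(), schema, 1L,
                         feedback = cfg$feedback_enabled),
            if (!is.null(cur_h)) format_households_response(list(cur_h)) else NULL,
            diag, 1L)
          raw2 <- tryCatch(backend$generate(cprompt), error = function(e) e)
          if (inherits(raw2, "error")) {
            cur_h <- NULL
            fail_cls <- "api"
            diag <- conditionMessage(raw2)
            next
          }
          pr2 <- parse_households(raw2, 1L, schema)
          if (!pr2$ok) {
            cur_h <- NULL
            fail_cls <- if (pr2$class == "parse") "parse" else "schema"
            diag <- pr2$message
            next
          }
          cur_h <- pr2$households[[1]]
        }
        if (ok) {
          n_accepted <- n_accepted + 1L
          cur_h$id <- sprintf("h%06d", n_accepted)
          accepted[[n_accepted]] <- cur_h
          persons_cum <- persons_cum + length(cur_h$members)
          batch_accepted <- batch_accepted + 1L
          tally_household(cur_h)
        } else {
          n_failed <- n_failed + 1L
        }
      }
    }
    err_total <- err_total + batch_err
    batches[[batch_no]] <- list(
      batch = batch_no, requested = b, accepted = batch_accepted,
      failed = b - batch_accepted,
      households_cum = n_accepted, persons_cum = persons_cum,
      errors = batch_err, retries = retries_used,
      snapshot = snapshot())
    slots_done <- slots_done + b
  }

  pop <- population(accepted[seq_len(n_accepted)],
                    provenance = list(seed = cfg$seed, backend = backend$name,
                                      batch_size = cfg$batch_size,
                                      feedback = cfg$feedback_enabled,
                                      requested = N))
  trace <- structure(
    list(batches = batches,
         attempted = N, accepted = n_accepted, failed = n_failed,
         error_counts = err_total,
         success_rate = if (N > 0) 100 * n_accepted / N else NA_real_),
    class = "generation_trace")
  list(population = pop, trace = trace)
}

#' @export
print.generation_trace <- function(x, ...) {
  cat(sprintf("<generation_trace> %d/%d households accepted (%.1f%%), %d batches\n",
              x$accepted, x$attempted, x$success_rate, length(x$batches)))
  cat("errors:", paste(names(x$error_counts), x$error_counts,
                       sep = "=", collapse = " "), "\n")
  invisible(x)
}
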