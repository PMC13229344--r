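# The iterative feedback-driven generation loop: build a prompt from targets
# and the current empirical distributions, query a pluggable backend, parse,
# validate, retry with diagnostics, and accumulate until N households.

#' Generation configuration
#'
#' @param target_households Number of households to generate (N).
#' @param batch_size Households requested per backend call (default 10).
#' @param retry_limit Maximum total attempts per household slot (default 3).
#' @param seed Integer seed recorded in provenance; backends carry their own
#'   seeded streams.
#' @param feedback_enabled When `FALSE` the prompt omits the
#'   current-distribution block, reproducing the no-feedback ablation.
#' @param weights Optional per-descriptor weights (recorded, used by combined
#'   summaries).
#' @param epsilon Deficit floor for deficit-proportional samplers.
#' @return A list of class `generation_config`.
#' @export
generation_config <- function(target_households, batch_size = 10, retry_limit = 3,
                              seed = 1, feedback_enabled = TRUE, weights = NULL,
                              epsilon = 1e-6) {
  if (target_households < 1 || batch_size < 1 || batch_size > target_households) {
    hh_abort("need N >= 1 and 1 <= batch_size <= N", "hhsynth_config_error")
  }
  if (retry_limit < 1 || epsilon <= 0) {
    hh_abort("retry_limit must be >= 1 and epsilon > 0", "hhsynth_config_error")
  }
  structure(list(target_households = as.integer(target_households),
                 batch_size = as.integer(batch_size),
                 retry_limit = as.integer(retry_limit),
                 seed = as.integer(seed),
                 feedback_enabled = isTRUE(feedback_enabled),
                 weights = weights, epsilon = epsilon),
            class = "generation_config")
}

# --- prompt construction -----------------------------------------------------

csv_quote <- function(x) paste0('"', gsub('"', '""', x), '"')

format_descriptor_block <- function(d, total = NULL) {
  head <- sprintf("## descriptor name=%s level=%s ordered=%s%s",
                  d$name, d$level, tolower(as.character(d$ordered)),
                  if (!is.null(total)) sprintf(" units=%d", as.integer(total)) else "")
  c(head, "category,share",
    sprintf("%s,%.15g", csv_quote(d$categories), d$shares))
}

#' Build the generation prompt
#'
#' Assembles, in order: task instructions (including the required JSON output
#' structure and the batch size), a schema excerpt, the target distributions
#' tabulated per descriptor, and — unless feedback is disabled — the current
#' synthetic distributions tabulated identically.
#'
#' @param targets A [descriptor_set()].
#' @param current Named list of `empirical_descriptor`s computed from the
#'   population so far (all-zero at the start); ignored when
#'   `feedback = FALSE`.
#' @param schema A [population_schema()].
#' @param B Number of households requested.
#' @param feedback Include the current-distribution block?
#' @return A single prompt string.
#' @export
build_prompt <- function(targets, current, schema, B, feedback = TRUE) {
  schema_json <- jsonlite::toJSON(
    list(attributes = unname(schema$attributes),
         relationships = schema$relationships),
    auto_unbox = TRUE, digits = NA)
  lines <- c(
    "# TASK",
    sprintf(paste0(
      "Generate exactly %d household(s) for a synthetic population. ",
      "Respond with a single JSON object of the form ",
      '{"households": [{"members": [{"age": <integer>, "gender": "<label>", ',
      '"relationship": "<role>"}, ...]}, ...]} and nothing else. ',
      "List the head first in each household. Every household must contain ",
      "exactly one head, no minor may live alone, and parents must be older ",
      "than their children. Match the target distributions below; where ",
      "current distributions are shown, compensate for their deviation from ",
      "the targets."), B),
    sprintf("households-requested: %d", B),
    "",
    "# SCHEMA",
    as.character(schema_json),
    "",
    "# TARGET DISTRIBUTIONS",
    unlist(lapply(targets$descriptors, format_descriptor_block), use.names = FALSE)
  )
  if (feedback) {
    cur_lines <- unlist(lapply(current, function(d) {
      format_descriptor_block(d, total = d$total %||% 0L)
    }), use.names = FALSE)
    lines <- c(lines, "", "# CURRENT DISTRIBUTIONS", cur_lines)
  }
  paste(lines, collapse = "\n")
}

# Parse a prompt back into its components (used by the reference sampler,
# which sees only the prompt text, exactly as an external model would).
parse_prompt <- function(prompt) {
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  stop_at <- which(lines == "# PREVIOUS RESPONSE (REJECTED)")
  if (length(stop_at)) lines <- lines[seq_len(stop_at[1] - 1L)]
  b_line <- grep("^households-requested: ", lines, value = TRUE)
  B <- if (length(b_line)) as.integer(sub("^households-requested: ", "", b_line[1])) else 1L

  section <- function(name) {
    i <- which(lines == paste0("# ", name))
    if (!length(i)) return(NULL)
    j <- grep("^# ", lines)
    j <- j[j > i[1]]
    end <- if (length(j)) j[1] - 1L else length(lines)
    lines[(i[1] + 1L):end]
  }
  parse_blocks <- function(block_lines) {
    if (is.null(block_lines)) return(NULL)
    starts <- grep("^## descriptor ", block_lines)
    out <- list()
    for (k in seq_along(starts)) {
      end <- if (k < length(starts)) starts[k + 1] - 1L else length(block_lines)
      chunk <- block_lines[starts[k]:end]
      head <- chunk[1]
      get_attr <- function(key) {
        m <- regmatches(head, regexec(paste0(key, "=([^ ]+)"), head))[[1]]
        if (length(m) < 2) NA_character_ else m[2]
      }
      body <- chunk[-1]
      body <- body[nzchar(trimws(body))]
      df <- utils::read.csv(text = paste(body, collapse = "\n"),
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c("character", "numeric"))
      d <- list(name = get_attr("name"),
                level = get_attr("level"),
                ordered = identical(get_attr("ordered"), "true"),
                categories = trimws2(df$category),
                shares = df$share,
                total = if (!is.na(get_attr("units"))) as.integer(get_attr("units")) else NULL)
      out[[d$name]] <- d
    }
    out
  }
  schema_lines <- section("SCHEMA")
  schema <- if (!is.null(schema_lines)) {
    jsonlite::fromJSON(paste(schema_lines, collapse = "\n"), simplifyVector = FALSE)
  }
  list(B = B, schema = schema,
       targets = parse_blocks(section("TARGET DISTRIBUTIONS")),
       current = parse_blocks(section("CURRENT DISTRIBUTIONS")))
}

retry_prompt <- function(base_prompt, raw, diagnostics, B) {
  paste0(base_prompt,
         "\n# PREVIOUS RESPONSE (REJECTED)\n", raw %||% "(no response: backend error)",
         "\n# ERRORS\n", diagnostics,
         sprintf("\nReturn a corrected JSON object with exactly %d household(s).", B))
}

# --- response parsing --------------------------------------------------------

#' Parse a backend response into households
#'
#' Distinguishes parse/format failures (malformed JSON) from structure
#' failures (valid JSON of the wrong shape, field set, or household count).
#' Failures are returned as data, not thrown.
#'
#' @param raw Raw response text.
#' @param B Expected number of households.
#' @param schema A [population_schema()] (names the required member fields).
#' @return A list: `ok = TRUE` with `households`, or `ok = FALSE` with
#'   `class` (`"parse"` or `"structure"`) and a diagnostic `message`.
#' @export
parse_households <- function(raw, B, schema) {
  fail <- function(class, message) list(ok = FALSE, class = class, message = message)
  if (!is.character(raw) || length(raw) != 1L) {
    return(fail("parse", "response is not a single text string"))
  }
  obj <- tryCatch(jsonlite::fromJSON(raw, simplifyVector = FALSE),
                  error = function(e) e)
  if (inherits(obj, "error")) {
    return(fail("parse", paste0("malformed JSON: ", conditionMessage(obj))))
  }
  if (!is.list(obj) || is.null(obj$households) || !is.list(obj$households)) {
    return(fail("structure", 'top-level object must contain a "households" array'))
  }
  hhs <- obj$households
  if (length(hhs) != B) {
    return(fail("structure",
                sprintf("expected exactly %d household(s), got %d", B, length(hhs))))
  }
  person_attrs <- vapply(
    Filter(function(a) identical(a$level %||% "person", "person"), schema$attributes),
    `[[`, character(1), "name")
  out <- vector("list", length(hhs))
  for (i in seq_along(hhs)) {
    h <- hhs[[i]]
    if (!is.list(h) || is.null(h$members) || !is.list(h$members) ||
        length(h$members) == 0L) {
      return(fail("structure",
                  sprintf('household %d must contain a non-empty "members" array', i)))
    }
    members <- h$members
    for (j in seq_along(members)) {
      m <- members[[j]]
      if (!is.list(m) || is.null(names(m))) {
        return(fail("structure",
                    sprintf("household %d member %d is not an attribute map", i, j)))
      }
      missing <- setdiff(person_attrs, names(m))
      if (length(missing)) {
        return(fail("structure",
                    sprintf("household %d member %d: missing field(s) %s",
                            i, j, paste(missing, collapse = ", "))))
      }
      if (is.numeric(m$age)) members[[j]]$age <- as.integer(m$age)
    }
    out[[i]] <- household(members, id = sprintf("pending%03d", i))
  }
  list(ok = TRUE, households = out)
}

# Serialise households into the response dialect (used by scripted backends
# and corrective prompts).
#' Format households as a backend response
#'
#' Serialises households into the JSON dialect that [parse_households()]
#' expects — useful for scripted backends in tests.
#'
#' @param households List of [household()] objects.
#' @return A JSON string with a top-level `households` array.
#' @export
format_households_response <- function(households) {
  as.character(jsonlite::toJSON(
    list(households = lapply(households, function(h) list(members = h$members))),
    auto_unbox = TRUE, digits = NA))
}

# --- backends ----------------------------------------------------------------

new_backend <- function(name, generate, deterministic) {
  structure(list(name = name, generate = generate, deterministic = deterministic),
            class = "generator_backend")
}

#' @export
print.generator_backend <- function(x, ...) {
  cat(sprintf("<generator_backend> %s (%s)\n", x$name,
              if (x$deterministic) "deterministic" else "stochastic"))
  invisible(x)
}

#' Scripted backend for testing and fault injection
#'
#' Replays a fixed sequence of responses. Each element is either a response
#' string or a function of the prompt returning one (or stopping, to emulate
#' an infrastructure failure).
#'
#' @param responses List of character responses and/or functions.
#' @param recycle When the script is exhausted, start again from the last
#'   element (`TRUE`) or raise an error (`FALSE`).
#' @return A `generator_backend`.
#' @export
scripted_backend <- function(responses, recycle = TRUE) {
  if (!is.list(responses)) responses <- list(responses)
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  gen <- function(prompt) {
    env$i <- env$i + 1L
    idx <- if (env$i <= length(responses)) {
      env$i
    } else if (recycle) {
      length(responses)
    } else {
      stop("scripted backend exhausted")
    }
    r <- responses[[idx]]
    if (is.function(r)) r(prompt) else r
  }
  new_backend("scripted", gen, deterministic = TRUE)
}

#' Adapter for a remote text-generation service
#'
#' Wraps a user-supplied transport function (e.g. an HTTP client closure)
#' behind the backend contract. Transport failures surface as errors, which
#' the generation loop records as API-class failures; reported token usage is
#' accumulated on the backend.
#'
#' @param transport Function `(prompt, config)` returning either the raw
#'   response text or a list with `text` and optional `tokens`.
#' @param name Backend name recorded in provenance.
#' @param config Passed through to the transport (endpoint, model,
#'   temperature, top_p, ...); credentials should come from environment
#'   variables, not this list.
#' @return A `generator_backend` with a `usage` environment tracking token
#'   counts.
#' @export
llm_backend <- function(transport, name = "llm", config = list()) {
  usage <- new.env(parent = emptyenv())
  usage$tokens <- 0
  usage$calls <- 0L
  gen <- function(prompt) {
    res <- transport(prompt, config)
    usage$calls <- usage$calls + 1L
    if (is.list(res)) {
      if (!is.null(res$tokens)) usage$tokens <- usage$tokens + res$tokens
      res <- res$text
    }
    if (!is.character(res) || length(res) != 1L) {
      stop("transport returned no response text")
    }
    res
  }
  b <- new_backend(name, gen, deterministic = FALSE)
  b$usage <- usage
  b$config <- config
  b
}
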