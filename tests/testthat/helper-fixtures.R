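# Shared fixtures, built in code at test time.

hh <- function(..., id = NULL) household(list(...), id = id)

# One household per row of the composition mapping table, in priority order.
mapping_fixtures <- function() {
  list(
    head_young   = hh(person(40, "male", "head")),
    head_old     = hh(person(70, "female", "head")),
    couple       = hh(person(40, "male", "head"), person(38, "female", "partner")),
    lone_parent  = hh(person(40, "female", "head"), person(10, "male", "child")),
    couple_dep   = hh(person(45, "male", "head"), person(44, "female", "partner"),
                      person(17, "female", "child"), person(20, "male", "child")),
    couple_nondep = hh(person(55, "male", "head"), person(54, "female", "partner"),
                       person(25, "female", "child")),
    relatives    = hh(person(40, "male", "head"), person(70, "female", "grandparent")),
    housemates   = hh(person(30, "male", "head"), person(29, "male", "housemate")),
    catch_all    = hh(person(45, "male", "head"), person(44, "female", "partner"),
                      person(12, "male", "child"), person(30, "female", "housemate"))
  )
}

# Latent fixture shared across tests (cheap enough to build once per run).
latent_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_latent_population(latent_population_spec(seed = 42))
    }
    cache
  }
})

fixture_targets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- marginals_from_population(latent_fixture())
    cache
  }
})

# A canned valid single-household response for scripted backends.
valid_response_1 <- function() {
  format_households_response(list(hh(person(40, "male", "head"))))
}

# Independent brute-force metric oracles: written as explicit element-wise
# loops, deliberately sharing no code with the package implementations.
oracle_srmse <- function(p, q) {
  acc <- 0
  for (i in seq_along(p)) acc <- acc + (p[i] - q[i]) * (p[i] - q[i])
  rmse <- sqrt(acc / length(p))
  rmse / (1 / length(p))
}
oracle_jsd <- function(p, q) {
  acc <- 0
  for (i in seq_along(p)) {
    m <- (p[i] + q[i]) / 2
    if (p[i] > 0) acc <- acc + 0.5 * p[i] * (log(p[i] / m) / log(2))
    if (q[i] > 0) acc <- acc + 0.5 * q[i] * (log(q[i] / m) / log(2))
  }
  acc
}
oracle_w1 <- function(p, q) {
  fp <- 0; fq <- 0; acc <- 0
  for (i in seq_along(p)) {
    fp <- fp + p[i]; fq <- fq + q[i]
    acc <- acc + abs(fp - fq)
  }
  acc
}

random_share_pair <- function(n) {
  p <- stats::rexp(n); q <- stats::rexp(n)
  # occasionally zero out entries to exercise empty-support terms
  p[stats::runif(n) < 0.2] <- 0
  q[stats::runif(n) < 0.2] <- 0
  if (sum(p) == 0) p[1] <- 1
  if (sum(q) == 0) q[1] <- 1
  list(p = p / sum(p), q = q / sum(q))
}
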