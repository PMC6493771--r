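# Shared in-code fixtures: tiny hand-built models with known answers, the
# default fixture matrix for the enumeration oracle, and a sampling oracle
# for the reaction-level tail statistics.

# R1: -> A ; R2/R3: parallel A -> B.  Minimal networks for B: {R1, R2} and
# {R1, R3}; the shared source R1 is the only high-frequency reaction.
toy_parallel_model <- function() {
  minea_model(
    "toy_parallel",
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(id = c("R1", "R2", "R3"), lb = 0, ub = 1000,
                           subsystem = c("source", "conv", "conv")),
    stoich = data.frame(
      metabolite = c("A", "A", "B", "A", "B"),
      reaction = c("R1", "R2", "R2", "R3", "R3"),
      coefficient = c(1, -1, 1, -1, 1)),
    gprs = list(R1 = parse_gpr("g1"), R2 = parse_gpr("g2 and g3"),
                R3 = parse_gpr("g4")))
}

# linear chain -> A -> B -> C with a reversible middle step
toy_chain_model <- function(rev_mid = FALSE) {
  minea_model(
    "toy_chain",
    metabolites = data.frame(id = c("A", "B", "C"), compartment = "c"),
    reactions = data.frame(id = c("R1", "R2", "R3"),
                           lb = c(0, if (rev_mid) -1000 else 0, 0),
                           ub = c(100, 1000, 1000),
                           subsystem = c("s1", "s1", "s2")),
    stoich = data.frame(
      metabolite = c("A", "A", "B", "B", "C"),
      reaction = c("R1", "R2", "R2", "R3", "R3"),
      coefficient = c(1, -1, 1, -1, 1)),
    gprs = list(R2 = parse_gpr("g1 or (g1 and g2)")))
}

extdata_path <- function(name) {
  path <- system.file("extdata", name, package = "minea")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}

# default fixture matrix: 20 specs, all well under the oracle's size cap
fixture_specs <- function() {
  base <- list(
    list(b = c(2L), L = 1L, d = 0L, cof = integer(0)),
    list(b = c(3L), L = 1L, d = 2L, cof = integer(0)),
    list(b = c(2L, 2L), L = 1L, d = 1L, cof = integer(0)),
    list(b = c(2L, 3L), L = 1L, d = 2L, cof = integer(0)),
    list(b = c(2L, 2L), L = 2L, d = 1L, cof = 1L),
    list(b = c(3L, 2L), L = 1L, d = 3L, cof = 2L),
    list(b = c(4L), L = 2L, d = 2L, cof = 1L),
    list(b = c(2L, 2L, 2L), L = 1L, d = 2L, cof = integer(0)),
    list(b = integer(0), L = 2L, d = 1L, cof = integer(0)),
    list(b = c(1L, 3L), L = 2L, d = 2L, cof = integer(0)))
  c(base, base)  # seeds differ across the two halves
}

enumerate_fixture <- function(spec, seed) {
  fx <- make_parallel_gem(spec$b, spec$L, spec$d,
                          cofactor_stages = spec$cof, seed = seed)
  prep <- prepare_task(split_reversible(fx$model), fx$task)
  aset <- enumerate_alternatives(prep$model, prep$task)
  list(fixture = fx, prep = prep, altset = aset,
       active_sets = lapply(aset$networks, function(n) n$active_reactions))
}

# sampling oracle for the joint reaction-regulation tail: draw T reactions
# without replacement and count "at least T_a of category a and at most T_b
# of category b" events
mc_tail_frequency <- function(census, min_census, mode, n_draws = 1e5) {
  R <- census[1]; R_up <- census[2]; R_down <- census[3]; R_no <- census[4]
  T_tot <- min_census[1]
  if (mode == "up") {
    R_a <- R_up; R_b <- R_down; T_a <- min_census[2]; T_b <- min_census[3]
  } else {
    R_a <- R_down; R_b <- R_up; T_a <- min_census[3]; T_b <- min_census[2]
  }
  i <- stats::rhyper(n_draws, R_a, R - R_a, T_tot)
  j <- stats::rhyper(n_draws, R_b, R_no, T_tot - i)
  mean(i >= T_a & j <= T_b)
}

# random valid (model census, network census) pair for the tail statistics
random_census_pair <- function(R_max = 15) {
  R <- sample(4:R_max, 1)
  splits <- sort(sample(0:R, 2))
  census <- c(R, splits[1], splits[2] - splits[1], R - splits[2])
  T_tot <- sample(1:R, 1)
  states <- sample(rep(c("up", "down", "no"), times = census[2:4]), T_tot)
  min_census <- c(T_tot, sum(states == "up"), sum(states == "down"))
  list(census = census, min_census = min_census)
}
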