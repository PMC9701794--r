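#' Simulation configuration
#'
#' Build and validate the full parameterization of one simulation scenario:
#' a prey population of fixed size under implicit predation with a per-step
#' kill quota, neutral alleles (no mutation, migration or selection), and
#' optional within-lifetime learning that raises an individual's escape
#' probability after surviving attacks.
#'
#' Defaults follow the baseline scenario: 1000 individuals carrying one of
#' 100 neutral alleles, initial escape probability 0.5, escape cap 0.99,
#' 100 time steps, 500 individuals removed per step, accelerating learning
#' applied at the end of each step at rate 0.09 per update.
#'
#' @param population_size Number of prey at the start and end of every step.
#' @param n_initial_alleles Number of distinct allele labels at step 0.
#' @param n_steps Number of time steps to simulate.
#' @param n_removed Predation kill quota per step; identical between learning
#'   and non-learning scenarios so population-level mortality is matched.
#' @param initial_escape Escape probability of every newborn (and of every
#'   individual at initialization).
#' @param escape_cap Upper bound on the escape probability; learning can
#'   never raise an individual past this value.
#' @param learning_enabled Whether survivors of attacks learn at all.
#' @param learning_mode `"accelerating"` (update proportional to the current
#'   value) or `"decelerating"` (proportional to the remaining headroom below
#'   the cap).
#' @param learning_timing `"step_end"` (one update at the end of the step for
#'   any individual that escaped at least one attack, however many) or
#'   `"immediate"` (one update after every escaped attack).
#' @param learning_rate Proportion used by the update rule; must be >= 0.
#' @param reproduction_mode `"haploid_asexual"`, `"haploid_sexual"` or
#'   `"diploid_sexual"`.
#' @param max_age Maximum age in steps; individuals strictly older die at the
#'   start of the step, outside the predation quota. `Inf` disables the cap.
#' @param init_allele_scheme `"uniform_random"` (each allele slot drawn
#'   independently and uniformly from the label set) or `"balanced"` (each
#'   label gets exactly `population_size / n_initial_alleles` copies per
#'   slot; requires divisibility).
#' @param seed Optional integer seed stored with the configuration; when
#'   `NULL`, the seed passed to [run_simulation()] is used.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(population_size = 100, n_initial_alleles = 10,
#'                   n_removed = 50, n_steps = 20)
#' cfg$n_removed
#' @export
sim_config <- function(population_size = 1000L,
                       n_initial_alleles = 100L,
                       n_steps = 100L,
                       n_removed = 500L,
                       initial_escape = 0.5,
                       escape_cap = 0.99,
                       learning_enabled = FALSE,
                       learning_mode = c("accelerating", "decelerating"),
                       learning_timing = c("step_end", "immediate"),
                       learning_rate = 0.09,
                       reproduction_mode = c("haploid_asexual",
                                             "haploid_sexual",
                                             "diploid_sexual"),
                       max_age = Inf,
                       init_allele_scheme = c("uniform_random", "balanced"),
                       seed = NULL) {
  cfg <- list(
    population_size = as.integer(population_size),
    n_initial_alleles = as.integer(n_initial_alleles),
    n_steps = as.integer(n_steps),
    n_removed = as.integer(n_removed),
    initial_escape = as.numeric(initial_escape),
    escape_cap = as.numeric(escape_cap),
    learning_enabled = isTRUE(learning_enabled),
    learning_mode = match.arg(learning_mode),
    learning_timing = match.arg(learning_timing),
    learning_rate = as.numeric(learning_rate),
    reproduction_mode = match.arg(reproduction_mode),
    max_age = if (is.infinite(max_age)) Inf else as.integer(max_age),
    init_allele_scheme = match.arg(init_allele_scheme),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant a runnable scenario must satisfy;
#' called by [sim_config()] and [load_config()].
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly unchanged, or an error naming the offending key.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  sexual <- cfg$reproduction_mode != "haploid_asexual"
  diploid <- cfg$reproduction_mode == "diploid_sexual"
  chk(cfg$population_size >= 1L, "population_size: must be >= 1")
  chk(cfg$n_initial_alleles >= 1L &&
        cfg$n_initial_alleles <= cfg$population_size * (1L + diploid),
      "n_initial_alleles: must be in [1, number of allele slots]")
  chk(cfg$n_steps >= 1L, "n_steps: must be >= 1")
  chk(cfg$n_removed >= 1L, "n_removed: must be >= 1")
  chk(cfg$population_size - cfg$n_removed >= if (sexual) 2L else 1L,
      paste0("n_removed: quota must leave at least ",
             if (sexual) "2 survivors (sexual reproduction)" else
               "1 survivor", "; got n_removed = ", cfg$n_removed,
             " with population_size = ", cfg$population_size))
  chk(cfg$escape_cap > 0 && cfg$escape_cap < 1,
      "escape_cap: must lie strictly in (0, 1) so every attack can kill")
  chk(cfg$initial_escape > 0 && cfg$initial_escape <= cfg$escape_cap,
      "initial_escape: must satisfy 0 < initial_escape <= escape_cap")
  chk(cfg$learning_rate >= 0, "learning_rate: must be >= 0")
  chk(is.infinite(cfg$max_age) || cfg$max_age >= 1L,
      "max_age: must be >= 1 or Inf")
  if (cfg$init_allele_scheme == "balanced")
    chk(cfg$population_size %% cfg$n_initial_alleles == 0L,
        "init_allele_scheme: balanced requires population_size divisible by n_initial_alleles")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-20s %s\n", k, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

config_keys <- function() {
  setdiff(names(formals(sim_config)), "...")
}

#' Read a configuration file
#'
#' Reads a flat key/value YAML or JSON file whose keys are exactly the
#' [sim_config()] argument names. Missing keys resolve to the defaults;
#' unknown keys are an error. `max_age` may be given as the string `"Inf"`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$max_age) && identical(raw$max_age, "Inf"))
    raw$max_age <- Inf
  do.call(sim_config, raw)
}

#' Write a configuration file
#'
#' Serializes a `sim_config` to flat YAML so that
#' `load_config(write_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param cfg A `sim_config`.
#' @param path Output path (`.yaml` recommended).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  if (is.infinite(out$max_age)) out$max_age <- "Inf"
  yaml::write_yaml(out, path)
  invisible(path)
}
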