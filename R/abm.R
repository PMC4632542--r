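#' Integer initial occupancies for the finite-population model
#'
#' Scales the mean-field initial condition by the colony size `N`. Every
#' compartment must come out integer — `N L (1 - z)`, `N L z / 2`,
#' `N H (1 - z)` and `N H z / 2` — so that the stochastic and mean-field
#' models start from exactly the same composition. Non-integer compartments
#' are a configuration error by default; `rounding = "largest_remainder"`
#' opts into explicit apportionment that preserves the class totals.
#'
#' @param params A [nest_params()] object.
#' @param rounding `"none"` (default, error on non-integer compartments) or
#'   `"largest_remainder"`.
#' @return A named integer vector of length nine (class `nest_counts`)
#'   summing to `N`.
#' @examples
#' initial_counts(nest_params(H = 0.2, z = 0.3, N = 100))
#' @export
initial_counts <- function(params, rounding = c("none", "largest_remainder")) {
  stopifnot(inherits(params, "nest_params"))
  rounding <- match.arg(rounding)
  exact <- as_state_vector(initial_state(params)) * params$N
  tol <- 1e-9
  if (rounding == "none") {
    off <- abs(exact - round(exact)) > tol
    if (any(off))
      stop("initial compartment counts are not integers at N = ", params$N,
           ": ", paste0(names(exact)[off], " = ", format(exact[off]),
                        collapse = ", "),
           "; choose H, z, N so every compartment is integer, or use ",
           "rounding = \"largest_remainder\"")
    n <- as.integer(round(exact))
  } else {
    n <- integer(9)
    for (idx in list(low_idx(), high_idx())) {
      target <- round(sum(exact[idx]))
      base <- floor(exact[idx] + tol)
      rem <- exact[idx] - base
      short <- as.integer(target - sum(base))
      give <- integer(length(idx))
      if (short > 0) give[order(rem, decreasing = TRUE)[seq_len(short)]] <- 1L
      n[idx] <- as.integer(base + give)
    }
  }
  names(n) <- count_names()
  class(n) <- "nest_counts"
  n
}

as_count_vector <- function(counts) {
  if (inherits(counts, "nest_counts")) return(unclass(counts))
  n <- as.integer(counts)
  if (length(n) != 9L) stop("occupancy vectors have exactly nine components")
  if (any(n < 0)) stop("occupancy counts must be non-negative")
  names(n) <- count_names()
  n
}

#' The fifteen Poisson event channels
#'
#' One channel per term of the mean-field equations: four mass-action
#' recruitment channels (current-nest ants recruited to the poor site by
#' poor-site recruiters, or to the good site by either kind of good-site
#' recruiter, at per-ant rate recruiters / N), three committed-to-recruiter
#' conversions, the poor-to-good switch of high-threshold visitors, and seven
#' leakage channels returning each away-from-home compartment to the current
#' nest. Each event moves exactly one ant. Per-capita, these rates reproduce
#' [ode_rhs()] in the large-`N` limit.
#'
#' @param counts A nine-component integer occupancy vector.
#' @param params A [nest_params()] object.
#' @return A data frame with one row per channel: `channel` (1--15), `name`,
#'   `from`, `to`, and the current `rate`.
#' @examples
#' ev <- event_rates(initial_counts(nest_preset("baseline")),
#'                   nest_preset("baseline"))
#' sum(ev$rate)
#' @export
event_rates <- function(counts, params) {
  stopifnot(inherits(params, "nest_params"))
  n <- as_count_vector(counts)
  r <- cpp_event_rates(n, params$N, params$alpha_p, params$alpha_g,
                       params$alpha_s, params$alpha_leak)
  cn <- count_names()
  from <- cn[c(1, 1, 2, 2, 3, 5, 6, 4, 3, 5, 7, 8, 4, 6, 9)]
  to <- cn[c(3, 5, 4, 6, 7, 8, 9, 6, 1, 1, 1, 1, 2, 2, 2)]
  data.frame(
    channel = 1:15,
    name = c("recruit_lc_poor", "recruit_lc_good", "recruit_hc_poor",
             "recruit_hc_good", "convert_lpcom", "convert_lgcom",
             "convert_hgcom", "switch_hpvis",
             "leak_lpcom", "leak_lgcom", "leak_lprec", "leak_lgrec",
             "leak_hpvis", "leak_hgcom", "leak_hgrec"),
    from = from, to = to, rate = as.numeric(r))
}

run_outcome <- function(res, seed, engine, params) {
  counts <- as.integer(res$counts)
  names(counts) <- count_names()
  structure(
    list(result = c("good_quorum", "poor_quorum", "unsuccessful",
                    "censored")[res$result],
         t_event = res$t_event, n_events = res$n_events, counts = counts,
         seed = seed, engine = engine, params = params,
         event_log = res$event_log),
    class = "nest_run")
}

#' @export
print.nest_run <- function(x, ...) {
  cat(sprintf("Stochastic emigration run (%s engine, seed %d)\n", x$engine,
              x$seed))
  cat(sprintf("  outcome: %s at t = %.4g after %g events\n", x$result,
              x$t_event, x$n_events))
  invisible(x)
}

validate_quorum_n <- function(params) {
  q_n <- as.integer(round(params$quorum_fraction * params$N))
  v0 <- as.integer(round(params$N * params$z / 2))
  if (q_n <= v0)
    stop("quorum threshold (", q_n, " ants) is not above the initial vote ",
         "of ", v0, " scouts per site; the run would be quorate at t = 0")
  q_n
}

#' Exact event-driven simulation of one emigration
#'
#' Continuous-time stochastic simulation of the finite-population model:
#' exponential waiting times from the total event rate, the next channel
#' chosen with probability proportional to its rate (the classic exact SSA).
#' After every event the integer votes for the two sites are compared with
#' the quorum threshold `quorum_fraction * N`; the run terminates at the
#' first quorum (recording which site), when the total rate hits zero
#' (an unsuccessful emigration: leakage returned every ant home), or at
#' `t_max` (censored — surfaced separately because it should be rare).
#'
#' @param params A [nest_params()] object whose initial counts are integer.
#' @param seed Integer seed; identical `(params, seed)` reproduce the run
#'   bit-for-bit.
#' @param t_max Censoring horizon in model time units (default `1e5`).
#' @param log_events If `TRUE`, attach an event log: one row per event with
#'   `time`, `channel` (see [event_rates()] for the numbering) and the nine
#'   counts after the event.
#' @param max_log Cap on logged events (0 = unlimited).
#' @return A `nest_run` object: `result` (one of `good_quorum`,
#'   `poor_quorum`, `unsuccessful`, `censored`), `t_event`, `n_events`, the
#'   final `counts`, `seed`, and optionally `event_log`.
#' @examples
#' gillespie_run(nest_preset("baseline"), seed = 1)
#' @export
gillespie_run <- function(params, seed, t_max = 1e5, log_events = FALSE,
                          max_log = 0L) {
  stopifnot(inherits(params, "nest_params"), t_max > 0)
  q_n <- validate_quorum_n(params)
  n0 <- as_count_vector(initial_counts(params))
  set.seed(as.integer(seed))
  res <- cpp_ssa(n0, params$N, params$alpha_p, params$alpha_g,
                 params$alpha_s, params$alpha_leak, q_n, t_max,
                 numeric(0), log_events, as.integer(max_log))
  if (log_events) {
    colnames(res$event_log) <- c("time", "channel", count_names())
    res$event_log <- as.data.frame(res$event_log)
  }
  run_outcome(res, as.integer(seed), "gillespie", params)
}

#' Mean stochastic trajectory on a fixed time grid
#'
#' Runs the event-driven engine without the quorum stopping rule and records
#' the compartment counts in force at each requested time. Used to check the
#' mean-field limit: averaged over runs and divided by `N`, these occupancies
#' approach the Euler trajectory as `N` grows.
#'
#' @param params A [nest_params()] object.
#' @param seed Integer seed.
#' @param times Strictly increasing snapshot times.
#' @param t_max Censoring horizon (defaults to just past `max(times)`).
#' @return A data frame: `time` plus the nine count columns.
#' @export
abm_trajectory <- function(params, seed, times, t_max = max(times) + 1) {
  stopifnot(inherits(params, "nest_params"), length(times) >= 1,
            all(diff(times) > 0), all(times >= 0))
  n0 <- as_count_vector(initial_counts(params))
  set.seed(as.integer(seed))
  res <- cpp_ssa(n0, params$N, params$alpha_p, params$alpha_g,
                 params$alpha_s, params$alpha_leak, 0L, t_max,
                 as.numeric(times), FALSE, 0L)
  snaps <- res$snapshots
  colnames(snaps) <- count_names()
  data.frame(time = times, snaps)
}

#' Discrete-time cross-validation engine
#'
#' Fixed-step variant of [gillespie_run()]: in each step of length `dt`
#' every ant undergoes each of its possible transitions independently with
#' probability `rate * dt` (competing exits are drawn as an exact multinomial
#' split). As `dt -> 0` its outcome distribution converges to the exact
#' event-driven engine's; it exists to cross-validate that engine, not to
#' replace it. Every per-ant per-step probability must stay below 0.1, else
#' the run aborts naming the offending channel.
#'
#' @inheritParams gillespie_run
#' @param dt Step length (default 0.01).
#' @return A `nest_run` object (`n_events` counts ant moves).
#' @examples
#' discrete_time_run(nest_preset("baseline"), seed = 1, dt = 0.01)
#' @export
discrete_time_run <- function(params, seed, dt = 0.01, t_max = 1e5) {
  stopifnot(inherits(params, "nest_params"), dt > 0, t_max >= dt)
  q_n <- validate_quorum_n(params)
  n0 <- as_count_vector(initial_counts(params))
  set.seed(as.integer(seed))
  res <- cpp_discrete(n0, params$N, params$alpha_p, params$alpha_g,
                      params$alpha_s, params$alpha_leak, dt, q_n, t_max, 0.1)
  run_outcome(res, as.integer(seed), "discrete", params)
}
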