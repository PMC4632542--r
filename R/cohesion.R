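#' Parameters for the multi-nest cohesion experiment
#'
#' In the cohesion setting every candidate site is equally good, which is
#' modelled with a single (low) acceptance threshold for the whole colony and
#' no site switching. `N_nest` identical sites each start with
#' `N z / N_nest` scouts (which must be integer), and a run finishes when a
#' fraction `finish_fraction` of the colony (default 0.9) has emigrated to
#' the new sites; no quorum rule applies.
#'
#' @param N Colony size.
#' @param N_nest Number of new sites, `>= 2`.
#' @param z Scout fraction; `N z / N_nest` must be integer.
#' @param alpha Committed-to-recruiter conversion rate.
#' @param alpha_leak Leakage rate back to the current nest.
#' @param finish_fraction Emigrated fraction at which a run finishes,
#'   in `(0, 1]`.
#' @return An object of class `cohesion_params`.
#' @examples
#' cohesion_params(N = 100, N_nest = 4, z = 0.12)
#' @export
cohesion_params <- function(N = 100L, N_nest = 2L, z = 0.12, alpha = 0.1,
                            alpha_leak = 0.05, finish_fraction = 0.9) {
  stopifnot(N >= 1, N == round(N), N_nest >= 2, N_nest == round(N_nest),
            z >= 0, z < 1, alpha >= 0, alpha_leak >= 0)
  if (finish_fraction <= 0 || finish_fraction > 1)
    stop("finish_fraction must lie in (0, 1]")
  per_site <- N * z / N_nest
  if (abs(per_site - round(per_site)) > 1e-9)
    stop("N * z / N_nest = ", format(per_site), " is not integer; each site ",
         "must start with the same whole number of scouts")
  structure(list(N = as.integer(N), N_nest = as.integer(N_nest), z = z,
                 alpha = alpha, alpha_leak = alpha_leak,
                 finish_fraction = finish_fraction),
            class = "cohesion_params")
}

#' Entropy-based cohesion index
#'
#' `C = 1 - (-sum(p_i log p_i)) / log(N_nest)`: one minus the Shannon entropy
#' of the final distribution of emigrants over sites, normalized by its
#' maximum. `C = 1` when every emigrant settles in a single site (perfect
#' cohesion) and `C = 0` when they spread uniformly over all sites; zero
#' entries contribute nothing. The logarithm base cancels.
#'
#' @param p Probability vector of length `>= 2`: non-negative, summing to 1.
#' @return Cohesion in `[0, 1]`.
#' @examples
#' cohesion_index(c(1, 0, 0, 0))        # 1
#' cohesion_index(rep(0.25, 4))         # 0
#' cohesion_index(c(0.75, 0.25))
#' @export
cohesion_index <- function(p) {
  if (length(p) < 2L) stop("need at least two sites")
  if (any(p < 0)) stop("p must be non-negative")
  if (abs(sum(p) - 1) > 1e-8)
    stop("p must sum to 1 (got ", format(sum(p)), "); normalize occupancies ",
         "before computing cohesion")
  pp <- p[p > 0]
  entropy <- -sum(pp * log(pp))
  C <- 1 - entropy / log(length(p))
  # the closed form gives exactly 0 at uniform and 1 at degenerate p;
  # clamp the ~1e-16 round-off so the endpoints are exact
  if (abs(C) < 1e-12) C <- 0
  min(max(C, 0), 1)
}

#' Initial occupancies for the multi-nest model
#'
#' @param params A [cohesion_params()] object.
#' @return A list: `n_current` (`N (1 - z)` ants at home), `committed`
#'   (`N z / N_nest` per site), `recruiting` (zeros).
#' @examples
#' cohesion_initial(cohesion_params(N = 100, N_nest = 4, z = 0.12))
#' @export
cohesion_initial <- function(params) {
  stopifnot(inherits(params, "cohesion_params"))
  per_site <- as.integer(round(params$N * params$z / params$N_nest))
  list(n_current = as.integer(params$N - params$N_nest * per_site),
       committed = rep(per_site, params$N_nest),
       recruiting = rep(0L, params$N_nest))
}

#' One multi-nest emigration run
#'
#' Event-driven simulation of the equal-quality multi-site model: ants at
#' home are recruited to site i at per-ant rate `recruiters_i / N`, committed
#' ants convert to recruiters at `alpha`, and both leak home at
#' `alpha_leak`. The run finishes when `finish_fraction * N` ants occupy the
#' new sites; cohesion is then computed from the per-site occupancy
#' (committed + recruiting, each site's recruiters belonging to it) shares
#' among the emigrants.
#'
#' @param params A [cohesion_params()] object.
#' @param seed Integer seed.
#' @param t_max Censoring horizon.
#' @return A `cohesion_run` list: `result` (`finished`, `unsuccessful` or
#'   `censored`), `T_f`, `site_counts`, `n_current`, `C` (cohesion over
#'   emigrants; `NA` unless finished), `p` (occupancy shares), `n_events`,
#'   `seed`.
#' @examples
#' cohesion_run(cohesion_params(N = 100, N_nest = 2, z = 0.12), seed = 1)
#' @export
cohesion_run <- function(params, seed, t_max = 1e5) {
  stopifnot(inherits(params, "cohesion_params"), t_max > 0)
  init <- cohesion_initial(params)
  finish_n <- as.integer(ceiling(params$finish_fraction * params$N - 1e-9))
  set.seed(as.integer(seed))
  res <- cpp_cohesion(init$n_current, init$committed, init$recruiting,
                      params$N, params$alpha, params$alpha_leak, finish_n,
                      t_max)
  occ <- as.integer(res$site_counts)
  finished <- res$result == 1L
  p <- if (sum(occ) > 0) occ / sum(occ) else rep(NA_real_, params$N_nest)
  structure(list(
    result = c("finished", NA, "unsuccessful", "censored")[res$result],
    T_f = res$t_event, site_counts = occ, n_current = res$n_current,
    p = p, C = if (finished) cohesion_index(p) else NA_real_,
    n_events = res$n_events, seed = as.integer(seed), params = params),
    class = "cohesion_run")
}

#' Monte-Carlo batch of multi-nest emigrations
#'
#' Repeats [cohesion_run()] with counter-derived per-run seeds and averages
#' the finish time `T_f` and cohesion `C` over finished runs only;
#' unsuccessful (all ants leaked home) and censored runs are excluded and
#' counted. With `finish_fraction` at or near 1 and leakage on, finished
#' runs can become rare — the summary reports that rather than hanging.
#'
#' @param params A [cohesion_params()] object.
#' @param n_runs Number of runs.
#' @param seed Master seed.
#' @param t_max Censoring horizon per run.
#' @param ci_mode Passed to [ci_halfwidth()].
#' @return A `cohesion_summary` list: run accounting, `T_f_mean`, `T_f_ci`,
#'   `C_mean`, `C_ci`, mean per-site occupancy shares `p_mean`, `seed`.
#' @examples
#' cohesion_batch(cohesion_params(N_nest = 2), n_runs = 20, seed = 1)
#' @export
cohesion_batch <- function(params, n_runs = 10000L, seed = 1L, t_max = 1e5,
                           ci_mode = "standard") {
  stopifnot(inherits(params, "cohesion_params"), n_runs >= 1)
  tf <- numeric(n_runs)
  cc <- numeric(n_runs)
  status <- character(n_runs)
  pmat <- matrix(NA_real_, n_runs, params$N_nest)
  for (i in seq_len(n_runs)) {
    r <- cohesion_run(params, seed = derive_seed(seed, i), t_max = t_max)
    status[i] <- r$result
    tf[i] <- r$T_f
    cc[i] <- r$C
    pmat[i, ] <- r$p
  }
  fin <- status == "finished"
  out <- list(
    n_runs = as.integer(n_runs), n_finished = sum(fin),
    n_unsuccessful = sum(status == "unsuccessful"),
    n_censored = sum(status == "censored"),
    T_f_mean = if (any(fin)) mean(tf[fin]) else NA_real_,
    T_f_ci = if (sum(fin) >= 2L) ci_halfwidth(tf[fin], ci_mode) else NA_real_,
    C_mean = if (any(fin)) mean(cc[fin]) else NA_real_,
    C_ci = if (sum(fin) >= 2L) ci_halfwidth(cc[fin], ci_mode) else NA_real_,
    p_mean = if (any(fin)) colMeans(pmat[fin, , drop = FALSE]) else
      rep(NA_real_, params$N_nest),
    seed = as.integer(seed), params = params)
  if (out$n_finished == 0L)
    warning("no finished runs; T_f and C are undefined for this batch")
  class(out) <- "cohesion_summary"
  out
}

#' @export
print.cohesion_summary <- function(x, ...) {
  cat(sprintf("Cohesion batch: %d runs, N_nest = %d, z = %g, alpha = %g\n",
              x$n_runs, x$params$N_nest, x$params$z, x$params$alpha))
  cat(sprintf("  finished %d | unsuccessful %d | censored %d\n",
              x$n_finished, x$n_unsuccessful, x$n_censored))
  if (x$n_finished > 0L)
    cat(sprintf("  T_f = %.3f +/- %.3f, C = %.4f +/- %.4f\n", x$T_f_mean,
                x$T_f_ci, x$C_mean, x$C_ci))
  invisible(x)
}

#' Sweep a cohesion parameter
#'
#' One [cohesion_batch()] per value of `z` or `alpha` (optionally crossed
#' with several `N_nest`), summarized in a tidy data frame. The canonical
#' experiments fix `z = 0.12` (equal scouts per site for `N_nest` 2, 4 and
#' 6 at `N = 100`) while varying `alpha`, or fix `alpha` while varying `z`.
#'
#' @param params Base [cohesion_params()].
#' @param vary `"z"` or `"alpha"`.
#' @param values Values of the swept parameter.
#' @param n_nest_values `N_nest` values to cross with the sweep (default:
#'   just the base value).
#' @param n_runs Runs per cell.
#' @param seed Master seed.
#' @param t_max Censoring horizon per run.
#' @return A data frame, one row per (N_nest, value) cell: accounting plus
#'   `T_f_mean`, `T_f_ci`, `C_mean`, `C_ci`.
#' @export
cohesion_sweep <- function(params, vary = c("z", "alpha"), values,
                           n_nest_values = params$N_nest, n_runs = 10000L,
                           seed = 1L, t_max = 1e5) {
  vary <- match.arg(vary)
  rows <- list()
  j <- 0L
  for (k in n_nest_values) {
    for (v in values) {
      j <- j + 1L
      args <- list(N = params$N, N_nest = k, z = params$z,
                   alpha = params$alpha, alpha_leak = params$alpha_leak,
                   finish_fraction = params$finish_fraction)
      args[[vary]] <- v
      pj <- do.call(cohesion_params, args)
      b <- cohesion_batch(pj, n_runs = n_runs, seed = batch_seed(seed, j),
                          t_max = t_max)
      rows[[j]] <- data.frame(
        N_nest = k, value = v, n_finished = b$n_finished,
        n_unsuccessful = b$n_unsuccessful, n_censored = b$n_censored,
        T_f_mean = b$T_f_mean, T_f_ci = b$T_f_ci, C_mean = b$C_mean,
        C_ci = b$C_ci)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "vary") <- vary
  attr(out, "seed") <- as.integer(seed)
  out
}
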