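SEED_MOD <- 2147483629  # large prime < 2^31; keeps derived seeds in int range

derive_seed <- function(master, i) as.integer((master + i - 1) %% SEED_MOD)

batch_seed <- function(master, j) as.integer((master + 100003 * j) %% SEED_MOD)

#' Confidence-interval half-width for a mean
#'
#' `"standard"` is the usual large-sample 95% half-width
#' `1.96 * sd(x) / sqrt(n)` (sample sd, n - 1 denominator) and is the
#' default. `"literal"` divides by `n` instead of `sqrt(n)`; that formula
#' appears in some published figure captions (almost certainly a typo for the
#' standard error) and is kept only so such intervals can be reproduced
#' verbatim.
#'
#' @param samples Numeric vector, length at least 2.
#' @param mode `"standard"` or `"literal"`.
#' @return Non-negative half-width.
#' @examples
#' ci_halfwidth(c(0, 2))             # 1.96
#' ci_halfwidth(c(0, 2), "literal")  # 1.96 * sqrt(2) / 2
#' @export
ci_halfwidth <- function(samples, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (length(samples) < 2L)
    stop("need at least 2 samples for a confidence interval")
  s <- stats::sd(samples)
  if (mode == "standard") 1.96 * s / sqrt(length(samples))
  else 1.96 * s / length(samples)
}

#' Pearson correlation of summary points
#'
#' Product-moment correlation of paired points, typically the
#' (mean time-to-quorum, accuracy) summaries of a parameter sweep. A
#' positive correlation across a sweep signals a speed--accuracy trade-off
#' (slower decisions are the more accurate ones); a negative one means speed
#' and accuracy improve together.
#'
#' @param x,y Numeric vectors of equal length `>= 3`, or `x` a two-column
#'   matrix/data frame with `y` missing.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' pearson_r(1:3, c(3, 2, 1))
#' @export
pearson_r <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2L)
    y <- x[, 2L]
    x <- x[, 1L]
  }
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 points for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a coordinate is constant")
  stats::cor(x, y)
}

#' Monte-Carlo batch of emigrations
#'
#' Runs `n_runs` independent simulations with per-run seeds derived from the
#' master seed by an additive counter (run i uses seed
#' `(seed + i - 1) mod 2147483629`, so any single run can be replayed).
#' Unsuccessful and censored runs are excluded from every statistic: the mean
#' time-to-quorum `T_mean` and its confidence half-width are computed over
#' quorate runs only, and the accuracy `P` is the fraction of quorate runs in
#' which the good site became quorate first. The exclusion counts are
#' first-class outputs and always sum with `n_quorate` to `n_runs`.
#'
#' @param params A [nest_params()] object.
#' @param n_runs Number of runs (default 10000, matching the usual
#'   replication for these experiments).
#' @param seed Master seed.
#' @param engine `"gillespie"` (exact, default) or `"discrete"`.
#' @param dt Step for the discrete engine.
#' @param t_max Censoring horizon per run.
#' @param ci_mode Passed to [ci_halfwidth()].
#' @return A `batch_summary` list: `n_runs`, `n_quorate`, `n_unsuccessful`,
#'   `n_censored`, `T_mean`, `T_ci_halfwidth`, `P`, `seed`, `engine`,
#'   `params`, and the per-run vectors `times` and `good` (quorate runs, in
#'   run order).
#' @examples
#' b <- run_batch(nest_preset("baseline"), n_runs = 50, seed = 1)
#' c(b$T_mean, b$P)
#' @export
run_batch <- function(params, n_runs = 10000L, seed = 1L,
                      engine = c("gillespie", "discrete"), dt = 0.01,
                      t_max = 1e5, ci_mode = "standard") {
  stopifnot(inherits(params, "nest_params"), n_runs >= 1)
  engine <- match.arg(engine)
  q_n <- validate_quorum_n(params)
  n0 <- as_count_vector(initial_counts(params))
  results <- integer(n_runs)
  times <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(derive_seed(seed, i))
    res <- if (engine == "gillespie")
      cpp_ssa(n0, params$N, params$alpha_p, params$alpha_g, params$alpha_s,
              params$alpha_leak, q_n, t_max, numeric(0), FALSE, 0L)
    else
      cpp_discrete(n0, params$N, params$alpha_p, params$alpha_g,
                   params$alpha_s, params$alpha_leak, dt, q_n, t_max, 0.1)
    results[i] <- res$result
    times[i] <- res$t_event
  }
  quorate <- results <= 2L
  out <- list(
    n_runs = as.integer(n_runs),
    n_quorate = sum(quorate),
    n_unsuccessful = sum(results == 3L),
    n_censored = sum(results == 4L),
    T_mean = if (any(quorate)) mean(times[quorate]) else NA_real_,
    T_ci_halfwidth = if (sum(quorate) >= 2L)
      ci_halfwidth(times[quorate], ci_mode) else NA_real_,
    P = if (any(quorate)) mean(results[quorate] == 1L) else NA_real_,
    seed = as.integer(seed), engine = engine, params = params,
    times = times[quorate], good = results[quorate] == 1L)
  if (out$n_quorate == 0L)
    warning("no quorate runs; T and P are undefined for this batch")
  if (out$n_censored > 0L)
    warning(out$n_censored, " run(s) censored at t_max = ", t_max,
            "; consider a larger horizon")
  class(out) <- "batch_summary"
  out
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("Batch of %d runs (%s engine, master seed %d)\n", x$n_runs,
              x$engine, x$seed))
  cat(sprintf("  quorate %d | unsuccessful %d | censored %d\n", x$n_quorate,
              x$n_unsuccessful, x$n_censored))
  if (x$n_quorate > 0L)
    cat(sprintf("  T = %.3f +/- %.3f, P = %.4f\n", x$T_mean,
                x$T_ci_halfwidth, x$P))
  invisible(x)
}

set_param <- function(params, name, value) {
  if (name == "alpha")
    return(nest_params(H = params$H, z = params$z, alpha = value,
                       alpha_s = params$alpha_s,
                       alpha_leak = params$alpha_leak, N = params$N,
                       quorum_fraction = params$quorum_fraction))
  args <- list(H = params$H, z = params$z, alpha_p = params$alpha_p,
               alpha_g = params$alpha_g, alpha_s = params$alpha_s,
               alpha_leak = params$alpha_leak, N = params$N,
               quorum_fraction = params$quorum_fraction)
  if (!name %in% names(args))
    stop("unknown parameter '", name, "'")
  args[[name]] <- value
  do.call(nest_params, args)
}

#' Sweep one parameter and correlate speed with accuracy
#'
#' Runs one Monte-Carlo batch per parameter value (per-batch master seeds are
#' derived from `seed` so batches are independent but reproducible) and
#' correlates the resulting `(T_mean, P)` summary points with [pearson_r()].
#' One point per parameter value, unweighted — the diagnostic asks how the
#' summaries covary, not the pooled runs. Values whose initial compartments
#' are not integers at the given `N` are reported as errors in the result,
#' never silently skipped.
#'
#' @param params Base [nest_params()].
#' @param vary Name of the swept parameter: `"H"`, `"z"`,
#'   `"quorum_fraction"`, `"alpha_s"`, `"alpha"`, `"alpha_p"`, `"alpha_g"`,
#'   or `"alpha_leak"`.
#' @param values Numeric vector of parameter values (in sweep order).
#' @param n_runs Runs per value.
#' @param seed Master seed for the whole sweep.
#' @param ... Passed to [run_batch()].
#' @return A `sweep_result` list: `vary`, `values`, `summaries` (a tidy data
#'   frame, one row per value: `value`, `n_quorate`, `n_unsuccessful`,
#'   `n_censored`, `T_mean`, `T_ci`, `P`, `error`), `pearson_r` (of the
#'   valid `(T_mean, P)` points; `NA` with fewer than 3), `batches` (the
#'   full [run_batch()] objects), and `seed`.
#' @examples
#' sw <- sweep_param(nest_preset("baseline"), "H", c(0, 0.4, 0.8),
#'                   n_runs = 30, seed = 1)
#' sw$summaries
#' @export
sweep_param <- function(params, vary, values, n_runs = 10000L, seed = 1L,
                        ...) {
  stopifnot(inherits(params, "nest_params"), length(values) >= 1)
  ok_vary <- c("H", "z", "quorum_fraction", "alpha_s", "alpha", "alpha_p",
               "alpha_g", "alpha_leak")
  if (!vary %in% ok_vary)
    stop("unknown sweep parameter '", vary, "'; one of: ",
         paste(ok_vary, collapse = ", "))
  batches <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (j in seq_along(values)) {
    pj <- try(set_param(params, vary, values[j]), silent = TRUE)
    b <- if (inherits(pj, "try-error")) pj else
      try(run_batch(pj, n_runs = n_runs, seed = batch_seed(seed, j), ...),
          silent = TRUE)
    if (inherits(b, "try-error")) {
      rows[[j]] <- data.frame(value = values[j], n_quorate = NA_integer_,
                              n_unsuccessful = NA_integer_,
                              n_censored = NA_integer_, T_mean = NA_real_,
                              T_ci = NA_real_, P = NA_real_,
                              error = conditionMessage(attr(b, "condition")))
    } else {
      batches[[j]] <- b
      rows[[j]] <- data.frame(value = values[j], n_quorate = b$n_quorate,
                              n_unsuccessful = b$n_unsuccessful,
                              n_censored = b$n_censored, T_mean = b$T_mean,
                              T_ci = b$T_ci_halfwidth, P = b$P,
                              error = NA_character_)
    }
  }
  summaries <- do.call(rbind, rows)
  ok <- is.na(summaries$error) & !is.na(summaries$T_mean) &
    !is.na(summaries$P)
  r <- if (sum(ok) >= 3L && stats::sd(summaries$T_mean[ok]) > 0 &&
           stats::sd(summaries$P[ok]) > 0)
    pearson_r(summaries$T_mean[ok], summaries$P[ok]) else NA_real_
  structure(list(vary = vary, values = values, summaries = summaries,
                 pearson_r = r, batches = batches, seed = as.integer(seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d values, master seed %d)\n", x$vary,
              length(x$values), x$seed))
  print(x$summaries, row.names = FALSE)
  cat(sprintf("  Pearson r of (T, P) points: %s\n",
              ifelse(is.na(x$pearson_r), "undefined",
                     sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' Default six-point H grid
#'
#' The evenly spaced six-point grid over the high-threshold fraction that
#' keeps every initial compartment integer at `N = 100`, `z = 0.3`. Used by
#' the standard speed--accuracy sweep; override freely where the
#' integer-compartment constraint allows.
#'
#' @return `c(0, 0.2, 0.4, 0.6, 0.8, 1)`.
#' @export
default_H_grid <- function() seq(0, 1, by = 0.2)
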