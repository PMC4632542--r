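#' Mean-field initial condition
#'
#' At time zero a fraction `z` of the colony are scouts, half of whom have
#' found the good site and half the poor site; everyone else is in the current
#' nest. Low-threshold scouts commit immediately to the site they found;
#' high-threshold scouts at the poor site only visit it. No ant is recruiting
#' yet.
#'
#' @param params A [nest_params()] object.
#' @return A named numeric vector of length nine (class `nest_state`): the
#'   colony fractions `x_lc`, `x_hc`, `x_lpcom`, `x_hpvis`, `x_lgcom`,
#'   `x_hgcom`, `x_lprec`, `x_lgrec`, `x_hgrec`, summing to one.
#' @examples
#' initial_state(nest_params(H = 0.2, z = 0.3))
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "nest_params"))
  x <- c(params$L * (1 - params$z), params$H * (1 - params$z),
         params$L * params$z / 2, params$H * params$z / 2,
         params$L * params$z / 2, params$H * params$z / 2,
         0, 0, 0)
  names(x) <- state_names()
  class(x) <- "nest_state"
  x
}

as_state_vector <- function(state) {
  if (inherits(state, "nest_state")) return(unclass(state))
  x <- as.numeric(state)
  if (length(x) != 9L) stop("a model state has exactly nine components")
  names(x) <- state_names()
  x
}

#' Right-hand side of the mean-field equations
#'
#' Time derivatives of the nine compartment fractions: mass-action
#' recruitment of current-nest ants by recruiters (per-pair rate one),
#' committed-to-recruiter conversion at `alpha_p` / `alpha_g`, poor-to-good
#' switching of high-threshold visitors at `alpha_s`, and leakage of every
#' away-from-home class back to the current nest at `alpha_leak`. The
#' derivatives sum to zero, separately within the low- and high-threshold
#' classes, so both class totals are conserved.
#'
#' @param state A nine-component state (fractions).
#' @param params A [nest_params()] object.
#' @return Named numeric vector of the nine derivatives.
#' @export
ode_rhs <- function(state, params) {
  stopifnot(inherits(params, "nest_params"))
  x <- as_state_vector(state)
  d <- cpp_ode_rhs(x, params$alpha_p, params$alpha_g, params$alpha_s,
                   params$alpha_leak)
  names(d) <- state_names()
  d
}

#' Integrate the mean-field model by forward Euler
#'
#' The reference integrator is the forward Euler scheme with step `dt`
#' (default 0.001), which is exact enough for these smooth, contracting
#' dynamics and keeps the class-sum constraints to round-off. The stored
#' trajectory keeps every `stride`-th step; quorum detection should use
#' [ode_quorum_time()], which runs at full step resolution regardless of
#' `stride`.
#'
#' @param params A [nest_params()] object.
#' @param dt Euler step (time units), default `0.001`.
#' @param t_max Final time, `>= dt`.
#' @param stride Keep every `stride`-th step in the returned trajectory
#'   (plus t = 0 and the final step). Default 10.
#' @param neg_tol Largest tolerated negative excursion of any component
#'   before integration aborts (the exact dynamics preserve positivity, so a
#'   real violation means `dt` is too large). Default `1e-12`. Excursions
#'   within tolerance are clipped to zero in the returned trajectory.
#' @return A data frame of class `nest_trajectory` with columns `time`, the
#'   nine state fractions, and the running votes `v_good`, `v_poor`.
#' @examples
#' tr <- integrate_euler(nest_preset("baseline"), t_max = 10)
#' tail(tr[, c("time", "v_good", "v_poor")], 3)
#' @export
integrate_euler <- function(params, dt = 1e-3, t_max = 100, stride = 10L,
                            neg_tol = 1e-12) {
  stopifnot(inherits(params, "nest_params"), dt > 0, t_max >= dt,
            stride >= 1)
  y0 <- as_state_vector(initial_state(params))
  res <- cpp_euler(y0, params$alpha_p, params$alpha_g, params$alpha_s,
                   params$alpha_leak, dt, t_max, as.integer(stride), neg_tol)
  states <- res$states
  colnames(states) <- state_names()
  traj <- data.frame(time = res$times, states)
  traj$v_good <- rowSums(states[, good_idx(), drop = FALSE])
  traj$v_poor <- rowSums(states[, poor_idx(), drop = FALSE])
  attr(traj, "params") <- params
  attr(traj, "dt") <- dt
  class(traj) <- c("nest_trajectory", "data.frame")
  traj
}

#' Votes for the two candidate sites
#'
#' The vote for the good site counts every ant committed or recruiting to it;
#' the vote for the poor site additionally counts high-threshold ants merely
#' visiting it (they are present at the site even though they will never
#' commit). Votes are what the quorum rule compares against its threshold.
#'
#' @param state A nine-component state (fractions) or a `nest_trajectory`.
#' @return For a single state, a named numeric vector `c(v_good, v_poor)`;
#'   for a trajectory, a data frame with columns `time`, `v_good`, `v_poor`.
#' @examples
#' votes(initial_state(nest_params(z = 0.3)))  # z/2 apiece
#' @export
votes <- function(state) {
  if (inherits(state, "nest_trajectory"))
    return(state[, c("time", "v_good", "v_poor")])
  x <- as_state_vector(state)
  c(v_good = sum(x[good_idx()]), v_poor = sum(x[poor_idx()]))
}

#' Deterministic time to quorum
#'
#' Earliest time at which either site's vote reaches the quorum fraction in
#' the mean-field model. Called on parameters it re-integrates at full step
#' resolution without storing the trajectory; called on a stored trajectory
#' it scans the stored grid (coarser by `stride`).
#'
#' A configuration whose initial votes (`z / 2` apiece) already meet the
#' quorum is rejected: a sweep over such settings would measure nothing. Set
#' `allow_initial_quorum = TRUE` to downgrade this to a warning and report
#' time zero.
#'
#' @param x A [nest_params()] object or a `nest_trajectory`.
#' @param quorum_fraction Quorum threshold as a fraction of the colony;
#'   defaults to the value carried by the parameters.
#' @param dt,t_max Integration controls when `x` is a parameter object.
#' @param allow_initial_quorum Tolerate configurations quorate at t = 0.
#' @param ... Passed between methods.
#' @return A list with `time` (numeric, or `NULL` if the quorum is never
#'   reached before `t_max`) and `site` (`"good"`, `"poor"`, or `NA`).
#' @examples
#' ode_quorum_time(nest_preset("baseline"), t_max = 50)
#' @export
ode_quorum_time <- function(x, ...) UseMethod("ode_quorum_time")

check_initial_quorum <- function(z, quorum_fraction, allow) {
  if (quorum_fraction <= z / 2) {
    msg <- sprintf(
      "quorum fraction %g is already met by the initial scout vote z/2 = %g",
      quorum_fraction, z / 2)
    if (!allow) stop(msg, " (set allow_initial_quorum = TRUE to override)")
    warning(msg, "; reporting time 0")
    return(TRUE)
  }
  FALSE
}

#' @rdname ode_quorum_time
#' @export
ode_quorum_time.nest_params <- function(x, quorum_fraction = x$quorum_fraction,
                                        dt = 1e-3, t_max = 100,
                                        allow_initial_quorum = FALSE, ...) {
  if (check_initial_quorum(x$z, quorum_fraction, allow_initial_quorum))
    return(list(time = 0, site = "tie"))
  y0 <- as_state_vector(initial_state(x))
  res <- cpp_ode_quorum(y0, x$alpha_p, x$alpha_g, x$alpha_s, x$alpha_leak,
                        dt, t_max, quorum_fraction)
  list(time = res$time,
       site = if (res$site == 0) NA_character_ else
              c("good", "poor")[res$site])
}

#' @rdname ode_quorum_time
#' @export
ode_quorum_time.nest_trajectory <- function(x, quorum_fraction = NULL,
                                            allow_initial_quorum = FALSE,
                                            ...) {
  params <- attr(x, "params")
  if (is.null(quorum_fraction)) quorum_fraction <- params$quorum_fraction
  if (check_initial_quorum(params$z, quorum_fraction, allow_initial_quorum))
    return(list(time = 0, site = "tie"))
  hit <- which(x$v_good >= quorum_fraction | x$v_poor >= quorum_fraction)
  if (length(hit) == 0L) return(list(time = NULL, site = NA_character_))
  i <- hit[1L]
  list(time = x$time[i],
       site = if (x$v_good[i] >= quorum_fraction) "good" else "poor")
}
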