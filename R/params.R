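#' Model parameters for collective nest-site choice
#'
#' Bundles every rate constant, the population composition and the experiment
#' thresholds of the two-site nest-choice model into one validated record.
#' Time is measured in units of the recruiting rate per recruiter--recruitee
#' pair, which is fixed at unity; all `alpha` rates are expressed in that
#' unit.
#'
#' @param H Fraction of high-threshold ants (those satisfied only by the good
#'   site), in `[0, 1]`. The low-threshold fraction is `L = 1 - H`.
#' @param z Initial scout fraction in `[0, 1)`; scouts split equally between
#'   the two new sites.
#' @param alpha Convenience parameter setting `alpha_p = alpha_g = alpha`
#'   jointly (the usual symmetric choice). Ignored when both `alpha_p` and
#'   `alpha_g` are given.
#' @param alpha_p Rate at which an ant committed to the poor site converts to
#'   a recruiter.
#' @param alpha_g Conversion rate at the good site.
#' @param alpha_s Rate at which a high-threshold visitor abandons the poor
#'   site for the good one.
#' @param alpha_leak Rate at which any ant away from the current nest returns
#'   to it.
#' @param N Colony size (positive integer). Used only by the stochastic
#'   model; the mean-field equations are written in fractions.
#' @param quorum_fraction Quorum threshold as a fraction of `N`, in `(0, 1]`.
#'
#' @return An object of class `nest_params`: a named list with fields `H`,
#'   `L`, `z`, `alpha_p`, `alpha_g`, `alpha_s`, `alpha_leak`, `N`,
#'   `quorum_fraction`.
#' @seealso [nest_preset()] for named parameter sets, [initial_state()],
#'   [initial_counts()].
#' @examples
#' p <- nest_params(H = 0.2, z = 0.3, alpha = 0.1, alpha_s = 0.1,
#'                  alpha_leak = 0.05, N = 100, quorum_fraction = 0.5)
#' p$alpha_g
#' @export
nest_params <- function(H = 0.2, z = 0.3, alpha = 0.1, alpha_p = NULL,
                        alpha_g = NULL, alpha_s = 0.1, alpha_leak = 0.05,
                        N = 100L, quorum_fraction = 0.5) {
  if (is.null(alpha_p)) alpha_p <- alpha
  if (is.null(alpha_g)) alpha_g <- alpha
  stopifnot(is.numeric(H), length(H) == 1L, is.numeric(z), length(z) == 1L)
  if (H < 0 || H > 1) stop("H must lie in [0, 1], got ", H)
  if (z < 0 || z >= 1) stop("z must lie in [0, 1), got ", z)
  for (nm in c("alpha_p", "alpha_g", "alpha_s", "alpha_leak")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop(nm, " must be a single non-negative rate, got ", format(v))
  }
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("N must be a positive integer, got ", format(N))
  if (!is.numeric(quorum_fraction) || quorum_fraction <= 0 ||
      quorum_fraction > 1)
    stop("quorum_fraction must lie in (0, 1], got ", format(quorum_fraction))
  structure(
    list(H = H, L = 1 - H, z = z, alpha_p = alpha_p, alpha_g = alpha_g,
         alpha_s = alpha_s, alpha_leak = alpha_leak, N = as.integer(N),
         quorum_fraction = quorum_fraction),
    class = "nest_params")
}

#' @export
print.nest_params <- function(x, ...) {
  cat("Nest-choice model parameters\n")
  cat(sprintf("  composition: H = %g, L = %g, scouts z = %g, N = %d\n",
              x$H, x$L, x$z, x$N))
  cat(sprintf("  rates: alpha_p = %g, alpha_g = %g, alpha_s = %g, alpha_leak = %g\n",
              x$alpha_p, x$alpha_g, x$alpha_s, x$alpha_leak))
  cat(sprintf("  quorum threshold: %g N = %g ants\n", x$quorum_fraction,
              x$quorum_fraction * x$N))
  invisible(x)
}

#' Named parameter presets
#'
#' `"baseline"` is the standard simulation setting for the two-site model:
#' `alpha = 0.1`, `alpha_s = 0.1`, `alpha_leak = 0.05`, `H = 0.2`, `z = 0.3`,
#' `N = 100`, quorum at `0.5 N`. `"pratt"` rescales the tandem-running rate
#' constants estimated by Pratt et al. (2002) for Temnothorax albipennis
#' emigrations into this model's time unit, giving `alpha = 0.5` and
#' `alpha_s = 0.25` (other fields as in `"baseline"`).
#'
#' @param name Preset name, `"baseline"` or `"pratt"`.
#' @return A [nest_params()] object.
#' @examples
#' nest_preset("pratt")$alpha_s
#' @export
nest_preset <- function(name = c("baseline", "pratt")) {
  name <- match.arg(name)
  switch(name,
    baseline = nest_params(H = 0.2, z = 0.3, alpha = 0.1, alpha_s = 0.1,
                           alpha_leak = 0.05, N = 100L,
                           quorum_fraction = 0.5),
    pratt = nest_params(H = 0.2, z = 0.3, alpha = 0.5, alpha_s = 0.25,
                        alpha_leak = 0.05, N = 100L, quorum_fraction = 0.5))
}

state_names <- function() {
  c("x_lc", "x_hc", "x_lpcom", "x_hpvis", "x_lgcom", "x_hgcom",
    "x_lprec", "x_lgrec", "x_hgrec")
}

count_names <- function() {
  c("n_lc", "n_hc", "n_lpcom", "n_hpvis", "n_lgcom", "n_hgcom",
    "n_lprec", "n_lgrec", "n_hgrec")
}

low_idx <- function() c(1L, 3L, 5L, 7L, 8L)   # lc, lpcom, lgcom, lprec, lgrec
high_idx <- function() c(2L, 4L, 6L, 9L)      # hc, hpvis, hgcom, hgrec
good_idx <- function() c(5L, 6L, 8L, 9L)      # lgcom, hgcom, lgrec, hgrec
poor_idx <- function() c(3L, 4L, 7L)          # lpcom, hpvis, lprec
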