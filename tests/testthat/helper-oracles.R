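# Independent R-side oracles used to cross-check the compiled engines.

# Mean-field right-hand side written directly from the published form of the
# compartment equations, independently of the C++ implementation.
ref_rhs <- function(x, ap, ag, as_, al) {
  with(as.list(x), {
    rec <- x_lprec + x_lgrec + x_hgrec
    grec <- x_lgrec + x_hgrec
    c(x_lc = -rec * x_lc + al * (x_lpcom + x_lprec + x_lgcom + x_lgrec),
      x_hc = -rec * x_hc + al * (x_hpvis + x_hgcom + x_hgrec),
      x_lpcom = x_lprec * x_lc - ap * x_lpcom - al * x_lpcom,
      x_hpvis = x_lprec * x_hc - as_ * x_hpvis - al * x_hpvis,
      x_lgcom = grec * x_lc - ag * x_lgcom - al * x_lgcom,
      x_hgcom = grec * x_hc + as_ * x_hpvis - ag * x_hgcom - al * x_hgcom,
      x_lprec = ap * x_lpcom - al * x_lprec,
      x_lgrec = ag * x_lgcom - al * x_lgrec,
      x_hgrec = ag * x_hgcom - al * x_hgrec)
  })
}

# A random valid mean-field state with class totals L and H.
random_state <- function(H) {
  L <- 1 - H
  low <- stats::runif(5)
  high <- stats::runif(4)
  x <- c(L * low[1] / sum(low), H * high[1] / sum(high),
         L * low[2] / sum(low), H * high[2] / sum(high),
         L * low[3] / sum(low), H * high[3] / sum(high),
         L * low[4] / sum(low), L * low[5] / sum(low),
         H * high[4] / sum(high))
  names(x) <- c("x_lc", "x_hc", "x_lpcom", "x_hpvis", "x_lgcom", "x_hgcom",
                "x_lprec", "x_lgrec", "x_hgrec")
  x
}

low_cols <- c("x_lc", "x_lpcom", "x_lgcom", "x_lprec", "x_lgrec")
high_cols <- c("x_hc", "x_hpvis", "x_hgcom", "x_hgrec")
low_counts <- c("n_lc", "n_lpcom", "n_lgcom", "n_lprec", "n_lgrec")
high_counts <- c("n_hc", "n_hpvis", "n_hgcom", "n_hgrec")

baseline <- function() nest_preset("baseline")
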