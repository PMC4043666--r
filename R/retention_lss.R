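# Linear-solvent-strength (LSS) gradient retention model.
#
# Retention follows log10 k(phi) = logkw - S * phi, with k the retention
# factor, phi the organic-modifier volume fraction, logkw the value
# extrapolated to pure water (the chromatographic lipophilicity index)
# and S > 0 the solvent-strength slope. S is reported positive; retention
# decreases with phi. Gradient elution is modeled with the classic
# fundamental condition: the solute elutes at tR = te + t0 where te
# solves
#
#   integral_0^te dt / k(phi_inlet(t)) = t0,
#
# phi_inlet(t) being the programmed composition arriving at the column
# inlet: phi0 during the dwell period tD, then a linear ramp to phif over
# tG, then held at phif.

#' LSS retention parameters
#'
#' @param logkw log10 retention factor extrapolated to 0% organic
#'   modifier.
#' @param S Solvent-strength slope (positive; log k decreases by S per
#'   unit volume fraction of organic).
#' @return Object of class `lss_params`.
#' @export
lss_params <- function(logkw, S) {
  stopifnot(is.finite(logkw), is.finite(S), S > 0)
  structure(list(logkw = logkw, S = S), class = "lss_params")
}

#' Linear gradient program
#'
#' @param tG Gradient time in minutes (ramp duration).
#' @param phi0,phif Initial and final organic volume fractions; the
#'   lipophilicity runs use 0.05 to 1.00.
#' @return Object of class `gradient_program`.
#' @export
gradient_program <- function(tG, phi0 = 0.05, phif = 1.00) {
  stopifnot(tG > 0, phi0 >= 0, phi0 < phif, phif <= 1)
  structure(list(phi0 = phi0, phif = phif, tG = tG),
            class = "gradient_program")
}

#' Instrument parameters
#'
#' @param t0 Column dead time (min), transit time of an unretained
#'   solute; must be positive.
#' @param tD Dwell time (min), delay before the programmed gradient
#'   reaches the column inlet; non-negative.
#' @return Object of class `instrument_params`.
#' @export
instrument_params <- function(t0, tD) {
  stopifnot(t0 > 0, tD >= 0)
  structure(list(t0 = t0, tD = tD), class = "instrument_params")
}

#' Retention factor at a given mobile-phase composition
#'
#' @param p An [lss_params()].
#' @param phi Organic volume fraction in `[0, 1]` (vectorized).
#' @return `k = 10^(logkw - S * phi)`, strictly decreasing in `phi`.
#' @export
k_at_phi <- function(p, phi) {
  stopifnot(all(phi >= 0 & phi <= 1))
  10^(p$logkw - p$S * phi)
}

# Vectorized closed-form gradient retention time. All arguments recycle
# elementwise. Returns tR in minutes; always finite (indefinite hold at
# phif). Branches:
#   pre-gradient  - elutes at initial composition before the ramp arrives
#   gradient      - elutes during the linear ramp (the LSS closed form)
#   post-gradient - elutes isocratically at phif after the ramp
.lss_tr_closed <- function(logkw, S, phi0, phif, tG, t0, tD) {
  n <- max(lengths(list(logkw, S, phi0, phif, tG, t0, tD)))
  logkw <- rep_len(logkw, n); S <- rep_len(S, n)
  phi0 <- rep_len(phi0, n);  phif <- rep_len(phif, n)
  tG <- rep_len(tG, n); t0 <- rep_len(t0, n); tD <- rep_len(tD, n)

  dphi <- phif - phi0
  k0 <- 10^(logkw - S * phi0)
  kf <- 10^(logkw - S * phif)
  ln10 <- log(10)

  tr <- numeric(n)
  # isocratic limit S -> 0 (also covers dphi == 0)
  iso <- (S * dphi) == 0
  tr[iso] <- t0[iso] * (1 + k0[iso])
  act <- which(!iso)
  if (length(act)) {
    # pre-gradient branch: entire migration done at phi0
    pre <- act[t0[act] * k0[act] <= tD[act]]
    tr[pre] <- t0[pre] * (1 + k0[pre])
    ramp <- setdiff(act, pre)
    if (length(ramp)) {
      b <- t0[ramp] * S[ramp] * dphi[ramp] / tG[ramp]   # gradient steepness
      f <- 1 - tD[ramp] / (t0[ramp] * k0[ramp])         # fraction left at ramp start
      arg <- ln10 * b * k0[ramp] * f + 1
      te <- (t0[ramp] / b) * log10(arg)                 # elution time into ramp
      during <- te <= tG[ramp]
      tr[ramp[during]] <- (t0[ramp] + tD[ramp] + te)[during]
      if (any(!during)) {
        rp <- ramp[!during]
        # migration fraction consumed over the full ramp, then finish at phif
        g <- (10^(S[rp] * dphi[rp]) - 1) /
             (k0[rp] * ln10 * S[rp] * dphi[rp] / tG[rp]) / t0[rp]
        rem <- pmax(1 - tD[rp] / (t0[rp] * k0[rp]) - g, 0)
        tr[rp] <- t0[rp] + tD[rp] + tG[rp] + kf[rp] * t0[rp] * rem
      }
    }
  }
  tr
}

#' Predict gradient retention time
#'
#' Solves the fundamental gradient-elution condition for the LSS model
#' (closed form; see [fit_lss_two_runs()] for the inverse). The dwell
#' period, the linear ramp and the post-gradient hold are all handled.
#'
#' @param p An [lss_params()].
#' @param g A [gradient_program()].
#' @param inst An [instrument_params()].
#' @param method `"closed"` (analytic) or `"quadrature"` (adaptive
#'   numerical integration of the elution condition; the two agree to
#'   better than 1e-4 min and the quadrature route exists as an internal
#'   cross-check).
#' @param hold Maximum post-gradient hold (min) before a species is
#'   flagged as non-eluting; default `Inf` never flags.
#' @param details Return a list with the elution branch instead of a bare
#'   number?
#' @return Retention time in minutes, or `NA` with a warning when elution
#'   would occur later than `tD + tG + t0 + hold`. With `details = TRUE`,
#'   a list with `tr`, `branch` and `eluted`.
#' @export
predict_gradient_tr <- function(p, g, inst,
                                method = c("closed", "quadrature"),
                                hold = Inf, details = FALSE) {
  method <- match.arg(method)
  tr <- if (method == "closed") {
    .lss_tr_closed(p$logkw, p$S, g$phi0, g$phif, g$tG, inst$t0, inst$tD)
  } else {
    .lss_tr_quadrature(p, g, inst)
  }
  k0 <- k_at_phi(p, g$phi0)
  branch <- if (p$S == 0 || inst$t0 * k0 <= inst$tD) {
    if (p$S == 0) "isocratic" else "pre_gradient"
  } else if (tr <= inst$t0 + inst$tD + g$tG) "gradient" else "post_gradient"
  eluted <- tr <= inst$tD + g$tG + inst$t0 + hold
  if (!eluted) {
    warning("species does not elute within the gradient plus a ",
            hold, " min hold (tR would be ", format(tr, digits = 6),
            " min)")
  }
  if (details) {
    list(tr = if (eluted) tr else NA_real_, branch = branch,
         eluted = eluted, tr_unbounded = tr)
  } else {
    if (eluted) tr else NA_real_
  }
}

# Numerical route: adaptive quadrature of dt/k along the programmed
# composition, bisection on the elution time. Absolute tolerance 1e-8 on
# the accumulated migration integral.
.lss_tr_quadrature <- function(p, g, inst) {
  kfun <- function(t) {
    phi <- ifelse(t <= inst$tD, g$phi0,
           ifelse(t <= inst$tD + g$tG,
                  g$phi0 + (g$phif - g$phi0) * (t - inst$tD) / g$tG,
                  g$phif))
    10^(p$logkw - p$S * phi)
  }
  migrated <- function(te) {       # integral_0^te dt / k, piecewise
    cuts <- sort(unique(pmin(pmax(c(0, inst$tD, inst$tD + g$tG, te), 0), te)))
    tot <- 0
    for (s in seq_len(length(cuts) - 1L)) {
      tot <- tot + integrate(function(t) 1 / kfun(t), cuts[s], cuts[s + 1L],
                             abs.tol = 1e-8, rel.tol = 1e-10)$value
    }
    tot
  }
  target <- inst$t0
  hi <- inst$tD + g$tG
  while (migrated(hi) < target) hi <- hi * 2 + 1
  te <- uniroot(function(t) migrated(t) - target, c(0, hi),
                tol = 1e-10)$root
  te + inst$t0
}

#' Fit LSS parameters from two gradient runs
#'
#' Inverts the gradient-elution model: given the retention times of one
#' species under two linear gradients of different duration (e.g. 30 and
#' 60 min), solves for the unique `(logkw, S)` that reproduces both.
#' This is the two-run lipophilicity determination normally performed by
#' method-development software. Deterministic: nested one-dimensional
#' root finding (for fixed S, `logkw` is solved by monotone bisection on
#' the first run; the outer root matches the second run).
#'
#' @param tr1,tr2 Observed retention times (min) under `g1` and `g2`.
#' @param g1,g2 [gradient_program()]s with different `tG`.
#' @param inst [instrument_params()].
#' @param logkw_box,S_box Search intervals.
#' @return An [lss_params()]; the fitted values reproduce both retention
#'   times through [predict_gradient_tr()] to better than 1e-3 min.
#' @export
fit_lss_two_runs <- function(tr1, g1, tr2, g2, inst,
                             logkw_box = c(-1, 8), S_box = c(0.1, 20)) {
  if (abs(g1$tG - g2$tG) < 1e-9) {
    stop("the two gradient programs must have different gradient times")
  }
  if (tr1 <= inst$t0 || tr2 <= inst$t0) {
    stop("retention times must exceed the dead time")
  }
  pred <- function(logkw, S, g) {
    .lss_tr_closed(logkw, S, g$phi0, g$phif, g$tG, inst$t0, inst$tD)
  }
  solve_logkw <- function(S, g, tr) {
    lo <- pred(logkw_box[1], S, g) - tr
    hi <- pred(logkw_box[2], S, g) - tr
    if (lo * hi > 0) return(NA_real_)
    uniroot(function(lk) pred(lk, S, g) - tr, logkw_box, tol = 1e-12)$root
  }
  resid2 <- function(S) {
    lk <- solve_logkw(S, g1, tr1)
    if (is.na(lk)) return(NA_real_)
    pred(lk, S, g2) - tr2
  }
  Sgrid <- seq(S_box[1], S_box[2], length.out = 120)
  r <- vapply(Sgrid, resid2, 0)
  ok <- which(!is.na(r))
  if (length(ok) < 2L) {
    stop("no admissible (logkw, S) in the search box reproduces run 1")
  }
  sgn <- sign(r[ok])
  flip <- which(diff(sgn) != 0)
  if (!length(flip)) {
    stop("no (logkw, S) in the box [", logkw_box[1], ",", logkw_box[2],
         "] x [", S_box[1], ",", S_box[2], "] reproduces both retention ",
         "times; residual range on run 2: ",
         paste(format(range(r[ok]), digits = 4), collapse = " to "),
         " min. Identical or inconsistent retention time pairs cannot ",
         "be fit by two distinct gradient programs.")
  }
  i <- ok[flip[1]]
  Shat <- uniroot(resid2, c(Sgrid[i], Sgrid[ok[flip[1] + 1L]]),
                  tol = 1e-12)$root
  lkhat <- solve_logkw(Shat, g1, tr1)
  fit <- lss_params(lkhat, Shat)
  err <- max(abs(pred(lkhat, Shat, g1) - tr1),
             abs(pred(lkhat, Shat, g2) - tr2))
  if (err > 1e-3) {
    stop("two-run fit did not converge: residual ",
         format(err, digits = 4), " min")
  }
  fit
}

#' Calibrate instrument dead and dwell time against a retention table
#'
#' The dead time t0 and dwell time tD of the original instrument are not
#' part of a published retention table, yet the two-run fit depends on
#' them. This routine recovers them by least squares: it predicts both
#' gradient retention times for every record from the record's tabulated
#' `(S, logkw)` and minimizes the summed squared difference to the
#' tabulated retention times over a deterministic (t0, tD) grid, followed
#' by Nelder-Mead refinement.
#'
#' @param records Data frame with columns `tr_30`, `tr_60`, `s_value`,
#'   `logkw` (one row per species), e.g. from
#'   [load_fixture]`("table2")`.
#' @param g30,g60 The two [gradient_program()]s.
#' @param t0_range,tD_range Search intervals (min).
#' @param coarse_step,fine_step Grid steps (min) for the global and the
#'   zoomed pass.
#' @return List with `t0`, `tD` ([instrument_params()] in `inst`), the
#'   attained objective (sum of squared retention-time residuals, min^2),
#'   `rmse` per retention time, and `n_records`. A single record leaves
#'   the problem formally determined (2 equations, 2 unknowns) but is
#'   flagged with a low-confidence warning.
#' @export
calibrate_instrument <- function(records, g30, g60,
                                 t0_range = c(0.5, 5), tD_range = c(0, 5),
                                 coarse_step = 0.05, fine_step = 0.01) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no retention records supplied for calibration")
  }
  if (nrow(records) == 1L) {
    warning("calibrating from a single record: formally solvable but ",
            "low confidence")
  }
  obj_grid <- function(t0v, tDv) {
    sse <- numeric(length(t0v))
    for (r in seq_len(nrow(records))) {
      p30 <- .lss_tr_closed(records$logkw[r], records$s_value[r],
                            g30$phi0, g30$phif, g30$tG, t0v, tDv)
      p60 <- .lss_tr_closed(records$logkw[r], records$s_value[r],
                            g60$phi0, g60$phif, g60$tG, t0v, tDv)
      sse <- sse + (p30 - records$tr_30[r])^2 + (p60 - records$tr_60[r])^2
    }
    sse
  }
  pass <- function(t0s, tDs) {
    grid <- expand.grid(t0 = t0s, tD = tDs)
    list(grid = grid, sse = obj_grid(grid$t0, grid$tD))
  }
  p1 <- pass(seq(t0_range[1], t0_range[2], by = coarse_step),
             seq(tD_range[1], tD_range[2], by = coarse_step))
  best <- p1$grid[which.min(p1$sse), ]
  p2 <- pass(
    seq(max(t0_range[1], best$t0 - coarse_step),
        min(t0_range[2], best$t0 + coarse_step), by = fine_step),
    seq(max(tD_range[1], best$tD - coarse_step),
        min(tD_range[2], best$tD + coarse_step), by = fine_step))
  best <- p2$grid[which.min(p2$sse), ]
  ref <- optim(c(best$t0, best$tD), function(par) {
    if (par[1] < t0_range[1] || par[1] > t0_range[2] ||
        par[2] < tD_range[1] || par[2] > tD_range[2]) return(1e10)
    obj_grid(par[1], par[2])
  }, method = "Nelder-Mead",
  control = list(reltol = 1e-12, maxit = 500))
  list(t0 = ref$par[1], tD = ref$par[2],
       inst = instrument_params(ref$par[1], max(0, ref$par[2])),
       objective = ref$value,
       rmse = sqrt(ref$value / (2 * nrow(records))),
       n_records = nrow(records))
}

#' Build a retention table by fitting every row
#'
#' Applies [fit_lss_two_runs()] to each (compound, isomer) row of a raw
#' retention-time table, mirroring the layout of a two-gradient
#' lipophilicity study: retention times under the 30- and 60-min
#' gradients in, fitted `s_value` and `logkw` appended.
#'
#' @param raw Data frame (or CSV path) with columns `compound`, `isomer`,
#'   `tr_30`, `tr_60`.
#' @param inst [instrument_params()].
#' @param g30,g60 [gradient_program()]s.
#' @return Data frame `compound, isomer, tr_30, tr_60, s_value, logkw`;
#'   rows whose fit fails carry `NA` and the failures are reported in the
#'   `"failures"` attribute rather than aborting the table.
#' @export
build_retention_table <- function(raw, inst,
                                  g30 = gradient_program(30),
                                  g60 = gradient_program(60)) {
  if (is.character(raw)) raw <- read.csv(raw, stringsAsFactors = FALSE)
  need <- c("compound", "isomer", "tr_30", "tr_60")
  if (!all(need %in% names(raw))) {
    stop("raw table must have columns ", paste(need, collapse = ", "))
  }
  out <- raw[, need, drop = FALSE]
  out$s_value <- rep(NA_real_, nrow(out))
  out$logkw <- rep(NA_real_, nrow(out))
  failures <- character()
  for (r in seq_len(nrow(out))) {
    fit <- tryCatch(
      fit_lss_two_runs(out$tr_30[r], g30, out$tr_60[r], g60, inst),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, paste0(out$compound[r], "-", out$isomer[r],
                                     ": ", conditionMessage(fit)))
    } else {
      out$s_value[r] <- fit$S
      out$logkw[r] <- fit$logkw
    }
  }
  attr(out, "failures") <- failures
  out
}
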