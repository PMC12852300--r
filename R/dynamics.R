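#' Assemble a kinetic model
#'
#' Couples the volume-scaled stoichiometric matrix with calibrated rate
#' laws into the right-hand side `U' = S R(U)` of the nonlinear ODE
#' system.  State variables are the local concentrations of the internal
#' components (the frame the matrix entries were scaled for); nutrient
#' concentrations are boundary parameters held constant between events.
#'
#' @param network a `bp_network`.
#' @param S its `bp_smatrix`.
#' @param laws calibrated laws from [build_kinetics()].
#' @param U_ss_local reference local concentrations of the internal
#'   components (uM).
#' @param nutrients named nutrient concentrations (uM).
#' @return an object of class `bp_model`.
#' @export
assemble_system <- function(network, S, laws, U_ss_local, nutrients) {
  missing <- setdiff(S$reaction_index, names(laws))
  if (length(missing))
    stop("missing rate law(s): ", paste(missing, collapse = ", "))
  laws <- laws[S$reaction_index]
  state_names <- S$component_index
  model <- structure(list(network = network, S = S, laws = laws,
                          U_ss = U_ss_local[state_names],
                          nutrients = nutrients,
                          alpha_cell = network$morphology$alpha_cell),
                     class = "bp_model")
  res <- model_rhs(model, model$U_ss)
  scale <- max(1, max(abs(rate_vector(model, model$U_ss))))
  if (max(abs(res)) > 1e-8 * scale)
    warning("right-hand side at U_ss is not zero (max |dU/dt| = ",
            format(max(abs(res))), "); U_ss is not a steady state")
  model
}

#' @export
print.bp_model <- function(x, ...) {
  cat("Kinetic model:", length(x$U_ss), "state variables,",
      length(x$laws), "rate laws,",
      sum(vapply(x$laws, function(l) length(l$regulation) > 0, TRUE)),
      "regulated reactions\n")
  invisible(x)
}

#' Rate vector at a state
#' @param model a `bp_model`.
#' @param U named local concentrations of the internal components.
#' @return named rates over all reactions.
#' @export
rate_vector <- function(model, U) {
  pool <- c(as.list(U), as.list(model$nutrients))
  vapply(model$laws, evaluate_rate, numeric(1), U_local = pool)
}

model_rhs <- function(model, U) {
  as.numeric(model$S$matrix %*% rate_vector(model, U))
}

#' Perturbation specification
#'
#' @param kind `concentration_step` (multiply one state variable),
#'   `nutrient_step` (multiply a boundary nutrient concentration) or
#'   `rate_constant_step` (multiply one reaction's k).
#' @param target component or reaction id.
#' @param factor multiplicative factor (> 0); 1.5 is +50%, 0.8 is -20%.
#' @param time event time in minutes (default 50).
#' @return object of class `bp_perturbation`.
#' @export
perturbation <- function(kind = c("concentration_step", "nutrient_step",
                                  "rate_constant_step"),
                         target, factor, time = 50) {
  kind <- match.arg(kind)
  if (factor <= 0) stop("factor must be > 0")
  if (time < 0) stop("time must be >= 0")
  structure(list(kind = kind, target = target, factor = factor,
                 time = time), class = "bp_perturbation")
}

apply_perturbation <- function(model, U, spec) {
  if (spec$kind == "concentration_step") {
    if (!spec$target %in% names(U))
      stop("unknown state component ", spec$target)
    U[[spec$target]] <- U[[spec$target]] * spec$factor
  } else if (spec$kind == "nutrient_step") {
    if (!spec$target %in% names(model$nutrients))
      stop("unknown nutrient ", spec$target)
    model$nutrients[[spec$target]] <-
      model$nutrients[[spec$target]] * spec$factor
  } else {
    if (!spec$target %in% names(model$laws))
      stop("unknown reaction ", spec$target)
    model$laws[[spec$target]]$k <- model$laws[[spec$target]]$k * spec$factor
  }
  list(model = model, U = U)
}

#' Integrate the kinetic model
#'
#' Stiff adaptive integration (lsoda) of `U' = S R(U)`.  Perturbation
#' events are applied as exact state or parameter discontinuities by
#' splitting the integration at the event times.  Small negative
#' excursions (within the absolute tolerance) are clamped to zero;
#' larger negatives or a solver failure yield an `undetermined`
#' trajectory with diagnostics.
#'
#' @param model a `bp_model`.
#' @param U0 initial local concentrations; defaults to the model's U_ss.
#' @param t_end horizon in minutes.
#' @param events list of [perturbation()]s.
#' @param dt output sampling interval (min).
#' @param rtol,atol relative and absolute solver tolerances.
#' @return object of class `bp_trajectory`: `times`, `states` (matrix,
#'   one column per component, local uM), `events`, `diagnostics`.
#' @export
integrate_model <- function(model, U0 = NULL, t_end = 500, events = list(),
                            dt = 1, rtol = 1e-8, atol = 1e-10) {
  if (t_end <= 0) stop("t_end must be > 0")
  if (is.null(U0)) U0 <- model$U_ss
  U0 <- U0[names(model$U_ss)]
  if (any(U0 < 0)) stop("initial state must be nonnegative")
  events <- events[order(vapply(events, `[[`, numeric(1), "time"))]
  breaks <- unique(c(0, vapply(events, `[[`, numeric(1), "time"), t_end))
  breaks <- breaks[breaks <= t_end]
  if (max(breaks) < t_end) breaks <- c(breaks, t_end)

  deriv <- function(t, y, parms) {
    y[y < 0 & y > -atol] <- 0
    list(parms$rhs(y))
  }
  cur_model <- model
  U <- U0
  all_times <- numeric(0)
  all_states <- NULL
  diagnostics <- character(0)
  ok <- TRUE
  for (seg in seq_len(length(breaks) - 1)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1]
    for (ev in events) {
      if (abs(ev$time - t0) < 1e-12) {
        upd <- apply_perturbation(cur_model, U, ev)
        cur_model <- upd$model; U <- upd$U
      }
    }
    times <- unique(c(seq(t0, t1, by = dt), t1))
    rhs_fun <- local({
      m <- cur_model
      function(y) {
        names(y) <- names(m$U_ss)
        model_rhs(m, y)
      }
    })
    sol <- withCallingHandlers(
      try(deSolve::ode(y = unname(U), times = times, func = deriv,
                       parms = list(rhs = rhs_fun), method = "lsoda",
                       rtol = rtol, atol = atol), silent = TRUE),
      warning = function(w) {
        # step collapse etc. is diagnostic payload, not a user warning;
        # the outcome classifier interprets it
        diagnostics <<- c(diagnostics, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(sol, "try-error") || anyNA(sol) ||
        nrow(sol) < length(times)) {
      ok <- FALSE
      diagnostics <- c(diagnostics,
                       sprintf("solver failure in segment [%g, %g]", t0, t1))
      if (inherits(sol, "try-error") || !is.matrix(sol) || nrow(sol) < 2)
        break
      sol <- sol[stats::complete.cases(sol), , drop = FALSE]
    }
    seg_states <- sol[, -1, drop = FALSE]
    if (min(seg_states) < -1000 * atol) {
      ok <- FALSE
      diagnostics <- c(diagnostics, sprintf(
        "negative concentration %.3g in segment [%g, %g]",
        min(seg_states), t0, t1))
      break
    }
    seg_states[seg_states < 0] <- 0
    keep <- if (seg == 1) seq_len(nrow(sol)) else -1L
    all_times <- c(all_times, sol[keep, 1])
    all_states <- rbind(all_states, seg_states[keep, , drop = FALSE])
    U <- stats::setNames(seg_states[nrow(seg_states), ], names(model$U_ss))
    if (!ok) break  # keep the partial segment for diagnosis, go no further
  }
  colnames(all_states) <- names(model$U_ss)
  structure(list(times = all_times, states = all_states,
                 events = events, complete = ok,
                 diagnostics = diagnostics, model_U_ss = model$U_ss),
            class = "bp_trajectory")
}

#' @export
print.bp_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "time points over [",
      min(x$times), ",", max(x$times), "] min,",
      ncol(x$states), "components",
      if (!x$complete) "(incomplete)" else "", "\n")
  invisible(x)
}

#' Normalized view of a trajectory
#' @param traj a `bp_trajectory`.
#' @param U_ref reference state (defaults to the model's U_ss).
#' @return matrix of `U(t)/U_ref`, component-wise.
#' @export
normalize_trajectory <- function(traj, U_ref = NULL) {
  if (is.null(U_ref)) U_ref <- traj$model_U_ss
  sweep(traj$states, 2, U_ref[colnames(traj$states)], "/")
}

#' Classify the outcome of a trajectory
#'
#' Inspects the tail of the trajectory (default the last 20%):
#' `at_reference_steady_state` when all normalized deviations stay below
#' `ref_tol`; `blowup` when any normalized component exceeds
#' `blowup_threshold` or the integration aborted; `oscillation` when the
#' tail shows a sustained sign-alternating derivative with relative
#' amplitude above `ref_tol`; `new_steady_state` when the tail derivative
#' has settled; otherwise `undetermined`.
#'
#' @param traj a `bp_trajectory`.
#' @param model the `bp_model` that produced it.
#' @param tail_window fraction of the trajectory to inspect.
#' @param ref_tol relative tolerance for "at reference".
#' @param blowup_threshold normalized blowup threshold.
#' @return object of class `bp_outcome` with `class`, `final`,
#'   `ratios` (new/reference, for steady outcomes), `convergence_time`.
#' @export
classify_outcome <- function(traj, model, tail_window = 0.2,
                             ref_tol = 1e-3, blowup_threshold = 1e3) {
  U_ref <- model$U_ss
  norm <- normalize_trajectory(traj, U_ref)
  nt <- nrow(norm)
  tail_idx <- seq.int(max(1L, floor(nt * (1 - tail_window))), nt)
  final <- traj$states[nt, ]
  dev <- abs(norm - 1)

  out <- function(cls, ratios = NULL, conv = NA_real_) {
    structure(list(class = cls, final = final, ratios = ratios,
                   convergence_time = conv, diagnostics = traj$diagnostics),
              class = "bp_outcome")
  }
  if (!traj$complete || max(norm, na.rm = TRUE) > blowup_threshold)
    return(out("blowup"))
  if (max(dev[tail_idx, ]) < ref_tol) {
    ok <- apply(dev, 1, max) < ref_tol
    first_ok <- if (all(ok)) 1L else max(which(!ok)) + 1L
    conv <- traj$times[min(first_ok, nt)]
    return(out("at_reference_steady_state", ratios = final / U_ref,
               conv = conv))
  }
  # oscillation: sustained sign alternation of the derivative in the tail
  tail_states <- norm[tail_idx, , drop = FALSE]
  osc <- FALSE
  for (jc in seq_len(ncol(tail_states))) {
    d <- diff(tail_states[, jc])
    amp <- max(tail_states[, jc]) - min(tail_states[, jc])
    flips <- sum(diff(sign(d[d != 0])) != 0)
    if (amp > ref_tol && flips >= 4) { osc <- TRUE; break }
  }
  if (osc) return(out("oscillation"))
  # settled somewhere else?
  dU <- model_rhs(model, stats::setNames(final, names(U_ref)))
  scale <- max(abs(traj$states))
  if (max(abs(dU)) < 1e-6 * max(1, scale))
    return(out("new_steady_state", ratios = final / U_ref))
  out("undetermined")
}

#' @export
print.bp_outcome <- function(x, ...) {
  cat("Outcome:", x$class,
      if (!is.na(x$convergence_time))
        paste0("(converged by t = ", signif(x$convergence_time, 4), " min)"),
      "\n")
  invisible(x)
}

#' Run a perturbation experiment
#'
#' Integrates the model with one perturbation applied and classifies the
#' outcome; for steady outcomes a per-component ratio table
#' (new/reference) is attached.
#'
#' @param model a `bp_model`.
#' @param spec a [perturbation()].
#' @param t_end horizon in minutes.
#' @param ... passed to [integrate_model()].
#' @return list with `trajectory`, `outcome` and `ratios` (data.frame or
#'   NULL).
#' @export
perturbation_experiment <- function(model, spec, t_end = 2000, ...) {
  traj <- integrate_model(model, t_end = t_end, events = list(spec), ...)
  outcome <- classify_outcome(traj, model)
  ratios <- NULL
  if (!is.null(outcome$ratios))
    ratios <- data.frame(component = names(model$U_ss),
                         ratio = as.numeric(outcome$ratios),
                         stringsAsFactors = FALSE)
  list(trajectory = traj, outcome = outcome, ratios = ratios)
}

#' Verify a candidate steady state
#'
#' @param model a `bp_model`.
#' @param U candidate local concentrations (defaults to the model U_ss).
#' @param tol relative pass threshold.
#' @return list with per-component derivatives, the scaled residual and
#'   `pass`.
#' @export
verify_steady_state <- function(model, U = NULL, tol = 1e-8) {
  if (is.null(U)) U <- model$U_ss
  U <- U[names(model$U_ss)]
  dU <- model_rhs(model, U)
  names(dU) <- names(model$U_ss)
  scale <- max(1, max(abs(rate_vector(model, U))))
  resid <- max(abs(dU)) / scale
  list(dU = dU, residual = resid, pass = resid < tol,
       worst = names(dU)[which.max(abs(dU))])
}
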