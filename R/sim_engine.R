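#' Construct an instantiation
#'
#' An instantiation assigns concrete parameter values and non-negative
#' initial values, turning a model into a simulable closed system.
#'
#' @param parameter_values named numeric vector/list of parameter values.
#' @param initial_values named numeric vector/list of initial state values
#'   (non-negative); states not listed fall back to the model's declared
#'   initial amounts.
#' @return An object of class \code{"sf_instantiation"}.
#' @export
instantiation <- function(parameter_values = list(), initial_values = list()) {
  pv <- unlist(parameter_values)
  iv <- unlist(initial_values)
  if (length(pv) > 0L && (is.null(names(pv)) || any(!nzchar(names(pv)))))
    stop("parameter values must be named", call. = FALSE)
  if (length(iv) > 0L && (is.null(names(iv)) || any(!nzchar(names(iv)))))
    stop("initial values must be named", call. = FALSE)
  if (any(!is.finite(iv)) || any(iv < 0))
    stop("initial values must be finite and non-negative: ",
         paste(names(iv)[!is.finite(iv) | iv < 0], collapse = ", "),
         call. = FALSE)
  structure(list(parameter_values = as.list(pv), initial_values = as.list(iv)),
            class = "sf_instantiation")
}

instantiation_to_list <- function(inst)
  list(parameter_values = inst$parameter_values,
       initial_values = inst$initial_values)

instantiation_from_list <- function(x)
  instantiation(x$parameter_values %||% list(), x$initial_values %||% list())

#' Construct a simulation setup
#'
#' Describes a uniform time-course experiment: output grid, recorded
#' integration-algorithm identity (a KiSAO annotation -- metadata, not a
#' dispatch key), instantaneous state perturbations, and named
#' post-processing expressions evaluated pointwise on the raw data.
#'
#' @param t_start,t_end simulation interval in minutes (\code{t_end >
#'   t_start}).
#' @param step output grid step in minutes (> 0); decoupled from the
#'   integrator's internal steps.
#' @param algorithm an \code{\link{annotation}} in the \code{kisao}
#'   namespace.
#' @param perturbations list of lists \code{list(time =, symbol =, delta =)};
#'   each applied as an instantaneous state increment at its time.
#' @param postprocess named list of unevaluated expressions (or strings) over
#'   state symbols and algebraic definitions.
#' @return An object of class \code{"sf_simulation_setup"}.
#' @export
simulation_setup <- function(t_start = 0, t_end, step,
                             algorithm = annotation("kisao", "KISAO_0000019"),
                             perturbations = list(),
                             postprocess = list()) {
  if (!is.finite(t_start) || !is.finite(t_end) || t_end <= t_start)
    stop("t_end must be greater than t_start", call. = FALSE)
  if (!is.finite(step) || step <= 0)
    stop("step must be positive", call. = FALSE)
  if (step > t_end - t_start)
    stop("step exceeds the simulation interval", call. = FALSE)
  stopifnot(is_annotation(algorithm))
  for (p in perturbations) {
    if (is.null(p$time) || is.null(p$symbol) || is.null(p$delta))
      stop("each perturbation needs time, symbol and delta", call. = FALSE)
    if (p$time < t_start || p$time > t_end)
      stop("perturbation time ", p$time, " outside [t_start, t_end]",
           call. = FALSE)
  }
  postprocess <- lapply(postprocess, function(e)
    if (is.character(e)) parse_expr_text(e, "postprocess expression") else e)
  if (length(postprocess) > 0L && (is.null(names(postprocess)) ||
                                   any(!nzchar(names(postprocess)))))
    stop("postprocess expressions must be named", call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end, step = step,
                 algorithm = algorithm, perturbations = perturbations,
                 postprocess = postprocess),
            class = "sf_simulation_setup")
}

setup_to_list <- function(s)
  list(t_start = s$t_start, t_end = s$t_end, step = s$step,
       algorithm = annotation_to_list(s$algorithm),
       perturbations = s$perturbations,
       postprocess = lapply(s$postprocess, deparse1))

setup_from_list <- function(x)
  simulation_setup(t_start = x$t_start, t_end = x$t_end, step = x$step,
                   algorithm = annotation_from_list(x$algorithm),
                   perturbations = x$perturbations %||% list(),
                   postprocess = x$postprocess %||% list())

#' Close a model over an instantiation
#'
#' Checks that every declared parameter has a value and every initial value
#' is non-negative, then compiles the programme's right-hand sides (with
#' parameter values bound) into a derivative function for the integrator.
#'
#' @param model an \code{\link{ode_model}}.
#' @param inst an \code{\link{instantiation}}; values override the model's
#'   declared parameter values and initial amounts.
#' @return An object of class \code{"sf_sim_instance"}.
#' @export
instantiate <- function(model, inst = instantiation()) {
  stopifnot(inherits(model, "sf_ode_model"), inherits(inst, "sf_instantiation"))
  prog <- build_programme(model)
  params <- model$parameters
  for (p in names(inst$parameter_values)) {
    if (!p %in% names(params))
      stop("instantiation sets unknown parameter ", sQuote(p), call. = FALSE)
    params[[p]] <- inst$parameter_values[[p]]
  }
  unset <- names(params)[vapply(params, function(v) is.null(v) || is.na(v),
                                logical(1))]
  if (length(unset) > 0L)
    stop("model not fully instantiated; unset parameter(s): ",
         paste(unset, collapse = ", "), call. = FALSE)
  x0 <- model_initial_values(model)
  for (s in names(inst$initial_values)) {
    if (!s %in% names(x0))
      stop("initial value for unknown state ", sQuote(s), call. = FALSE)
    if (inst$initial_values[[s]] < 0)
      stop("initial value of ", s, " must be non-negative", call. = FALSE)
    x0[[s]] <- inst$initial_values[[s]]
  }
  pv <- unlist(params)
  structure(list(model = model, programme = prog,
                 parameters = pv, x0 = x0,
                 constants = prog$constants,
                 rhs_fun = compile_rhs(prog, pv),
                 jac_fun = compile_jacobian(prog, pv)),
            class = "sf_sim_instance")
}

#' @export
print.sf_sim_instance <- function(x, ...) {
  cat("<sim instance>", x$model$id, "-", length(x$x0), "states,",
      length(x$parameters), "parameters\n")
  invisible(x)
}

# generate a fast derivative function: parameter and constant-species values
# are baked in as literals, algebraic definitions evaluated in order
compile_rhs <- function(prog, params) {
  state <- prog$state_symbols
  lines <- c("function(t, y, parms) {",
             sprintf("%s <- y[[%d]]", state, seq_along(state)))
  for (nm in names(prog$constants))
    lines <- c(lines, sprintf("%s <- %.17g", nm, prog$constants[[nm]]))
  for (nm in names(params))
    lines <- c(lines, sprintf("%s <- %.17g", nm, params[[nm]]))
  for (nm in prog$algebraic_order)
    lines <- c(lines, sprintf("%s <- %s", nm, deparse1(prog$algebraic[[nm]])))
  lines <- c(lines,
             sprintf("list(c(%s))",
                     paste(vapply(prog$rhs[state], deparse1, character(1)),
                           collapse = ", ")),
             "}")
  eval(parse(text = paste(lines, collapse = "\n")), envir = baseenv())
}

compile_jacobian <- function(prog, params) {
  state <- prog$state_symbols
  jex <- programme_jacobian_exprs(prog)
  n <- length(state)
  lines <- c("function(y) {",
             sprintf("%s <- y[[%d]]", state, seq_along(state)))
  for (nm in names(prog$constants))
    lines <- c(lines, sprintf("%s <- %.17g", nm, prog$constants[[nm]]))
  for (nm in names(params))
    lines <- c(lines, sprintf("%s <- %.17g", nm, params[[nm]]))
  entries <- vapply(seq_len(n * n), function(k) {
    i <- (k - 1L) %% n + 1L; j <- (k - 1L) %/% n + 1L
    deparse1(jex[[i, j]])
  }, character(1))
  lines <- c(lines,
             sprintf("matrix(c(%s), %d, %d)", paste(entries, collapse = ", "),
                     n, n),
             "}")
  eval(parse(text = paste(lines, collapse = "\n")), envir = baseenv())
}

#' Run a uniform time course
#'
#' Integrates the instantiated model with a stiff-capable solver
#' (\code{deSolve::lsoda}) and samples the solution exactly on the output
#' grid.  Perturbations are applied as instantaneous state increments;
#' zero-delta perturbations are no-ops and are dropped before integration.
#' States are required to stay above \code{-1e-9} (mass-action systems with
#' non-negative initial values should remain non-negative; a violation
#' signals solver trouble and raises an error rather than being clipped).
#'
#' @param instance an \code{\link{instantiate}}d model.
#' @param setup a \code{\link{simulation_setup}}.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return An object of class \code{"sf_trajectory"}: \code{index} (the time
#'   grid), \code{raw} (matrix time x states) and \code{outcome} (matrix of
#'   post-processed series; filled by \code{\link{postprocess}}, which
#'   \code{run_timecourse} calls automatically when the setup carries
#'   post-processing expressions).
#' @export
run_timecourse <- function(instance, setup, rtol = 1e-9, atol = 1e-9) {
  stopifnot(inherits(instance, "sf_sim_instance"),
            inherits(setup, "sf_simulation_setup"))
  times <- seq(setup$t_start, setup$t_end, by = setup$step)
  if (times[length(times)] < setup$t_end - 1e-12)
    times <- c(times, setup$t_end)
  perts <- Filter(function(p) p$delta != 0, setup$perturbations)
  events <- NULL
  if (length(perts) > 0L) {
    for (p in perts)
      if (!p$symbol %in% instance$programme$state_symbols)
        stop("perturbation targets unknown state ", sQuote(p$symbol),
             call. = FALSE)
    events <- list(data = data.frame(
      var = vapply(perts, `[[`, character(1), "symbol"),
      time = vapply(perts, `[[`, numeric(1), "time"),
      value = vapply(perts, `[[`, numeric(1), "delta"),
      method = "add", stringsAsFactors = FALSE))
    times <- sort(unique(c(times, events$data$time)))
  }
  y0 <- unlist(instance$x0)
  out <- suppressWarnings(deSolve::lsoda(
    y = y0, times = times, func = instance$rhs_fun, parms = NULL,
    rtol = rtol, atol = atol, events = events, maxsteps = 50000L))
  n_ok <- nrow(out)
  if (n_ok < length(times) || anyNA(out[n_ok, ]))
    stop("solver failure: integration stopped at t = ",
         format(out[max(1L, n_ok - 1L), 1L]),
         " (step-size underflow or repeated convergence failure)",
         call. = FALSE)
  grid <- seq(setup$t_start, setup$t_end, by = setup$step)
  keep <- match(round(grid, 12), round(out[, 1L], 12))
  raw <- out[keep, -1L, drop = FALSE]
  rownames(raw) <- NULL
  if (min(raw) < -1e-9)
    stop("negative state beyond tolerance (min = ", format(min(raw)),
         "): solver trouble on a mass-action-type system", call. = FALSE)
  traj <- structure(list(index = grid, raw = raw, outcome = NULL,
                         model_id = instance$model$id),
                    class = "sf_trajectory")
  if (length(setup$postprocess) > 0L)
    traj <- postprocess(traj, instance$model, setup$postprocess,
                        parameters = instance$parameters)
  traj
}

#' @export
print.sf_trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$index), "time points, states:",
      paste(colnames(x$raw), collapse = ", "), "\n")
  if (!is.null(x$outcome))
    cat("  outcome columns:", paste(colnames(x$outcome), collapse = ", "), "\n")
  invisible(x)
}

#' Post-process raw simulation data into outcome series
#'
#' Evaluates named expressions pointwise over the raw state columns (with
#' the model's algebraic definitions, parameters and constant pools in
#' scope) and stores them as outcome columns.  The raw data is unchanged.
#'
#' @param traj an \code{sf_trajectory}.
#' @param model the \code{\link{ode_model}} that produced it.
#' @param expressions named list of unevaluated expressions or strings;
#'   defaults to none (returns \code{traj} unchanged).
#' @param parameters named parameter values (e.g. from the instance that
#'   produced the trajectory); override the model's declared values.
#' @return The trajectory with \code{outcome} filled.
#' @export
postprocess <- function(traj, model, expressions = list(),
                        parameters = list()) {
  stopifnot(inherits(traj, "sf_trajectory"), inherits(model, "sf_ode_model"))
  if (length(expressions) == 0L) return(traj)
  expressions <- lapply(expressions, function(e)
    if (is.character(e)) parse_expr_text(e, "postprocess expression") else e)
  prog <- build_programme(model)
  known <- c(prog$state_symbols, names(prog$constants),
             names(model$parameters), names(model$algebraic), "t")
  env <- list2env(c(as.list(prog$constants),
                    Filter(function(v) !is.null(v) && !is.na(v),
                           model$parameters),
                    as.list(parameters)))
  names_raw <- colnames(traj$raw)
  for (j in seq_along(names_raw)) assign(names_raw[[j]], traj$raw[, j], envir = env)
  assign("t", traj$index, envir = env)
  # only the algebraic definitions the expressions (transitively) use are
  # evaluated, so unrelated definitions cannot fail the computation
  used <- unique(unlist(lapply(expressions, expr_symbols)))
  repeat {
    more <- intersect(names(model$algebraic), used)
    grown <- union(used, unlist(lapply(prog$algebraic[more], expr_symbols)))
    if (length(grown) == length(used)) break
    used <- grown
  }
  for (nm in intersect(prog$algebraic_order, used))
    assign(nm, eval(prog$algebraic[[nm]], env), envir = env)
  cols <- lapply(names(expressions), function(nm) {
    e <- expressions[[nm]]
    bad <- setdiff(expr_symbols(e), known)
    if (length(bad) > 0L)
      stop("postprocess expression ", sQuote(nm),
           " references unknown symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    v <- eval(e, env)
    if (length(v) == 1L) v <- rep(v, length(traj$index))
    v
  })
  outcome <- do.call(cbind, cols)
  colnames(outcome) <- names(expressions)
  traj$outcome <- outcome
  traj
}

#' Export a trajectory as delimited text
#'
#' Writes a tab-separated table with a header row; time is the first column,
#' followed by the raw state columns and any outcome columns.
#'
#' @param traj an \code{sf_trajectory}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sf_trajectory"))
  tab <- cbind(time = traj$index, traj$raw)
  if (!is.null(traj$outcome)) tab <- cbind(tab, traj$outcome)
  utils::write.table(format(as.data.frame(tab), digits = 15, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
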