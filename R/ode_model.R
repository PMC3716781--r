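#' Construct a species
#'
#' @param id symbol (string) naming the species; must be unique in a model.
#' @param name human-readable name.
#' @param initial_amount non-negative initial amount (model units).
#' @param constant if \code{TRUE} the species is a boundary pool whose amount
#'   never changes (it appears in kinetic laws but gets no rate equation).
#' @param annotations list of \code{\link{annotation}} objects.
#' @return An object of class \code{"sf_species"}.
#' @export
species <- function(id, name = id, initial_amount = 0, constant = FALSE,
                    annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.finite(initial_amount) || initial_amount < 0)
    stop("initial_amount of ", id, " must be a non-negative number", call. = FALSE)
  if (is_annotation(annotations)) annotations <- list(annotations)
  structure(list(id = id, name = name, initial_amount = initial_amount,
                 constant = isTRUE(constant), annotations = annotations),
            class = "sf_species")
}

#' Construct a reaction
#'
#' @param id reaction identifier.
#' @param reactants,products named integer vectors mapping species id to
#'   (positive) stoichiometry; may be empty.
#' @param modifiers character vector of species ids appearing in the kinetic
#'   law without being consumed or produced.
#' @param kinetic_law an unevaluated R expression (see \code{\link{quote}}) in
#'   species, parameter and algebraic symbols, using only \code{+ - * /} and
#'   integer powers.
#' @param name human-readable name.
#' @param annotations list of \code{\link{annotation}} objects.
#' @return An object of class \code{"sf_reaction"}.
#' @export
reaction <- function(id, reactants = integer(), products = integer(),
                     modifiers = character(), kinetic_law, name = id,
                     annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_stoich <- function(x, what) {
    if (length(x) == 0L) return(invisible())
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, " of ", id, " must be a named vector", call. = FALSE)
    if (any(x <= 0) || any(x != round(x)))
      stop(what, " stoichiometries of ", id, " must be positive integers",
           call. = FALSE)
  }
  check_stoich(reactants, "reactants")
  check_stoich(products, "products")
  expr_check_supported(kinetic_law, paste0("kinetic law of ", id))
  if (is_annotation(annotations)) annotations <- list(annotations)
  structure(list(id = id, name = name,
                 reactants = reactants, products = products,
                 modifiers = modifiers, kinetic_law = kinetic_law,
                 annotations = annotations),
            class = "sf_reaction")
}

#' Construct an ODE model from a reaction network
#'
#' The container behind the structural facets: species (entities), reactions
#' with kinetic laws (relations), global parameters and algebraic definitions
#' (assignment rules), from which the ODE programme is derived.
#'
#' @param id model identifier.
#' @param species list of \code{\link{species}} objects.
#' @param parameters named list mapping parameter symbol to value, or to
#'   \code{NA} for declared-but-unset parameters.
#' @param algebraic named list of unevaluated expressions defining derived
#'   symbols (must be acyclic).
#' @param reactions list of \code{\link{reaction}} objects.
#' @param name human-readable name.
#' @param units free-text amount/time units (no unit conversion is performed).
#' @param annotations list of \code{\link{annotation}}s at model level.
#' @return An object of class \code{"sf_ode_model"}.
#' @export
ode_model <- function(id, species = list(), parameters = list(),
                      algebraic = list(), reactions = list(), name = id,
                      units = "dimensionless amount; time in min",
                      annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sp_ids <- vapply(species, `[[`, character(1), "id")
  if (anyDuplicated(sp_ids)) stop("duplicate species ids", call. = FALSE)
  if (length(parameters) > 0L &&
      (is.null(names(parameters)) || any(!nzchar(names(parameters)))))
    stop("parameters must be named", call. = FALSE)
  alg_order <- algebraic_order(algebraic)   # errors on cycles
  known <- c(sp_ids, names(parameters), names(algebraic), "t")
  for (a in names(algebraic)) {
    expr_check_supported(algebraic[[a]], paste0("algebraic definition of ", a))
    bad <- setdiff(expr_symbols(algebraic[[a]]), known)
    if (length(bad) > 0L)
      stop("algebraic definition of ", a, " references undeclared symbol(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  for (r in reactions) {
    if (!inherits(r, "sf_reaction")) stop("reactions must be reaction objects",
                                          call. = FALSE)
    bad_sp <- setdiff(c(names(r$reactants), names(r$products), r$modifiers),
                      sp_ids)
    if (length(bad_sp) > 0L)
      stop("reaction ", r$id, " references unknown species: ",
           paste(bad_sp, collapse = ", "), call. = FALSE)
    bad <- setdiff(expr_symbols(r$kinetic_law), known)
    if (length(bad) > 0L)
      stop("kinetic law of reaction ", r$id,
           " references undeclared symbol(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is_annotation(annotations)) annotations <- list(annotations)
  structure(list(id = id, name = name, species = species,
                 parameters = parameters, algebraic = algebraic,
                 algebraic_order = alg_order,
                 reactions = reactions, independent_variable = "t",
                 units = units, annotations = annotations),
            class = "sf_ode_model")
}

# topological order of algebraic definitions; error on cycles
algebraic_order <- function(algebraic) {
  nms <- names(algebraic)
  if (length(nms) == 0L) return(character())
  deps <- lapply(algebraic, function(e) intersect(expr_symbols(e), nms))
  order <- character()
  remaining <- nms
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(n)
      all(deps[[n]] %in% order), logical(1))]
    if (length(ready) == 0L)
      stop("cyclic algebraic definitions among: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' @export
print.sf_ode_model <- function(x, ...) {
  n_const <- sum(vapply(x$species, `[[`, logical(1), "constant"))
  cat("<ode model>", x$id, "\n")
  cat("  species:", length(x$species),
      sprintf("(%d constant/boundary)", n_const), "\n")
  cat("  reactions:", length(x$reactions),
      " parameters:", length(x$parameters),
      " algebraic:", length(x$algebraic), "\n")
  invisible(x)
}

model_species_ids <- function(model)
  vapply(model$species, `[[`, character(1), "id")

model_state_ids <- function(model) {
  ids <- model_species_ids(model)
  ids[!vapply(model$species, `[[`, logical(1), "constant")]
}

model_constant_values <- function(model) {
  const <- vapply(model$species, `[[`, logical(1), "constant")
  vals <- vapply(model$species[const], `[[`, numeric(1), "initial_amount")
  names(vals) <- model_species_ids(model)[const]
  vals
}

model_initial_values <- function(model) {
  ids <- model_state_ids(model)
  vals <- vapply(model$species, `[[`, numeric(1), "initial_amount")
  names(vals) <- model_species_ids(model)
  vals[ids]
}

#' Derive the ODE programme from a reaction network
#'
#' The programme of a kinetic model is the set of ODEs implied by its
#' reactions: for each non-constant species, the right-hand side is the sum
#' over reactions of the net stoichiometry (products minus reactants) times
#' the reaction's kinetic law.  Constant (boundary) species are excluded from
#' the state.
#'
#' @param model an \code{\link{ode_model}}.
#' @return An object of class \code{"sf_programme"} with elements
#'   \code{state_symbols} (ordered character vector) and \code{rhs}
#'   (named list of unevaluated expressions), plus the model's algebraic
#'   definitions and parameters for evaluation.
#' @export
build_programme <- function(model) {
  stopifnot(inherits(model, "sf_ode_model"))
  state <- model_state_ids(model)
  contrib <- setNames(vector("list", length(state)), state)
  for (r in model$reactions) {
    net <- setNames(numeric(length(state)), state)
    for (s in names(r$reactants))
      if (s %in% state) net[[s]] <- net[[s]] - r$reactants[[s]]
    for (s in names(r$products))
      if (s %in% state) net[[s]] <- net[[s]] + r$products[[s]]
    for (s in state) {
      if (net[[s]] == 0) next
      term <- if (abs(net[[s]]) == 1) r$kinetic_law
              else call("*", abs(net[[s]]), r$kinetic_law)
      contrib[[s]] <- c(contrib[[s]],
                        list(list(sign = as.integer(sign(net[[s]])),
                                  term = term)))
    }
  }
  rhs <- lapply(contrib, function(terms) terms_to_expr(terms %||% list()))
  structure(list(state_symbols = state, rhs = rhs,
                 algebraic = model$algebraic,
                 algebraic_order = model$algebraic_order,
                 parameters = model$parameters,
                 constants = model_constant_values(model),
                 model_id = model$id),
            class = "sf_programme")
}

#' @export
print.sf_programme <- function(x, ...) {
  cat("<programme>", length(x$state_symbols), "state equations\n")
  for (s in x$state_symbols)
    cat("  d", s, "/dt = ", deparse1(x$rhs[[s]]), "\n", sep = "")
  invisible(x)
}

programme_eval_env <- function(prog, state, extra = list()) {
  env <- list2env(c(as.list(state), as.list(prog$constants),
                    Filter(function(v) !is.na(v), prog$parameters), extra))
  for (nm in prog$algebraic_order)
    assign(nm, eval(prog$algebraic[[nm]], env), envir = env)
  env
}

#' Instantaneous drift of a candidate conserved total
#'
#' Evaluates the sum of the right-hand sides of the given member states at a
#' state point: the time derivative of the weighted total (all weights 1).
#' For a conserved moiety (e.g. total cdc2 in the Tyson model) the result is
#' identically zero.
#'
#' @param prog a programme from \code{\link{build_programme}}.
#' @param members character vector of state symbols.
#' @param state named numeric vector assigning every state symbol (parameter
#'   overrides may be appended).
#' @return The numeric drift of the total at \code{state}.
#' @export
conserved_total_residual <- function(prog, members, state) {
  stopifnot(inherits(prog, "sf_programme"))
  bad <- setdiff(members, prog$state_symbols)
  if (length(bad) > 0L)
    stop("unknown state symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  env <- programme_eval_env(prog, state)
  sum(vapply(members, function(s) eval(prog$rhs[[s]], env), numeric(1)))
}

#' Symbolic drift of a candidate conserved total
#'
#' Sums the right-hand sides of the member states and cancels syntactically
#' identical terms of opposite sign.  Returns the surviving expression; the
#' number \code{0} means the total is conserved identically, term by term.
#'
#' @inheritParams conserved_total_residual
#' @return An unevaluated expression, or the number \code{0}.
#' @export
conserved_total_symbolic <- function(prog, members) {
  stopifnot(inherits(prog, "sf_programme"))
  bad <- setdiff(members, prog$state_symbols)
  if (length(bad) > 0L)
    stop("unknown state symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  sum_exprs_cancelled(prog$rhs[members])
}

# substitute algebraic definitions into the rhs, yielding closed-form
# expressions over state symbols and parameters only
programme_closed_rhs <- function(prog) {
  defs <- prog$algebraic[rev(prog$algebraic_order)]
  lapply(prog$rhs, function(e) expr_substitute(e, defs))
}

# symbolic Jacobian d rhs_i / d state_j as a matrix of expressions
programme_jacobian_exprs <- function(prog) {
  closed <- programme_closed_rhs(prog)
  state <- prog$state_symbols
  jac <- matrix(list(), length(state), length(state),
                dimnames = list(state, state))
  for (i in seq_along(state))
    for (j in seq_along(state))
      jac[[i, j]] <- stats::D(closed[[state[[i]]]], state[[j]])
  jac
}
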