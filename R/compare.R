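# Facet-based comparison of two models: structural annotation overlap,
# behavioural class-set relation, and numerical verification of an
# abstraction (variable-lumping) mapping between two models' trajectories.

#' Structural comparison of two facet records
#'
#' Per facet (cell, side), intersects the resource-annotation sets of the
#' two records by (namespace, identifier); no ontology-graph inference is
#' performed, so a shared entry is exact-identifier evidence.  Free text is
#' compared only by exact string match and flagged as weak evidence.
#'
#' @param recA,recB \code{\link{facet_record}}s.
#' @return An object of class \code{"sf_structural_report"}: per (cell,
#'   side), character vectors \code{shared}, \code{source_only},
#'   \code{target_only} of annotation keys, and a \code{text_match} flag.
#' @export
compare_structure <- function(recA, recB) {
  stopifnot(inherits(recA, "sf_facet_record"), inherits(recB, "sf_facet_record"))
  cell_anns <- function(rec, cell, side) {
    keys <- paste(cell, side, .facet_aspects[[cell]][[side]], sep = ".")
    anns <- unlist(lapply(keys, function(k) {
      s <- rec$slots[[k]]
      if (is.null(s)) list() else s$annotations
    }), recursive = FALSE)
    unique(vapply(anns %||% list(), annotation_key, character(1)))
  }
  cell_text <- function(rec, cell, side) {
    keys <- paste(cell, side, .facet_aspects[[cell]][[side]], sep = ".")
    txt <- unlist(lapply(keys, function(k) rec$slots[[k]]$text))
    paste(txt %||% character(), collapse = "\n")
  }
  cells <- list()
  for (cell in .facet_cells) {
    for (side in .facet_sides) {
      a <- cell_anns(recA, cell, side)
      b <- cell_anns(recB, cell, side)
      ta <- cell_text(recA, cell, side)
      cells[[paste(cell, side, sep = ".")]] <- list(
        shared = intersect(a, b),
        source_only = setdiff(a, b),
        target_only = setdiff(b, a),
        text_match = nzchar(ta) && identical(ta, cell_text(recB, cell, side)))
    }
  }
  structure(list(source = recA$model_id, target = recB$model_id,
                 cells = cells),
            class = "sf_structural_report")
}

#' @export
print.sf_structural_report <- function(x, ...) {
  cat("<structural comparison>", x$source, "vs", x$target, "\n")
  for (nm in names(x$cells)) {
    c <- x$cells[[nm]]
    if (length(c$shared) + length(c$source_only) + length(c$target_only) == 0L)
      next
    cat("  ", nm, ": shared {", paste(c$shared, collapse = ", "),
        "}  source-only {", paste(c$source_only, collapse = ", "),
        "}  target-only {", paste(c$target_only, collapse = ", "), "}",
        if (c$text_match) "  [exact text match: weak evidence]" else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Relation between two sets of dynamics classes
#'
#' @param classesA,classesB character vectors of class labels (or lists of
#'   dynamics-class objects) produced under the same protocol family.
#' @return One of \code{"equal"}, \code{"subset"}, \code{"superset"},
#'   \code{"disjoint"}, \code{"overlapping"}.
#' @export
compare_behaviour <- function(classesA, classesB) {
  lab <- function(x) {
    if (is.list(x)) x <- vapply(x, function(c)
      if (inherits(c, "sf_dynamics_class")) c$label else as.character(c),
      character(1))
    unique(as.character(x))
  }
  a <- lab(classesA); b <- lab(classesB)
  if (setequal(a, b)) return("equal")
  if (all(a %in% b)) return("subset")
  if (all(b %in% a)) return("superset")
  if (length(intersect(a, b)) == 0L) return("disjoint")
  "overlapping"
}

#' Construct a variable mapping
#'
#' Assigns each target-model symbol an expression over source-model symbols
#' and algebraic definitions -- the formal content of an abstraction
#' relation (e.g. lumping the Tyson six-variable model onto the two-variable
#' model via u = M/CT, v = (Y + pM + M)/CT, alpha = k4p/k4).
#'
#' @param assignments named list of unevaluated expressions or strings;
#'   names are target symbols.
#' @return An object of class \code{"sf_variable_mapping"}.
#' @export
variable_mapping <- function(assignments) {
  if (length(assignments) == 0L || is.null(names(assignments)))
    stop("assignments must be a non-empty named list", call. = FALSE)
  assignments <- lapply(assignments, function(e)
    if (is.character(e)) parse_expr_text(e, "mapping expression") else e)
  structure(list(assignments = assignments), class = "sf_variable_mapping")
}

#' Numerically verify an abstraction mapping between two models
#'
#' Simulates source and target on the same time grid, applies the variable
#' mapping to the source trajectory, and reports per-mapped-variable maximum
#' and root-mean-square deviation from the target trajectory.  The verdict
#' is \code{consistent} iff the maximum deviation stays below
#' \code{tolerance}; consistency is expected only under the abstraction's
#' additional assumptions and is inexact in general.
#'
#' @param source_instance,target_instance \code{\link{instantiate}}d source
#'   and target models.
#' @param mapping a \code{\link{variable_mapping}} from source symbols to
#'   target symbols.
#' @param setup a \code{\link{simulation_setup}} (used for both runs; the
#'   grids therefore match).
#' @param tolerance maximum tolerated deviation.
#' @return An object of class \code{"sf_abstraction_report"} with
#'   \code{deviation} (data frame: variable, max, rms), \code{verdict} and
#'   the tolerance.
#' @export
check_abstraction <- function(source_instance, target_instance, mapping,
                              setup, tolerance = 0.05) {
  stopifnot(inherits(mapping, "sf_variable_mapping"),
            inherits(setup, "sf_simulation_setup"))
  src <- run_timecourse(source_instance, setup)
  tgt <- run_timecourse(target_instance, setup)
  if (length(src$index) != length(tgt$index) ||
      max(abs(src$index - tgt$index)) > 1e-12)
    stop("time grid mismatch between source and target runs", call. = FALSE)
  # evaluate mapping expressions on the source trajectory (columns are
  # vectors, algebraic definitions and parameters in scope)
  sprog <- source_instance$programme
  env <- list2env(c(as.list(sprog$constants),
                    as.list(source_instance$parameters)))
  for (j in seq_len(ncol(src$raw)))
    assign(colnames(src$raw)[[j]], src$raw[, j], envir = env)
  for (nm in sprog$algebraic_order)
    assign(nm, eval(sprog$algebraic[[nm]], env), envir = env)
  tprog <- target_instance$programme
  tenv <- list2env(c(as.list(tprog$constants),
                     as.list(target_instance$parameters)))
  for (j in seq_len(ncol(tgt$raw)))
    assign(colnames(tgt$raw)[[j]], tgt$raw[, j], envir = tenv)
  for (nm in tprog$algebraic_order)
    assign(nm, eval(tprog$algebraic[[nm]], tenv), envir = tenv)
  rows <- list()
  for (v in names(mapping$assignments)) {
    known <- ls(env)
    bad <- setdiff(expr_symbols(mapping$assignments[[v]]), known)
    if (length(bad) > 0L)
      stop("mapping for ", v, " references unknown source symbol(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!exists(v, envir = tenv, inherits = FALSE))
      stop("mapping target ", sQuote(v),
           " is neither a state nor an algebraic symbol of the target model",
           call. = FALSE)
    mapped <- eval(mapping$assignments[[v]], env)
    target <- get(v, envir = tenv)
    if (length(mapped) == 1L) mapped <- rep(mapped, length(tgt$index))
    if (length(target) == 1L) target <- rep(target, length(tgt$index))
    d <- abs(mapped - target)
    rows[[v]] <- data.frame(variable = v, max = max(d),
                            rms = sqrt(mean(d^2)), stringsAsFactors = FALSE)
  }
  deviation <- do.call(rbind, rows)
  rownames(deviation) <- NULL
  structure(list(source = source_instance$model$id,
                 target = target_instance$model$id,
                 deviation = deviation,
                 tolerance = tolerance,
                 verdict = if (max(deviation$max) < tolerance) "consistent"
                           else "inconsistent",
                 note = paste("consistency is expected only under the",
                              "abstraction's additional assumptions;",
                              "the mapping is inexact in general")),
            class = "sf_abstraction_report")
}

#' @export
print.sf_abstraction_report <- function(x, ...) {
  cat("<abstraction check>", x$source, "->", x$target, ":", x$verdict,
      sprintf("(tolerance %g)\n", x$tolerance))
  print(x$deviation, row.names = FALSE)
  invisible(x)
}
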