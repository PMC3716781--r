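# DYML: a small declarative dynamics-assertion language.  A document names a
# model and lists statements, each relating parameter constraints (closed
# intervals or fixed values) to an asserted qualitative dynamics class.  The
# concrete syntax is a versioned YAML dialect defined by this package.

#' Construct a DYML statement
#'
#' @param constraints named list; each element either a fixed numeric value
#'   or a length-2 numeric vector \code{c(lo, hi)} (a non-empty closed
#'   interval).
#' @param asserted asserted class label (\code{"stable_fixed_point"},
#'   \code{"limit_cycle_oscillation"}, \code{"excitable_switch"}).
#' @param note optional free-text comment.
#' @return An object of class \code{"sf_dyml_statement"}.
#' @export
dyml_statement <- function(constraints, asserted, note = NULL) {
  if (length(constraints) == 0L || is.null(names(constraints)) ||
      any(!nzchar(names(constraints))))
    stop("constraints must be a non-empty named list", call. = FALSE)
  for (nm in names(constraints)) {
    v <- constraints[[nm]]
    if (!is.numeric(v) || !length(v) %in% 1:2 || any(!is.finite(v)))
      stop("constraint on ", nm, " must be a fixed value or c(lo, hi)",
           call. = FALSE)
    if (length(v) == 2L && v[[2L]] < v[[1L]])
      stop("empty interval for ", nm, ": hi < lo", call. = FALSE)
  }
  asserted <- match.arg(asserted, c("stable_fixed_point",
                                    "limit_cycle_oscillation",
                                    "excitable_switch"))
  structure(list(constraints = constraints, asserted = asserted, note = note),
            class = "sf_dyml_statement")
}

#' Construct a DYML document
#'
#' @param model_ref identifier of the model the statements are about.
#' @param statements list of \code{\link{dyml_statement}}s.
#' @param seed optional default sampling seed for \code{\link{check_dyml}}.
#' @return An object of class \code{"sf_dyml"}.
#' @export
dyml_document <- function(model_ref, statements = list(), seed = NULL) {
  stopifnot(is.character(model_ref), nzchar(model_ref))
  for (s in statements)
    if (!inherits(s, "sf_dyml_statement"))
      stop("statements must be dyml_statement objects", call. = FALSE)
  structure(list(model_ref = model_ref, statements = statements,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "sf_dyml")
}

#' @export
print.sf_dyml <- function(x, ...) {
  cat("<DYML document> model:", x$model_ref, "-", length(x$statements),
      "statement(s)\n")
  for (s in x$statements) {
    cons <- vapply(names(s$constraints), function(nm) {
      v <- s$constraints[[nm]]
      if (length(v) == 1L) paste0(nm, " = ", format(v))
      else paste0(nm, " in [", format(v[[1L]]), ", ", format(v[[2L]]), "]")
    }, character(1))
    cat("  ", paste(cons, collapse = ", "), " => ", s$asserted, "\n", sep = "")
  }
  invisible(x)
}

dyml_to_list <- function(doc) {
  list(format = "semfacets-dyml", format_version = 1L,
       model_ref = doc$model_ref, seed = doc$seed,
       statements = lapply(doc$statements, function(s)
         list(constraints = lapply(s$constraints, as.numeric),
              asserted = s$asserted, note = s$note)))
}

dyml_from_list <- function(x) {
  if (!identical(x$format, "semfacets-dyml"))
    stop("not a semfacets DYML document", call. = FALSE)
  dyml_document(x$model_ref,
                statements = lapply(x$statements %||% list(), function(s)
                  dyml_statement(lapply(s$constraints, as.numeric),
                                 s$asserted, s$note)),
                seed = x$seed)
}

#' Read/write DYML documents
#'
#' @param doc an \code{sf_dyml} document.
#' @param path file path.
#' @return \code{write_dyml}: \code{path}, invisibly; \code{read_dyml}: the
#'   document.
#' @export
write_dyml <- function(doc, path) {
  stopifnot(inherits(doc, "sf_dyml"))
  writeLines(yaml::as.yaml(precision = 17L, x = dyml_to_list(doc)), path)
  invisible(path)
}

#' @rdname write_dyml
#' @export
read_dyml <- function(path) {
  dyml_from_list(yaml::read_yaml(path))
}

#' Check DYML assertions against a model
#'
#' For each statement, samples parameter points satisfying its constraints
#' (Latin-hypercube over the constraint box, seeded and reproducible),
#' classifies the model at each point under the protocol, and passes iff
#' every sample classifies to the asserted class.  Counterexample points are
#' reported.  A statement whose constraint region is degenerate-empty passes
#' vacuously with a warning.
#'
#' @param doc an \code{sf_dyml} document.
#' @param model an \code{\link{ode_model}} (its id should match
#'   \code{doc$model_ref}).
#' @param base an \code{\link{instantiation}} supplying unconstrained
#'   parameters and initial values.
#' @param protocol a \code{\link{classification_protocol}}.
#' @param n_samples samples per statement.
#' @param seed sampling seed; defaults to the document's seed, and is
#'   mandatory in one place or the other.
#' @return An object of class \code{"sf_dyml_report"}: per-statement
#'   verdicts with observed labels and counterexamples, plus an overall
#'   \code{pass} flag.
#' @export
check_dyml <- function(doc, model, base, protocol = classification_protocol(),
                       n_samples = 16L, seed = NULL) {
  stopifnot(inherits(doc, "sf_dyml"), inherits(model, "sf_ode_model"))
  seed <- seed %||% doc$seed
  if (is.null(seed))
    stop("a sampling seed is required (in the document or as an argument)",
         call. = FALSE)
  verdicts <- list()
  for (si in seq_along(doc$statements)) {
    st <- doc$statements[[si]]
    unknown <- setdiff(names(st$constraints), names(model$parameters))
    if (length(unknown) > 0L)
      stop("statement ", si, " constrains unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    lo <- vapply(st$constraints, function(v) v[[1L]], numeric(1))
    hi <- vapply(st$constraints, function(v) v[[length(v)]], numeric(1))
    free <- hi > lo
    d <- sum(free)
    set.seed(seed + si)
    if (d > 0L) {
      u <- lhs::randomLHS(n_samples, d)
    } else {
      u <- matrix(numeric(0), n_samples, 0L)
    }
    labels <- character(n_samples)
    points <- vector("list", n_samples)
    for (k in seq_len(n_samples)) {
      p <- lo
      if (d > 0L) {
        # sample log-uniformly on strictly positive boxes (rate constants)
        fl <- names(st$constraints)[free]
        p[fl] <- ifelse(lo[fl] > 0,
                        exp(log(lo[fl]) + u[k, ] * (log(hi[fl]) - log(lo[fl]))),
                        lo[fl] + u[k, ] * (hi[fl] - lo[fl]))
      }
      spec <- base
      for (nm in names(p)) spec$parameter_values[[nm]] <- p[[nm]]
      labels[[k]] <- tryCatch(
        classify(instantiate(model, spec), protocol)$class$label,
        error = function(e) "unclassified")
      points[[k]] <- p
    }
    pass <- all(labels == st$asserted)
    verdicts[[si]] <- list(statement = st, pass = pass,
                           labels = labels,
                           counterexamples = points[labels != st$asserted])
  }
  structure(list(model_ref = doc$model_ref, verdicts = verdicts,
                 pass = all(vapply(verdicts, `[[`, logical(1), "pass")),
                 n_samples = n_samples, seed = seed),
            class = "sf_dyml_report")
}

#' @export
print.sf_dyml_report <- function(x, ...) {
  cat("<DYML check>", x$model_ref, "-",
      if (x$pass) "PASS" else "FAIL", "\n")
  for (i in seq_along(x$verdicts)) {
    v <- x$verdicts[[i]]
    cat(sprintf("  statement %d (%s): %s", i, v$statement$asserted,
                if (v$pass) "pass" else
                  paste0("fail, ", length(v$counterexamples),
                         " counterexample(s)")), "\n")
  }
  invisible(x)
}
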