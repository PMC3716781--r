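#' Two-parameter regime scan
#'
#' Classifies the model's dynamics on the grid spanned by two parameter
#' axes: cell (i, j) is \code{\link{classify}} at the base instantiation
#' overridden with \code{axis1$values[i]} and \code{axis2$values[j]}.
#' Solver failures in a cell downgrade to an \code{unclassified} cell with a
#' diagnostic; the scan continues.  Boundaries are the grid edges between
#' neighbouring cells with different labels.
#'
#' @param model an \code{\link{ode_model}}.
#' @param axis1,axis2 lists \code{list(symbol =, values =)}; symbols must be
#'   model parameters, values finite and sorted.
#' @param base an \code{\link{instantiation}} supplying all remaining
#'   parameter and initial values.
#' @param protocol a \code{\link{classification_protocol}}.
#' @return An object of class \code{"sf_regime_map"}: \code{axes},
#'   \code{labels} (matrix of class labels, rows follow axis1),
#'   \code{details} (list-matrix of classify results), \code{boundaries}
#'   (data frame of differing-label edges) and the scan's base/protocol.
#' @export
scan <- function(model, axis1, axis2, base, protocol = classification_protocol()) {
  stopifnot(inherits(model, "sf_ode_model"))
  for (ax in list(axis1, axis2)) {
    if (!ax$symbol %in% names(model$parameters))
      stop("axis symbol ", sQuote(ax$symbol), " is not a model parameter",
           call. = FALSE)
    if (any(!is.finite(ax$values)) || is.unsorted(ax$values))
      stop("axis values must be finite and sorted", call. = FALSE)
  }
  n1 <- length(axis1$values); n2 <- length(axis2$values)
  labels <- matrix(NA_character_, n1, n2)
  details <- vector("list", n1 * n2)
  dim(details) <- c(n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      inst_spec <- base
      inst_spec$parameter_values[[axis1$symbol]] <- axis1$values[[i]]
      inst_spec$parameter_values[[axis2$symbol]] <- axis2$values[[j]]
      res <- tryCatch(
        classify(instantiate(model, inst_spec), protocol),
        error = function(e) list(
          class = dynamics_class("unclassified"),
          characteristics = characteristics(diagnostic = conditionMessage(e))))
      labels[i, j] <- res$class$label
      details[[i, j]] <- res
    }
  }
  structure(list(axes = list(axis1, axis2), labels = labels,
                 details = details, boundaries = map_boundaries(labels),
                 base = base, protocol = protocol, model_id = model$id),
            class = "sf_regime_map")
}

map_boundaries <- function(labels) {
  n1 <- nrow(labels); n2 <- ncol(labels)
  rows <- list()
  add <- function(i1, j1, i2, j2) {
    if (labels[i1, j1] != labels[i2, j2])
      rows[[length(rows) + 1L]] <<- data.frame(
        i1 = i1, j1 = j1, i2 = i2, j2 = j2,
        label1 = labels[i1, j1], label2 = labels[i2, j2],
        stringsAsFactors = FALSE)
  }
  if (n1 > 1L) for (i in seq_len(n1 - 1L)) for (j in seq_len(n2)) add(i, j, i + 1L, j)
  if (n2 > 1L) for (i in seq_len(n1)) for (j in seq_len(n2 - 1L)) add(i, j, i, j + 1L)
  if (length(rows) == 0L)
    return(data.frame(i1 = integer(), j1 = integer(), i2 = integer(),
                      j2 = integer(), label1 = character(),
                      label2 = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @export
print.sf_regime_map <- function(x, ...) {
  cat("<regime map>", x$axes[[1L]]$symbol, "x", x$axes[[2L]]$symbol, ":",
      nrow(x$labels), "x", ncol(x$labels), "cells\n")
  print(table(x$labels))
  cat(" ", nrow(x$boundaries), "boundary edges\n")
  invisible(x)
}

#' Instance factory for parameter-space operations
#'
#' @param model an \code{\link{ode_model}}.
#' @param base an \code{\link{instantiation}}.
#' @return A function taking a named list/vector of parameter overrides and
#'   returning an \code{\link{instantiate}}d model.
#' @export
make_instance_factory <- function(model, base) {
  force(model); force(base)
  function(overrides = list()) {
    spec <- base
    for (p in names(overrides))
      spec$parameter_values[[p]] <- overrides[[p]]
    instantiate(model, spec)
  }
}

# geometric interpolation between two positive parameter points (the axes of
# a regime scan are log-spaced); falls back to linear for non-positive values
interp_params <- function(p1, p2, s) {
  mapply(function(a, b) {
    if (a > 0 && b > 0) exp((1 - s) * log(a) + s * log(b))
    else (1 - s) * a + s * b
  }, p1, p2, SIMPLIFY = TRUE)
}

#' Locate and type bifurcation boundaries of a regime map
#'
#' Every boundary edge between a stable-fixed-point cell and a
#' limit-cycle-oscillation cell is refined by bisection along the parameter
#' segment connecting the two cells: the equilibrium is continued by Newton
#' iteration (warm-started from the stable side), and the bisection tracks
#' the leading eigenvalue real part of its Jacobian until it crosses zero
#' within tolerance.  Such a crossing is a Hopf bifurcation and is labelled
#' with the TEDDY term for it (TEDDY_0000074); edges between other label
#' pairs, or edges where the eigenvalue does not change sign or the
#' equilibrium branch is lost, are labelled \code{unknown} with a
#' diagnostic.
#'
#' @param map an \code{sf_regime_map} from \code{\link{scan}}.
#' @param factory an instance factory from
#'   \code{\link{make_instance_factory}} (matching the scan's model and
#'   base).
#' @param tol bisection stops when |Re(lambda)| at the midpoint equilibrium
#'   falls below \code{tol}.
#' @param max_iter maximum bisection steps per edge.
#' @return A list with one entry per boundary edge: the edge row, the
#'   boundary \code{label} (\code{"hopf"} or \code{"unknown"}), the TEDDY
#'   annotation for Hopf boundaries, the crossing parameter point and the
#'   residual eigenvalue real part.
#' @export
locate_bifurcation <- function(map, factory, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(map, "sf_regime_map"))
  edges <- map$boundaries
  out <- list()
  if (nrow(edges) == 0L) return(out)
  sym1 <- map$axes[[1L]]$symbol; sym2 <- map$axes[[2L]]$symbol
  for (k in seq_len(nrow(edges))) {
    e <- edges[k, ]
    lbls <- c(e$label1, e$label2)
    is_hopf_pair <- setequal(lbls, c("stable_fixed_point",
                                     "limit_cycle_oscillation"))
    if (!is_hopf_pair) {
      out[[k]] <- list(edge = e, label = "unknown", teddy = NULL,
                       point = NULL, re_lambda = NA_real_,
                       diagnostic = paste("boundary", lbls[1L], "|", lbls[2L],
                                          "is not typed by this method"))
      next
    }
    # orient the segment from the stable side to the oscillating side
    if (e$label1 == "stable_fixed_point") {
      idx_s <- c(e$i1, e$j1); idx_o <- c(e$i2, e$j2)
    } else {
      idx_s <- c(e$i2, e$j2); idx_o <- c(e$i1, e$j1)
    }
    p_s <- c(map$axes[[1L]]$values[[idx_s[1L]]],
             map$axes[[2L]]$values[[idx_s[2L]]])
    p_o <- c(map$axes[[1L]]$values[[idx_o[1L]]],
             map$axes[[2L]]$values[[idx_o[2L]]])
    names(p_s) <- names(p_o) <- c(sym1, sym2)
    eq_guess <- map$details[[idx_s[1L], idx_s[2L]]]$characteristics$steady_state_values
    res <- tryCatch({
      lam_at <- function(s, guess) {
        inst <- factory(as.list(interp_params(p_s, p_o, s)))
        eq <- newton_equilibrium(inst, guess)
        list(lam = max(Re(eigen(inst$jac_fun(eq), only.values = TRUE)$values)),
             eq = eq)
      }
      a <- 0; b <- 1
      ra <- lam_at(a, eq_guess)
      rb <- lam_at(b, ra$eq)
      if (sign(ra$lam) == sign(rb$lam))
        stop("eigenvalue real part does not change sign across the edge")
      guess <- ra$eq
      mid <- NULL
      for (it in seq_len(max_iter)) {
        m <- (a + b) / 2
        rm <- lam_at(m, guess)
        guess <- rm$eq
        mid <- rm
        if (abs(rm$lam) < tol) break
        if (sign(rm$lam) == sign(ra$lam)) { a <- m; ra <- rm } else { b <- m }
      }
      if (abs(mid$lam) >= tol)
        stop("bisection did not reach the eigenvalue tolerance")
      list(edge = e, label = "hopf",
           teddy = annotation("teddy", "TEDDY_0000074"),
           point = interp_params(p_s, p_o, (a + b) / 2),
           equilibrium = mid$eq, re_lambda = mid$lam, diagnostic = NULL)
    }, error = function(err)
      list(edge = e, label = "unknown", teddy = NULL, point = NULL,
           re_lambda = NA_real_, diagnostic = conditionMessage(err)))
    out[[k]] <- res
  }
  out
}

#' Export a regime map as delimited text
#'
#' Writes the grid of class labels (rows follow the first axis) and the
#' boundary edge list as tab-separated tables.
#'
#' @param map an \code{sf_regime_map}.
#' @param path base file path; the grid goes to \code{path} and the boundary
#'   list to \code{paste0(path, ".boundaries.tsv")}.
#' @return \code{path}, invisibly.
#' @export
write_regime_map <- function(map, path) {
  stopifnot(inherits(map, "sf_regime_map"))
  grid <- as.data.frame(map$labels)
  colnames(grid) <- paste0(map$axes[[2L]]$symbol, "=",
                           format(map$axes[[2L]]$values, digits = 8))
  grid <- cbind(setNames(data.frame(format(map$axes[[1L]]$values, digits = 8)),
                         map$axes[[1L]]$symbol), grid)
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(map$boundaries, paste0(path, ".boundaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
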