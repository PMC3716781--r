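# Arithmetic-expression utilities for kinetic laws and algebraic definitions.
#
# Supported operator set is deliberately small: + - * / and integer powers,
# plus parentheses, numbers and symbols.  This is sufficient for mass-action
# and Hill-free polynomial/rational kinetics; anything else is rejected
# explicitly rather than silently misread.

.allowed_ops <- c("+", "-", "*", "/", "^", "(")

expr_check_supported <- function(e, context = "expression") {
  if (is.numeric(e) || is.name(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (!op %in% .allowed_ops)
      stop("unsupported operator or function ", sQuote(op), " in ", context,
           " (supported: + - * / ^ and parentheses)", call. = FALSE)
    if (op == "^") {
      exponent <- e[[3L]]
      if (!(is.numeric(exponent) && exponent == round(exponent)))
        stop("only integer powers are supported in ", context, call. = FALSE)
    }
    for (i in seq_along(e)[-1L]) expr_check_supported(e[[i]], context)
    return(invisible(TRUE))
  }
  stop("unsupported expression element in ", context, ": ",
       deparse(e), call. = FALSE)
}

expr_symbols <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e))
    return(unique(unlist(lapply(as.list(e)[-1L], expr_symbols))))
  character()
}

# recursively substitute definitions (named list of expressions) into e
expr_substitute <- function(e, defs) {
  if (length(defs) == 0L) return(e)
  repeat {
    syms <- expr_symbols(e)
    hit <- intersect(syms, names(defs))
    if (length(hit) == 0L) return(e)
    e <- eval(call("substitute", e,
                   lapply(defs[hit], function(d) call("(", d))))
  }
}

# flatten an expression into a list of (sign, term) over top-level + / -
signed_terms <- function(e, sign = 1L) {
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "+" && length(e) == 3L)
      return(c(signed_terms(e[[2L]], sign), signed_terms(e[[3L]], sign)))
    if (op == "-" && length(e) == 3L)
      return(c(signed_terms(e[[2L]], sign), signed_terms(e[[3L]], -sign)))
    if (op == "-" && length(e) == 2L)
      return(signed_terms(e[[2L]], -sign))
    if (op == "+" && length(e) == 2L)
      return(signed_terms(e[[2L]], sign))
    if (op == "(")
      return(signed_terms(e[[2L]], sign))
  }
  list(list(sign = sign, term = e))
}

# cancel syntactically identical terms of opposite sign; returns the list of
# surviving signed terms (possibly empty -> the sum is identically zero)
cancel_terms <- function(terms) {
  keys <- vapply(terms, function(t) deparse1(t$term), character(1))
  net <- tapply(vapply(terms, `[[`, integer(1), "sign"), keys, sum)
  out <- list()
  for (k in names(net)) {
    n <- net[[k]]
    if (n == 0) next
    term <- terms[[match(k, keys)]]$term
    out[[length(out) + 1L]] <- list(sign = sign(n), term = term, mult = abs(n))
  }
  out
}

terms_to_expr <- function(terms) {
  if (length(terms) == 0L) return(0)
  e <- NULL
  for (t in terms) {
    piece <- t$term
    if (!is.null(t$mult) && t$mult != 1L) piece <- call("*", t$mult, piece)
    if (is.null(e)) {
      e <- if (t$sign < 0) call("-", piece) else piece
    } else {
      e <- if (t$sign < 0) call("-", e, piece) else call("+", e, piece)
    }
  }
  e
}

# sum a list of expressions, dropping syntactic cancellations
sum_exprs_cancelled <- function(exprs) {
  terms <- list()
  for (e in exprs) terms <- c(terms, signed_terms(e))
  terms_to_expr(cancel_terms(terms))
}

# numeric equality of two expressions at n random positive states
expr_equal_numeric <- function(e1, e2, symbols, n = 100L, tol = 1e-9,
                               seed = 1L, defs = list(), params = list()) {
  set.seed(seed)
  for (i in seq_len(n)) {
    env <- as.list(stats::runif(length(symbols), 0.05, 2))
    names(env) <- symbols
    env <- c(env, params)
    ee <- list2env(env)
    for (nm in names(defs)) assign(nm, eval(defs[[nm]], ee), envir = ee)
    v1 <- eval(e1, ee)
    v2 <- eval(e2, ee)
    if (!is.finite(v1) || !is.finite(v2)) return(FALSE)
    if (abs(v1 - v2) > tol * max(1, abs(v1), abs(v2))) return(FALSE)
  }
  TRUE
}

# ---------------------------------------------------------------------------
# MathML (content markup) conversion for the SBML kineticLaw subset
# ---------------------------------------------------------------------------

.mathml_op <- c("+" = "plus", "-" = "minus", "*" = "times",
                "/" = "divide", "^" = "power")

expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    if (e == round(e) && abs(e) < 2^31)
      return(sprintf('<cn type="integer">%d</cn>', as.integer(e)))
    return(sprintf("<cn>%.17g</cn>", e))
  }
  if (is.name(e)) return(sprintf("<ci>%s</ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(expr_to_mathml(e[[2L]]))
    tag <- .mathml_op[[op]]
    if (is.null(tag)) stop("cannot serialize operator ", sQuote(op),
                           " to MathML", call. = FALSE)
    args <- vapply(as.list(e)[-1L], expr_to_mathml, character(1))
    return(paste0("<apply><", tag, "/>", paste(args, collapse = ""), "</apply>"))
  }
  stop("cannot serialize expression to MathML: ", deparse(e), call. = FALSE)
}

mathml_wrap <- function(e) {
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
         expr_to_mathml(e), "</math>")
}

mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L)
      stop("MathML math element must have exactly one child", call. = FALSE)
    return(mathml_to_expr(kids[[1L]]))
  }
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    opname <- xml2::xml_name(kids[[1L]])
    op <- names(.mathml_op)[match(opname, .mathml_op)]
    if (is.na(op))
      stop("unsupported MathML operator ", sQuote(opname), call. = FALSE)
    args <- lapply(kids[-1L], mathml_to_expr)
    if (length(args) == 1L) {
      if (op == "-") return(call("-", args[[1L]]))
      if (op == "+") return(args[[1L]])
      stop("MathML operator ", sQuote(opname), " needs two operands",
           call. = FALSE)
    }
    e <- args[[1L]]
    for (i in seq_along(args)[-1L]) e <- call(op, e, args[[i]])
    return(e)
  }
  stop("unsupported MathML element ", sQuote(name), call. = FALSE)
}

# parse an expression given as text (package-defined documents use plain
# infix text rather than MathML)
parse_expr_text <- function(text, context = "expression") {
  e <- tryCatch(str2lang(text),
                error = function(err) stop("cannot parse ", context, ": ",
                                           sQuote(text), call. = FALSE))
  expr_check_supported(e, context)
  e
}
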