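#' Resource annotations (MIRIAM URN / identifiers.org URL)
#'
#' An annotation is a cross-reference from a model component to an entry in a
#' biological database or ontology, identified by a registry collection name
#' (namespace, e.g. \code{"uniprot"}, \code{"obo.go"}, \code{"taxonomy"},
#' \code{"biomodels.sbo"}, \code{"teddy"}, \code{"kisao"}) and an accession
#' string within that collection.  An optional qualifier records the relation
#' between the component and the referenced entry (\code{"is"},
#' \code{"isVersionOf"}, ...).
#'
#' Annotations round-trip losslessly through two textual forms: the MIRIAM URN
#' \code{urn:miriam:<namespace>:<identifier>} (with \code{:} and \code{%}
#' percent-encoded inside the identifier segment) and the resolver URL
#' \code{http://identifiers.org/<namespace>/<identifier>}.
#'
#' @param namespace registry collection name; non-empty string.
#' @param identifier accession within the collection; non-empty string.
#' @param qualifier optional relation tag, or \code{NULL}.
#' @return An object of class \code{"sf_annotation"}.
#' @examples
#' a <- annotation("uniprot", "P04551", qualifier = "is")
#' format_urn(a)   # "urn:miriam:uniprot:P04551"
#' format_url(a)   # "http://identifiers.org/uniprot/P04551"
#' @export
annotation <- function(namespace, identifier, qualifier = NULL) {
  if (!is.character(namespace) || length(namespace) != 1L || !nzchar(namespace))
    stop("annotation namespace must be a non-empty string", call. = FALSE)
  if (!is.character(identifier) || length(identifier) != 1L || !nzchar(identifier))
    stop("annotation identifier must be a non-empty string", call. = FALSE)
  if (!is.null(qualifier)) qualifier <- as.character(qualifier)[1L]
  structure(list(namespace = namespace, identifier = identifier,
                 qualifier = qualifier),
            class = "sf_annotation")
}

#' @export
print.sf_annotation <- function(x, ...) {
  q <- if (is.null(x$qualifier)) "" else paste0(" [", x$qualifier, "]")
  cat("<annotation> ", format_urn(x), q, "\n", sep = "")
  invisible(x)
}

#' @export
format.sf_annotation <- function(x, ...) format_urn(x)

is_annotation <- function(x) inherits(x, "sf_annotation")

# identifier-segment escaping: ':' and '%' are the only characters that can
# collide with the URN syntax itself
urn_escape <- function(x) gsub(":", "%3A", gsub("%", "%25", x, fixed = TRUE), fixed = TRUE)
urn_unescape <- function(x) gsub("%25", "%", gsub("%3A", ":", x, fixed = TRUE), fixed = TRUE)

#' Format an annotation as a MIRIAM URN
#'
#' @param ann an \code{\link{annotation}}.
#' @return A string \code{urn:miriam:<namespace>:<identifier>}.
#' @export
format_urn <- function(ann) {
  stopifnot(is_annotation(ann))
  paste0("urn:miriam:", ann$namespace, ":", urn_escape(ann$identifier))
}

#' Format an annotation as an identifiers.org URL
#'
#' @param ann an \code{\link{annotation}}.
#' @return A string \code{http://identifiers.org/<namespace>/<identifier>}.
#' @export
format_url <- function(ann) {
  stopifnot(is_annotation(ann))
  paste0("http://identifiers.org/", ann$namespace, "/", ann$identifier)
}

#' Parse a MIRIAM URN or identifiers.org URL into an annotation
#'
#' Accepts the two standard textual forms for cross-references:
#' \code{urn:miriam:<namespace>:<identifier>} and
#' \code{http(s)://identifiers.org/<namespace>/<identifier>}.
#'
#' @param text a single string in either form.
#' @return An \code{\link{annotation}} (qualifier unset).
#' @examples
#' parse_identifier("urn:miriam:uniprot:P04551")
#' parse_identifier("http://identifiers.org/taxonomy/7625")
#' @export
parse_identifier <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("identifier text must be a single string", call. = FALSE)
  if (!nzchar(text))
    stop("cannot parse empty identifier text", call. = FALSE)
  if (startsWith(text, "urn:")) {
    rest <- sub("^urn:", "", text)
    if (!startsWith(rest, "miriam:"))
      stop("unsupported URN scheme segment ", sQuote(sub(":.*$", "", rest)),
           " (expected 'miriam')", call. = FALSE)
    rest <- sub("^miriam:", "", rest)
    parts <- strsplit(rest, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !all(nzchar(parts)))
      stop("malformed MIRIAM URN body ", sQuote(rest),
           " (expected '<namespace>:<identifier>')", call. = FALSE)
    return(annotation(parts[[1L]], urn_unescape(parts[[2L]])))
  }
  if (grepl("^https?://identifiers\\.org/", text)) {
    rest <- sub("^https?://identifiers\\.org/", "", text)
    parts <- strsplit(rest, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !all(nzchar(parts)))
      stop("malformed identifiers.org path ", sQuote(rest),
           " (expected '<namespace>/<identifier>')", call. = FALSE)
    return(annotation(parts[[1L]], parts[[2L]]))
  }
  stop("cannot parse identifier ", sQuote(text),
       ": leading segment is neither 'urn:miriam:' nor an identifiers.org URL",
       call. = FALSE)
}

annotation_key <- function(ann) paste0(ann$namespace, ":", ann$identifier)

annotation_to_list <- function(ann) {
  out <- list(namespace = ann$namespace, identifier = ann$identifier)
  if (!is.null(ann$qualifier)) out$qualifier <- ann$qualifier
  out
}

annotation_from_list <- function(x) {
  annotation(x$namespace, x$identifier, qualifier = x$qualifier)
}
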