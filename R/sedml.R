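# SED-ML-lite: a faithful subset of the simulation-experiment description
# idea (uniform time course, parameter/initial changes, algorithm KiSAO id,
# perturbations, post-processing data generators), serialized as a small XML
# dialect.  Documents carry a subset marker so they are not mistaken for
# compliant SED-ML.

.sedml_marker <- "SED-ML-lite subset; not a compliant SED-ML document"

#' Write a simulation experiment description (SED-ML-lite)
#'
#' @param setup a \code{\link{simulation_setup}}.
#' @param overrides an \code{\link{instantiation}} with parameter/initial
#'   changes to apply on top of the model (may be empty).
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_sedml_lite <- function(setup, overrides = instantiation(), path) {
  stopifnot(inherits(setup, "sf_simulation_setup"),
            inherits(overrides, "sf_instantiation"))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sedmlLite version="1" subset="%s">', .sedml_marker),
    sprintf('<uniformTimeCourse initialTime="%.17g" outputEndTime="%.17g" outputStep="%.17g"/>',
            setup$t_start, setup$t_end, setup$step),
    sprintf('<algorithm kisaoID="%s" namespace="%s"/>',
            xml_escape(setup$algorithm$identifier),
            xml_escape(setup$algorithm$namespace)))
  if (length(overrides$parameter_values) + length(overrides$initial_values) > 0L) {
    lines <- c(lines, "<listOfChanges>")
    for (p in names(overrides$parameter_values))
      lines <- c(lines, sprintf('<changeParameter symbol="%s" value="%.17g"/>',
                                xml_escape(p), overrides$parameter_values[[p]]))
    for (s in names(overrides$initial_values))
      lines <- c(lines, sprintf('<changeInitial symbol="%s" value="%.17g"/>',
                                xml_escape(s), overrides$initial_values[[s]]))
    lines <- c(lines, "</listOfChanges>")
  }
  if (length(setup$perturbations) > 0L) {
    lines <- c(lines, "<listOfPerturbations>")
    for (p in setup$perturbations)
      lines <- c(lines, sprintf(
        '<perturbation time="%.17g" symbol="%s" delta="%.17g"/>',
        p$time, xml_escape(p$symbol), p$delta))
    lines <- c(lines, "</listOfPerturbations>")
  }
  if (length(setup$postprocess) > 0L) {
    lines <- c(lines, "<listOfDataGenerators>")
    for (nm in names(setup$postprocess))
      lines <- c(lines, sprintf('<dataGenerator id="%s" expression="%s"/>',
                                xml_escape(nm),
                                xml_escape(deparse1(setup$postprocess[[nm]]))))
    lines <- c(lines, "</listOfDataGenerators>")
  }
  lines <- c(lines, "</sedmlLite>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation experiment description (SED-ML-lite)
#'
#' @param path path to a SED-ML-lite document.
#' @return A list with elements \code{setup} (a
#'   \code{\link{simulation_setup}}) and \code{overrides} (an
#'   \code{\link{instantiation}}).
#' @export
read_sedml_lite <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_ns_strip(doc)
  if (xml2::xml_name(root) != "sedmlLite")
    stop("not a SED-ML-lite document: root element is ",
         xml2::xml_name(root), call. = FALSE)
  for (bad in c("steadyState", "oneStep", "analysis"))
    if (length(xml2::xml_find_all(root, paste0(".//", bad))) > 0L)
      stop("unsupported simulation type ", sQuote(bad),
           " (only uniformTimeCourse is supported)", call. = FALSE)
  utc <- xml2::xml_find_first(root, "./uniformTimeCourse")
  if (inherits(utc, "xml_missing"))
    stop("document contains no uniformTimeCourse element", call. = FALSE)
  alg <- xml2::xml_find_first(root, "./algorithm")
  if (inherits(alg, "xml_missing"))
    stop("document contains no algorithm element (a KiSAO id is required)",
         call. = FALSE)
  ns <- xml2::xml_attr(alg, "namespace")
  algorithm <- annotation(if (is.na(ns)) "kisao" else ns,
                          xml2::xml_attr(alg, "kisaoID"))
  perts <- lapply(xml2::xml_find_all(root, "./listOfPerturbations/perturbation"),
                  function(p) list(time = as.numeric(xml2::xml_attr(p, "time")),
                                   symbol = xml2::xml_attr(p, "symbol"),
                                   delta = as.numeric(xml2::xml_attr(p, "delta"))))
  gens <- xml2::xml_find_all(root, "./listOfDataGenerators/dataGenerator")
  post <- setNames(lapply(gens, function(g)
    parse_expr_text(xml2::xml_attr(g, "expression"), "data generator")),
    vapply(gens, function(g) xml2::xml_attr(g, "id"), character(1)))
  setup <- simulation_setup(
    t_start = as.numeric(xml2::xml_attr(utc, "initialTime")),
    t_end = as.numeric(xml2::xml_attr(utc, "outputEndTime")),
    step = as.numeric(xml2::xml_attr(utc, "outputStep")),
    algorithm = algorithm, perturbations = perts, postprocess = post)
  pc <- xml2::xml_find_all(root, "./listOfChanges/changeParameter")
  ic <- xml2::xml_find_all(root, "./listOfChanges/changeInitial")
  overrides <- instantiation(
    parameter_values = setNames(
      lapply(pc, function(x) as.numeric(xml2::xml_attr(x, "value"))),
      vapply(pc, function(x) xml2::xml_attr(x, "symbol"), character(1))),
    initial_values = setNames(
      lapply(ic, function(x) as.numeric(xml2::xml_attr(x, "value"))),
      vapply(ic, function(x) xml2::xml_attr(x, "symbol"), character(1))))
  list(setup = setup, overrides = overrides)
}
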