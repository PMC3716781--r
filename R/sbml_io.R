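# SBML Level 2 Version 4 subset: species, reactions with MathML kinetic laws,
# global parameters, assignment rules (for algebraic definitions), and RDF
# (MIRIAM) annotations.  Events, rate/algebraic rules, function definitions
# and constraints are outside the subset and raise explicit errors; purely
# declarative extras (compartments, unit definitions) are reported via a
# warning and skipped.

.sbml_ns <- "http://www.sbml.org/sbml/level2/version4"
.rdf_ns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.bqbiol_ns <- "http://biomodels.net/biology-qualifiers/"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

rdf_block <- function(anns, about) {
  if (length(anns) == 0L) return("")
  for (a in anns)
    if (!is_annotation(a) || !nzchar(a$namespace))
      stop("refusing to serialize annotation with empty namespace", call. = FALSE)
  quals <- vapply(anns, function(a) a$qualifier %||% "is", character(1))
  body <- character()
  for (q in unique(quals)) {
    lis <- vapply(anns[quals == q], function(a)
      sprintf('<rdf:li rdf:resource="%s"/>', xml_escape(format_urn(a))),
      character(1))
    body <- c(body, sprintf("<bqbiol:%s><rdf:Bag>%s</rdf:Bag></bqbiol:%s>",
                            q, paste(lis, collapse = ""), q))
  }
  paste0("<annotation>",
         sprintf('<rdf:RDF xmlns:rdf="%s" xmlns:bqbiol="%s">', .rdf_ns, .bqbiol_ns),
         sprintf('<rdf:Description rdf:about="#meta_%s">', xml_escape(about)),
         paste(body, collapse = ""),
         "</rdf:Description></rdf:RDF></annotation>")
}

#' Write a model to an SBML (Level 2 Version 4 subset) document
#'
#' Serializes species (with boundary-condition markings for constant pools),
#' global parameters, algebraic definitions as assignment rules, reactions
#' with MathML kinetic laws, and MIRIAM resource annotations as RDF.
#'
#' @param model an \code{\link{ode_model}}.
#' @param record optional \code{\link{facet_record}}; resource annotations in
#'   its S1-extrinsic slots are merged into the model-level annotation so
#'   that a read-back harvests them again.
#' @param path file path to write to.
#' @return \code{path}, invisibly.
#' @export
write_sbml <- function(model, record = NULL, path) {
  stopifnot(inherits(model, "sf_ode_model"))
  model_anns <- model$annotations
  if (!is.null(record)) {
    seen <- vapply(model_anns, annotation_key, character(1))
    for (key in c("S1.extrinsic.biological_system", "S1.extrinsic.conceptual_level")) {
      s <- record$slots[[key]]
      if (is.null(s)) next
      for (a in s$annotations)
        if (!annotation_key(a) %in% seen) {
          model_anns <- c(model_anns, list(a))
          seen <- c(seen, annotation_key(a))
        }
    }
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="2" version="4">', .sbml_ns),
    sprintf('<model id="%s" name="%s">', xml_escape(model$id),
            xml_escape(model$name)),
    rdf_block(model_anns, model$id),
    "<listOfSpecies>")
  for (sp in model$species) {
    bc <- if (sp$constant) ' boundaryCondition="true" constant="true"' else ""
    ann <- rdf_block(sp$annotations, sp$id)
    lines <- c(lines, sprintf(
      '<species id="%s" name="%s" initialAmount="%.17g"%s>%s</species>',
      xml_escape(sp$id), xml_escape(sp$name), sp$initial_amount, bc, ann))
  }
  lines <- c(lines, "</listOfSpecies>")
  if (length(model$parameters) + length(model$algebraic) > 0L) {
    lines <- c(lines, "<listOfParameters>")
    for (p in names(model$parameters)) {
      v <- model$parameters[[p]]
      lines <- c(lines, if (is.null(v) || is.na(v))
        sprintf('<parameter id="%s" constant="true"/>', xml_escape(p))
        else sprintf('<parameter id="%s" value="%.17g" constant="true"/>',
                     xml_escape(p), v))
    }
    for (a in names(model$algebraic))
      lines <- c(lines, sprintf('<parameter id="%s" constant="false"/>',
                                xml_escape(a)))
    lines <- c(lines, "</listOfParameters>")
  }
  if (length(model$algebraic) > 0L) {
    lines <- c(lines, "<listOfRules>")
    for (a in names(model$algebraic))
      lines <- c(lines, sprintf(
        '<assignmentRule variable="%s">%s</assignmentRule>',
        xml_escape(a), mathml_wrap(model$algebraic[[a]])))
    lines <- c(lines, "</listOfRules>")
  }
  if (length(model$reactions) > 0L) {
    lines <- c(lines, "<listOfReactions>")
    for (r in model$reactions) {
      lines <- c(lines, sprintf('<reaction id="%s" name="%s" reversible="false">',
                                xml_escape(r$id), xml_escape(r$name)),
                 rdf_block(r$annotations, r$id))
      ref <- function(tag, x) {
        if (length(x) == 0L) return(character())
        c(sprintf("<listOf%ss>", tag),
          vapply(names(x), function(s) sprintf(
            '<speciesReference species="%s" stoichiometry="%d"/>',
            xml_escape(s), as.integer(x[[s]])), character(1)),
          sprintf("</listOf%ss>", tag))
      }
      lines <- c(lines, ref("Reactant", r$reactants), ref("Product", r$products))
      if (length(r$modifiers) > 0L)
        lines <- c(lines, "<listOfModifiers>",
                   vapply(r$modifiers, function(s) sprintf(
                     '<modifierSpeciesReference species="%s"/>', xml_escape(s)),
                     character(1)),
                   "</listOfModifiers>")
      lines <- c(lines, sprintf("<kineticLaw>%s</kineticLaw>",
                                mathml_wrap(r$kinetic_law)),
                 "</reaction>")
    }
    lines <- c(lines, "</listOfReactions>")
  }
  lines <- c(lines, "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

read_rdf_annotations <- function(node) {
  # node: an element that may contain <annotation><rdf:RDF>...
  out <- list()
  descs <- xml2::xml_find_all(node, "./*[local-name()='annotation']//*[local-name()='Description']")
  for (d in descs) {
    for (qual in xml2::xml_children(d)) {
      qname <- xml2::xml_name(qual)
      lis <- xml2::xml_find_all(qual, ".//*[local-name()='li']")
      for (li in lis) {
        res <- xml2::xml_attr(li, "resource")
        if (is.na(res)) next
        a <- parse_identifier(res)
        a$qualifier <- qname
        out <- c(out, list(a))
      }
    }
  }
  out
}

#' Read a model from an SBML (Level 2 Version 4 subset) document
#'
#' Builds an \code{\link{ode_model}} and harvests the annotation content into
#' a partial \code{\link{facet_record}}: species become S2-intrinsic
#' entities, reactions and kinetic laws S3-intrinsic relations/programme,
#' parameter values and initial amounts F2-intrinsic, and RDF resource
#' annotations the corresponding extrinsic slots.
#'
#' @param path path to an SBML file.
#' @return A list with elements \code{model} (the \code{\link{ode_model}})
#'   and \code{record} (a partial \code{\link{facet_record}}).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_ns_strip(doc)
  if (xml2::xml_name(root) != "sbml")
    stop("not an SBML document: root element is ", xml2::xml_name(root),
         call. = FALSE)
  model_node <- xml2::xml_find_first(root, "./model")
  if (inherits(model_node, "xml_missing"))
    stop("SBML document contains no model element", call. = FALSE)

  for (bad in c("listOfEvents", "listOfFunctionDefinitions", "listOfConstraints"))
    if (length(xml2::xml_find_all(model_node, paste0("./", bad))) > 0L)
      stop("unsupported SBML construct: ", bad, call. = FALSE)
  for (bad in c("rateRule", "algebraicRule"))
    if (length(xml2::xml_find_all(model_node, paste0(".//", bad))) > 0L)
      stop("unsupported SBML construct: ", bad,
           " (only assignment rules are supported)", call. = FALSE)
  for (skip in c("listOfCompartments", "listOfUnitDefinitions"))
    if (length(xml2::xml_find_all(model_node, paste0("./", skip))) > 0L)
      warning("SBML construct ", skip, " is outside the supported subset; ",
              "its content is not interpreted", call. = FALSE)

  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"
  model_name <- xml2::xml_attr(model_node, "name")
  if (is.na(model_name)) model_name <- model_id
  model_anns <- read_rdf_annotations(model_node)

  sp_list <- list()
  for (sn in xml2::xml_find_all(model_node, "./listOfSpecies/species")) {
    ia <- xml2::xml_attr(sn, "initialAmount")
    sp_list <- c(sp_list, list(species(
      id = xml2::xml_attr(sn, "id"),
      name = {nm <- xml2::xml_attr(sn, "name"); if (is.na(nm)) xml2::xml_attr(sn, "id") else nm},
      initial_amount = if (is.na(ia)) 0 else as.numeric(ia),
      constant = identical(xml2::xml_attr(sn, "boundaryCondition"), "true") ||
                 identical(xml2::xml_attr(sn, "constant"), "true"),
      annotations = read_rdf_annotations(sn))))
  }

  params <- list()
  alg_syms <- character()
  for (pn in xml2::xml_find_all(model_node, "./listOfParameters/parameter")) {
    pid <- xml2::xml_attr(pn, "id")
    v <- xml2::xml_attr(pn, "value")
    if (identical(xml2::xml_attr(pn, "constant"), "false")) {
      alg_syms <- c(alg_syms, pid)
    } else {
      params[[pid]] <- if (is.na(v)) NA_real_ else as.numeric(v)
    }
  }

  algebraic <- list()
  for (rn in xml2::xml_find_all(model_node, "./listOfRules/assignmentRule")) {
    var <- xml2::xml_attr(rn, "variable")
    math <- xml2::xml_find_first(rn, "./math")
    if (inherits(math, "xml_missing"))
      stop("assignment rule for ", var, " has no math element", call. = FALSE)
    algebraic[[var]] <- mathml_to_expr(math)
  }
  for (a in setdiff(alg_syms, names(algebraic)))
    params[[a]] <- NA_real_   # declared non-constant but never ruled

  reactions <- list()
  for (rn in xml2::xml_find_all(model_node, "./listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rn, "id")
    stoich_of <- function(xpath) {
      refs <- xml2::xml_find_all(rn, xpath)
      if (length(refs) == 0L) return(integer())
      st <- vapply(refs, function(x) {
        s <- xml2::xml_attr(x, "stoichiometry")
        if (is.na(s)) 1L else as.integer(as.numeric(s))
      }, integer(1))
      names(st) <- vapply(refs, function(x) xml2::xml_attr(x, "species"),
                          character(1))
      st
    }
    math <- xml2::xml_find_first(rn, "./kineticLaw/math")
    if (inherits(math, "xml_missing"))
      stop("reaction ", rid, " has no kineticLaw math", call. = FALSE)
    rname <- xml2::xml_attr(rn, "name")
    reactions <- c(reactions, list(reaction(
      id = rid, name = if (is.na(rname)) rid else rname,
      reactants = stoich_of("./listOfReactants/speciesReference"),
      products = stoich_of("./listOfProducts/speciesReference"),
      modifiers = vapply(
        xml2::xml_find_all(rn, "./listOfModifiers/modifierSpeciesReference"),
        function(x) xml2::xml_attr(x, "species"), character(1)),
      kinetic_law = mathml_to_expr(math),
      annotations = read_rdf_annotations(rn))))
  }

  model <- ode_model(id = model_id, name = model_name, species = sp_list,
                     parameters = params, algebraic = algebraic,
                     reactions = reactions, annotations = model_anns)
  list(model = model, record = harvest_record(model))
}

# build the partial facet record an SBML document carries on its face
harvest_record <- function(model) {
  rec <- facet_record(model$id)
  sp_ids <- model_species_ids(model)
  rec <- set_slot(rec, facet_slot("S2.intrinsic.entities",
    text = paste0("species: ", paste(sp_ids, collapse = ", "))))
  rec <- set_slot(rec, facet_slot("S2.intrinsic.attributes",
    text = "species amounts as continuous state variables"))
  if (length(model$reactions) > 0L) {
    rec <- set_slot(rec, facet_slot("S3.intrinsic.relations",
      text = paste0("reactions: ",
                    paste(vapply(model$reactions, `[[`, character(1), "id"),
                          collapse = ", "))))
    rec <- set_slot(rec, facet_slot("S3.intrinsic.programme",
      text = "ODE system derived from the reaction kinetic laws",
      structured = list(type = "programme", value = model$id)))
  }
  set_params <- Filter(function(v) !is.na(v), model$parameters)
  if (length(set_params) > 0L || length(sp_ids) > 0L) {
    rec <- set_slot(rec, facet_slot("F2.intrinsic.instantiation",
      text = paste0("parameter values: ",
                    paste(names(set_params),
                          vapply(set_params, format, character(1)),
                          sep = "=", collapse = ", "))))
    inits <- vapply(model$species, `[[`, numeric(1), "initial_amount")
    rec <- set_slot(rec, facet_slot("F2.intrinsic.initial_values",
      text = paste0("initialAmount: ",
                    paste(sp_ids, format(inits), sep = "=", collapse = ", "))))
  }
  sp_anns <- unlist(lapply(model$species, `[[`, "annotations"),
                    recursive = FALSE)
  if (length(sp_anns) > 0L)
    rec <- set_slot(rec, facet_slot("S2.extrinsic.objects",
      annotations = sp_anns))
  rx_anns <- unlist(lapply(model$reactions, `[[`, "annotations"),
                    recursive = FALSE)
  if (length(rx_anns) > 0L)
    rec <- set_slot(rec, facet_slot("S3.extrinsic.interactions",
      annotations = rx_anns))
  if (length(model$annotations) > 0L)
    rec <- set_slot(rec, facet_slot("S1.extrinsic.biological_system",
      annotations = model$annotations))
  rec
}
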