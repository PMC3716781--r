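#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# The facet address space
#
# A bio-model's meaning is viewed from three perspectives (structure,
# function, behaviour), each split into three cells (S1-S3, F1-F3, B1-B3),
# each cell having an intrinsic side (the model as a formal object) and an
# extrinsic side (its biological interpretation), and each (cell, side)
# carrying exactly two named aspects.  That closed vocabulary yields
# 9 x 2 x 2 = 36 addresses.
# ---------------------------------------------------------------------------

.facet_cells <- c("S1", "S2", "S3", "F1", "F2", "F3", "B1", "B2", "B3")
.facet_sides <- c("intrinsic", "extrinsic")

.facet_aspects <- list(
  S1 = list(intrinsic = c("formal_system", "formalism"),
            extrinsic = c("biological_system", "conceptual_level")),
  S2 = list(intrinsic = c("entities", "attributes"),
            extrinsic = c("objects", "quantities")),
  S3 = list(intrinsic = c("relations", "programme"),
            extrinsic = c("interactions", "mechanisms")),
  F1 = list(intrinsic = c("intended_use", "constraints"),
            extrinsic = c("questions", "assumptions")),
  F2 = list(intrinsic = c("instantiation", "initial_values"),
            extrinsic = c("boundary_conditions", "initial_state")),
  F3 = list(intrinsic = c("setup", "post_processing"),
            extrinsic = c("experimental_settings", "result_calculation")),
  B1 = list(intrinsic = c("dynamics", "diversification"),
            extrinsic = c("phenomena", "variability")),
  B2 = list(intrinsic = c("raw_data", "index"),
            extrinsic = c("measurements", "key")),
  B3 = list(intrinsic = c("outcome", "characteristics"),
            extrinsic = c("results", "observables"))
)

# guiding question per aspect, used by completeness_questions()
.facet_questions <- list(
  "S1.intrinsic.formal_system"      = "Which formal system is specified by the encoded model (the model itself)?",
  "S1.intrinsic.formalism"          = "Which formalism is employed by the model (modelling framework, spatiality, stochasticity)?",
  "S1.extrinsic.biological_system"  = "Which biological system corresponds to the formal system (species, cell type, biochemical system)?",
  "S1.extrinsic.conceptual_level"   = "Which conceptual level is reflected by the used formalism (system type, granularity, spatial and temporal resolution)?",
  "S2.intrinsic.entities"           = "What are the entities of the formal system (individuals, collections, agents)?",
  "S2.intrinsic.attributes"         = "Which attributes of the entities describe the state of the system (variables, terms)?",
  "S2.extrinsic.objects"            = "What biological objects correspond to the model entities (molecules, substances, cells)?",
  "S2.extrinsic.quantities"         = "Which quantities (amounts, concentrations, units) correspond to the model attributes?",
  "S3.intrinsic.relations"          = "What are the relations between the entities (inter-dependencies, correlation, neighbourhood)?",
  "S3.intrinsic.programme"          = "What is the programme describing changes of the attributes of related entities (operations, equations, update rules)?",
  "S3.extrinsic.interactions"       = "What biological interactions correspond to the model relations (reactions, transformations, diffusion)?",
  "S3.extrinsic.mechanisms"         = "What biological mechanisms realising the interactions between objects correspond to the model programme (reaction steps, bonding, activity)?",
  "F1.intrinsic.intended_use"       = "What is the intended use of the model (simulation type, combination of simulations, desired outcome)?",
  "F1.intrinsic.constraints"        = "Which constraints are imposed on the model (value restrictions, ratios, conservation rules)?",
  "F1.extrinsic.questions"          = "Which biological questions are addressed to the model (explanation, hypothesis testing, exploration, dependency analysis)?",
  "F1.extrinsic.assumptions"        = "Which assumptions provide the basis for the constraints (likelihoods, justification, evidence)?",
  "F2.intrinsic.instantiation"      = "Which instantiation of the model is used for the simulation (parameter values, parameter ranges)?",
  "F2.intrinsic.initial_values"     = "Which initial values are chosen for the entities' attributes (value assignment to variables)?",
  "F2.extrinsic.boundary_conditions" = "Which boundary conditions correspond to the model instantiation (environment, kinetic data, plausible ranges)?",
  "F2.extrinsic.initial_state"      = "Which initial state of the biological system corresponds to the initial values set for the model (initial concentrations)?",
  "F3.intrinsic.setup"              = "Which setup is used for simulation experiments (simulation algorithm, algorithm settings, perturbations)?",
  "F3.intrinsic.post_processing"    = "Which post-processing of the raw simulation data generates the desired outcome (normalisation, conversions of units, calculations)?",
  "F3.extrinsic.experimental_settings" = "Which biological experimental settings correspond to the setup for simulations of the model (experimental protocol)?",
  "F3.extrinsic.result_calculation" = "Which result calculation produces the requested results of the experiment (normalisation, conversions of units, calculations)?",
  "B1.intrinsic.dynamics"           = "Which types of dynamics does the model show in simulations (fixed points, periodic behaviours, chaotic behaviour)?",
  "B1.intrinsic.diversification"    = "Which diversification in the dynamics does the model possess (stability, bifurcations)?",
  "B1.extrinsic.phenomena"          = "Which biological phenomena correspond to the model dynamics (cyclic behaviour, steady state)?",
  "B1.extrinsic.variability"        = "Which variability of the biological phenomena corresponds to the diversification in the dynamics of the model (switching behaviour, excitability)?",
  "B2.intrinsic.raw_data"           = "Which raw data does the model produce in simulations (series of values)?",
  "B2.intrinsic.index"              = "Which index is used for the raw data (modelling time, parameter value, initial value)?",
  "B2.extrinsic.measurements"       = "Which experimental measurements correspond to the yielded raw data (series of values)?",
  "B2.extrinsic.key"                = "Which key is used to identify the single measurements (time, conditions, initial states)?",
  "B3.intrinsic.outcome"            = "What is the outcome of the simulation (specific values, time courses, phase portraits, bifurcation diagram)?",
  "B3.intrinsic.characteristics"    = "Which characteristics of the model dynamics can be identified (maximal and minimal values, periods)?",
  "B3.extrinsic.results"            = "Which experimental results correspond to the outcome of the simulation (specific values, time courses, phase portraits)?",
  "B3.extrinsic.observables"        = "Which observables correspond to the characteristics of the model dynamics (maximal and minimal concentrations, cycle length, stability)?"
)

.perspective_of_cell <- c(S = "structure", F = "function", B = "behaviour")

# structured payloads are only legal under the addresses whose content they
# realize
.payload_addresses <- list(
  simulation_setup = "F3.intrinsic.setup",
  instantiation    = c("F2.intrinsic.instantiation", "F2.intrinsic.initial_values"),
  dyml             = c("B1.intrinsic.dynamics", "B1.intrinsic.diversification"),
  trajectory       = "B2.intrinsic.raw_data",
  programme        = "S3.intrinsic.programme",
  model            = "S1.intrinsic.formal_system"
)

.relation_types <- c("abstraction", "refinement", "version_of",
                     "integrated_from", "competing", "modified_version_of")

#' All 36 facet addresses
#'
#' @return Character vector of the 36 address keys in canonical order
#'   (cells S1..B3, intrinsic before extrinsic, aspect pairs in fixed order).
#' @export
facet_addresses <- function() {
  unlist(lapply(.facet_cells, function(cell)
    lapply(.facet_sides, function(side)
      paste(cell, side, .facet_aspects[[cell]][[side]], sep = "."))),
    use.names = FALSE)
}

#' Construct a facet address
#'
#' A facet address names one of the 36 aspects of the meaning of a bio-model:
#' a perspective (structure/function/behaviour), a cell index 1-3, a side
#' (intrinsic/extrinsic) and one of the two aspect names of that (cell, side).
#'
#' @param perspective \code{"structure"}, \code{"function"} or
#'   \code{"behaviour"}; alternatively a cell code such as \code{"S1"} may be
#'   given here with \code{index} missing.
#' @param index integer 1-3.
#' @param side \code{"intrinsic"} or \code{"extrinsic"}.
#' @param aspect aspect name valid for that (cell, side).
#' @return An object of class \code{"sf_facet_address"}.
#' @examples
#' facet_address("structure", 1, "intrinsic", "formal_system")
#' facet_address("S1", side = "intrinsic", aspect = "formal_system")
#' @export
facet_address <- function(perspective, index = NULL, side, aspect) {
  if (is.null(index) && grepl("^[SFB][123]$", perspective)) {
    cell <- perspective
    perspective <- unname(.perspective_of_cell[substr(cell, 1, 1)])
    index <- as.integer(substr(cell, 2, 2))
  } else {
    perspective <- match.arg(perspective, c("structure", "function", "behaviour"))
    index <- as.integer(index)
    if (!index %in% 1:3) stop("facet index must be 1, 2 or 3", call. = FALSE)
    cell <- paste0(toupper(substr(ifelse(perspective == "behaviour", "B",
                                         substr(perspective, 1, 1)), 1, 1)), index)
  }
  side <- match.arg(side, .facet_sides)
  ok <- .facet_aspects[[cell]][[side]]
  if (!aspect %in% ok)
    stop("aspect ", sQuote(aspect), " is not valid for ", cell, "-", side,
         " (expected one of: ", paste(ok, collapse = ", "), ")", call. = FALSE)
  structure(list(perspective = perspective, index = index, cell = cell,
                 side = side, aspect = aspect,
                 key = paste(cell, side, aspect, sep = ".")),
            class = "sf_facet_address")
}

#' @export
print.sf_facet_address <- function(x, ...) {
  cat("<facet address>", x$key, "\n")
  invisible(x)
}

#' Parse an address key string
#'
#' @param key a string such as \code{"S1.intrinsic.formal_system"}, or an
#'   \code{sf_facet_address} (returned unchanged).
#' @return An \code{sf_facet_address}.
#' @export
as_facet_address <- function(key) {
  if (inherits(key, "sf_facet_address")) return(key)
  parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("facet address key must have the form '<cell>.<side>.<aspect>': ",
         sQuote(key), call. = FALSE)
  facet_address(parts[[1L]], side = parts[[2L]], aspect = parts[[3L]])
}

# ---------------------------------------------------------------------------
# Slots and records
# ---------------------------------------------------------------------------

#' Construct a facet slot
#'
#' A slot holds the content filled in at one facet address.  Content is
#' dual-channel: free text, resource annotations, and/or a structured payload
#' for addresses whose content is executable (a simulation setup, an
#' instantiation, a DYML document, a trajectory handle).
#'
#' @param address an \code{\link{facet_address}} or address key string.
#' @param text optional free-text description.
#' @param annotations list of \code{\link{annotation}} objects (a single
#'   annotation is accepted).
#' @param structured optional payload: a list \code{list(type =, value =)}
#'   where \code{type} is one of \code{simulation_setup}, \code{instantiation},
#'   \code{dyml}, \code{trajectory}, \code{programme}, \code{model}.
#' @return An object of class \code{"sf_facet_slot"}.
#' @export
facet_slot <- function(address, text = NULL, annotations = list(),
                       structured = NULL) {
  address <- as_facet_address(address)
  if (is_annotation(annotations)) annotations <- list(annotations)
  if (!is.list(annotations)) stop("annotations must be a list", call. = FALSE)
  if (!is.null(text)) {
    text <- as.character(text)[1L]
    if (!nzchar(text)) text <- NULL
  }
  structure(list(address = address, text = text, annotations = annotations,
                 structured = structured),
            class = "sf_facet_slot")
}

slot_filled <- function(slot) {
  !is.null(slot$text) || length(slot$annotations) > 0L || !is.null(slot$structured)
}

#' Global meta-information of a model
#'
#' Information about a model's role in research rather than its content: the
#' origin (publication, authors, date), access to encoded forms (location,
#' format, encoding date, curation notes), and relations to other models drawn
#' from a closed vocabulary: abstraction, refinement, version_of,
#' integrated_from, competing, modified_version_of.
#'
#' @param origin list with elements \code{publication_id}, \code{authors},
#'   \code{date}.
#' @param access list of lists, each with a non-empty \code{location} and
#'   optionally \code{format}, \code{encoding_date}, \code{curation}.
#' @param relations list of lists, each with \code{other_model_id},
#'   \code{relation_type} (closed vocabulary) and optional \code{note}.
#' @return An object of class \code{"sf_global_meta"}.
#' @export
global_meta <- function(origin = list(), access = list(), relations = list()) {
  for (acc in access)
    if (is.null(acc$location) || !nzchar(acc$location))
      stop("every access entry needs a non-empty location", call. = FALSE)
  for (rel in relations) {
    if (is.null(rel$relation_type) || !rel$relation_type %in% .relation_types)
      stop("relation_type must be one of: ",
           paste(.relation_types, collapse = ", "), call. = FALSE)
    if (is.null(rel$other_model_id) || !nzchar(rel$other_model_id))
      stop("every relation needs an other_model_id", call. = FALSE)
  }
  structure(list(origin = origin, access = access, relations = relations),
            class = "sf_global_meta")
}

#' Construct a facet record
#'
#' The central container of the framework: one slot per filled facet address
#' plus global meta-information, describing the complete meaning of one model.
#'
#' @param model_id identifier of the described model.
#' @param slots list of \code{\link{facet_slot}} objects.
#' @param meta a \code{\link{global_meta}}.
#' @return An object of class \code{"sf_facet_record"}.
#' @export
facet_record <- function(model_id, slots = list(), meta = global_meta()) {
  stopifnot(is.character(model_id), length(model_id) == 1L, nzchar(model_id))
  named <- list()
  for (s in slots) {
    if (!inherits(s, "sf_facet_slot")) stop("slots must be facet_slot objects",
                                            call. = FALSE)
    named[[s$address$key]] <- s
  }
  structure(list(model_id = model_id, slots = named, meta = meta),
            class = "sf_facet_record")
}

#' Set or replace a slot of a record
#'
#' @param record an \code{\link{facet_record}}.
#' @param slot a \code{\link{facet_slot}}.
#' @return The updated record.
#' @export
set_slot <- function(record, slot) {
  stopifnot(inherits(record, "sf_facet_record"), inherits(slot, "sf_facet_slot"))
  record$slots[[slot$address$key]] <- slot
  record
}

#' @export
print.sf_facet_record <- function(x, ...) {
  cat("<facet record> model:", x$model_id, "\n")
  filled <- sum(vapply(x$slots, slot_filled, logical(1)))
  cat("  ", filled, "of 36 aspects filled\n")
  cov <- coverage(x)
  cat("  coverage:", sum(cov$cells$covered), "of 18 (cell, side) combinations\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

issue <- function(severity, message, address = NA_character_) {
  list(severity = severity, address = address, message = message)
}

#' Validate a facet record
#'
#' Checks the single hard rule of the framework -- a model with no extrinsic
#' interpretation is biologically meaningless, so at least one extrinsic slot
#' must be filled -- plus well-formedness of annotations, placement of
#' structured payloads, and the global meta-information vocabulary.  Every
#' unfilled aspect is reported as a \code{"gap"} (incompleteness, not
#' invalidity).
#'
#' @param record an \code{\link{facet_record}}.
#' @return An object of class \code{"sf_issues"}: a list of issues, each with
#'   \code{severity} (\code{"error"} or \code{"gap"}), \code{address} and
#'   \code{message}.  Empty (no error issues and no gaps) only for a complete,
#'   well-formed record.
#' @export
validate <- function(record) {
  stopifnot(inherits(record, "sf_facet_record"))
  issues <- list()

  extrinsic_filled <- FALSE
  for (s in record$slots) {
    if (!slot_filled(s)) next
    if (s$address$side == "extrinsic") extrinsic_filled <- TRUE
  }
  if (!extrinsic_filled)
    issues <- c(issues, list(issue("error",
      "no extrinsic interpretation: at least one extrinsic slot must be filled")))

  for (s in record$slots) {
    for (a in s$annotations) {
      if (!is_annotation(a) || !nzchar(a$namespace) || !nzchar(a$identifier)) {
        issues <- c(issues, list(issue("error",
          "malformed annotation (empty namespace or identifier)", s$address$key)))
        next
      }
      ok <- tryCatch({
        b <- parse_identifier(format_urn(a))
        identical(b$namespace, a$namespace) && identical(b$identifier, a$identifier)
      }, error = function(e) FALSE)
      if (!ok)
        issues <- c(issues, list(issue("error",
          paste0("annotation does not round-trip: ", annotation_key(a)),
          s$address$key)))
    }
    if (!is.null(s$structured)) {
      type <- s$structured$type
      allowed <- .payload_addresses[[type %||% ""]]
      if (is.null(allowed)) {
        issues <- c(issues, list(issue("error",
          paste0("unknown structured payload type ", sQuote(type %||% "<missing>")),
          s$address$key)))
      } else if (!s$address$key %in% allowed) {
        issues <- c(issues, list(issue("error",
          paste0("structured payload of type ", sQuote(type),
                 " is not allowed at ", s$address$key,
                 " (allowed: ", paste(allowed, collapse = ", "), ")"),
          s$address$key)))
      }
    }
  }

  meta_ok <- tryCatch({
    global_meta(record$meta$origin, record$meta$access, record$meta$relations)
    TRUE
  }, error = function(e) {
    issues <<- c(issues, list(issue("error", conditionMessage(e))))
    FALSE
  })

  for (key in facet_addresses()) {
    s <- record$slots[[key]]
    if (is.null(s) || !slot_filled(s))
      issues <- c(issues, list(issue("gap",
        paste0("unfilled aspect: ", .facet_questions[[key]]), key)))
  }

  structure(issues, class = "sf_issues")
}

#' @export
print.sf_issues <- function(x, ...) {
  if (length(x) == 0L) {
    cat("no issues\n")
    return(invisible(x))
  }
  for (i in x)
    cat(sprintf("[%s] %s%s\n", i$severity,
                if (is.na(i$address)) "" else paste0(i$address, ": "),
                i$message))
  invisible(x)
}

#' Extract severities or addresses from a validation issue list
#'
#' @param issues an \code{sf_issues} list from \code{\link{validate}}.
#' @return Character vector of severities or addresses (NA for record-level
#'   issues).
#' @export
issue_severities <- function(issues) vapply(issues, `[[`, character(1), "severity")

#' @rdname issue_severities
#' @export
issue_addresses  <- function(issues) vapply(issues, `[[`, character(1), "address")

# ---------------------------------------------------------------------------
# Coverage
# ---------------------------------------------------------------------------

#' Coverage report over the 18 (cell, side) combinations
#'
#' A (cell, side) combination is covered iff at least one of its two aspect
#' slots is filled.  Filling more slots never removes coverage.
#'
#' @param record an \code{\link{facet_record}}.
#' @return An object of class \code{"sf_coverage"} with elements
#'   \code{cells} (data frame: cell, side, covered, sources) and
#'   \code{gaps} (character vector of unfilled aspect addresses).
#' @export
coverage <- function(record) {
  stopifnot(inherits(record, "sf_facet_record"))
  rows <- list()
  gaps <- character()
  for (cell in .facet_cells) {
    for (side in .facet_sides) {
      keys <- paste(cell, side, .facet_aspects[[cell]][[side]], sep = ".")
      sources <- character()
      covered <- FALSE
      for (key in keys) {
        s <- record$slots[[key]]
        if (!is.null(s) && slot_filled(s)) {
          covered <- TRUE
          if (!is.null(s$text)) sources <- c(sources, paste0(key, ":text"))
          sources <- c(sources,
                       vapply(s$annotations, annotation_key, character(1)))
          if (!is.null(s$structured))
            sources <- c(sources, paste0(key, ":", s$structured$type))
        } else {
          gaps <- c(gaps, key)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cell, side = side, covered = covered,
        sources = paste(unique(sources), collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(cells = do.call(rbind, rows), gaps = gaps),
            class = "sf_coverage")
}

#' @export
print.sf_coverage <- function(x, ...) {
  cat("<coverage report>", sum(x$cells$covered), "of", nrow(x$cells),
      "(cell, side) combinations covered\n")
  print(x$cells[, c("cell", "side", "covered")], row.names = FALSE)
  invisible(x)
}

#' Guiding questions for the unfilled aspects of a record
#'
#' Returns, for every unfilled aspect, the guiding question that describes
#' what information is missing -- a non-interactive completeness assistant.
#'
#' @param record an \code{\link{facet_record}}.
#' @return Data frame with columns \code{address} and \code{question}, in
#'   canonical address order; zero rows for a fully filled record.
#' @export
completeness_questions <- function(record) {
  stopifnot(inherits(record, "sf_facet_record"))
  keys <- facet_addresses()
  missing <- keys[vapply(keys, function(k) {
    s <- record$slots[[k]]
    is.null(s) || !slot_filled(s)
  }, logical(1))]
  data.frame(address = missing,
             question = unlist(.facet_questions[missing], use.names = FALSE),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Serialization (one human-readable YAML document per record, stable key
# order, versioned header)
# ---------------------------------------------------------------------------

slot_to_list <- function(s) {
  out <- list()
  if (!is.null(s$text)) out$text <- s$text
  if (length(s$annotations) > 0L)
    out$annotations <- lapply(s$annotations, annotation_to_list)
  if (!is.null(s$structured))
    out$structured <- payload_to_list(s$structured)
  out
}

slot_from_list <- function(key, x) {
  anns <- lapply(x$annotations %||% list(), annotation_from_list)
  facet_slot(key, text = x$text, annotations = anns,
             structured = if (!is.null(x$structured))
               payload_from_list(x$structured))
}

payload_to_list <- function(p) {
  value <- p$value
  if (inherits(value, "sf_simulation_setup")) value <- setup_to_list(value)
  else if (inherits(value, "sf_instantiation")) value <- instantiation_to_list(value)
  else if (inherits(value, "sf_dyml")) value <- dyml_to_list(value)
  list(type = p$type, value = value)
}

payload_from_list <- function(x) {
  value <- x$value
  if (identical(x$type, "simulation_setup")) value <- setup_from_list(value)
  else if (identical(x$type, "instantiation")) value <- instantiation_from_list(value)
  else if (identical(x$type, "dyml")) value <- dyml_from_list(value)
  list(type = x$type, value = value)
}

record_to_list <- function(record) {
  keys <- sort(names(record$slots))
  keys <- keys[vapply(keys, function(k) slot_filled(record$slots[[k]]), logical(1))]
  list(format = "semfacets-record",
       format_version = 1L,
       model_id = record$model_id,
       meta = list(origin = record$meta$origin,
                   access = record$meta$access,
                   relations = record$meta$relations),
       slots = setNames(lapply(keys, function(k) slot_to_list(record$slots[[k]])),
                        keys))
}

#' Write a facet record to a document
#'
#' Records are serialized as a YAML document with a versioned header and
#' stable (sorted) slot-key order, so that differences between two records
#' are reviewable as text diffs.  \code{read_facet_record} inverts it.
#'
#' @param record an \code{\link{facet_record}}.
#' @param path file path to write to.
#' @return \code{path}, invisibly.
#' @export
write_facet_record <- function(record, path) {
  stopifnot(inherits(record, "sf_facet_record"))
  writeLines(yaml::as.yaml(precision = 17L, x = record_to_list(record)), path)
  invisible(path)
}

#' @rdname write_facet_record
#' @param path file path to read from.
#' @export
read_facet_record <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$format, "semfacets-record"))
    stop("not a semfacets record document: ", path, call. = FALSE)
  slots <- lapply(names(x$slots %||% list()), function(k)
    slot_from_list(k, x$slots[[k]]))
  meta <- global_meta(origin = x$meta$origin %||% list(),
                      access = x$meta$access %||% list(),
                      relations = x$meta$relations %||% list())
  facet_record(x$model_id, slots = slots, meta = meta)
}
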