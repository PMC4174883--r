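# Reading and writing LEMS XML documents. The root element <Lems> has
# exactly seven kinds of children: Target, Include, Dimension, Unit,
# Constant, ComponentType and Component. Components may be written either
# as <Component type="T"/> or with the type name as the tag (<T .../>);
# both normalize to the same raw component record. XML namespaces are
# ignored (local names only) and element order is unconstrained.

LEMS_ROOT_KINDS <- c("Target", "Include", "Dimension", "Unit", "Constant",
                     "ComponentType", "Component")

#' The seven root-level element kinds of a LEMS document
#' @return Character vector of the element names the root parser
#'   dispatches on.
#' @export
lems_root_kinds <- function() LEMS_ROOT_KINDS

# ---- raw element tree ---------------------------------------------------

# Generic raw element: list(tag, attrs = named character, children = list)
xml_to_raw <- function(node) {
  attrs <- xml2::xml_attrs(node)
  # strip namespace prefixes from attribute names
  if (length(attrs)) names(attrs) <- sub("^.*:", "", names(attrs))
  kids <- xml2::xml_children(node)
  list(tag = xml2::xml_name(node),
       attrs = attrs,
       children = lapply(kids, xml_to_raw))
}

raw_attr <- function(raw, name, default = NULL) {
  if (!name %in% names(raw$attrs)) return(default)
  v <- raw$attrs[[name]]
  if (is.null(v) || is.na(v)) default else v
}

# Normalize a component element: <Component type="T"/> and <T/> both become
# list(type = "T", id = ..., attrs = ..., children = ...). Anonymous
# components get stable synthetic ids later (parentId_elementName_ordinal).
raw_to_component <- function(raw) {
  if (raw$tag == "Component") {
    type <- raw_attr(raw, "type")
    if (is.null(type)) {
      stop("<Component> element without a 'type' attribute", call. = FALSE)
    }
    attrs <- raw$attrs[setdiff(names(raw$attrs), "type")]
  } else {
    type <- raw$tag
    attrs <- raw$attrs
  }
  id <- if ("id" %in% names(attrs)) attrs[["id"]] else NULL
  attrs <- attrs[setdiff(names(attrs), "id")]
  if (anyDuplicated(names(attrs))) {
    stop("duplicate attribute names on component element <", raw$tag, ">",
         call. = FALSE)
  }
  list(type = type,
       id = if (is.null(id)) NA_character_ else id,
       tag = raw$tag,
       attrs = attrs,
       children = lapply(raw$children, raw_to_component))
}

# Assign synthetic ids to anonymous nested components.
assign_synthetic_ids <- function(comp, parent_id = NULL) {
  if (is.na(comp$id)) {
    comp$id <- if (is.null(parent_id)) comp$type else
      paste0(parent_id, "_", comp$tag)
  }
  counts <- new.env(parent = emptyenv())
  comp$children <- lapply(comp$children, function(ch) {
    key <- ch$tag
    k <- if (is.null(counts[[key]])) 0L else counts[[key]]
    counts[[key]] <- k + 1L
    if (is.na(ch$id)) ch$id <- paste0(comp$id, "_", ch$tag, "_", k)
    assign_synthetic_ids(ch, comp$id)
  })
  comp
}

# ---- document parsing ---------------------------------------------------

new_lems_document <- function() {
  structure(list(targets = character(),
                 dimensions = list(),
                 units = list(),
                 constants = list(),
                 types = list(),      # name -> raw ComponentType element
                 components = list(), # id -> raw component record
                 errors = character()),
            class = "lems_document")
}

#' Parse a LEMS XML document
#'
#' Reads a LEMS file (or literal XML text), resolves `<Include>` elements
#' depth-first against the search paths, and classifies all root children
#' into the seven root element kinds. Each physical file is loaded at most
#' once, so repeated inclusion is idempotent and include cycles are
#' detected rather than looping.
#'
#' @param source Path to a LEMS XML file, or a string containing XML
#'   (anything starting with `<` is treated as literal XML).
#' @param include_dirs Character vector of directories searched, in order,
#'   when resolving `<Include file="..."/>`; the directory of the
#'   including file is always searched first.
#' @return An object of class `lems_document` with fields `targets`,
#'   `dimensions`, `units`, `constants` (as SI `lems_quantity` values),
#'   `types` (raw ComponentType declarations) and `components`.
#' @export
parse_lems <- function(source, include_dirs = character()) {
  doc <- new_lems_document()
  state <- new.env(parent = emptyenv())
  state$loaded <- character()   # normalized paths already merged
  state$loading <- character()  # stack for cycle detection
  doc <- parse_lems_source(doc, source, include_dirs, state)
  # second pass: resolve units (forward dimension references are legal
  # after the full first pass) and then constants
  doc <- finalize_units(doc)
  for (nm in names(doc$constants)) {
    if (is.character(doc$constants[[nm]])) {
      doc$constants[[nm]] <- parse_quantity(doc$constants[[nm]], doc$units)
    }
  }
  for (target in doc$targets) {
    if (is.null(doc$components[[target]])) {
      doc$errors <- c(doc$errors,
                      paste0("Target '", target,
                             "' does not name a component in the document"))
    }
  }
  doc
}

parse_lems_source <- function(doc, source, include_dirs, state) {
  is_text <- grepl("^\\s*<", source)
  if (!is_text) {
    if (!file.exists(source)) {
      stop("cannot open LEMS file '", source, "'", call. = FALSE)
    }
    path <- normalizePath(source)
    if (path %in% state$loaded) return(doc)
    if (path %in% state$loading) {
      stop("include cycle detected: ",
           paste(c(state$loading, path), collapse = " -> "), call. = FALSE)
    }
    state$loading <- c(state$loading, path)
    on.exit(state$loading <- setdiff(state$loading, path), add = TRUE)
    xml <- tryCatch(xml2::read_xml(path),
                    error = function(e) {
                      stop("malformed XML in '", source, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
    local_dirs <- c(dirname(path), include_dirs)
  } else {
    path <- NULL
    xml <- tryCatch(xml2::read_xml(source),
                    error = function(e) {
                      stop("malformed XML: ", conditionMessage(e),
                           call. = FALSE)
                    })
    local_dirs <- if (length(include_dirs)) include_dirs else "."
  }
  root <- xml_to_raw(xml2::xml_root(xml))
  if (root$tag != "Lems") {
    stop("root element must be <Lems>, got <", root$tag, ">", call. = FALSE)
  }
  for (child in root$children) {
    doc <- add_root_element(doc, child, local_dirs, state)
  }
  # a file only counts as loaded once fully processed, so that true
  # include cycles are reported rather than silently skipped
  if (!is.null(path)) state$loaded <- c(state$loaded, path)
  doc
}

resolve_include <- function(file, dirs) {
  for (d in dirs) {
    cand <- file.path(d, file)
    if (file.exists(cand)) return(cand)
  }
  NULL
}

add_root_element <- function(doc, raw, dirs, state) {
  tag <- raw$tag
  if (tag == "Target") {
    doc$targets <- c(doc$targets, raw_attr(raw, "component"))
  } else if (tag == "Include") {
    file <- raw_attr(raw, "file")
    path <- resolve_include(file, dirs)
    if (is.null(path)) {
      stop("include file '", file, "' not found (searched: ",
           paste(dirs, collapse = ", "), ")", call. = FALSE)
    }
    doc <- parse_lems_source(doc, path, dirs, state)
  } else if (tag == "Dimension") {
    nm <- raw_attr(raw, "name")
    args <- lapply(lems_base_dimensions(), function(b) {
      v <- raw_attr(raw, b, "0")
      as.numeric(v)
    })
    names(args) <- lems_base_dimensions()
    if (!is.null(doc$dimensions[[nm]])) {
      stop("duplicate dimension name '", nm, "'", call. = FALSE)
    }
    doc$dimensions[[nm]] <- do.call(lems_dimension, c(list(name = nm), args))
  } else if (tag == "Unit") {
    sym <- raw_attr(raw, "symbol")
    dimname <- raw_attr(raw, "dimension")
    if (!is.null(doc$units[[sym]])) {
      stop("duplicate unit symbol '", sym, "'", call. = FALSE)
    }
    # dimension may be a forward reference; store raw and resolve lazily
    doc$units[[sym]] <- list(raw = raw, symbol = sym, dimension = dimname)
  } else if (tag == "Constant") {
    nm <- raw_attr(raw, "name")
    if (!is.null(doc$constants[[nm]])) {
      stop("duplicate constant name '", nm, "'", call. = FALSE)
    }
    doc$constants[[nm]] <- raw_attr(raw, "value")
  } else if (tag == "ComponentType") {
    nm <- raw_attr(raw, "name")
    if (!is.null(doc$types[[nm]])) {
      stop("duplicate component type name '", nm, "'", call. = FALSE)
    }
    doc$types[[nm]] <- raw
  } else {
    # Component, either literal or using the type name as the tag.
    comp <- tryCatch(raw_to_component(raw), error = function(e) e)
    if (inherits(comp, "error")) {
      doc$errors <- c(doc$errors, conditionMessage(comp))
      return(doc)
    }
    comp <- assign_synthetic_ids(comp)
    if (!is.null(doc$components[[comp$id]])) {
      stop("duplicate component id '", comp$id, "'", call. = FALSE)
    }
    doc$components[[comp$id]] <- comp
  }
  doc
}

# Units are stored raw until all dimensions are known; finalize on access.
finalize_units <- function(doc) {
  for (sym in names(doc$units)) {
    u <- doc$units[[sym]]
    if (inherits(u, "lems_unit")) next
    dim <- doc$dimensions[[u$dimension]]
    if (is.null(dim)) {
      stop("unit '", sym, "' references unknown dimension '", u$dimension,
           "'", call. = FALSE)
    }
    doc$units[[sym]] <- lems_unit(
      sym, dim,
      power10 = as.numeric(raw_attr(u$raw, "power", "0")),
      scale = as.numeric(raw_attr(u$raw, "scale", "1")),
      offset = as.numeric(raw_attr(u$raw, "offset", "0")))
  }
  doc
}

#' @export
print.lems_document <- function(x, ...) {
  cat("<lems_document>\n")
  rep <- document_report(x)
  for (nm in names(rep$counts)) {
    cat("  ", nm, ": ", rep$counts[[nm]], "\n", sep = "")
  }
  if (length(rep$targets)) {
    cat("  targets: ", paste(rep$targets, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Summarize a parsed LEMS document
#'
#' @param doc A `lems_document`.
#' @return A list with `counts` (per root element kind), `targets`, and
#'   `unresolved` (dangling targets, unknown component types, unit
#'   dimension references that do not resolve).
#' @export
document_report <- function(doc) {
  counts <- list(dimensions = length(doc$dimensions),
                 units = length(doc$units),
                 constants = length(doc$constants),
                 component_types = length(doc$types),
                 components = length(doc$components),
                 targets = length(doc$targets))
  unresolved <- character()
  for (target in doc$targets) {
    if (is.null(doc$components[[target]])) {
      unresolved <- c(unresolved, paste0("target '", target, "'"))
    }
  }
  for (id in names(doc$components)) {
    tp <- doc$components[[id]]$type
    if (is.null(doc$types[[tp]])) {
      unresolved <- c(unresolved,
                      paste0("component '", id, "' of unknown type '", tp,
                             "'"))
    }
  }
  for (nm in names(doc$types)) {
    ext <- raw_attr(doc$types[[nm]], "extends")
    if (!is.null(ext) && is.null(doc$types[[ext]])) {
      unresolved <- c(unresolved,
                      paste0("type '", nm, "' extends unknown type '", ext,
                             "'"))
    }
  }
  list(counts = counts, targets = doc$targets, unresolved = unresolved,
       errors = doc$errors)
}

# ---- serialization ------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

write_element <- function(tag, attrs, children_text, indent) {
  pad <- strrep("  ", indent)
  astr <- if (length(attrs)) {
    paste0(" ", paste0(names(attrs), "=\"", xml_escape(unname(attrs)), "\"",
                       collapse = " "))
  } else ""
  if (!length(children_text)) {
    paste0(pad, "<", tag, astr, "/>")
  } else {
    paste0(pad, "<", tag, astr, ">\n",
           paste(children_text, collapse = "\n"),
           "\n", pad, "</", tag, ">")
  }
}

raw_element_text <- function(raw, indent) {
  write_element(raw$tag, raw$attrs,
                vapply(raw$children, raw_element_text, character(1),
                       indent = indent + 1L),
                indent)
}

component_text <- function(comp, indent, top = FALSE) {
  attrs <- c(if (!is.na(comp$id)) c(id = comp$id), comp$attrs)
  write_element(comp$tag, attrs,
                vapply(comp$children, component_text, character(1),
                       indent = indent + 1L),
                indent)
}

#' Serialize a LEMS document back to XML text
#'
#' The output re-parses to a structurally identical document (element
#' names, attributes, child order). Included files are emitted as already
#' merged content, flagged with a provenance comment. Output is 2-space
#' indented with attributes in declaration order.
#'
#' @param doc A `lems_document`.
#' @return A single string of XML.
#' @export
serialize_lems <- function(doc) {
  parts <- character()
  for (target in doc$targets) {
    parts <- c(parts, write_element("Target", c(component = target),
                                    character(), 1L))
  }
  for (nm in names(doc$dimensions)) {
    d <- doc$dimensions[[nm]]
    exps <- d$exponents
    attrs <- c(name = nm)
    for (b in lems_base_dimensions()) {
      if (exps[[b]] != 0L) attrs[[b]] <- as.character(exps[[b]])
    }
    parts <- c(parts, write_element("Dimension", attrs, character(), 1L))
  }
  for (sym in names(doc$units)) {
    u <- doc$units[[sym]]
    if (inherits(u, "lems_unit")) {
      attrs <- c(symbol = sym, dimension = u$dimension$name,
                 power = as.character(u$power10))
      if (u$scale != 1) attrs[["scale"]] <- format_num(u$scale)
      if (u$offset != 0) attrs[["offset"]] <- format_num(u$offset)
      parts <- c(parts, write_element("Unit", attrs, character(), 1L))
    } else {
      parts <- c(parts, raw_element_text(u$raw, 1L))
    }
  }
  for (nm in names(doc$constants)) {
    v <- doc$constants[[nm]]
    value <- if (inherits(v, "lems_quantity")) {
      # emit in SI with a matching declared unit when one exists
      format_constant(v, doc)
    } else v
    parts <- c(parts, write_element("Constant",
                                    c(name = nm,
                                      dimension = constant_dim_name(v, doc),
                                      value = value),
                                    character(), 1L))
  }
  for (nm in names(doc$types)) {
    parts <- c(parts, raw_element_text(doc$types[[nm]], 1L))
  }
  for (id in names(doc$components)) {
    parts <- c(parts, component_text(doc$components[[id]], 1L, top = TRUE))
  }
  if (!length(parts)) return("<Lems/>\n")
  paste0("<Lems>\n",
         "  <!-- serialized by lemsim; includes merged -->\n",
         paste(parts, collapse = "\n"), "\n</Lems>\n")
}

constant_dim_name <- function(v, doc) {
  if (!inherits(v, "lems_quantity")) {
    q <- tryCatch(parse_quantity(v, doc$units), error = function(e) NULL)
    if (is.null(q)) return("none")
    v <- q
  }
  for (nm in names(doc$dimensions)) {
    if (dim_equal(doc$dimensions[[nm]], v$dimension)) return(nm)
  }
  v$dimension$name
}

format_constant <- function(q, doc) {
  doc <- finalize_units(doc)
  for (sym in names(doc$units)) {
    u <- doc$units[[sym]]
    if (dim_equal(u$dimension, q$dimension) && u$offset == 0 &&
        u$power10 == 0L && u$scale == 1) {
      return(format_quantity(q, u))
    }
  }
  if (is_dimensionless(q$dimension)) return(format_num(q$magnitude))
  # fall back to any compatible unit
  for (sym in names(doc$units)) {
    u <- doc$units[[sym]]
    if (dim_equal(u$dimension, q$dimension) && u$offset == 0) {
      return(format_quantity(q, u))
    }
  }
  format_num(q$magnitude)
}

# Structural equality of two documents (used by round-trip tests).
lems_structurally_equal <- function(a, b) {
  strip <- function(doc) {
    doc <- finalize_units(doc)
    list(targets = doc$targets,
         dims = lapply(doc$dimensions, function(d) unname(d$exponents)),
         units = lapply(doc$units, function(u)
           list(unname(u$dimension$exponents), u$power10, u$scale,
                u$offset)),
         constants = lapply(doc$constants, function(q)
           if (inherits(q, "lems_quantity"))
             list(q$magnitude, unname(q$dimension$exponents)) else q),
         types = lapply(doc$types, strip_raw),
         components = lapply(doc$components, strip_comp))
  }
  strip_raw <- function(raw) {
    list(raw$tag, as.list(raw$attrs), lapply(raw$children, strip_raw))
  }
  strip_comp <- function(c) {
    list(c$type, c$id, as.list(c$attrs), lapply(c$children, strip_comp))
  }
  isTRUE(all.equal(strip(a), strip(b), tolerance = 1e-12))
}
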