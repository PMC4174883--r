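# ComponentType interpretation and inheritance resolution, Component
# validation against resolved types, and dimension checking of Dynamics.

time_dim <- function() lems_dimension("time", t = 1)

# ---- interpreting a raw ComponentType declaration -----------------------

parse_expr_attr <- function(raw, attr, ctx) {
  txt <- raw_attr(raw, attr)
  if (is.null(txt)) {
    stop("missing '", attr, "' attribute on <", raw$tag, "> in ", ctx,
         call. = FALSE)
  }
  parse_expression(txt)
}

interpret_assignments <- function(raws, ctx) {
  out <- list()
  for (r in raws) {
    if (r$tag == "StateAssignment") {
      out[[length(out) + 1L]] <- list(
        kind = "assign",
        variable = raw_attr(r, "variable"),
        value = parse_expr_attr(r, "value", ctx))
    } else if (r$tag == "EventOut") {
      out[[length(out) + 1L]] <- list(kind = "emit",
                                      port = raw_attr(r, "port"))
    } else if (r$tag == "Transition") {
      out[[length(out) + 1L]] <- list(kind = "transition",
                                      regime = raw_attr(r, "regime"))
    } else {
      stop("unexpected element <", r$tag, "> in ", ctx, call. = FALSE)
    }
  }
  out
}

interpret_dynamics_body <- function(raws, ctx) {
  dyn <- list(state_variables = list(), derived_variables = list(),
              time_derivatives = list(), on_start = list(),
              on_events = list(), on_conditions = list(),
              kinetic_schemes = list())
  for (r in raws) {
    tag <- r$tag
    if (tag == "StateVariable") {
      nm <- raw_attr(r, "name")
      dyn$state_variables[[nm]] <- list(
        name = nm, dimension = raw_attr(r, "dimension", "none"),
        exposure = raw_attr(r, "exposure"))
    } else if (tag == "DerivedVariable") {
      nm <- raw_attr(r, "name")
      sel <- raw_attr(r, "select")
      dyn$derived_variables[[nm]] <- list(
        name = nm, dimension = raw_attr(r, "dimension", "none"),
        exposure = raw_attr(r, "exposure"),
        value = if (is.null(sel)) parse_expr_attr(r, "value", ctx),
        select = sel,
        reduce = raw_attr(r, "reduce", "add"))
    } else if (tag == "TimeDerivative") {
      v <- raw_attr(r, "variable")
      if (!is.null(dyn$time_derivatives[[v]])) {
        stop("duplicate TimeDerivative for state variable '", v, "' in ",
             ctx, call. = FALSE)
      }
      dyn$time_derivatives[[v]] <- parse_expr_attr(r, "value", ctx)
    } else if (tag == "OnStart") {
      dyn$on_start <- c(dyn$on_start, interpret_assignments(r$children, ctx))
    } else if (tag == "OnEvent") {
      dyn$on_events[[length(dyn$on_events) + 1L]] <- list(
        port = raw_attr(r, "port"),
        actions = interpret_assignments(r$children, ctx))
    } else if (tag == "OnCondition") {
      test <- parse_expr_attr(r, "test", ctx)
      if (!is_boolean_ast(test)) {
        stop("OnCondition test must be a boolean expression in ", ctx,
             call. = FALSE)
      }
      dyn$on_conditions[[length(dyn$on_conditions) + 1L]] <- list(
        test = test,
        actions = interpret_assignments(r$children, ctx))
    } else if (tag == "KineticScheme") {
      dyn$kinetic_schemes[[length(dyn$kinetic_schemes) + 1L]] <- list(
        name = raw_attr(r, "name", "ks"),
        nodes = raw_attr(r, "nodes"),
        state_variable = raw_attr(r, "stateVariable"),
        edges = raw_attr(r, "edges"),
        edge_source = raw_attr(r, "edgeSource", "from"),
        edge_target = raw_attr(r, "edgeTarget", "to"),
        forward_rate = raw_attr(r, "forwardRate", "rf"),
        reverse_rate = raw_attr(r, "reverseRate", "rr"))
    } else if (tag == "Regime") {
      # handled by caller
    } else {
      stop("unexpected element <", tag, "> in Dynamics of ", ctx,
           call. = FALSE)
    }
  }
  dyn
}

interpret_regime <- function(r, ctx) {
  body_raws <- Filter(function(ch) ch$tag != "OnEntry", r$children)
  entry_raws <- Filter(function(ch) ch$tag == "OnEntry", r$children)
  body <- interpret_dynamics_body(body_raws, ctx)
  on_entry <- list()
  for (e in entry_raws) {
    on_entry <- c(on_entry, interpret_assignments(e$children, ctx))
  }
  list(name = raw_attr(r, "name"),
       initial = identical(raw_attr(r, "initial", "false"), "true"),
       time_derivatives = body$time_derivatives,
       on_conditions = body$on_conditions,
       on_events = body$on_events,
       on_entry = on_entry)
}

interpret_type <- function(raw, doc) {
  nm <- raw_attr(raw, "name")
  ctx <- paste0("ComponentType '", nm, "'")
  ty <- list(name = nm,
             extends = raw_attr(raw, "extends"),
             parameters = list(), derived_parameters = list(),
             constants = list(), texts = character(),
             exposures = list(), requirements = list(),
             children_slots = list(), refs = list(), attachments = list(),
             ports = list(), dynamics = NULL, regimes = list(),
             structure = list())
  dyn_raw <- NULL
  for (ch in raw$children) {
    tag <- ch$tag
    if (tag == "Parameter") {
      ty$parameters[[raw_attr(ch, "name")]] <- raw_attr(ch, "dimension",
                                                        "none")
    } else if (tag == "DerivedParameter") {
      ty$derived_parameters[[raw_attr(ch, "name")]] <- list(
        dimension = raw_attr(ch, "dimension", "none"),
        value = parse_expr_attr(ch, "value", ctx))
    } else if (tag == "Constant") {
      ty$constants[[raw_attr(ch, "name")]] <- raw_attr(ch, "value")
    } else if (tag == "Text") {
      ty$texts <- c(ty$texts, raw_attr(ch, "name"))
    } else if (tag == "Exposure") {
      ty$exposures[[raw_attr(ch, "name")]] <- raw_attr(ch, "dimension",
                                                       "none")
    } else if (tag == "Requirement") {
      ty$requirements[[raw_attr(ch, "name")]] <- raw_attr(ch, "dimension",
                                                          "none")
    } else if (tag == "Child") {
      ty$children_slots[[raw_attr(ch, "name")]] <- list(
        type = raw_attr(ch, "type"), arity = "one")
    } else if (tag == "Children") {
      ty$children_slots[[raw_attr(ch, "name")]] <- list(
        type = raw_attr(ch, "type"), arity = "many")
    } else if (tag == "ComponentReference") {
      ty$refs[[raw_attr(ch, "name")]] <- raw_attr(ch, "type", NA_character_)
    } else if (tag == "Attachments") {
      ty$attachments[[raw_attr(ch, "name")]] <- raw_attr(ch, "type")
    } else if (tag == "EventPort") {
      ty$ports[[raw_attr(ch, "name")]] <- raw_attr(ch, "direction", "in")
    } else if (tag == "Dynamics") {
      dyn_raw <- ch
    } else if (tag == "Structure") {
      for (d in ch$children) {
        ty$structure[[length(ty$structure) + 1L]] <- c(
          list(directive = d$tag), as.list(d$attrs))
      }
    } else {
      stop("unexpected element <", tag, "> in ", ctx, call. = FALSE)
    }
  }
  if (!is.null(dyn_raw)) {
    ty$dynamics <- interpret_dynamics_body(
      Filter(function(ch) ch$tag != "Regime", dyn_raw$children), ctx)
    for (r in Filter(function(ch) ch$tag == "Regime", dyn_raw$children)) {
      reg <- interpret_regime(r, ctx)
      ty$regimes[[reg$name]] <- reg
    }
  }
  ty
}

# ---- inheritance resolution ---------------------------------------------

merge_named <- function(base, derived, what, type_name,
                        conflict = c("error", "override", "same_dim")) {
  conflict <- match.arg(conflict)
  out <- base
  for (nm in names(derived)) {
    if (!is.null(out[[nm]]) && conflict == "error") {
      stop("type '", type_name, "': ", what, " '", nm,
           "' conflicts with an inherited member", call. = FALSE)
    }
    if (!is.null(out[[nm]]) && conflict == "same_dim" &&
        !identical(out[[nm]], derived[[nm]])) {
      stop("type '", type_name, "': ", what, " '", nm,
           "' redeclared with conflicting dimension ('", out[[nm]],
           "' vs '", derived[[nm]], "')", call. = FALSE)
    }
    out[[nm]] <- derived[[nm]]
  }
  out
}

#' Resolve a component type, merging its inheritance chain
#'
#' An extending type inherits all parameters, exposures, requirements,
#' event ports, child slots, structure and dynamics of its base. A derived
#' type may add members, and may override an inherited DerivedVariable,
#' TimeDerivative or Regime by redeclaring the same name; parameters and
#' exposures may not change dimension. A type satisfies a child-slot
#' requirement for any of its ancestor types.
#'
#' @param name Component type name.
#' @param doc A `lems_document`.
#' @return A resolved type: a list with merged member maps and a `lineage`
#'   (the type itself first, then its ancestors).
#' @export
resolve_type <- function(name, doc) {
  seen <- character()
  resolve <- function(nm) {
    if (nm %in% seen) {
      stop("cyclic extension involving type '", nm, "': ",
           paste(c(seen, nm), collapse = " -> "), call. = FALSE)
    }
    raw <- doc$types[[nm]]
    if (is.null(raw)) {
      stop("unknown component type '", nm, "'", call. = FALSE)
    }
    seen <<- c(seen, nm)
    ty <- interpret_type(raw, doc)
    if (is.null(ty$extends)) {
      ty$lineage <- nm
      return(ty)
    }
    base <- resolve(ty$extends)
    merged <- base
    merged$name <- nm
    merged$lineage <- c(nm, base$lineage)
    merged$extends <- ty$extends
    merged$parameters <- merge_named(base$parameters, ty$parameters,
                                     "parameter", nm, "same_dim")
    merged$exposures <- merge_named(base$exposures, ty$exposures,
                                    "exposure", nm, "same_dim")
    merged$requirements <- merge_named(base$requirements, ty$requirements,
                                       "requirement", nm, "same_dim")
    merged$derived_parameters <- merge_named(
      base$derived_parameters, ty$derived_parameters, "derived parameter",
      nm, "override")
    merged$constants <- merge_named(base$constants, ty$constants,
                                    "constant", nm, "override")
    merged$texts <- union(base$texts, ty$texts)
    merged$children_slots <- merge_named(base$children_slots,
                                         ty$children_slots, "child slot",
                                         nm, "override")
    merged$refs <- merge_named(base$refs, ty$refs, "component reference",
                               nm, "override")
    merged$attachments <- merge_named(base$attachments, ty$attachments,
                                      "attachment", nm, "override")
    merged$ports <- merge_named(base$ports, ty$ports, "event port", nm,
                                "override")
    merged$structure <- c(base$structure, ty$structure)
    merged$dynamics <- merge_dynamics(base$dynamics, ty$dynamics, nm)
    merged$regimes <- merge_named(base$regimes, ty$regimes, "regime", nm,
                                  "override")
    merged
  }
  rt <- resolve(name)
  validate_resolved_type(rt)
  rt
}

merge_dynamics <- function(base, derived, type_name) {
  if (is.null(base)) return(derived)
  if (is.null(derived)) return(base)
  out <- base
  out$state_variables <- merge_named(base$state_variables,
                                     derived$state_variables,
                                     "state variable", type_name,
                                     "same_dim")
  # a derived type may replace an inherited derived variable or time
  # derivative of the same name (specialization)
  out$derived_variables <- merge_named(base$derived_variables,
                                       derived$derived_variables,
                                       "derived variable", type_name,
                                       "override")
  out$time_derivatives <- merge_named(base$time_derivatives,
                                      derived$time_derivatives,
                                      "time derivative", type_name,
                                      "override")
  out$on_start <- c(base$on_start, derived$on_start)
  out$on_events <- c(base$on_events, derived$on_events)
  out$on_conditions <- c(base$on_conditions, derived$on_conditions)
  out$kinetic_schemes <- c(base$kinetic_schemes, derived$kinetic_schemes)
  out
}

validate_resolved_type <- function(rt) {
  # value-namespace uniqueness: parameters, derived parameters, constants,
  # texts, requirements, state variables and derived variables share one
  # namespace. Exposures name published quantities and are bound to the
  # state/derived variable carrying the same exposure tag.
  dyn <- rt$dynamics
  groups <- list(parameter = names(rt$parameters),
                 `derived parameter` = names(rt$derived_parameters),
                 constant = names(rt$constants),
                 text = rt$texts,
                 requirement = names(rt$requirements),
                 `state variable` = if (!is.null(dyn))
                   names(dyn$state_variables) else character(),
                 `derived variable` = if (!is.null(dyn))
                   names(dyn$derived_variables) else character())
  all_names <- unlist(groups, use.names = FALSE)
  dup <- unique(all_names[duplicated(all_names)])
  if (length(dup)) {
    stop("type '", rt$name, "': name collision after inheritance merge: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(rt$regimes)) {
    ini <- vapply(rt$regimes, function(r) isTRUE(r$initial), logical(1))
    if (sum(ini) != 1L) {
      stop("type '", rt$name, "': exactly one regime must carry ",
           "initial=\"true\" (found ", sum(ini), ")", call. = FALSE)
    }
  }
  invisible(rt)
}

# Does type `sub` (resolved or name) extend-or-equal `base_name`?
is_subtype <- function(sub, base_name, doc) {
  lineage <- if (is.character(sub)) resolve_type(sub, doc)$lineage else
    sub$lineage
  base_name %in% lineage
}

# ---- component checking -------------------------------------------------

lookup_dim <- function(dimname, doc, ctx) {
  if (is.null(dimname) || dimname == "none") return(dimensionless())
  d <- doc$dimensions[[dimname]]
  if (is.null(d)) {
    stop("unknown dimension '", dimname, "' referenced by ", ctx,
         call. = FALSE)
  }
  d
}

#' Validate a raw component against its type and bind SI parameter values
#'
#' Every parameter attribute is parsed with [parse_quantity()] and its
#' unit's dimension checked against the declaration; missing and unknown
#' attributes are errors. Child elements are matched to child slots by
#' element name first, then by type compatibility, and slot arity is
#' enforced (exactly one for `Child`, any number for `Children`).
#'
#' @param raw A raw component record from a parsed document (an entry of
#'   `doc$components`).
#' @param doc The `lems_document` it came from.
#' @return A typed component: a list with `id`, `type` (the resolved
#'   type), `params` (named numerics in SI), `texts`, `refs` and
#'   `children` (typed components grouped by slot).
#' @export
check_component <- function(raw, doc) {
  rt <- resolve_type(raw$type, doc)
  ctx <- paste0("component '", raw$id, "' (type ", rt$name, ")")
  params <- list()
  texts <- list()
  refs <- list()
  for (attr_name in names(raw$attrs)) {
    val <- raw$attrs[[attr_name]]
    if (!is.null(rt$parameters[[attr_name]])) {
      q <- tryCatch(parse_quantity(val, doc$units), error = function(e) {
        stop(ctx, ": parameter '", attr_name, "': ", conditionMessage(e),
             call. = FALSE)
      })
      want <- lookup_dim(rt$parameters[[attr_name]], doc, ctx)
      if (!dim_equal(q$dimension, want) &&
          !(q$magnitude == 0 && is_dimensionless(q$dimension))) {
        stop(ctx, ": parameter '", attr_name, "' has dimension '",
             q$dimension$name, "' but '", rt$parameters[[attr_name]],
             "' is required", call. = FALSE)
      }
      params[[attr_name]] <- q$magnitude
    } else if (attr_name %in% rt$texts) {
      texts[[attr_name]] <- val
    } else if (attr_name %in% names(rt$refs)) {
      refs[[attr_name]] <- val
    } else {
      stop(ctx, ": unknown attribute '", attr_name, "'", call. = FALSE)
    }
  }
  missing <- setdiff(names(rt$parameters), names(params))
  if (length(missing)) {
    stop(ctx, ": missing parameter", if (length(missing) > 1) "s", " ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  }
  # reference targets must exist and have (an extension of) the declared type
  for (ref_name in names(refs)) {
    target <- doc$components[[refs[[ref_name]]]]
    if (is.null(target)) {
      stop(ctx, ": reference '", ref_name, "' targets unknown component '",
           refs[[ref_name]], "'", call. = FALSE)
    }
    want_type <- rt$refs[[ref_name]]
    if (!is.na(want_type) && !is_subtype(target$type, want_type, doc)) {
      stop(ctx, ": reference '", ref_name, "' requires type '", want_type,
           "' but component '", target$id, "' has type '", target$type,
           "'", call. = FALSE)
    }
  }
  # global constants are usable in expressions; derived parameters are
  # functions of parameters and constants, evaluated once here
  const_bind <- lapply(doc$constants, function(q) q$magnitude)
  for (cn in names(rt$constants)) {
    params[[cn]] <- parse_quantity(rt$constants[[cn]], doc$units)$magnitude
  }
  for (dp in names(rt$derived_parameters)) {
    spec <- rt$derived_parameters[[dp]]
    params[[dp]] <- eval_expression(spec$value, c(params, const_bind))
  }
  children <- match_children(raw, rt, doc, ctx)
  structure(list(id = raw$id, type = rt, params = params, texts = texts,
                 refs = refs, children = children$by_slot,
                 raw = raw),
            class = "lems_typed_component")
}

match_children <- function(raw, rt, doc, ctx) {
  by_slot <- lapply(rt$children_slots, function(s) list())
  for (ch in raw$children) {
    slot_name <- NULL
    actual <- ch
    if (!is.null(rt$children_slots[[ch$tag]])) {
      # element named after the slot; concrete type from its 'type'
      # attribute, else the slot type itself
      slot_name <- ch$tag
      slot <- rt$children_slots[[slot_name]]
      tname <- raw_attr(ch, "type", slot$type)
      actual$type <- tname
      actual$attrs <- actual$attrs[setdiff(names(actual$attrs), "type")]
    } else {
      # element named after a component type: first slot whose declared
      # type is an ancestor of it
      for (sn in names(rt$children_slots)) {
        slot <- rt$children_slots[[sn]]
        ok <- tryCatch(is_subtype(ch$type, slot$type, doc),
                       error = function(e) FALSE)
        if (ok) {
          slot_name <- sn
          break
        }
      }
      if (is.null(slot_name)) {
        stop(ctx, ": child element <", ch$tag,
             "> does not fit any declared child slot", call. = FALSE)
      }
    }
    slot <- rt$children_slots[[slot_name]]
    typed <- check_component(actual, doc)
    if (!is_subtype(typed$type, slot$type, doc)) {
      stop(ctx, ": child '", typed$id, "' of type '", typed$type$name,
           "' does not extend slot type '", slot$type, "' (slot '",
           slot_name, "')", call. = FALSE)
    }
    by_slot[[slot_name]] <- c(by_slot[[slot_name]], list(typed))
  }
  for (sn in names(rt$children_slots)) {
    slot <- rt$children_slots[[sn]]
    n <- length(by_slot[[sn]])
    if (slot$arity == "one" && n != 1L) {
      stop(ctx, ": child slot '", sn, "' requires exactly one <",
           slot$type, ">, found ", n, call. = FALSE)
    }
  }
  list(by_slot = by_slot)
}

# ---- dynamics dimension checking ----------------------------------------

# Dimension environment for expressions of a resolved type.
type_symbol_dims <- function(rt, doc, extra = list()) {
  ctx <- paste0("type '", rt$name, "'")
  dims <- list(t = time_dim())
  for (nm in names(rt$parameters)) {
    dims[[nm]] <- lookup_dim(rt$parameters[[nm]], doc, ctx)
  }
  for (nm in names(rt$derived_parameters)) {
    dims[[nm]] <- lookup_dim(rt$derived_parameters[[nm]]$dimension, doc,
                             ctx)
  }
  for (nm in names(rt$constants)) {
    dims[[nm]] <- parse_quantity(rt$constants[[nm]], doc$units)$dimension
  }
  for (nm in names(rt$requirements)) {
    dims[[nm]] <- lookup_dim(rt$requirements[[nm]], doc, ctx)
  }
  dyn <- rt$dynamics
  if (!is.null(dyn)) {
    for (nm in names(dyn$state_variables)) {
      dims[[nm]] <- lookup_dim(dyn$state_variables[[nm]]$dimension, doc,
                               ctx)
    }
    for (nm in names(dyn$derived_variables)) {
      dv <- dyn$derived_variables[[nm]]
      dn <- dv$dimension
      if (identical(dn, "none") && !is.null(dv$exposure) &&
          !is.null(rt$exposures[[dv$exposure]])) {
        dn <- rt$exposures[[dv$exposure]]
      }
      dims[[nm]] <- lookup_dim(dn, doc, ctx)
    }
  }
  for (nm in names(doc$constants)) {
    if (is.null(dims[[nm]])) dims[[nm]] <- doc$constants[[nm]]$dimension
  }
  c(dims, extra)
}

check_expr_dim <- function(expr, dims, want, what, report) {
  got <- tryCatch(infer_dimension_raw(expr, dims), error = function(e) e)
  if (inherits(got, "error")) {
    return(c(report, paste0(what, ": ", conditionMessage(got))))
  }
  if (is.null(got)) return(report) # literal 0 matches any dimension
  if (identical(got, "boolean")) {
    if (identical(want, "boolean")) return(report)
    return(c(report, paste0(what, ": boolean expression where '",
                            want$name, "' expected")))
  }
  if (identical(want, "boolean")) {
    return(c(report, paste0(what, ": expected a boolean condition, got '",
                            got$name, "'")))
  }
  if (!dim_equal(got, want)) {
    return(c(report, paste0(what, ": expression has dimension '",
                            got$name, "' but '", want$name,
                            "' is required")))
  }
  report
}

check_handler_dims <- function(actions, dims, rt, doc, where, report,
                               in_event = FALSE) {
  hdims <- dims
  if (in_event) hdims$weight <- dimensionless()
  for (act in actions) {
    if (act$kind == "assign") {
      target <- dims[[act$variable]]
      if (is.null(target)) {
        report <- c(report, paste0(where, ": assignment to unknown ",
                                   "variable '", act$variable, "'"))
        next
      }
      report <- check_expr_dim(act$value, hdims, target,
                               paste0(where, ": assignment to '",
                                      act$variable, "'"), report)
    } else if (act$kind == "emit") {
      if (!identical(rt$ports[[act$port]], "out")) {
        report <- c(report, paste0(where, ": EventOut on '", act$port,
                                   "' which is not an out-port"))
      }
    } else if (act$kind == "transition") {
      if (is.null(rt$regimes[[act$regime]])) {
        report <- c(report, paste0(where, ": transition to unknown ",
                                   "regime '", act$regime, "'"))
      }
    }
  }
  report
}

#' Dimension-check the dynamics of a resolved type
#'
#' For each TimeDerivative of state `X` the expression's dimension must
#' equal `dim(X)/time`; DerivedVariable expressions must match their
#' declared dimension; StateAssignment right-hand sides must match their
#' target; conditions must compare like dimensions. All violations are
#' collected (the check does not stop at the first).
#'
#' @param rt A resolved type from [resolve_type()].
#' @param doc The `lems_document`.
#' @return Character vector of violations; empty when consistent.
#' @export
check_dynamics <- function(rt, doc) {
  report <- character()
  dyn <- rt$dynamics
  if (is.null(dyn) && !length(rt$regimes)) return(report)
  dims <- type_symbol_dims(rt, doc)
  ctx <- paste0("type '", rt$name, "'")
  check_td_set <- function(tds, svs, where, report) {
    for (v in names(tds)) {
      sv <- svs[[v]]
      if (is.null(sv)) {
        report <- c(report, paste0(where, ": TimeDerivative for unknown ",
                                   "state variable '", v, "'"))
        next
      }
      want <- dim_combine(lookup_dim(sv$dimension, doc, ctx), time_dim(),
                          "divide")
      report <- check_expr_dim(tds[[v]], dims, want,
                               paste0(where, ": d", v, "/dt"), report)
    }
    report
  }
  check_conditions <- function(conds, where, report) {
    for (i in seq_along(conds)) {
      oc <- conds[[i]]
      report <- check_expr_dim(oc$test, dims, "boolean",
                               paste0(where, ": OnCondition ", i), report)
      report <- check_handler_dims(oc$actions, dims, rt, doc,
                                   paste0(where, ": OnCondition ", i),
                                   report)
    }
    report
  }
  if (!is.null(dyn)) {
    report <- check_td_set(dyn$time_derivatives, dyn$state_variables,
                           ctx, report)
    for (nm in names(dyn$derived_variables)) {
      dv <- dyn$derived_variables[[nm]]
      if (is.null(dv$value)) next # select paths are checked at build time
      report <- check_expr_dim(dv$value, dims, dims[[nm]],
                               paste0(ctx, ": DerivedVariable '", nm, "'"),
                               report)
    }
    report <- check_handler_dims(dyn$on_start, dims, rt, doc,
                                 paste0(ctx, ": OnStart"), report)
    for (oe in dyn$on_events) {
      if (!identical(rt$ports[[oe$port]], "in")) {
        report <- c(report, paste0(ctx, ": OnEvent on '", oe$port,
                                   "' which is not an in-port"))
      }
      report <- check_handler_dims(oe$actions, dims, rt, doc,
                                   paste0(ctx, ": OnEvent '", oe$port,
                                          "'"), report, in_event = TRUE)
    }
    report <- check_conditions(dyn$on_conditions, ctx, report)
  }
  for (rg in rt$regimes) {
    where <- paste0(ctx, ": regime '", rg$name, "'")
    report <- check_td_set(rg$time_derivatives,
                           if (!is.null(dyn)) dyn$state_variables else
                             list(), where, report)
    report <- check_conditions(rg$on_conditions, where, report)
    report <- check_handler_dims(rg$on_entry, dims, rt, doc,
                                 paste0(where, ": OnEntry"), report)
  }
  report
}

#' Validate an entire document
#'
#' Resolves every component type, checks every top-level component, and
#' dimension-checks the dynamics of every type used. A non-empty result
#' blocks simulation.
#'
#' @param doc A `lems_document`.
#' @return Character vector of all violations found (empty when clean).
#' @export
validate_lems <- function(doc) {
  issues <- c(doc$errors, document_report(doc)$unresolved)
  for (tn in names(doc$types)) {
    rt <- tryCatch(resolve_type(tn, doc), error = function(e) e)
    if (inherits(rt, "error")) {
      issues <- c(issues, conditionMessage(rt))
      next
    }
    issues <- c(issues, check_dynamics(rt, doc))
  }
  for (id in names(doc$components)) {
    tc <- tryCatch(check_component(doc$components[[id]], doc),
                   error = function(e) e)
    if (inherits(tc, "error")) issues <- c(issues, conditionMessage(tc))
  }
  unique(issues)
}
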