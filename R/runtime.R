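# Runtime instance trees: Structure directives (multi-instantiation,
# child instances, event connections with delays/weights and dynamically
# attached receivers), hierarchical value scoping, and the event queue.

# Instance nodes are environments so that state is mutable in place:
#   id, seg, path, typed (lems_typed_component), type (resolved type),
#   params (named numeric, SI), texts, refs, states (named numeric),
#   regime (name or NA), children (seg -> node), collections
#   (slot -> character vector of segs), parent, out_conns (port -> list).

new_instance_node <- function(typed, parent, seg) {
  node <- new.env(parent = emptyenv())
  node$id <- typed$id
  node$seg <- seg
  node$path <- if (is.null(parent)) seg else paste0(parent$path, "/", seg)
  node$typed <- typed
  node$type <- typed$type
  node$params <- typed$params
  node$texts <- typed$texts
  node$refs <- typed$refs
  dyn <- typed$type$dynamics
  svs <- if (!is.null(dyn)) names(dyn$state_variables) else character()
  node$states <- stats::setNames(numeric(length(svs)), svs)
  node$regime <- NA_character_
  node$children <- list()
  node$collections <- list()
  node$parent <- parent
  node$out_conns <- list()
  node
}

add_child_node <- function(parent, node, collection = NULL) {
  if (!is.null(parent$children[[node$seg]])) {
    stop("duplicate instance path '", node$path, "'", call. = FALSE)
  }
  parent$children[[node$seg]] <- node
  if (!is.null(collection)) {
    parent$collections[[collection]] <- c(parent$collections[[collection]],
                                          node$seg)
  }
  node
}

# Phase 1: instantiate a typed component and its contained children,
# executing instantiation directives (MultiInstantiate, ChildInstance).
instantiate_component <- function(typed, doc, parent = NULL,
                                  seg = typed$id) {
  node <- new_instance_node(typed, parent, seg)
  for (slot in names(typed$children)) {
    slot_spec <- typed$type$children_slots[[slot]]
    for (child_typed in typed$children[[slot]]) {
      child_seg <- if (slot_spec$arity == "one") slot else child_typed$id
      add_child_node(node, instantiate_component(child_typed, doc, node,
                                                 child_seg),
                     collection = slot)
    }
  }
  for (slot in names(typed$type$attachments)) {
    node$collections[[slot]] <- character()
  }
  for (d in typed$type$structure) {
    if (d$directive == "MultiInstantiate") {
      count <- node$params[[d$number]]
      if (is.null(count) || !is.finite(count) || count < 0 ||
          count != round(count)) {
        stop("instance '", node$path, "': population count parameter '",
             d$number, "' must be a non-negative integer, got ",
             deparse(count), call. = FALSE)
      }
      ref_id <- node$refs[[d$component]]
      if (is.null(ref_id)) {
        stop("instance '", node$path, "': unresolvable component ",
             "reference '", d$component, "'", call. = FALSE)
      }
      ref_typed <- check_component(doc$components[[ref_id]], doc)
      for (k in seq_len(count) - 1L) {
        add_child_node(node,
                       instantiate_component(ref_typed, doc, node,
                                             paste0(ref_id, "[", k, "]")),
                       collection = d$component)
      }
    } else if (d$directive == "ChildInstance") {
      ref_id <- node$refs[[d$component]]
      if (is.null(ref_id)) {
        stop("instance '", node$path, "': unresolvable component ",
             "reference '", d$component, "'", call. = FALSE)
      }
      ref_typed <- check_component(doc$components[[ref_id]], doc)
      add_child_node(node, instantiate_component(ref_typed, doc, node,
                                                 d$component))
    }
  }
  node
}

# Resolve an instance path relative to `node`; "." is the node itself.
# If the first segment does not match below `node`, the search falls back
# to the parent (connection components address siblings through their
# enclosing network).
resolve_path <- function(node, path) {
  if (identical(path, ".")) return(node)
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  walk <- function(from) {
    cur <- from
    for (s in segs) {
      nxt <- cur$children[[s]]
      if (is.null(nxt)) return(NULL)
      cur <- nxt
    }
    cur
  }
  hit <- walk(node)
  if (is.null(hit) && !is.null(node$parent)) hit <- walk(node$parent)
  if (is.null(hit)) {
    stop("cannot resolve instance path '", path, "' from '", node$path,
         "'", call. = FALSE)
  }
  hit
}

# from/to/port attributes may name a Text member of the declaring
# component; otherwise they are literal.
structure_attr_value <- function(node, value) {
  if (!is.null(value) && !is.null(node$texts[[value]])) {
    node$texts[[value]]
  } else {
    value
  }
}

structure_quantity <- function(node, value, doc, default) {
  if (is.null(value)) return(default)
  if (!is.null(node$params[[value]])) return(node$params[[value]])
  parse_quantity(value, doc$units)$magnitude
}

#' Connect an out-port to an in-port (optionally attaching a receiver)
#'
#' When `receiver` is given, a fresh instance of that component is
#' created in the target node's `receiver_container` attachment slot
#' (instances are named `slot[k]` in creation order) and the connection
#' targets the new instance. When the source emits, an event is enqueued
#' for delivery at `t_emit + delay`; `weight` is made available to the
#' receiving handler as a reserved symbol.
#'
#' @param source,target Instance nodes (see [build_instance_tree()]).
#' @param source_port,target_port Port names; directions are checked.
#' @param delay Delay in seconds (default 0).
#' @param weight Weight factor (default 1).
#' @param receiver Optional typed component to attach onto `target`.
#' @param receiver_container Attachment slot name on `target`.
#' @param doc The document (needed to instantiate a receiver).
#' @return The node whose in-port is connected (invisibly).
#' @export
connect_event <- function(source, target, source_port, target_port,
                          delay = 0, weight = 1, receiver = NULL,
                          receiver_container = NULL, doc = NULL) {
  if (!identical(source$type$ports[[source_port]], "out")) {
    stop("'", source$path, "' has no out-port '", source_port, "'",
         call. = FALSE)
  }
  if (!is.null(receiver)) {
    slot_type <- target$type$attachments[[receiver_container]]
    if (is.null(slot_type)) {
      stop("'", target$path, "' has no attachment slot '",
           receiver_container, "'", call. = FALSE)
    }
    if (!is_subtype(receiver$type, slot_type, doc)) {
      stop("receiver '", receiver$id, "' of type '", receiver$type$name,
           "' is incompatible with attachment slot '", receiver_container,
           "' (requires '", slot_type, "')", call. = FALSE)
    }
    k <- length(target$collections[[receiver_container]])
    inst <- instantiate_component(receiver, doc, target,
                                  paste0(receiver_container, "[", k, "]"))
    add_child_node(target, inst, collection = receiver_container)
    run_structure_connections(inst, doc)
    target <- inst
  }
  if (!identical(target$type$ports[[target_port]], "in")) {
    stop("'", target$path, "' has no in-port '", target_port, "'",
         call. = FALSE)
  }
  conn <- list(target = target, port = target_port,
               delay = as.numeric(delay), weight = as.numeric(weight))
  node_conns <- source$out_conns[[source_port]]
  source$out_conns[[source_port]] <-
    c(if (is.null(node_conns)) list() else node_conns, list(conn))
  invisible(target)
}

# Phase 2: execute EventConnection directives over a built subtree.
run_structure_connections <- function(node, doc) {
  for (d in node$typed$type$structure) {
    if (d$directive != "EventConnection") next
    from_path <- structure_attr_value(node, d$from)
    to_path <- structure_attr_value(node, d$to)
    source <- resolve_path(node, from_path)
    target <- resolve_path(node, to_path)
    src_port <- structure_attr_value(node, d$sourcePort)
    tgt_port <- structure_attr_value(node, d$targetPort)
    delay <- structure_quantity(node, d$delay, doc, 0)
    weight <- if (is.null(d$weight)) 1 else {
      if (!is.null(node$params[[d$weight]])) node$params[[d$weight]] else
        as.numeric(d$weight)
    }
    receiver <- NULL
    if (!is.null(d$receiver) && !is.null(node$refs[[d$receiver]])) {
      receiver <- check_component(doc$components[[node$refs[[d$receiver]]]],
                                  doc)
    }
    connect_event(source, target, src_port, tgt_port, delay, weight,
                  receiver = receiver,
                  receiver_container = d$receiverContainer, doc = doc)
  }
  for (child in node$children) run_structure_connections(child, doc)
}

walk_instances <- function(node, fn) {
  fn(node)
  for (child in node$children) walk_instances(child, fn)
  invisible(NULL)
}

# ---- scoped value access (tree walk) ------------------------------------

# Exposure name -> backing variable name for a resolved type.
exposure_variable <- function(rt, exposure) {
  dyn <- rt$dynamics
  if (!is.null(dyn)) {
    for (nm in names(dyn$state_variables)) {
      if (identical(dyn$state_variables[[nm]]$exposure, exposure)) {
        return(nm)
      }
    }
    for (nm in names(dyn$derived_variables)) {
      if (identical(dyn$derived_variables[[nm]]$exposure, exposure)) {
        return(nm)
      }
    }
  }
  NULL
}

parse_select <- function(select) {
  segs <- strsplit(select, "/", fixed = TRUE)[[1]]
  var <- segs[length(segs)]
  segs <- segs[-length(segs)]
  wildcard <- length(segs) == 1L && grepl("\\[\\*\\]$", segs[1])
  list(var = var,
       slot = if (wildcard) sub("\\[\\*\\]$", "", segs[1]) else NULL,
       path = if (!wildcard) paste(segs, collapse = "/") else NULL)
}

# Evaluate a local value symbol on a node: state, parameter, derived
# variable (on demand), global constant, requirement (nearest ancestor
# exposure), or the reserved time symbol t.
#' Resolve a value symbol on an instance node
#'
#' Local scope first (states, parameters, derived variables); a
#' Requirement of the node's type searches ancestors nearest-first for an
#' exposure of that name. Values are current as of the evaluation time.
#'
#' @param node An instance node from [build_instance_tree()].
#' @param symbol Symbol name (e.g. `"v"`).
#' @param t Simulation time in seconds.
#' @param doc The `lems_document` (for global constants).
#' @return Numeric scalar.
#' @export
resolve_value <- function(node, symbol, t = 0, doc = NULL) {
  tree_eval_symbol(node, symbol, t, doc)
}

tree_eval_symbol <- function(node, sym, t, doc, weight = NULL) {
  if (sym == "t") return(t)
  if (!is.null(weight) && sym == "weight") return(weight)
  sv <- node$states
  if (sym %in% names(sv)) return(sv[[sym]])
  p <- node$params[[sym]]
  if (!is.null(p)) return(p)
  dyn <- node$type$dynamics
  if (!is.null(dyn) && !is.null(dyn$derived_variables[[sym]])) {
    return(tree_eval_derived(node, sym, t, doc))
  }
  if (sym %in% names(node$type$requirements)) {
    anc <- node$parent
    while (!is.null(anc)) {
      var <- exposure_variable(anc$type, sym)
      if (!is.null(var) && !is.null(anc$type$exposures[[sym]])) {
        return(tree_eval_symbol(anc, var, t, doc))
      }
      anc <- anc$parent
    }
    stop("instance '", node$path, "': requirement '", sym,
         "' is not exposed by any ancestor", call. = FALSE)
  }
  if (!is.null(doc) && !is.null(doc$constants[[sym]])) {
    return(doc$constants[[sym]]$magnitude)
  }
  stop("instance '", node$path, "': cannot resolve symbol '", sym, "'",
       call. = FALSE)
}

tree_eval_derived <- function(node, dvname, t, doc) {
  dv <- node$type$dynamics$derived_variables[[dvname]]
  if (!is.null(dv$select)) {
    sel <- parse_select(dv$select)
    if (!is.null(sel$slot)) {
      members <- node$collections[[sel$slot]]
      vals <- vapply(members, function(seg) {
        tree_eval_exposed(node$children[[seg]], sel$var, t, doc)
      }, numeric(1))
      if (identical(dv$reduce, "multiply")) {
        return(prod(vals)) # empty product is 1
      }
      return(sum(vals))    # empty sum is 0
    }
    child <- resolve_path(node, sel$path)
    return(tree_eval_exposed(child, sel$var, t, doc))
  }
  tree_eval_expr(dv$value, node, t, doc)
}

# A selected quantity on a child may be named by exposure or by variable.
tree_eval_exposed <- function(node, var, t, doc) {
  if (!is.null(node$type$exposures[[var]])) {
    backed <- exposure_variable(node$type, var)
    if (!is.null(backed)) var <- backed
  }
  tree_eval_symbol(node, var, t, doc)
}

tree_eval_expr <- function(ast, node, t, doc, weight = NULL) {
  ev <- function(a) {
    switch(a$kind,
      num = a$value,
      sym = tree_eval_symbol(node, a$name, t, doc, weight),
      neg = -ev(a$arg),
      bin = {
        l <- ev(a$lhs); r <- ev(a$rhs)
        switch(a$op, "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r,
               "^" = l^r)
      },
      rel = {
        l <- ev(a$lhs); r <- ev(a$rhs)
        switch(a$op, ".lt." = l < r, ".gt." = l > r, ".leq." = l <= r,
               ".geq." = l >= r, ".eq." = l == r, ".neq." = l != r)
      },
      logic = {
        if (a$op == ".and.") ev(a$lhs) && ev(a$rhs) else
          ev(a$lhs) || ev(a$rhs)
      },
      call = apply_lems_fn(a$fn, lapply(a$args, ev), node$path),
      linoid = linoid_val(ev(a$arg)),
      stop("unknown AST node kind", call. = FALSE))
  }
  ev(ast)
}

# ---- initialization (phase 3) -------------------------------------------

run_assignments <- function(actions, node, t, doc, weight = NULL,
                            sink = NULL) {
  for (act in actions) {
    if (act$kind == "assign") {
      node$states[[act$variable]] <-
        tree_eval_expr(act$value, node, t, doc, weight)
    } else if (act$kind == "emit" && !is.null(sink)) {
      sink(node, act$port)
    } else if (act$kind == "transition") {
      enter_regime(node, act$regime, t, doc, sink)
    }
  }
}

enter_regime <- function(node, regime, t, doc, sink = NULL) {
  rg <- node$type$regimes[[regime]]
  if (is.null(rg)) {
    stop("instance '", node$path, "': unknown regime '", regime, "'",
         call. = FALSE)
  }
  node$regime <- regime
  run_assignments(rg$on_entry, node, t, doc, sink = sink)
  invisible(node)
}

# Initialize states: zeros, then OnStart in document order parent-first,
# then kinetic-scheme defaults, then the initial regime's OnEntry.
initialize_instances <- function(root, doc) {
  walk_instances(root, function(node) {
    dyn <- node$type$dynamics
    if (!is.null(dyn)) {
      run_assignments(dyn$on_start, node, 0, doc)
      for (ks in dyn$kinetic_schemes) {
        members <- node$collections[[ks$nodes]]
        occ <- vapply(members, function(seg) {
          node$children[[seg]]$states[[ks$state_variable]]
        }, numeric(1))
        if (length(members) && all(occ == 0)) {
          node$children[[members[1]]]$states[[ks$state_variable]] <- 1
        }
      }
    }
    if (length(node$type$regimes)) {
      ini <- names(node$type$regimes)[vapply(node$type$regimes,
                                             function(r) isTRUE(r$initial),
                                             logical(1))]
      enter_regime(node, ini[1], 0, doc)
    }
  })
  invisible(root)
}

#' Build the runtime instance tree for a target component
#'
#' Instantiates the component depth-first: `MultiInstantiate` creates
#' `count` sibling instances with independent state, `ChildInstance`
#' instantiates referenced components as named children, and
#' `EventConnection` directives wire event ports (attaching receiver
#' components per connection where declared). State variables start at 0,
#' `OnStart` assignments are applied in document order (parents first),
#' kinetic-scheme occupancies default to the first declared state, and
#' the initial regime is entered with its `OnEntry` applied.
#'
#' @param doc A `lems_document`.
#' @param target_id Component id to instantiate; defaults to the
#'   document's Target (following a Simulation element's `target`
#'   reference when present).
#' @return The root instance node (an environment).
#' @export
build_instance_tree <- function(doc, target_id = NULL) {
  if (is.null(target_id)) {
    if (!length(doc$targets)) {
      stop("document has no Target element; pass target_id", call. = FALSE)
    }
    target_id <- doc$targets[[1]]
    tc <- doc$components[[target_id]]
    if (!is.null(tc) && tc$type == "Simulation") {
      target_id <- tc$attrs[["target"]]
    }
  }
  raw <- doc$components[[target_id]]
  if (is.null(raw)) {
    stop("no component with id '", target_id, "' to instantiate",
         call. = FALSE)
  }
  typed <- check_component(raw, doc)
  root <- instantiate_component(typed, doc)
  run_structure_connections(root, doc)
  initialize_instances(root, doc)
  root
}

# ---- event queue --------------------------------------------------------

#' Create an empty event queue
#'
#' Events are ordered by (delivery time, insertion sequence); an event is
#' never delivered before its delivery time and delivery is FIFO among
#' equal times.
#'
#' @return An event queue object.
#' @export
event_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$events <- list()
  q$seq <- 0L
  class(q) <- "lems_event_queue"
  q
}

#' Schedule an event for delivery
#' @param queue An [event_queue()].
#' @param time Delivery time (seconds).
#' @param node Target instance node.
#' @param port Target in-port name.
#' @param weight Weight factor made available to the handler.
#' @export
schedule_event <- function(queue, time, node, port, weight = 1) {
  queue$seq <- queue$seq + 1L
  queue$events[[length(queue$events) + 1L]] <-
    list(time = time, seq = queue$seq, node = node, port = port,
         weight = weight)
  invisible(queue)
}

#' Remove and return all events due at or before `now`
#'
#' FIFO within equal delivery times; `now` must be non-decreasing across
#' calls.
#'
#' @param queue An [event_queue()].
#' @param now Current time (seconds).
#' @return List of events, each `list(time, node, port, weight)`.
#' @export
deliver_due_events <- function(queue, now) {
  if (!length(queue$events)) return(list())
  times <- vapply(queue$events, `[[`, numeric(1), "time")
  due_idx <- which(times <= now)
  if (!length(due_idx)) return(list())
  seqs <- vapply(queue$events[due_idx], `[[`, numeric(1), "seq")
  ord <- due_idx[order(times[due_idx], seqs)]
  due <- queue$events[ord]
  queue$events <- queue$events[-due_idx]
  due
}
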