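# Simulation engine: flattening of the instance tree into a compiled ODE
# system, fixed-step forward-Euler and 4th-order Runge-Kutta integration,
# discrete-event handling with edge-triggered conditions and regime
# transitions, kinetic-scheme occupancy dynamics, and trace recording.
#
# Update order within a step: (1) ODE update of the active-regime states,
# (2) delivery of due events and OnEvent handlers (drained to a fixpoint
# so zero-delay relays land within the same step), (3) OnCondition edge
# detection and handlers in document order, with regime OnEntry applied
# on transition, (4) a second drain for events emitted by condition
# handlers, (5) recomputation of derived variables, (6) recording.

# ---- flattening ---------------------------------------------------------

sanitize_path <- function(path) {
  gsub("[^A-Za-z0-9_]", "_", path)
}

flat_key <- function(node, var) paste0(node$path, "|", var)

collect_instances <- function(root) {
  out <- list()
  walk_instances(root, function(node) out[[length(out) + 1L]] <<- node)
  out
}

# Dependencies of one derived variable, as keys of other derived vars.
derived_deps <- function(node, dvname, doc) {
  dv <- node$type$dynamics$derived_variables[[dvname]]
  deps <- character()
  add_target <- function(tnode, var) {
    if (!is.null(tnode$type$exposures[[var]])) {
      backed <- exposure_variable(tnode$type, var)
      if (!is.null(backed)) var <- backed
    }
    dyn <- tnode$type$dynamics
    if (!is.null(dyn) && !is.null(dyn$derived_variables[[var]])) {
      deps <<- c(deps, flat_key(tnode, var))
    }
  }
  if (!is.null(dv$select)) {
    sel <- parse_select(dv$select)
    if (!is.null(sel$slot)) {
      for (seg in node$collections[[sel$slot]]) {
        add_target(node$children[[seg]], sel$var)
      }
    } else {
      add_target(resolve_path(node, sel$path), sel$var)
    }
    return(deps)
  }
  for (s in expr_symbols(dv$value)) {
    dyn <- node$type$dynamics
    if (!is.null(dyn$derived_variables[[s]])) {
      deps <- c(deps, flat_key(node, s))
    } else if (s %in% names(node$type$requirements) &&
               !s %in% names(node$states) &&
               is.null(node$params[[s]])) {
      anc <- node$parent
      while (!is.null(anc)) {
        if (!is.null(anc$type$exposures[[s]])) {
          add_target(anc, s)
          break
        }
        anc <- anc$parent
      }
    }
  }
  deps
}

topo_sort_derived <- function(entries, doc) {
  keys <- vapply(entries, function(e) e$key, character(1))
  deps <- lapply(entries, function(e) derived_deps(e$node, e$name, doc))
  names(deps) <- keys
  order <- character()
  state <- stats::setNames(rep(0L, length(keys)), keys) # 0 new 1 open 2 done
  visit <- function(key, stack) {
    if (state[[key]] == 2L) return(invisible(NULL))
    if (state[[key]] == 1L) {
      cyc <- c(stack[which(stack == key):length(stack)], key)
      stop("cycle among derived variables: ",
           paste(cyc, collapse = " -> "), call. = FALSE)
    }
    state[[key]] <<- 1L
    for (d in deps[[key]]) {
      if (d %in% keys) visit(d, c(stack, key))
    }
    state[[key]] <<- 2L
    order[[length(order) + 1L]] <<- key
    invisible(NULL)
  }
  for (k in keys) visit(k, character())
  entries[match(order, keys)]
}

#' Flatten a built instance tree into a compiled ODE system
#'
#' Scoped symbols are renamed with path prefixes, requirements are bound
#' to their resolved ancestor slots, derived variables are topologically
#' ordered (cycles are rejected), and the derivative and derived-variable
#' evaluations are compiled to R functions over a flat state vector.
#' Evaluating the flattened derivatives at any state equals evaluating
#' the instance tree at the same state.
#'
#' @param root Root instance node from [build_instance_tree()].
#' @param doc The `lems_document`.
#' @return A `lems_flat_system`.
#' @export
flatten <- function(root, doc) {
  instances <- collect_instances(root)
  state_index <- new.env(parent = emptyenv())
  y_names <- character()
  i <- 0L
  for (node in instances) {
    for (var in names(node$states)) {
      i <- i + 1L
      assign(flat_key(node, var), i, envir = state_index)
      y_names[i] <- paste0(node$path, "/", var)
    }
  }
  n_state <- i
  # regime slots
  regime_slot <- new.env(parent = emptyenv())
  regime_levels <- list()
  rg0 <- integer()
  for (node in instances) {
    if (length(node$type$regimes)) {
      slot <- length(rg0) + 1L
      assign(node$path, slot, envir = regime_slot)
      regime_levels[[slot]] <- names(node$type$regimes)
      rg0[slot] <- match(node$regime, names(node$type$regimes))
    }
  }
  # derived variables, topologically ordered
  entries <- list()
  for (node in instances) {
    dyn <- node$type$dynamics
    if (is.null(dyn)) next
    for (nm in names(dyn$derived_variables)) {
      entries[[length(entries) + 1L]] <-
        list(key = flat_key(node, nm), node = node, name = nm)
    }
  }
  entries <- topo_sort_derived(entries, doc)
  dlocal <- stats::setNames(
    paste0("D", seq_along(entries)),
    vapply(entries, function(e) e$key, character(1)))

  frag_state <- function(node, var) {
    sprintf("y[[%dL]]", get(flat_key(node, var), envir = state_index))
  }
  frag_exposed <- function(tnode, var) {
    if (!is.null(tnode$type$exposures[[var]])) {
      backed <- exposure_variable(tnode$type, var)
      if (!is.null(backed)) var <- backed
    }
    frag_sym(tnode, var)
  }
  frag_sym <- function(node, s) {
    if (s == "t") return("t")
    if (s %in% names(node$states)) return(frag_state(node, s))
    dyn <- node$type$dynamics
    if (!is.null(dyn) && !is.null(dyn$derived_variables[[s]])) {
      return(dlocal[[flat_key(node, s)]])
    }
    if (!is.null(node$params[[s]])) return(format_num(node$params[[s]]))
    if (s %in% names(node$type$requirements)) {
      anc <- node$parent
      while (!is.null(anc)) {
        if (!is.null(anc$type$exposures[[s]])) {
          return(frag_exposed(anc, s))
        }
        anc <- anc$parent
      }
      stop("instance '", node$path, "': requirement '", s,
           "' is not exposed by any ancestor", call. = FALSE)
    }
    if (!is.null(doc$constants[[s]])) {
      return(format_num(doc$constants[[s]]$magnitude))
    }
    stop("instance '", node$path, "': cannot compile symbol '", s, "'",
         call. = FALSE)
  }
  frag_expr <- function(ast, node) {
    symmap <- list()
    for (s in expr_symbols(ast)) symmap[[s]] <- frag_sym(node, s)
    ast_to_rcode(ast, symmap)
  }
  frag_derived <- function(e) {
    dv <- e$node$type$dynamics$derived_variables[[e$name]]
    if (is.null(dv$select)) return(frag_expr(dv$value, e$node))
    sel <- parse_select(dv$select)
    if (!is.null(sel$slot)) {
      members <- e$node$collections[[sel$slot]]
      frags <- vapply(members, function(seg) {
        frag_exposed(e$node$children[[seg]], sel$var)
      }, character(1))
      if (identical(dv$reduce, "multiply")) {
        if (!length(frags)) return("1")
        return(paste0("(", paste(frags, collapse = " * "), ")"))
      }
      if (!length(frags)) return("0")
      return(paste0("(", paste(frags, collapse = " + "), ")"))
    }
    frag_exposed(resolve_path(e$node, sel$path), sel$var)
  }

  derived_lines <- vapply(entries, function(e) {
    paste0("  ", dlocal[[e$key]], " <- ", frag_derived(e))
  }, character(1))

  # derivative lines, including regime gating and kinetic schemes
  dy_lines <- character()
  for (node in instances) {
    dyn <- node$type$dynamics
    if (is.null(dyn)) next
    top_tds <- dyn$time_derivatives
    for (var in names(top_tds)) {
      idx <- get(flat_key(node, var), envir = state_index)
      dy_lines <- c(dy_lines, paste0(
        "  dy[", idx, "L] <- ", frag_expr(top_tds[[var]], node)))
    }
    if (length(node$type$regimes)) {
      slot <- get(node$path, envir = regime_slot)
      regime_vars <- unique(unlist(lapply(node$type$regimes, function(r) {
        names(r$time_derivatives)
      })))
      for (var in regime_vars) {
        idx <- get(flat_key(node, var), envir = state_index)
        branches <- character()
        for (ri in seq_along(node$type$regimes)) {
          r <- node$type$regimes[[ri]]
          td <- r$time_derivatives[[var]]
          if (is.null(td)) next
          branches <- c(branches, paste0(
            "if (rg[", slot, "L] == ", ri, "L) ",
            frag_expr(td, node)))
        }
        dy_lines <- c(dy_lines, paste0(
          "  dy[", idx, "L] <- ", paste(branches, collapse = " else "),
          " else 0"))
      }
    }
    for (ks in dyn$kinetic_schemes) {
      members <- node$collections[[ks$nodes]]
      occ_idx <- stats::setNames(
        vapply(members, function(seg) {
          get(flat_key(node$children[[seg]], ks$state_variable),
              envir = state_index)
        }, integer(1)),
        vapply(members, function(seg) node$children[[seg]]$id,
               character(1)))
      terms <- stats::setNames(rep(list(character()), length(occ_idx)),
                               names(occ_idx))
      for (eseg in node$collections[[ks$edges]]) {
        edge <- node$children[[eseg]]
        from <- edge$texts[[ks$edge_source]]
        to <- edge$texts[[ks$edge_target]]
        if (is.null(from) || is.null(to) ||
            !(from %in% names(occ_idx)) || !(to %in% names(occ_idx))) {
          stop("kinetic scheme '", ks$name, "' on '", node$path,
               "': edge '", edge$id, "' references unknown states",
               call. = FALSE)
        }
        rf <- frag_exposed(edge, ks$forward_rate)
        rr <- frag_exposed(edge, ks$reverse_rate)
        ofrom <- sprintf("y[[%dL]]", occ_idx[[from]])
        oto <- sprintf("y[[%dL]]", occ_idx[[to]])
        terms[[from]] <- c(terms[[from]],
                           paste0("- ", rf, " * ", ofrom),
                           paste0("+ ", rr, " * ", oto))
        terms[[to]] <- c(terms[[to]],
                         paste0("+ ", rf, " * ", ofrom),
                         paste0("- ", rr, " * ", oto))
      }
      for (st in names(terms)) {
        if (!length(terms[[st]])) next
        dy_lines <- c(dy_lines, paste0(
          "  dy[", occ_idx[[st]], "L] <- ",
          paste(terms[[st]], collapse = " ")))
      }
    }
  }

  rate_text <- paste0(
    "function(t, y, rg) {\n",
    paste(derived_lines, collapse = "\n"),
    if (length(derived_lines)) "\n" else "",
    "  dy <- numeric(", n_state, "L)\n",
    paste(dy_lines, collapse = "\n"),
    if (length(dy_lines)) "\n" else "",
    "  dy\n}")
  derived_text <- paste0(
    "function(t, y, rg) {\n",
    paste(derived_lines, collapse = "\n"),
    if (length(derived_lines)) "\n" else "",
    "  c(", paste(vapply(seq_along(entries), function(k) {
      paste0("`", entries[[k]]$key, "` = ", dlocal[[entries[[k]]$key]])
    }, character(1)), collapse = ",\n    "), ")\n}")
  if (!length(entries)) {
    derived_text <- "function(t, y, rg) numeric(0)"
  }

  y0 <- numeric(n_state)
  for (node in instances) {
    for (var in names(node$states)) {
      y0[get(flat_key(node, var), envir = state_index)] <-
        node$states[[var]]
    }
  }
  names(y0) <- y_names

  structure(list(
    root = root, doc = doc, instances = instances,
    state_index = state_index, y0 = y0, n_state = n_state,
    regime_slot = regime_slot, regime_levels = regime_levels, rg0 = rg0,
    rate_fn = eval(parse(text = rate_text)[[1]]),
    derived_fn = eval(parse(text = derived_text)[[1]]),
    rate_text = rate_text,
    kinetic_groups = kinetic_groups(instances, state_index)),
    class = "lems_flat_system")
}

kinetic_groups <- function(instances, state_index) {
  groups <- list()
  for (node in instances) {
    dyn <- node$type$dynamics
    if (is.null(dyn)) next
    for (ks in dyn$kinetic_schemes) {
      idx <- vapply(node$collections[[ks$nodes]], function(seg) {
        get(flat_key(node$children[[seg]], ks$state_variable),
            envir = state_index)
      }, integer(1))
      if (length(idx)) groups[[length(groups) + 1L]] <- unname(idx)
    }
  }
  groups
}

#' @export
print.lems_flat_system <- function(x, ...) {
  cat("<lems_flat_system> ", x$n_state, " state variables, ",
      length(x$instances), " instances\n", sep = "")
  invisible(x)
}

# ---- simulation spec ----------------------------------------------------

read_simulation_spec <- function(doc) {
  if (!length(doc$targets)) return(NULL)
  raw <- doc$components[[doc$targets[[1]]]]
  if (is.null(raw) || raw$type != "Simulation") return(NULL)
  typed <- check_component(raw, doc)
  sinks <- list()
  event_files <- character()
  records <- character()
  for (of in typed$children[["outputs"]]) {
    cols <- vapply(of$children[["columns"]], function(col) {
      col$texts[["quantity"]]
    }, character(1))
    ids <- vapply(of$children[["columns"]], function(col) col$id,
                  character(1))
    names(cols) <- ids
    sinks[[of$texts[["fileName"]]]] <- cols
    records <- c(records, cols)
  }
  for (ef in typed$children[["eventOutputs"]]) {
    event_files <- c(event_files, ef$texts[["fileName"]])
  }
  list(target = typed$refs[["target"]],
       step = typed$params[["step"]],
       length = typed$params[["length"]],
       records = records, sinks = sinks, event_files = event_files)
}

resolve_record_path <- function(root, path) {
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  var <- segs[length(segs)]
  node <- if (length(segs) > 1L) {
    resolve_path(root, paste(segs[-length(segs)], collapse = "/"))
  } else {
    root
  }
  if (!is.null(node$type$exposures[[var]])) {
    backed <- exposure_variable(node$type, var)
    if (!is.null(backed)) var <- backed
  }
  dyn <- node$type$dynamics
  is_state <- var %in% names(node$states)
  is_derived <- !is.null(dyn) && !is.null(dyn$derived_variables[[var]])
  if (!is_state && !is_derived && is.null(node$params[[var]])) {
    stop("record path '", path, "' does not resolve to a state, derived ",
         "variable or parameter", call. = FALSE)
  }
  list(node = node, var = var,
       kind = if (is_state) "state" else if (is_derived) "derived" else
         "param")
}

# ---- condition / event rule tables --------------------------------------

build_rules <- function(instances) {
  conds <- list()
  events <- list()
  for (node in instances) {
    dyn <- node$type$dynamics
    if (!is.null(dyn)) {
      for (oc in dyn$on_conditions) {
        conds[[length(conds) + 1L]] <-
          list(node = node, regime = NA_character_, test = oc$test,
               actions = oc$actions)
      }
      for (oe in dyn$on_events) {
        events[[length(events) + 1L]] <-
          list(node = node, regime = NA_character_, port = oe$port,
               actions = oe$actions)
      }
    }
    for (rg in node$type$regimes) {
      for (oc in rg$on_conditions) {
        conds[[length(conds) + 1L]] <-
          list(node = node, regime = rg$name, test = oc$test,
               actions = oc$actions)
      }
      for (oe in rg$on_events) {
        events[[length(events) + 1L]] <-
          list(node = node, regime = rg$name, port = oe$port,
               actions = oe$actions)
      }
    }
  }
  list(conditions = conds, events = events)
}

rule_active <- function(rule) {
  is.na(rule$regime) || identical(rule$node$regime, rule$regime)
}

# ---- backends -----------------------------------------------------------

# A backend provides expression evaluation against the current state plus
# state mutation; the hybrid event loop is shared.

make_flat_backend <- function(fs) {
  env <- new.env(parent = emptyenv())
  env$y <- fs$y0
  env$rg <- fs$rg0
  env$derived <- NULL
  invalidate <- function() env$derived <- NULL
  derived_vals <- function(t) {
    if (is.null(env$derived)) env$derived <- fs$derived_fn(t, env$y, env$rg)
    env$derived
  }
  eval_sym <- function(node, s, t, weight) {
    if (s == "t") return(t)
    if (!is.null(weight) && s == "weight") return(weight)
    if (s %in% names(node$states)) {
      return(env$y[[get(flat_key(node, s), envir = fs$state_index)]])
    }
    dyn <- node$type$dynamics
    if (!is.null(dyn) && !is.null(dyn$derived_variables[[s]])) {
      return(derived_vals(t)[[flat_key(node, s)]])
    }
    if (!is.null(node$params[[s]])) return(node$params[[s]])
    if (s %in% names(node$type$requirements)) {
      anc <- node$parent
      while (!is.null(anc)) {
        if (!is.null(anc$type$exposures[[s]])) {
          var <- exposure_variable(anc$type, s)
          return(eval_sym(anc, if (is.null(var)) s else var, t, weight))
        }
        anc <- anc$parent
      }
    }
    if (!is.null(fs$doc$constants[[s]])) {
      return(fs$doc$constants[[s]]$magnitude)
    }
    stop("instance '", node$path, "': cannot resolve symbol '", s, "'",
         call. = FALSE)
  }
  eval_expr <- function(ast, node, t, weight = NULL) {
    ev <- function(a) {
      switch(a$kind,
        num = a$value,
        sym = eval_sym(node, a$name, t, weight),
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
        logic = if (a$op == ".and.") ev(a$lhs) && ev(a$rhs) else
          ev(a$lhs) || ev(a$rhs),
        call = apply_lems_fn(a$fn, lapply(a$args, ev), node$path),
        linoid = linoid_val(ev(a$arg)))
    }
    ev(ast)
  }
  list(
    kind = "flat",
    env = env,
    eval_expr = eval_expr,
    set_state = function(node, var, val) {
      env$y[[get(flat_key(node, var), envir = fs$state_index)]] <- val
      invalidate()
    },
    set_regime = function(node, regime) {
      node$regime <- regime
      slot <- get(node$path, envir = fs$regime_slot)
      env$rg[slot] <- match(regime, names(node$type$regimes))
      invalidate()
    },
    ode_step = function(t, dt, method) {
      y <- env$y
      rg <- env$rg
      if (method == "euler") {
        y <- y + dt * fs$rate_fn(t, y, rg)
      } else {
        k1 <- fs$rate_fn(t, y, rg)
        k2 <- fs$rate_fn(t + dt / 2, y + dt / 2 * k1, rg)
        k3 <- fs$rate_fn(t + dt / 2, y + dt / 2 * k2, rg)
        k4 <- fs$rate_fn(t + dt, y + dt * k3, rg)
        y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      for (grp in fs$kinetic_groups) {
        occ <- pmin(pmax(y[grp], 0), 1)
        tot <- sum(occ)
        y[grp] <- if (tot > 0) occ / tot else 1 / length(grp)
      }
      env$y <- y
      invalidate()
      if (any(!is.finite(y))) {
        bad <- names(fs$y0)[which(!is.finite(y))[1]]
        stop("non-finite state after update at t = ", t + dt, ": '", bad,
             "'", call. = FALSE)
      }
    },
    record_value = function(rec, t) {
      if (rec$kind == "state") {
        env$y[[get(flat_key(rec$node, rec$var), envir = fs$state_index)]]
      } else if (rec$kind == "derived") {
        derived_vals(t)[[flat_key(rec$node, rec$var)]]
      } else {
        rec$node$params[[rec$var]]
      }
    })
}

make_tree_backend <- function(root, doc) {
  instances <- collect_instances(root)
  kin <- list()
  for (node in instances) {
    dyn <- node$type$dynamics
    if (is.null(dyn)) next
    for (ks in dyn$kinetic_schemes) {
      kin[[length(kin) + 1L]] <- list(node = node, ks = ks)
    }
  }
  eval_expr <- function(ast, node, t, weight = NULL) {
    tree_eval_expr(ast, node, t, doc, weight)
  }
  compute_derivs <- function(t) {
    out <- list()
    for (node in instances) {
      dyn <- node$type$dynamics
      if (is.null(dyn)) next
      d <- numeric(0)
      tds <- dyn$time_derivatives
      if (!is.na(node$regime)) {
        rtd <- node$type$regimes[[node$regime]]$time_derivatives
        tds[names(rtd)] <- rtd
        # states with a derivative only in other regimes are held
        other <- setdiff(unique(unlist(lapply(node$type$regimes,
          function(r) names(r$time_derivatives)))), names(tds))
        for (v in other) tds[[v]] <- NULL
      }
      for (var in names(tds)) {
        d[[var]] <- tree_eval_expr(tds[[var]], node, t, doc)
      }
      if (length(d)) out[[node$path]] <- d
    }
    for (entry in kin) {
      node <- entry$node
      ks <- entry$ks
      members <- node$collections[[ks$nodes]]
      occ <- stats::setNames(
        vapply(members, function(seg) {
          node$children[[seg]]$states[[ks$state_variable]]
        }, numeric(1)),
        vapply(members, function(seg) node$children[[seg]]$id,
               character(1)))
      docc <- stats::setNames(numeric(length(occ)), names(occ))
      for (eseg in node$collections[[ks$edges]]) {
        edge <- node$children[[eseg]]
        from <- edge$texts[[ks$edge_source]]
        to <- edge$texts[[ks$edge_target]]
        rf <- tree_eval_exposed(edge, ks$forward_rate, t, doc)
        rr <- tree_eval_exposed(edge, ks$reverse_rate, t, doc)
        docc[[from]] <- docc[[from]] - rf * occ[[from]] + rr * occ[[to]]
        docc[[to]] <- docc[[to]] + rf * occ[[from]] - rr * occ[[to]]
      }
      for (st in names(docc)) {
        seg <- members[match(st, names(occ))]
        key <- node$children[[seg]]$path
        cur <- out[[key]]
        if (is.null(cur)) cur <- numeric(0)
        cur[[ks$state_variable]] <- docc[[st]]
        out[[key]] <- cur
      }
    }
    out
  }
  by_path <- stats::setNames(instances,
                             vapply(instances, function(n) n$path,
                                    character(1)))
  list(
    kind = "tree",
    eval_expr = eval_expr,
    set_state = function(node, var, val) node$states[[var]] <- val,
    set_regime = function(node, regime) node$regime <- regime,
    ode_step = function(t, dt, method) {
      if (method != "euler") {
        stop("the tree-walk backend integrates with forward Euler only",
             call. = FALSE)
      }
      d <- compute_derivs(t)
      for (path in names(d)) {
        node <- by_path[[path]]
        for (var in names(d[[path]])) {
          node$states[[var]] <- node$states[[var]] + dt * d[[path]][[var]]
        }
      }
      for (entry in kin) {
        node <- entry$node
        ks <- entry$ks
        members <- node$collections[[ks$nodes]]
        occ <- vapply(members, function(seg) {
          node$children[[seg]]$states[[ks$state_variable]]
        }, numeric(1))
        occ <- pmin(pmax(occ, 0), 1)
        tot <- sum(occ)
        occ <- if (tot > 0) occ / tot else rep(1 / length(occ),
                                               length(occ))
        for (j in seq_along(members)) {
          node$children[[members[j]]]$states[[ks$state_variable]] <- occ[j]
        }
      }
      for (node in instances) {
        if (any(!is.finite(node$states))) {
          bad <- names(node$states)[which(!is.finite(node$states))[1]]
          stop("non-finite state after update at t = ", t + dt, ": '",
               paste0(node$path, "/", bad), "'", call. = FALSE)
        }
      }
    },
    record_value = function(rec, t) {
      if (rec$kind == "param") return(rec$node$params[[rec$var]])
      tree_eval_symbol(rec$node, rec$var, t, doc)
    })
}

# ---- hybrid stepping ----------------------------------------------------

run_rule_actions <- function(rule_actions, node, t, weight, backend,
                             queue, event_log, prev_env, rules) {
  for (act in rule_actions) {
    if (act$kind == "assign") {
      val <- backend$eval_expr(act$value, node, t, weight)
      backend$set_state(node, act$variable, val)
    } else if (act$kind == "emit") {
      emit_event(node, act$port, t, queue, event_log)
    } else if (act$kind == "transition") {
      transition_regime(node, act$regime, t, backend, queue, event_log,
                        prev_env, rules)
    }
  }
}

emit_event <- function(node, port, t, queue, event_log) {
  event_log$times <- c(event_log$times, t)
  event_log$paths <- c(event_log$paths, node$path)
  event_log$ports <- c(event_log$ports, port)
  for (conn in node$out_conns[[port]]) {
    schedule_event(queue, t + conn$delay, conn$target, conn$port,
                   conn$weight)
  }
}

transition_regime <- function(node, regime, t, backend, queue, event_log,
                              prev_env, rules) {
  backend$set_regime(node, regime)
  # re-arm edge detection for the newly entered regime's conditions
  for (ri in seq_along(rules$conditions)) {
    rule <- rules$conditions[[ri]]
    if (identical(rule$node$path, node$path) &&
        identical(rule$regime, regime)) {
      prev_env$flags[ri] <- FALSE
    }
  }
  rg <- node$type$regimes[[regime]]
  run_rule_actions(rg$on_entry, node, t, NULL, backend, queue, event_log,
                   prev_env, rules)
}

drain_events <- function(queue, t, tol, rules, backend, event_log,
                         prev_env) {
  repeat {
    due <- deliver_due_events(queue, t + tol)
    if (!length(due)) break
    for (evt in due) {
      for (rule in rules$events) {
        if (!identical(rule$node$path, evt$node$path)) next
        if (rule$port != evt$port) next
        if (!rule_active(rule)) next
        run_rule_actions(rule$actions, rule$node, t, evt$weight, backend,
                         queue, event_log, prev_env, rules)
      }
    }
  }
}

check_conditions <- function(rules, t, backend, queue, event_log,
                             prev_env, init = FALSE) {
  for (ri in seq_along(rules$conditions)) {
    rule <- rules$conditions[[ri]]
    if (!rule_active(rule)) {
      prev_env$flags[ri] <- FALSE
      next
    }
    val <- isTRUE(backend$eval_expr(rule$test, rule$node, t))
    if (val && !prev_env$flags[ri]) {
      prev_env$flags[ri] <- TRUE
      run_rule_actions(rule$actions, rule$node, t, NULL, backend, queue,
                       event_log, prev_env, rules)
    } else {
      prev_env$flags[ri] <- val
    }
  }
}

# ---- top-level simulate -------------------------------------------------

as_seconds <- function(x, doc, what) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) return(x)
  q <- parse_quantity(x, doc$units)
  if (!dim_equal(q$dimension, time_dim()) &&
      !is_dimensionless(q$dimension)) {
    stop(what, " must be a time quantity, got '", x, "'", call. = FALSE)
  }
  q$magnitude
}

#' Simulate a LEMS document
#'
#' Runs the document's Simulation element (or explicit overrides) with a
#' fixed-step scheme and records the requested quantities at every step.
#' Repeated runs with identical (document, seed, method, dt) are
#' bit-identical.
#'
#' @param doc A `lems_document` (or a path / XML string, which is parsed
#'   first).
#' @param method `"rk4"` (default; 4th-order Runge-Kutta on the flattened
#'   system), `"euler"` (forward Euler on the flattened system) or
#'   `"euler-tree"` (forward Euler by direct tree traversal).
#' @param dt,length Overrides for the step and total time; numeric
#'   seconds or quantity strings such as `"0.01 ms"`.
#' @param seed Integer seed for `random()` draws (also recorded in the
#'   output metadata).
#' @param records Optional character vector of record paths overriding
#'   the document's output columns.
#' @param target_id Optional component id to simulate, overriding the
#'   document Target.
#' @param validate If `TRUE` (default), refuse to run a document whose
#'   validation report is non-empty.
#' @return A `lems_traces` object: `time` (seconds), `records` (named
#'   list of numeric series), `events` (data.frame time/path/port) and
#'   `meta`.
#' @export
simulate_lems <- function(doc, method = c("rk4", "euler", "euler-tree"),
                          dt = NULL, length = NULL, seed = 1L,
                          records = NULL, target_id = NULL,
                          validate = TRUE) {
  if (is.character(doc)) doc <- parse_lems(doc)
  method <- match.arg(method)
  if (validate) {
    issues <- validate_lems(doc)
    if (base::length(issues)) {
      stop("document fails validation (", base::length(issues),
           " issue", if (base::length(issues) > 1) "s", "):\n  ",
           paste(issues, collapse = "\n  "), call. = FALSE)
    }
  }
  spec <- read_simulation_spec(doc)
  dt <- if (!is.null(dt)) as_seconds(dt, doc, "dt") else spec$step
  total <- if (!is.null(length)) as_seconds(length, doc, "length") else
    spec$length
  if (is.null(dt) || is.null(total)) {
    stop("no Simulation element found and dt/length not supplied",
         call. = FALSE)
  }
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (total < 0) stop("length must be non-negative", call. = FALSE)
  if (is.null(target_id)) target_id <- spec$target
  record_paths <- if (!is.null(records)) {
    spec$sinks <- NULL
    spec$event_files <- character()
    stats::setNames(records, records)
  } else {
    spec$records
  }
  set.seed(as.integer(seed))
  root <- build_instance_tree(doc, target_id)
  backend <- if (method == "euler-tree") {
    make_tree_backend(root, doc)
  } else {
    make_flat_backend(flatten(root, doc))
  }
  ode_method <- if (method == "rk4") "rk4" else "euler"
  recs <- lapply(record_paths, function(p) resolve_record_path(root, p))
  rules <- build_rules(collect_instances(root))
  queue <- event_queue()
  event_log <- new.env(parent = emptyenv())
  event_log$times <- numeric()
  event_log$paths <- character()
  event_log$ports <- character()
  prev_env <- new.env(parent = emptyenv())
  prev_env$flags <- rep(FALSE, base::length(rules$conditions))
  tol <- dt * 1e-6

  n_steps <- as.integer(round(total / dt))
  out <- matrix(NA_real_, nrow = n_steps + 1L,
                ncol = base::length(recs))
  # conditions already true at initialization fire once at t = 0
  check_conditions(rules, 0, backend, queue, event_log, prev_env,
                   init = TRUE)
  drain_events(queue, 0, tol, rules, backend, event_log, prev_env)
  if (base::length(recs)) {
    out[1L, ] <- vapply(recs, backend$record_value, numeric(1), t = 0)
  }
  t <- 0
  if (n_steps > 0) {
    for (k in seq_len(n_steps)) {
      backend$ode_step(t, dt, ode_method)
      t <- k * dt
      drain_events(queue, t, tol, rules, backend, event_log, prev_env)
      check_conditions(rules, t, backend, queue, event_log, prev_env)
      drain_events(queue, t, tol, rules, backend, event_log, prev_env)
      if (base::length(recs)) {
        out[k + 1L, ] <- vapply(recs, backend$record_value, numeric(1),
                                t = t)
      }
    }
  }
  record_series <- lapply(seq_along(recs), function(j) out[, j])
  names(record_series) <- names(recs)
  structure(list(
    time = (0:n_steps) * dt,
    records = record_series,
    record_paths = stats::setNames(unname(record_paths),
                                   names(record_paths)),
    events = data.frame(time = event_log$times, path = event_log$paths,
                        port = event_log$ports,
                        stringsAsFactors = FALSE),
    sinks = spec$sinks, event_files = spec$event_files,
    meta = list(method = method, dt = dt, length = total,
                seed = as.integer(seed), target = target_id)),
    class = "lems_traces")
}

#' @export
print.lems_traces <- function(x, ...) {
  cat("<lems_traces> ", base::length(x$time), " samples (dt = ",
      format(x$meta$dt), " s), ", base::length(x$records), " records, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Write recorded traces to delimited text files
#'
#' One tab-separated file per output sink: first column is time in
#' seconds, one column per record, full float precision. The event log is
#' written as a separate file with columns time, path and port.
#'
#' @param tr A `lems_traces` from [simulate_lems()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written (invisibly).
#' @export
write_traces <- function(tr, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  sinks <- tr$sinks
  if (!base::length(sinks)) {
    sinks <- list("traces.dat" = stats::setNames(tr$record_paths,
                                                 names(tr$records)))
  }
  for (file_name in names(sinks)) {
    cols <- sinks[[file_name]]
    ids <- names(cols)
    path <- file.path(dir, file_name)
    con <- file(path, open = "wb")
    header <- paste(c("time", ids), collapse = "\t")
    body <- do.call(paste, c(list(sprintf("%.17g", tr$time)),
                             lapply(ids, function(id) {
                               sprintf("%.17g", tr$records[[id]])
                             }),
                             sep = "\t"))
    writeLines(c(header, body), con, sep = "\n")
    close(con)
    written <- c(written, path)
  }
  event_files <- tr$event_files
  if (!base::length(event_files)) event_files <- "events.dat"
  for (ef in event_files) {
    path <- file.path(dir, ef)
    con <- file(path, open = "wb")
    writeLines(c("time\tpath\tport",
                 if (nrow(tr$events)) {
                   paste(sprintf("%.17g", tr$events$time), tr$events$path,
                         tr$events$port, sep = "\t")
                 }), con, sep = "\n")
    close(con)
    written <- c(written, path)
  }
  invisible(written)
}
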