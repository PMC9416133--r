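#' Build a fluidic network
#'
#' A fluidic network is a directed graph of hydraulic elements between
#' named nodes, with imposed (terminal) pressures at one or more nodes --
#' typically the two medium reservoirs. Solving the network (see
#' [solve_network()]) yields node pressures and signed element flows under
#' the quasi-static Hagen-Poiseuille model.
#'
#' @param elements List of [elements] (rect_channel, circular_tube,
#'   fixed_resistor, check_valve), each with `from` and `to` node names
#'   set. Elements without an `id` are assigned `"e<k>"`.
#' @param terminals Named numeric vector of imposed node pressures in Pa,
#'   e.g. `c(res1 = 2900, res2 = 0)`.
#' @param fluid A [fluid_properties()] object.
#' @param sample_ids Optional character vector naming the element(s)
#'   regarded as the perfused sample(s); used by the plant/controller
#'   layers for telemetry and by board-level analyses.
#' @return An object of class `fluidic_network`.
#' @examples
#' net <- fluidic_network(
#'   elements = list(
#'     circular_tube(0.08, 250e-6, from = "res1", to = "n1", id = "tube"),
#'     rect_channel(0.011, 500e-6, 500e-6, from = "n1", to = "res2",
#'                  id = "chip")),
#'   terminals = c(res1 = mbar_to_pa(29), res2 = 0),
#'   fluid = fluid("water-20C"))
#' solve_network(net)
#' @export
fluidic_network <- function(elements, terminals, fluid,
                            sample_ids = NULL) {
  stopifnot(is.list(elements), length(elements) > 0L,
            inherits(fluid, "fluid_properties"))
  for (k in seq_along(elements)) {
    el <- elements[[k]]
    if (!inherits(el, "hydraulic_element"))
      stop("elements[[", k, "]] is not a hydraulic element")
    if (is.null(el$from) || is.null(el$to))
      stop("element ", k, " has no from/to nodes")
    if (is.null(el$id)) elements[[k]]$id <- paste0("e", k)
  }
  ids <- vapply(elements, function(e) e$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate element ids: ", paste(unique(ids[duplicated(ids)]),
                                          collapse = ", "))
  if (is.null(names(terminals)) || any(!nzchar(names(terminals))))
    stop("terminals must be a named numeric vector (node -> pressure Pa)")
  if (any(!is.finite(terminals)))
    stop("terminal pressures must be finite")
  nodes <- unique(c(vapply(elements, function(e) e$from, character(1)),
                    vapply(elements, function(e) e$to, character(1))))
  missing_t <- setdiff(names(terminals), nodes)
  if (length(missing_t))
    stop("terminal node(s) not present in network: ",
         paste(missing_t, collapse = ", "))
  if (!is.null(sample_ids) && length(setdiff(sample_ids, ids)))
    stop("unknown sample_ids: ",
         paste(setdiff(sample_ids, ids), collapse = ", "))
  net <- structure(list(elements = elements,
                        terminals = terminals,
                        fluid = fluid,
                        nodes = nodes,
                        sample_ids = sample_ids),
                   class = "fluidic_network")
  comp <- network_components(net)
  if (length(unique(comp)) > 1L)
    stop("network graph is not connected")
  net
}

# connected-component labels over the undirected element graph
network_components <- function(net) {
  nodes <- net$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  adj <- vector("list", length(nodes))
  for (el in net$elements) {
    f <- idx[[el$from]]; t <- idx[[el$to]]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  comp <- rep(NA_integer_, length(nodes))
  lab <- 0L
  for (s in seq_along(nodes)) {
    if (!is.na(comp[s])) next
    lab <- lab + 1L
    queue <- s
    comp[s] <- lab
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- lab; queue <- c(queue, w) }
    }
  }
  comp
}

#' @export
print.fluidic_network <- function(x, ...) {
  nv <- sum(vapply(x$elements, inherits, logical(1), "check_valve"))
  cat(sprintf(
    "Fluidic network: %d nodes, %d elements (%d check valve%s), %d terminal%s\n",
    length(x$nodes), length(x$elements), nv, if (nv == 1) "" else "s",
    length(x$terminals), if (length(x$terminals) == 1) "" else "s"))
  cat("  fluid:", x$fluid$label, "\n")
  cat("  terminals:",
      paste(sprintf("%s = %.4g mbar", names(x$terminals),
                    pa_to_mbar(x$terminals)), collapse = ", "), "\n")
  invisible(x)
}

#' Precompile a network for repeated solving
#'
#' Indexes nodes and elements and resolves default check-valve parameters
#' once, so time-domain simulations can re-solve the same topology at
#' different terminal pressures cheaply. Solved valve-state matrices are
#' memoised inside the compiled object.
#'
#' @param net A [fluidic_network()].
#' @return An opaque object of class `compiled_network`, accepted by
#'   [solve_network()] wherever a network is.
#' @export
compile_network <- function(net) {
  stopifnot(inherits(net, "fluidic_network"))
  nodes <- net$nodes
  nn <- length(nodes)
  node_idx <- stats::setNames(seq_len(nn), nodes)
  is_term <- nodes %in% names(net$terminals)
  int_row <- integer(nn)            # 0 for terminal nodes
  int_row[!is_term] <- seq_len(sum(!is_term))
  ne <- length(net$elements)
  from <- to <- integer(ne)
  is_valve <- logical(ne)
  g <- pc <- numeric(ne)
  ids <- character(ne)
  for (k in seq_len(ne)) {
    el <- net$elements[[k]]
    from[k] <- node_idx[[el$from]]
    to[k] <- node_idx[[el$to]]
    ids[k] <- el$id
    if (inherits(el, "check_valve")) {
      is_valve[k] <- TRUE
      pc[k] <- el$cracking_pressure
      g[k] <- NA_real_              # filled below once defaults resolve
    } else {
      r <- element_resistance(el, net$fluid)
      if (!is.finite(r) || r <= 0)
        stop("element '", el$id, "' has non-positive resistance; ",
             "zero-resistance links are not supported by the solver ",
             "(merge the nodes instead)")
      g[k] <- 1 / r
    }
  }
  if (any(is_valve)) {
    r_min <- if (any(!is_valve)) min(1 / g[!is_valve]) else 1e9
    for (k in which(is_valve)) {
      fr <- net$elements[[k]]$forward_resistance
      if (is.null(fr)) fr <- 1e-3 * r_min
      g[k] <- 1 / fr
    }
  }
  term_nodes <- names(net$terminals)
  structure(list(net = net, nodes = nodes, node_idx = node_idx,
                 is_term = is_term, int_row = int_row,
                 n_int = sum(!is_term),
                 term_nodes = term_nodes,
                 term_pos = unname(node_idx[term_nodes]),
                 from = from, to = to, ids = ids,
                 is_valve = is_valve, g = g, pc = pc,
                 g_eps = max(g) * 1e-18,
                 cache = new.env(parent = emptyenv())),
            class = "compiled_network")
}

#' Solve a fluidic network for pressures and flows
#'
#' Performs a nodal conductance solve (Kirchhoff's current law at every
#' non-terminal node) with terminal nodes held at their imposed pressures.
#' Check valves are resolved by a deterministic active-set iteration:
#' starting from all valves open, the solve is repeated and the single
#' most-violated valve is flipped each round (ties broken by element
#' order) until complementarity holds -- a closed valve sees a forward
#' pressure drop below its cracking pressure and an open valve carries
#' non-negative flow. The iteration cap is `2^n_valves`; if it is reached
#' the last assignment is returned with `converged = FALSE`.
#'
#' An open valve behaves as a small forward resistance in series with its
#' cracking pressure; a closed valve carries exactly zero flow.
#'
#' @param net A [fluidic_network()] or [compile_network()] result.
#' @param terminals Optional named numeric vector (Pa) overriding the
#'   network's terminal pressures, e.g. to sweep a pressure difference.
#' @param warm_start Optional logical vector of initial valve open states.
#' @return A `flow_solution` with `node_pressures` (Pa), `element_flows`
#'   (m^3 s^-1, signed positive from -> to), `valve_states`, `converged`
#'   and `kcl_residual` (worst net flow at an internal node).
#' @export
solve_network <- function(net, terminals = NULL, warm_start = NULL) {
  cc <- if (inherits(net, "compiled_network")) net else compile_network(net)
  p_term <- cc$net$terminals
  if (!is.null(terminals)) {
    bad <- setdiff(names(terminals), names(p_term))
    if (length(bad)) stop("unknown terminal node(s): ",
                          paste(bad, collapse = ", "))
    p_term[names(terminals)] <- terminals
  }
  if (length(p_term) < 2L)
    stop("need at least 2 terminals for a nontrivial solve")
  if (any(!is.finite(p_term))) stop("terminal pressures must be finite")
  sol <- solve_compiled(cc, unname(p_term[cc$term_nodes]), warm_start)
  vs <- NULL
  if (!is.null(sol$open))
    vs <- stats::setNames(ifelse(sol$open, "open", "closed"),
                          cc$ids[cc$is_valve])
  structure(list(node_pressures = stats::setNames(sol$p, cc$nodes),
                 element_flows = stats::setNames(sol$q, cc$ids),
                 valve_states = vs,
                 converged = sol$converged,
                 kcl_residual = sol$kcl,
                 terminals = p_term,
                 sample_ids = cc$net$sample_ids),
            class = "flow_solution")
}

# core active-set solve over a compiled network; ptv is the vector of
# terminal pressures (Pa) in cc$term_nodes order
solve_compiled <- function(cc, ptv, warm_start = NULL) {
  nn <- length(cc$nodes)
  tol_p <- 1e-9 * max(1, max(abs(ptv)))
  nvi <- which(cc$is_valve)
  nv <- length(nvi)
  open <- if (is.null(warm_start)) rep(TRUE, nv) else as.logical(warm_start)
  stopifnot(length(open) == nv)
  max_iter <- max(1L, 2L^nv)
  converged <- FALSE
  q <- numeric(length(cc$ids))
  p_full <- numeric(nn)
  for (iter in seq_len(max_iter)) {
    p_full <- nodal_solve(cc, ptv, open)
    dp_el <- p_full[cc$from] - p_full[cc$to]
    ga <- cc$g
    if (nv) ga[nvi[!open]] <- 0
    q <- ga * dp_el
    if (nv) {
      op <- nvi[open]
      q[op] <- cc$g[op] * (dp_el[op] - cc$pc[op])
      q[nvi[!open]] <- 0
    }
    if (!nv) { converged <- TRUE; break }
    # complementarity violations, in pressure units for comparability
    viol <- numeric(nv)
    for (j in seq_len(nv)) {
      k <- nvi[j]
      viol[j] <- if (open[j]) max(0, -q[k] / cc$g[k])
                 else max(0, (dp_el[k] - cc$pc[k]))
    }
    if (all(viol <= tol_p)) { converged <- TRUE; break }
    flip <- which.max(viol)          # deterministic: first max wins
    open[flip] <- !open[flip]
  }
  # KCL residual at internal nodes
  kcl <- 0
  if (cc$n_int > 0) {
    net_out <- numeric(nn)
    for (k in seq_along(q)) {
      net_out[cc$from[k]] <- net_out[cc$from[k]] + q[k]
      net_out[cc$to[k]] <- net_out[cc$to[k]] - q[k]
    }
    kcl <- max(abs(net_out[!cc$is_term]))
  }
  list(p = p_full, q = q, open = if (nv) open,
       converged = converged, kcl = kcl)
}

# Dirichlet nodal solve for one valve assignment; memoises the inverse per
# assignment key. Returns full node pressure vector (Pa).
nodal_solve <- function(cc, ptv, open) {
  nn <- length(cc$nodes)
  p_full <- numeric(nn)
  p_full[cc$term_pos] <- ptv
  if (cc$n_int == 0L) return(p_full)
  p_ref <- ptv[1]
  nvi <- which(cc$is_valve)
  ga <- cc$g
  if (length(nvi)) ga[nvi[!open]] <- 0
  key <- if (length(nvi)) paste(as.integer(open), collapse = "") else ""
  Ainv <- cc$cache[[paste0("Ainv_", key)]]
  if (is.null(Ainv)) {
    A <- matrix(0, cc$n_int, cc$n_int)
    for (k in seq_along(ga)) {
      gk <- ga[k]
      if (gk == 0) next
      fi <- cc$int_row[cc$from[k]]
      ti <- cc$int_row[cc$to[k]]
      if (fi > 0) A[fi, fi] <- A[fi, fi] + gk
      if (ti > 0) A[ti, ti] <- A[ti, ti] + gk
      if (fi > 0 && ti > 0) {
        A[fi, ti] <- A[fi, ti] - gk
        A[ti, fi] <- A[ti, fi] - gk
      }
    }
    # vanishing shunt to the reference terminal keeps the system
    # nonsingular when closed valves isolate a node; its flow is far below
    # the mass-conservation tolerance
    diag(A) <- diag(A) + cc$g_eps
    Ainv <- solve(A)
    cc$cache[[paste0("Ainv_", key)]] <- Ainv
  }
  b <- rep(cc$g_eps * p_ref, cc$n_int)
  for (k in seq_along(ga)) {
    gk <- ga[k]
    if (gk == 0) next
    fi <- cc$int_row[cc$from[k]]
    ti <- cc$int_row[cc$to[k]]
    pck <- if (cc$is_valve[k]) cc$pc[k] else 0
    if (fi > 0) {
      b[fi] <- b[fi] + gk * pck
      if (ti == 0) b[fi] <- b[fi] + gk * p_full[cc$to[k]]
    }
    if (ti > 0) {
      b[ti] <- b[ti] - gk * pck
      if (fi == 0) b[ti] <- b[ti] + gk * p_full[cc$from[k]]
    }
  }
  p_int <- drop(Ainv %*% b)
  p_full[cc$int_row > 0] <- p_int
  p_full
}

#' Net flow leaving a terminal node
#'
#' @param sol A `flow_solution` from [solve_network()].
#' @param net The network (or compiled network) that produced it.
#' @param node Terminal node name; defaults to the first terminal.
#' @return Signed volumetric flow in m^3 s^-1 leaving `node` into the
#'   circuit.
#' @export
terminal_flow <- function(sol, net, node = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  nn <- if (inherits(net, "compiled_network")) net$net else net
  if (is.null(node)) node <- names(sol$terminals)[1]
  out <- 0
  for (el in nn$elements) {
    qk <- sol$element_flows[[el$id]]
    if (identical(el$from, node)) out <- out + qk
    if (identical(el$to, node)) out <- out - qk
  }
  out
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("Flow solution", if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("  node pressures (mbar):\n")
  p <- pa_to_mbar(x$node_pressures)
  for (nm in names(p)) cat(sprintf("    %-12s %10.4f\n", nm, p[[nm]]))
  cat("  element flows (uL/min):\n")
  q <- m3s_to_ulmin(x$element_flows)
  for (nm in names(q)) cat(sprintf("    %-12s %10.3f\n", nm, q[[nm]]))
  if (!is.null(x$valve_states)) {
    cat("  valves:",
        paste(sprintf("%s=%s", names(x$valve_states), x$valve_states),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.flow_solution <- function(object, ...) {
  q <- m3s_to_ulmin(object$element_flows)
  data.frame(element = names(q), flow_ulmin = as.numeric(q),
             row.names = NULL)
}
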