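#' Fluidic circuit board layout
#'
#' Describes the multiplexing manifold: a main feeder channel with
#' branches towards up to four organ-on-chip devices (three microfluidic
#' channels each) and a central waste channel collecting the flow towards
#' the opposite reservoir. Unoccupied slots are closed with dummy chips
#' and contribute no flow path. Feeder and waste segments default to
#' milled 1 mm x 1 mm square channels; these dimensions are fixture
#' values, configurable per segment.
#'
#' @param n_slots Number of device slots (default 4).
#' @param channels_per_slot Channels per device (default 3).
#' @param occupancy Logical vector (length `n_slots`): device present or
#'   dummy chip.
#' @param feeder_segment_lengths,waste_segment_lengths Lengths in m of
#'   the feeder/waste segments between consecutive slots.
#' @param manifold_width,manifold_height Feeder/waste cross-section, m.
#' @param channel A [rect_channel()] prototype for the sample channels
#'   (default 1.1 cm x 500 um x 500 um).
#' @param branch_resistance Extra lumped resistance in series with each
#'   channel (connector/tubing), Pa s m^-3; 0 omits it.
#' @return An object of class `fcb_layout`.
#' @export
fcb_layout <- function(n_slots = 4, channels_per_slot = 3,
                       occupancy = rep(TRUE, n_slots),
                       feeder_segment_lengths = rep(0.02, n_slots),
                       waste_segment_lengths = rep(0.02, n_slots),
                       manifold_width = 1e-3, manifold_height = 1e-3,
                       channel = rect_channel(0.011, 500e-6, 500e-6),
                       branch_resistance = 0) {
  stopifnot(n_slots >= 1, channels_per_slot >= 1,
            length(occupancy) == n_slots,
            length(feeder_segment_lengths) == n_slots,
            length(waste_segment_lengths) == n_slots,
            manifold_width > 0, manifold_height > 0,
            inherits(channel, "rect_channel"), branch_resistance >= 0)
  structure(list(n_slots = n_slots,
                 channels_per_slot = channels_per_slot,
                 occupancy = as.logical(occupancy),
                 feeder_segment_lengths = feeder_segment_lengths,
                 waste_segment_lengths = waste_segment_lengths,
                 manifold_width = manifold_width,
                 manifold_height = manifold_height,
                 channel = channel,
                 branch_resistance = branch_resistance),
            class = "fcb_layout")
}

#' Build the hydraulic network of a fluidic circuit board
#'
#' One inlet terminal, one outlet terminal, and the occupied sample
#' channels as parallel branches between the feeder and waste nodes of
#' their slot. Channel element ids are `s<slot>c<channel>` and are
#' registered as the network's sample ids.
#'
#' @param layout An [fcb_layout()].
#' @param fluid A [fluid_properties()] object.
#' @param dp_mbar Default terminal pressure difference, mbar (the inlet
#'   terminal is set to this, the outlet to 0; override at solve time).
#' @return A [fluidic_network()].
#' @export
build_fcb_network <- function(layout, fluid = fluid("medium-37C"),
                              dp_mbar = 29) {
  stopifnot(inherits(layout, "fcb_layout"))
  if (!any(layout$occupancy))
    stop("no occupied channels: at least one device must be connected")
  els <- list()
  add <- function(el) els[[length(els) + 1L]] <<- el
  feeder_node <- function(i) if (i == 0) "inlet" else paste0("f", i)
  waste_node <- function(i) if (i == 0) "outlet" else paste0("w", i)
  sample_ids <- character(0)
  for (i in seq_len(layout$n_slots)) {
    add(rect_channel(layout$feeder_segment_lengths[i],
                     layout$manifold_width, layout$manifold_height,
                     from = feeder_node(i - 1), to = feeder_node(i),
                     id = paste0("feeder", i)))
    add(rect_channel(layout$waste_segment_lengths[i],
                     layout$manifold_width, layout$manifold_height,
                     from = waste_node(i), to = waste_node(i - 1),
                     id = paste0("waste", i)))
    if (!layout$occupancy[i]) next
    for (j in seq_len(layout$channels_per_slot)) {
      chan_id <- paste0("s", i, "c", j)
      ch <- layout$channel
      if (layout$branch_resistance > 0) {
        mid <- paste0(chan_id, "_n")
        add(fixed_resistor(layout$branch_resistance,
                           from = feeder_node(i), to = mid,
                           id = paste0(chan_id, "_branch")))
        ch$from <- mid
      } else {
        ch$from <- feeder_node(i)
      }
      ch$to <- waste_node(i)
      ch$id <- chan_id
      add(ch)
      sample_ids <- c(sample_ids, chan_id)
    }
  }
  fluidic_network(els,
                  terminals = c(inlet = mbar_to_pa(dp_mbar), outlet = 0),
                  fluid = fluid, sample_ids = sample_ids)
}

#' Predict the dP-flow curve of a network
#'
#' Solves the network at each requested pressure difference (inlet
#' terminal at dP, outlet at 0) and tabulates the total flow and the
#' per-sample flows. For a linear network the curve is a straight line
#' through the origin with slope 1/R_total.
#'
#' @param net A [fluidic_network()] with terminals named; the first
#'   terminal is driven, the second grounded.
#' @param dp_values Pressure differences in mbar (>= 0).
#' @return A data.frame with `dp_mbar`, `q_total_ulmin` and one
#'   `q_<id>_ulmin` column per sample element.
#' @export
predict_dp_q_curve <- function(net, dp_values) {
  stopifnot(all(dp_values >= 0))
  cc <- if (inherits(net, "compiled_network")) net else compile_network(net)
  tn <- cc$term_nodes
  sid <- cc$net$sample_ids
  if (is.null(sid)) sid <- character(0)
  rows <- lapply(dp_values, function(dp) {
    sol <- solve_network(cc, terminals = stats::setNames(
      c(mbar_to_pa(dp), 0), tn[1:2]))
    qt <- m3s_to_ulmin(terminal_flow(sol, cc, tn[1]))
    qs <- m3s_to_ulmin(sol$element_flows[sid])
    c(dp_mbar = dp, q_total_ulmin = qt,
      stats::setNames(as.numeric(qs), paste0("q_", sid, "_ulmin")))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Per-channel flow redistribution when channels block
#'
#' Contrasts the two pumping philosophies when cell debris blocks a
#' channel. Under constant pressure difference (`constant_dp`) the
#' remaining channels keep their driving pressure, so their flows change
#' only through whatever feeder/waste resistance they share with the
#' blocked branch -- with negligible shared resistance they are
#' unaffected. Under constant total flow (`constant_total_q`, the
#' positive-displacement behaviour) the same total is forced through
#' fewer branches, so every remaining channel speeds up (blocking one of
#' six identical channels multiplies each remaining flow by 6/5).
#'
#' @param net A [fluidic_network()] with sample ids (e.g. from
#'   [build_fcb_network()]).
#' @param blocked_ids Character vector of sample element ids to block
#'   (may be empty: identity).
#' @param mode `"constant_dp"` or `"constant_total_q"`.
#' @param dp_mbar Reference pressure difference for the baseline solve.
#' @return A data.frame with `channel`, `q_before_ulmin`,
#'   `q_after_ulmin` (NA for blocked channels) and `ratio`.
#' @export
blockage_analysis <- function(net, blocked_ids,
                              mode = c("constant_dp", "constant_total_q"),
                              dp_mbar = 29) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "fluidic_network"))
  sid <- net$sample_ids
  if (is.null(sid)) stop("network has no sample ids")
  unknown <- setdiff(blocked_ids, sid)
  if (length(unknown))
    stop("unknown channel id(s): ", paste(unknown, collapse = ", "))
  if (length(setdiff(sid, blocked_ids)) == 0L)
    stop("all channels blocked: no flow path remains")
  tn <- names(net$terminals)
  p_drive <- stats::setNames(c(mbar_to_pa(dp_mbar), 0), tn[1:2])
  sol0 <- solve_network(net, terminals = p_drive)
  q0 <- m3s_to_ulmin(sol0$element_flows[sid])
  # total as the sum over sample branches: identical to the terminal
  # flow by mass balance, but numerically robust when the manifold
  # resistance is many orders below the channel resistance
  qt0 <- sum(q0)
  if (length(blocked_ids) == 0L) {
    return(data.frame(channel = sid, q_before_ulmin = as.numeric(q0),
                      q_after_ulmin = as.numeric(q0), ratio = 1))
  }
  # a blocked channel is a dummy chip: the branch disappears
  drop_ids <- blocked_ids
  for (bid in blocked_ids) {
    br <- paste0(bid, "_branch")
    if (br %in% vapply(net$elements, `[[`, "", "id")) drop_ids <- c(drop_ids, br)
  }
  keep <- vapply(net$elements, function(e) !(e$id %in% drop_ids), logical(1))
  net2 <- fluidic_network(net$elements[keep], net$terminals, net$fluid,
                          sample_ids = setdiff(sid, blocked_ids))
  sol1 <- solve_network(net2, terminals = p_drive)
  rem <- setdiff(sid, blocked_ids)
  qt1 <- sum(m3s_to_ulmin(sol1$element_flows[rem]))
  scale <- if (mode == "constant_total_q") qt0 / qt1 else 1
  q1 <- rep(NA_real_, length(sid))
  names(q1) <- sid
  q1[rem] <- m3s_to_ulmin(sol1$element_flows[rem]) * scale
  data.frame(channel = sid, q_before_ulmin = as.numeric(q0),
             q_after_ulmin = as.numeric(q1),
             ratio = as.numeric(q1) / as.numeric(q0))
}
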