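# Independent reduction oracle for series-parallel ladder networks.
# Built from plain arithmetic on purpose: it must not share code with the
# nodal solver it cross-checks.

# A ladder: optional series lead resistor from terminal T1 to a hub node,
# then n parallel branches to terminal T2, each branch a series chain of
# 1-3 resistors. Returns the network and the independently reduced total
# resistance.
random_ladder <- function(n_branches = NULL, with_lead = NULL) {
  if (is.null(n_branches)) n_branches <- sample(2:6, 1)
  if (is.null(with_lead)) with_lead <- runif(1) < 0.5
  wat <- fluid("water-20C")
  els <- list()
  r_branch <- numeric(n_branches)
  hub <- if (with_lead) "hub" else "T1"
  r_lead <- 0
  if (with_lead) {
    r_lead <- 10^runif(1, 8, 11)
    els[[1]] <- fixed_resistor(r_lead, from = "T1", to = "hub",
                               id = "lead")
  }
  for (b in seq_len(n_branches)) {
    n_seg <- sample(1:3, 1)
    rs <- 10^runif(n_seg, 8, 12)
    prev <- hub
    for (s in seq_len(n_seg)) {
      nxt <- if (s == n_seg) "T2" else sprintf("b%d_n%d", b, s)
      els[[length(els) + 1L]] <- fixed_resistor(
        rs[s], from = prev, to = nxt, id = sprintf("b%dr%d", b, s))
      prev <- nxt
    }
    r_branch[b] <- sum(rs)           # independent series reduction
  }
  r_total <- r_lead + 1 / sum(1 / r_branch)  # independent parallel law
  net <- fluidic_network(els, terminals = c(T1 = 2000, T2 = 0),
                         fluid = wat)
  list(net = net, r_total = r_total, r_branch = r_branch,
       with_lead = with_lead)
}

pneumatic_relax_for_test <- perfusim:::pneumatic_relax

# a near-ideal FCB layout: manifold segments so short that the feeder and
# waste resistance shared between channels is negligible
ideal_fcb_layout <- function(occupancy = c(TRUE, TRUE, FALSE, FALSE)) {
  fcb_layout(occupancy = occupancy,
             feeder_segment_lengths = rep(1e-12, 4),
             waste_segment_lengths = rep(1e-12, 4))
}
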