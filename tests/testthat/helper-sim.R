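# Shared fixtures for the test suite: a clade-labelled tree at moderate
# divergence and small utilities. All simulation inputs are generated in
# code; nothing is read from disk except packaged fixtures.

CLADE_TREE <- paste0(
  "((LIV:0.05,MOS:0.05):0.03,(HOR:0.04,(LYC:0.03,(FER:0.02,",
  "(GYM:0.02,ANG:0.02):0.02):0.02):0.02):0.03):0.02;")

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# small simulation used by several tests (shorter introns keep the
# all-vs-all scans fast; the methods vignette records the problem sizes)
small_sim <- function(seed, ...) {
  simulate_introns(simulation_params(tree = CLADE_TREE, seed = seed,
                                     intron_core_len = 300,
                                     maturase_aa = 240, ...))
}

# exhaustive minimum-cost gain/loss labeling for a single binary character
# (independent oracle: enumerates all internal labelings)
brute_gainloss_cost <- function(phy, states, w_gain, w_loss,
                                root_prior = "gain") {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  parents <- phy$edge[, 1]; kids <- phy$edge[, 2]
  nint <- phy$Nnode
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    lab <- integer(nn)
    lab[seq_len(ntip)] <- states
    lab[(ntip + 1):nn] <- bitwAnd(bitwShiftR(mask, 0:(nint - 1)), 1L)
    p <- lab[parents]; k <- lab[kids]
    cost <- w_gain * sum(p == 0 & k == 1) + w_loss * sum(p == 1 & k == 0)
    if (root_prior == "gain" && lab[ntip + 1L] == 1) cost <- cost + w_gain
    if (cost < best) best <- cost
  }
  best
}
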