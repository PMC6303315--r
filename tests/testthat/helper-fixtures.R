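# Shared fixtures: toy networks built from text, small MID sets.

parse_lines <- function(...) {
  emuflux:::parse_network_lines(c(...))
}

# convergence motif: labeled route T and unlabeled route U into pool P
convergence_net <- function() {
  parse_lines("SOURCE T 3", "SOURCE U 3", "SINK Q 3",
              "R1: T (abc) -> P (abc)",
              "R2: U (abc) -> P (abc)",
              "R3: P (abc) -> Q (abc)")
}

# build a one-row-per-entry mid_set from a named list of MID vectors
make_set <- function(mids, condition = "control", replicate = 1L) {
  mids_to_set(mids, condition = condition, replicate = replicate)
}

control_truth <- function() {
  c(SER = 0.10, GLY = 0.50, ASP = 0.70, OAA = 0.60, IMP = 0.85, UMP = 0.80)
}

# random strictly positive fluxes for a network, reproducible
random_fluxes <- function(net, seed) {
  set.seed(seed)
  stats::setNames(stats::runif(length(net$reaction_ids), 0.2, 2),
                  net$reaction_ids)
}
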