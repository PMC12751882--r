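#' Specification for synthetic regulatory-network instances
#'
#' Describes the random-network regime the generator emulates: a sparse
#' directed background graph with mostly activating edges (regulatory
#' pathway relations are predominantly positive), drugs acting on a handful
#' of immediate targets, and -- for planted instances -- a gadget wiring the
#' two drugs' effect clusters so that the combination is synergistic or
#' antagonistic by construction.
#'
#' @param n_nodes Number of nodes.
#' @param edge_prob Probability of each ordered background edge, in (0, 1).
#' @param positive_edge_frac Fraction of background edges that are positive,
#'   in [0, 1] (default 0.7).
#' @param targets_per_drug Immediate targets per drug (>= 1; planted
#'   instances need >= 2 so each drug has both an activated and an inhibited
#'   target).
#' @param planted One of `"none"`, `"synergism"`, `"antagonism"`.
#' @param cluster_separation Hop distance (>= 3) between opposing planted
#'   clusters.
#' @param seed RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 60, edge_prob = 0.02,
                           positive_edge_frac = 0.7, targets_per_drug = 4,
                           planted = c("none", "synergism", "antagonism"),
                           cluster_separation = 4, seed = 1) {
  planted <- match.arg(planted)
  stopifnot(n_nodes >= 0, edge_prob > 0, edge_prob < 1,
            positive_edge_frac >= 0, positive_edge_frac <= 1,
            targets_per_drug >= 1, cluster_separation >= 3)
  structure(list(n_nodes = as.integer(n_nodes), edge_prob = edge_prob,
                 positive_edge_frac = positive_edge_frac,
                 targets_per_drug = as.integer(targets_per_drug),
                 planted = planted,
                 cluster_separation = as.integer(cluster_separation),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synth_node_names <- function(n) sprintf("T%03d", seq_len(n))

# Random signed edges among `nodes`, one Bernoulli draw per ordered pair.
random_signed_edges <- function(nodes, edge_prob, positive_edge_frac) {
  n <- length(nodes)
  if (n < 2) return(reg_edges(character(0), character(0), character(0)))
  pairs <- expand.grid(source = nodes, destination = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$destination, ]
  keep <- runif(nrow(pairs)) < edge_prob
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(reg_edges(character(0), character(0), character(0)))
  }
  positive <- runif(nrow(pairs)) < positive_edge_frac
  reg_edges(pairs$source, pairs$destination,
            ifelse(positive, "activation", "inhibition"),
            pathway_id = "synthetic")
}

#' Generate a random signed directed regulatory network
#'
#' Each ordered node pair receives an edge with probability `edge_prob`,
#' positive (activation) with probability `positive_edge_frac`, otherwise
#' negative (inhibition). Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `regnet` object including isolated nodes.
#' @export
generate_network <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nodes <- synth_node_names(spec$n_nodes)
  with_seed(spec$seed, {
    edges <- random_signed_edges(nodes, spec$edge_prob,
                                 spec$positive_edge_frac)
    build_network(edges, nodes = nodes)
  })
}

# A directed chain from `from` to `to` through fresh relay nodes, all
# positive edges; length = number of edges.
chain_edges <- function(from, relays, to) {
  seqn <- c(from, relays, to)
  reg_edges(seqn[-length(seqn)], seqn[-1], "activation",
            pathway_id = "planted")
}

#' Generate one drug-pair instance with planted synergy or antagonism
#'
#' Builds a background random network on nodes disjoint from a planted
#' gadget, so opposing clusters stay at least `cluster_separation` hops
#' apart by construction. Each drug activates half of its immediate targets
#' (positive cluster) and inhibits the rest (negative cluster; drug-level
#' blocking keeps those clusters single nodes). For a synergistic instance
#' the same-sign clusters of the two drugs are joined by length-1 positive
#' chains, while the cross-sign cluster pairs are connected only through
#' long all-positive relay chains of `cluster_separation` hops; for an
#' antagonistic instance the cross-sign clusters get the short chains and
#' the same-sign pairs the long ones (the positive-positive relay chain is
#' 2 hops longer to absorb the 2-hop propagation leak out of the activated
#' cluster).
#'
#' @param spec A [synthetic_spec()] with `planted` set to `"synergism"` or
#'   `"antagonism"`.
#' @param drug_a,drug_b Drug identifiers for the two profiles.
#' @return List with `network` (`regnet`), `profile_a`, `profile_b`
#'   (`drug_profile`), and `record` (one-row data frame `drug_a`, `drug_b`,
#'   `label`).
#' @export
generate_combination <- function(spec = synthetic_spec(planted = "synergism"),
                                 drug_a = "DRUG_A", drug_b = "DRUG_B") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$planted == "none") {
    stop("generate_combination needs planted = 'synergism' or 'antagonism'")
  }
  tpd <- spec$targets_per_drug
  if (tpd < 2) {
    stop("infeasible spec: planted instances need targets_per_drug >= 2 ",
         "(each drug must have a positive and a negative cluster)")
  }
  npos <- ceiling(tpd / 2)
  nneg <- tpd - npos
  cs <- spec$cluster_separation
  n_relay <- if (spec$planted == "synergism") 2 * (cs - 1) else
    (cs - 1) + (cs + 1)
  gadget_n <- 2 * tpd + n_relay
  if (gadget_n > spec$n_nodes) {
    stop("infeasible spec: gadget needs ", gadget_n, " nodes but n_nodes = ",
         spec$n_nodes)
  }

  nodes <- synth_node_names(spec$n_nodes)
  ap <- nodes[seq_len(npos)]
  an <- nodes[npos + seq_len(nneg)]
  bp <- nodes[tpd + seq_len(npos)]
  bn <- nodes[tpd + npos + seq_len(nneg)]
  relays <- nodes[2 * tpd + seq_len(n_relay)]
  background <- nodes[-seq_len(gadget_n)]

  cyc <- function(i, k) ((i - 1) %% k) + 1   # map clusters of unequal size
  if (spec$planted == "synergism") {
    near <- rbind(
      reg_edges(ap, bp[cyc(seq_along(ap), npos)], "activation", "planted"),
      reg_edges(an, bn[cyc(seq_along(an), nneg)], "activation", "planted")
    )
    far <- rbind(
      chain_edges(bn[1], relays[seq_len(cs - 1)], ap[1]),        # (+,-) pair
      chain_edges(an[1], relays[cs - 1 + seq_len(cs - 1)], bp[1]) # (-,+) pair
    )
  } else {
    near <- rbind(
      reg_edges(ap, bn[cyc(seq_along(ap), nneg)], "activation", "planted"),
      reg_edges(an, bp[cyc(seq_along(an), npos)], "activation", "planted")
    )
    far <- rbind(
      chain_edges(an[1], relays[seq_len(cs - 1)], bn[1]),        # (-,-) pair
      chain_edges(bp[1], relays[cs - 1 + seq_len(cs + 1)], ap[1]) # (+,+) pair
    )
  }

  with_seed(spec$seed, {
    bg <- random_signed_edges(background, spec$edge_prob,
                              spec$positive_edge_frac)
    network <- build_network(rbind(near, far, bg), nodes = nodes)
    list(
      network = network,
      profile_a = drug_profile(drug_a, setNames(
        rep(c("activation", "inhibition"), c(npos, nneg)), c(ap, an))),
      profile_b = drug_profile(drug_b, setNames(
        rep(c("activation", "inhibition"), c(npos, nneg)), c(bp, bn))),
      record = data.frame(drug_a = drug_a, drug_b = drug_b,
                          label = spec$planted, stringsAsFactors = FALSE)
    )
  })
}

#' Generate a labeled benchmark of planted drug-pair instances
#'
#' Per-pair seeds are drawn (without replacement) from the benchmark seed so
#' any single instance can be regenerated in isolation; instances are
#' pairwise distinct.
#'
#' @param n_pairs Number of drug pairs (>= 2).
#' @param synergy_frac Fraction of synergistic pairs, in (0, 1); the class
#'   split is `round(n_pairs * synergy_frac)` synergistic, rest antagonistic.
#' @param spec Base [synthetic_spec()]; its `planted` and `seed` fields are
#'   overridden per pair.
#' @return List with `instances` (list of [generate_combination()] outputs)
#'   and `records` (data frame `drug_a`, `drug_b`, `label`).
#' @export
generate_benchmark <- function(n_pairs, synergy_frac = 0.5,
                               spec = synthetic_spec()) {
  stopifnot(n_pairs >= 2, synergy_frac > 0, synergy_frac < 1)
  n_syn <- round(n_pairs * synergy_frac)
  labels <- rep(c("synergism", "antagonism"), c(n_syn, n_pairs - n_syn))
  pair_seeds <- with_seed(spec$seed,
                          sample.int(.Machine$integer.max - 1L, n_pairs))
  instances <- lapply(seq_len(n_pairs), function(i) {
    sp <- spec
    sp$planted <- labels[i]
    sp$seed <- pair_seeds[i]
    generate_combination(sp, drug_a = sprintf("D%03dA", i),
                         drug_b = sprintf("D%03dB", i))
  })
  records <- do.call(rbind, lapply(instances, `[[`, "record"))
  rownames(records) <- NULL
  list(instances = instances, records = records)
}
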