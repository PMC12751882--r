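#' Attenuation parameters for drug-effect propagation
#'
#' The intensity of a drug's action decays as it propagates hop by hop along
#' regulatory edges. A path whose net sign is positive attenuates by
#' `delta_pos^hop`, a negative-net-sign path by `delta_neg^hop`. Both
#' coefficients must be at least 1 (attenuation, never amplification).
#' `hop_max` bounds the path length; the default of 2 hops balances capturing
#' downstream information against the combinatorial growth of overlapping
#' path effects.
#'
#' @param delta_pos Attenuation coefficient for positive regulation (>= 1).
#' @param delta_neg Attenuation coefficient for negative regulation (>= 1).
#' @param hop_max Maximum number of hops from an immediate target (>= 0).
#' @return An object of class `atten_params`.
#' @examples
#' attenuation_params()          # shipped defaults: 1.5, 1.1, 2 hops
#' @export
attenuation_params <- function(delta_pos = 1.5, delta_neg = 1.1, hop_max = 2) {
  if (!is.numeric(delta_pos) || delta_pos < 1) {
    stop("delta_pos must be >= 1 (attenuation, not amplification)")
  }
  if (!is.numeric(delta_neg) || delta_neg < 1) {
    stop("delta_neg must be >= 1 (attenuation, not amplification)")
  }
  hop_max <- as.integer(hop_max)
  if (is.na(hop_max) || hop_max < 0) stop("hop_max must be an integer >= 0")
  structure(list(delta_pos = delta_pos, delta_neg = delta_neg,
                 hop_max = hop_max), class = "atten_params")
}

# Out-adjacency of a regnet as a list keyed by source node; each element is a
# list(dest = character, sign = integer). Parallel opposite-sign edges stay
# distinct entries.
out_adjacency <- function(network) {
  e <- network$edges
  if (nrow(e) == 0) return(list())
  lapply(split(seq_len(nrow(e)), e$source),
         function(i) list(dest = e$destination[i], sign = e$sign[i]))
}

#' Enumerate admissible drug-action paths
#'
#' A drug-action path starts at an immediate target of the drug and follows
#' directed regulatory edges through at most `hop_max` hops, visiting each
#' node at most once. Negative regulation blocks downstream signaling: a path
#' whose latest edge is negative is terminal, so every non-terminal edge on an
#' admissible path is positive. A drug-level negative action (inhibition or
#' downregulation) likewise blocks propagation, so paths from such an
#' immediate target have length 0. The path's net sign is the drug-action
#' sign times the product of its edge signs.
#'
#' @param network A `regnet` object.
#' @param profile A `drug_profile`; targets absent from the network are
#'   skipped with a warning.
#' @param hop_max Maximum hop count (default 2).
#' @return A list of paths, each a list with elements `nodes` (node sequence),
#'   `edge_signs`, `drug_sign`, `hop`, `net_sign`.
#' @export
enumerate_action_paths <- function(network, profile, hop_max = 2) {
  stopifnot(inherits(network, "regnet"), inherits(profile, "drug_profile"))
  signs <- profile_signs(profile)
  missing <- setdiff(names(signs), network$nodes)
  if (length(missing)) {
    warning("drug ", profile$drug_id, ": ", length(missing),
            " target(s) absent from the network, skipped (",
            paste(utils::head(missing, 3), collapse = ", "), ")")
    signs <- signs[!names(signs) %in% missing]
  }
  adj <- out_adjacency(network)
  paths <- list()
  emit <- function(nodes, edge_signs, drug_sign) {
    net_sign <- drug_sign * prod(edge_signs)
    paths[[length(paths) + 1L]] <<- list(
      nodes = nodes, edge_signs = edge_signs, drug_sign = drug_sign,
      hop = length(edge_signs), net_sign = as.integer(net_sign)
    )
  }
  walk <- function(nodes, edge_signs) {
    nbr <- adj[[nodes[length(nodes)]]]
    if (is.null(nbr)) return()
    for (k in seq_along(nbr$dest)) {
      w <- nbr$dest[k]
      if (w %in% nodes) next              # simple paths only
      sg <- c(edge_signs, nbr$sign[k])
      emit(c(nodes, w), sg, 1L)
      # recurse only through positive edges (blocking) and within hop_max
      if (nbr$sign[k] > 0 && length(sg) < hop_max) walk(c(nodes, w), sg)
    }
  }
  for (t in names(signs)) {
    emit(t, integer(0), signs[[t]])
    if (signs[[t]] > 0 && hop_max > 0) walk(t, integer(0))
  }
  paths
}

# Per-node counts of admissible paths by hop and net sign; IA is then a cheap
# function of (delta_pos, delta_neg), which the optimizer exploits.
path_spectrum <- function(network, profile, hop_max = 2) {
  paths <- enumerate_action_paths(network, profile, hop_max)
  hops <- hop_max + 1L
  ends <- vapply(paths, function(p) p$nodes[length(p$nodes)], character(1))
  nodes <- unique(ends)
  pos <- matrix(0, length(nodes), hops, dimnames = list(nodes, NULL))
  neg <- pos
  for (p in paths) {
    v <- p$nodes[length(p$nodes)]
    h <- p$hop + 1L
    if (p$net_sign > 0) pos[v, h] <- pos[v, h] + 1 else
      neg[v, h] <- neg[v, h] + 1
  }
  list(pos = pos, neg = neg, hop_max = hop_max)
}

ia_from_spectrum <- function(spectrum, delta_pos, delta_neg) {
  h <- 0:spectrum$hop_max
  drop(spectrum$pos %*% (1 / delta_pos^h) - spectrum$neg %*% (1 / delta_neg^h))
}

#' Compute the intensity of action (IA) of a drug on every reachable node
#'
#' Sums, over every admissible drug-action path ending at a node, the path's
#' net sign attenuated by the matching coefficient raised to the hop count:
#' a positive-net path contributes `+1/delta_pos^hop`, a negative-net path
#' `-1/delta_neg^hop`; an immediate target contributes exactly +1 or -1
#' (hop 0). Nodes are then partitioned by the sign of their summed IA;
#' IA = 0 nodes (untouched, or exactly cancelled) belong to neither set.
#'
#' @param network A `regnet` object.
#' @param profile A `drug_profile` (empty or fully off-network profiles give
#'   an empty effect profile with a warning).
#' @param params An [attenuation_params()] object.
#' @return An object of class `node_effects`: list with `ia` (named numeric
#'   over reached nodes; unlisted nodes are implicitly 0), `positive_set`,
#'   `negative_set` (character vectors), and `drug_id`.
#' @examples
#' net <- build_network(reg_edges("A", "B", "inhibition"))
#' eff <- compute_ia(net, drug_profile("D", c(A = "activation")),
#'                   attenuation_params(1.5, 1.1))
#' eff$ia   # A: +1, B: -1/1.1
#' @export
compute_ia <- function(network, profile, params = attenuation_params()) {
  stopifnot(inherits(params, "atten_params"))
  spectrum <- path_spectrum(network, profile, params$hop_max)
  if (nrow(spectrum$pos) == 0) {
    warning("drug ", profile$drug_id,
            ": no targets in the network, empty effect profile")
    ia <- setNames(numeric(0), character(0))
  } else {
    ia <- ia_from_spectrum(spectrum, params$delta_pos, params$delta_neg)
    names(ia) <- rownames(spectrum$pos)
  }
  sets <- partition_nodes(ia)
  structure(list(ia = ia, positive_set = sets$positive_set,
                 negative_set = sets$negative_set, drug_id = profile$drug_id),
            class = "node_effects")
}

#' @export
print.node_effects <- function(x, ...) {
  cat("Drug", x$drug_id, "effect profile:", length(x$ia), "nodes reached (",
      length(x$positive_set), "positive /", length(x$negative_set),
      "negative )\n")
  invisible(x)
}

#' Partition nodes by the sign of their IA value
#'
#' @param x A `node_effects` object or a named numeric vector of IA values.
#' @return List with `positive_set` (IA > 0) and `negative_set` (IA < 0);
#'   nodes with IA exactly 0 appear in neither. The comparison is exact:
#'   contributions are sums of exact reciprocals and a tolerance would
#'   silently change set membership.
#' @export
partition_nodes <- function(x) {
  ia <- if (inherits(x, "node_effects")) x$ia else x
  list(positive_set = sort(names(ia)[ia > 0]),
       negative_set = sort(names(ia)[ia < 0]))
}

#' Write a node-effect profile as TSV
#'
#' Columns `node`, `ia`, `set` (`pos`, `neg`, or `zero`).
#'
#' @param effects A `node_effects` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_effect_profile <- function(effects, path) {
  stopifnot(inherits(effects, "node_effects"))
  out <- data.frame(node = names(effects$ia), ia = unname(effects$ia),
                    stringsAsFactors = FALSE)
  out$set <- ifelse(out$ia > 0, "pos", ifelse(out$ia < 0, "neg", "zero"))
  out <- out[order(out$node), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
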