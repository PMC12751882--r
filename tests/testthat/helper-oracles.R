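# Independent oracles and random-instance generators shared across tests.
# These deliberately avoid the package's own code paths: the IA oracle
# enumerates unpruned vertex paths and filters; the distance oracle runs a
# hand-rolled BFS plus a literal double loop; the AUC oracle counts
# concordant positive-negative pairs.

# --- random signed edge tables (may contain both-sign parallel pairs) -------

random_edge_table <- function(n_nodes, n_edges, dual_frac = 0.15) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  src <- sample(nodes, n_edges, replace = TRUE)
  dst <- sample(nodes, n_edges, replace = TRUE)
  keep <- src != dst
  src <- src[keep]; dst <- dst[keep]
  rel <- sample(c("activation", "inhibition", "expression", "repression"),
                length(src), replace = TRUE)
  # occasionally add the opposite-sign parallel edge
  dual <- runif(length(src)) < dual_frac
  df <- data.frame(source = c(src, src[dual]),
                   destination = c(dst, dst[dual]),
                   relation = c(rel, ifelse(rel[dual] %in%
                                              c("activation", "expression"),
                                            "inhibition", "activation")),
                   stringsAsFactors = FALSE)
  list(nodes = nodes, edges = df)
}

random_profile <- function(nodes, n_targets, id = "DX") {
  t <- sample(nodes, min(n_targets, length(nodes)))
  drug_profile(id, stats::setNames(
    sample(c("activation", "upregulation", "inhibition", "downregulation"),
           length(t), replace = TRUE), t))
}

# --- brute-force IA oracle --------------------------------------------------

# Enumerates every simple vertex path from each immediate target up to
# hop_max, expands every combination of parallel edge signs along it, keeps
# the admissible ones (all non-terminal signs positive; negatively-acted
# immediates contribute hop 0 only), and sums net_sign / delta^hop.
oracle_ia <- function(net, profile, delta_pos, delta_neg, hop_max) {
  e <- net$edges
  signs_between <- function(a, b) e$sign[e$source == a & e$destination == b]
  succ <- function(a) unique(e$destination[e$source == a])
  acts <- profile_signs(profile)
  acts <- acts[names(acts) %in% net$nodes]
  ia <- stats::setNames(numeric(length(net$nodes)), net$nodes)

  vertex_paths <- function(path) {
    out <- list(path)
    if (length(path) - 1 >= hop_max) return(out)
    for (w in succ(path[length(path)])) {
      if (w %in% path) next
      out <- c(out, vertex_paths(c(path, w)))
    }
    out
  }
  for (t in names(acts)) {
    s0 <- acts[[t]]
    ia[t] <- ia[t] + s0
    if (s0 < 0) next
    for (vp in vertex_paths(t)) {
      h <- length(vp) - 1
      if (h == 0) next
      sign_options <- lapply(seq_len(h), function(k) {
        signs_between(vp[k], vp[k + 1])
      })
      combos <- as.matrix(expand.grid(sign_options))
      for (r in seq_len(nrow(combos))) {
        combo <- as.numeric(combos[r, ])
        if (h > 1 && any(combo[-h] < 0)) next   # blocked mid-path
        net_sign <- prod(combo)
        delta <- if (net_sign > 0) delta_pos else delta_neg
        ia[vp[h + 1]] <- ia[vp[h + 1]] + net_sign / delta^h
      }
    }
  }
  ia
}

# --- BFS + double-loop set-distance oracle ----------------------------------

oracle_bfs_dists <- function(net, from) {
  e <- net$edges
  dist <- stats::setNames(rep(Inf, length(net$nodes)), net$nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in unique(e$destination[e$source == v])) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_set_distance <- function(net, I, J) {
  D <- t(vapply(net$nodes, function(v) oracle_bfs_dists(net, v),
                numeric(length(net$nodes))))
  term <- function(from, to) {
    vals <- c()
    for (i in from) {
      d <- D[i, to]
      d <- d[is.finite(d)]
      if (length(d)) vals <- c(vals, mean(d))
    }
    if (length(vals)) mean(vals) else NA_real_
  }
  t1 <- term(I, J)
  t2 <- term(J, I)
  if (is.na(t1) && is.na(t2)) NA_real_ else mean(c(t1, t2), na.rm = TRUE)
}

# --- pairwise-concordance AUC oracle ----------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "synergism"]
  neg <- scores[labels == "antagonism"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# --- small fixtures ---------------------------------------------------------

reference_pairs_path <- function() {
  system.file("extdata", "reference_pairs.tsv", package = "regnetsyn",
              mustWork = TRUE)
}

minimal_kgml <- function(relations,
                         entries = c('<entry id="1" name="hsa:10" type="gene"/>',
                                     '<entry id="2" name="hsa:20" type="gene"/>')) {
  paste0('<pathway name="path:test01" org="test">',
         paste(entries, collapse = ""), paste(relations, collapse = ""),
         "</pathway>")
}
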