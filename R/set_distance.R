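#' Relative network distance between two node sets
#'
#' Symmetrized, reachability-restricted mean of directed shortest-path
#' distances. For the forward term, every node `i` of `I` that can reach at
#' least one node of `J` contributes the mean hop-count distance to the `J`
#' nodes it reaches; the term is the mean of those contributions. The reverse
#' term (`J` to `I`) is defined symmetrically, and the distance is the mean of
#' the defined terms: both defined gives the half-sum, one defined gives that
#' term alone, neither gives `NA` (no regulation in either direction).
#' Shortest paths are unweighted hop counts on the full directed network,
#' ignoring edge signs; a node belonging to both sets contributes a zero
#' self-distance.
#'
#' @param network A `regnet` object.
#' @param I,J Character vectors of node identifiers; must be subsets of the
#'   network's nodes. Empty sets give `NA` with a warning.
#' @param dist_matrix Optional precomputed directed distance matrix whose row
#'   and column names cover `I` and `J` (rows = path sources); used internally
#'   to avoid repeated BFS when scoring many set pairs.
#' @return A single nonnegative number, or `NA` when undefined.
#' @examples
#' net <- build_network(reg_edges(c("a", "b", "x"), c("c", "x", "c"),
#'                                "activation"))
#' set_distance(net, c("a", "b"), "c")   # (1 + 2) / 2 = 1.5
#' @export
set_distance <- function(network, I, J, dist_matrix = NULL) {
  I <- unique(as.character(I))
  J <- unique(as.character(J))
  if (length(I) == 0 || length(J) == 0) {
    warning("empty node set: distance undefined")
    return(NA_real_)
  }
  if (!is.null(network)) {
    stopifnot(inherits(network, "regnet"))
    out <- setdiff(c(I, J), network$nodes)
    if (length(out)) {
      stop("node set members not in network: ",
           paste(utils::head(out, 3), collapse = ", "))
    }
  }
  if (is.null(dist_matrix)) {
    g <- as_igraph(network)
    u <- union(I, J)
    dist_matrix <- igraph::distances(g, v = u, to = u, mode = "out")
  }
  fwd <- directed_set_term(dist_matrix, I, J)
  rev <- directed_set_term(dist_matrix, J, I)
  terms <- c(fwd, rev)
  if (all(is.na(terms))) NA_real_ else mean(terms, na.rm = TRUE)
}

# One directed bracket term of the set-distance: mean over sources in `from`
# reaching anything in `to` of their mean distance to the reached nodes.
directed_set_term <- function(D, from, to) {
  per_source <- vapply(from, function(i) {
    d <- D[i, to]
    d <- d[is.finite(d)]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  per_source <- per_source[!is.na(per_source)]
  if (length(per_source)) mean(per_source) else NA_real_
}

#' Relative distances of the forward-regulated node-set pairs
#'
#' Given the four set distances of a drug pair -- positive-positive `d_pp`,
#' negative-negative `d_mm`, and the reverse-regulated cross pairs `d_pm`
#' (positive of one drug vs negative of the other) and `d_mp` -- subtracts the
#' minimum defined reverse-regulated distance from each forward distance:
#' `d_plus = d_pp - min(d_pm, d_mp)` and `d_minus = d_mm - min(d_pm, d_mp)`.
#' The `min` runs over the defined members of the reverse pair; if neither is
#' defined, or the forward distance itself is undefined, the corresponding
#' output is `NA`.
#'
#' @param d_pp,d_mm,d_pm,d_mp The four set distances (`NA` = undefined).
#'   Alternatively pass a single list/vector with these names as `d_pp`.
#' @return List with numeric `d_plus` and `d_minus` (possibly `NA`).
#' @examples
#' relative_distances(2.80, 3.91, 4.38, 4.51)  # -1.58, -0.47
#' @export
relative_distances <- function(d_pp, d_mm = NULL, d_pm = NULL, d_mp = NULL) {
  if (is.list(d_pp) || length(d_pp) == 4) {
    d <- as.list(d_pp)
    stopifnot(all(c("d_pp", "d_mm", "d_pm", "d_mp") %in% names(d)))
    d_mm <- d$d_mm; d_pm <- d$d_pm; d_mp <- d$d_mp; d_pp <- d$d_pp
  }
  rev_d <- c(d_pm, d_mp)
  m <- if (all(is.na(rev_d))) NA_real_ else min(rev_d, na.rm = TRUE)
  list(d_plus = if (is.na(m) || is.na(d_pp)) NA_real_ else d_pp - m,
       d_minus = if (is.na(m) || is.na(d_mm)) NA_real_ else d_mm - m)
}

#' Classify a drug combination from its relative distances
#'
#' Both relative distances negative means the same-sign effect sets of the
#' two drugs sit closer than any cross-sign pair: the drugs reinforce each
#' other (synergism). Either relative distance positive means a cross-sign
#' pair is closest: one drug's positive effects neighbor the other's negative
#' effects, counteracting them (antagonism). Both exactly zero, or either
#' undefined, is neither (indeterminate).
#'
#' @param d_plus,d_minus Relative distances (may be `NA`).
#' @return One of `"synergism"`, `"antagonism"`, `"indeterminate"`.
#' @export
classify_combination <- function(d_plus, d_minus) {
  if (is.na(d_plus) || is.na(d_minus)) return("indeterminate")
  if (d_plus < 0 && d_minus < 0) return("synergism")
  if (d_plus > 0 || d_minus > 0) return("antagonism")
  "indeterminate"
}

#' Continuous synergy ranking score
#'
#' `-max(d_plus, d_minus)`: larger is more synergistic. Its sign agrees with
#' [classify_combination()] except exactly at 0. Used to rank pairs for the
#' ROC curve; pairs with an undefined score are excluded from ROC with a
#' warning downstream.
#'
#' @param d_plus,d_minus Relative distances.
#' @return A number, or `NA` (with a warning) if either input is undefined.
#' @export
synergy_score <- function(d_plus, d_minus) {
  if (is.na(d_plus) || is.na(d_minus)) {
    warning("undefined relative distance: synergy score is NA")
    return(NA_real_)
  }
  -max(d_plus, d_minus)
}

#' Assess a drug pair on a regulatory network
#'
#' Full scoring pipeline for one combination: compute each drug's intensity
#' of action ([compute_ia()]), partition nodes into positive/negative effect
#' sets, evaluate the four set distances ([set_distance()]), derive the
#' relative distances ([relative_distances()]), classify, and attach the
#' ranking score.
#'
#' @param network A `regnet` object.
#' @param profile_a,profile_b `drug_profile` objects (non-empty).
#' @param params An [attenuation_params()] object.
#' @return An object of class `combo_assessment`: list with `drug_a`,
#'   `drug_b`, the four distances `d_pp`, `d_mm`, `d_pm`, `d_mp`, `d_plus`,
#'   `d_minus`, `call`, `score`.
#' @export
assess_pair <- function(network, profile_a, profile_b,
                        params = attenuation_params()) {
  eff_a <- compute_ia(network, profile_a, params)
  eff_b <- compute_ia(network, profile_b, params)
  assess_from_effects(network, eff_a, eff_b,
                      drug_a = profile_a$drug_id, drug_b = profile_b$drug_id)
}

# Assessment from precomputed effect profiles (shared with the optimizer).
assess_from_effects <- function(network, eff_a, eff_b,
                                drug_a = eff_a$drug_id,
                                drug_b = eff_b$drug_id,
                                dist_matrix = NULL) {
  Ip <- eff_a$positive_set; Im <- eff_a$negative_set
  Jp <- eff_b$positive_set; Jm <- eff_b$negative_set
  d <- list(d_pp = NA_real_, d_mm = NA_real_, d_pm = NA_real_,
            d_mp = NA_real_)
  if ((length(Ip) + length(Im)) == 0 || (length(Jp) + length(Jm)) == 0) {
    message("assess_pair: a drug has empty positive and negative sets; ",
            "call is indeterminate")
  } else {
    if (is.null(dist_matrix)) {
      u <- unique(c(Ip, Im, Jp, Jm))
      dist_matrix <- igraph::distances(as_igraph(network), v = u, to = u,
                                       mode = "out")
    }
    quiet_dist <- function(I, J) {
      if (length(I) == 0 || length(J) == 0) return(NA_real_)
      set_distance(NULL, I, J, dist_matrix = dist_matrix)
    }
    d <- list(d_pp = quiet_dist(Ip, Jp), d_mm = quiet_dist(Im, Jm),
              d_pm = quiet_dist(Ip, Jm), d_mp = quiet_dist(Im, Jp))
  }
  rel <- relative_distances(d)
  call <- classify_combination(rel$d_plus, rel$d_minus)
  score <- if (is.na(rel$d_plus) || is.na(rel$d_minus)) NA_real_ else
    -max(rel$d_plus, rel$d_minus)
  structure(c(list(drug_a = drug_a, drug_b = drug_b), d, rel,
              list(call = call, score = score)),
            class = "combo_assessment")
}

#' @export
print.combo_assessment <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat("Combination ", x$drug_a, " + ", x$drug_b, ": ", x$call, "\n",
      "  d(+,+)=", fmt(x$d_pp), "  d(-,-)=", fmt(x$d_mm),
      "  d(+,-)=", fmt(x$d_pm), "  d(-,+)=", fmt(x$d_mp), "\n",
      "  d_plus=", fmt(x$d_plus), "  d_minus=", fmt(x$d_minus),
      "  score=", fmt(x$score), "\n", sep = "")
  invisible(x)
}

#' Assess many drug pairs against one network
#'
#' @param network A `regnet` object.
#' @param profiles Named list of `drug_profile` objects keyed by drug id.
#' @param pairs Data frame with columns `drug_a`, `drug_b` (extra columns
#'   such as `label` are carried through untouched).
#' @param params An [attenuation_params()] object.
#' @return Data frame with one row per pair: ids, the four distances,
#'   `d_plus`, `d_minus`, `call`, `score`, plus any extra input columns.
#' @export
assess_pairs <- function(network, profiles, pairs,
                         params = attenuation_params()) {
  stopifnot(all(c("drug_a", "drug_b") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), names(profiles))
  if (length(missing)) {
    stop("no drug profile for: ", paste(utils::head(missing, 3),
                                        collapse = ", "))
  }
  effects <- lapply(profiles, compute_ia, network = network, params = params)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- suppressMessages(assess_from_effects(
      network, effects[[pairs$drug_a[i]]], effects[[pairs$drug_b[i]]],
      drug_a = pairs$drug_a[i], drug_b = pairs$drug_b[i]))
    as.data.frame(unclass(a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  extra <- setdiff(names(pairs), names(out))
  if (length(extra)) out <- cbind(out, pairs[, extra, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write pair assessments as TSV
#'
#' Columns `drug_a`, `drug_b`, `d_pp`, `d_mm`, `d_pm`, `d_mp`, `d_plus`,
#' `d_minus`, `call`, `score`; undefined values serialized as `NA`.
#'
#' @param assessments Data frame from [assess_pairs()], or a single
#'   `combo_assessment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  if (inherits(assessments, "combo_assessment")) {
    assessments <- as.data.frame(unclass(assessments),
                                 stringsAsFactors = FALSE)
  }
  cols <- c("drug_a", "drug_b", "d_pp", "d_mm", "d_pm", "d_mp",
            "d_plus", "d_minus", "call", "score")
  keep <- c(cols, setdiff(names(assessments), cols))
  write.table(assessments[, intersect(keep, names(assessments))], path,
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA",
              fileEncoding = "UTF-8")
  invisible(path)
}
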