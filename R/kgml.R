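#' Parse a KEGG KGML pathway document into signed regulatory edges
#'
#' Extracts the protein-protein (`PPrel`) and gene-expression (`GErel`)
#' relations whose subtype list contains at least one of the four signed
#' regulatory subtypes: `activation`, `inhibition`, `expression`,
#' `repression`. Each qualifying relation yields one directed edge
#' entry1 -> entry2 per pair of gene identifiers named by the two entries
#' (KGML entry `name` attributes may list several space-separated genes, which
#' expand combinatorially; `group` entries expand to their gene components).
#' Relations of other types (e.g. `ECrel`, `maplink`), relations carrying none
#' of the four subtypes (e.g. only `binding/association` or
#' `phosphorylation`), relations referencing unknown entry ids, and relations
#' whose endpoints name no gene entries (maps, compounds) are skipped and
#' tallied by reason. A relation carrying both a positive and a negative
#' subtype emits one edge per sign.
#'
#' @param x Path to a KGML file, or a single string of KGML/XML content.
#' @return A list with elements `edges` (a data frame as from [reg_edges()],
#'   with `pathway_id` set to the document's pathway name) and `skipped`
#'   (named integer vector of skip counts by reason:
#'   `other_relation_type`, `no_signed_subtype`, `unknown_entry`,
#'   `non_gene_entry`).
#' @examples
#' kgml <- paste0(
#'   '<pathway name="path:test">',
#'   '<entry id="1" name="hsa:10" type="gene"/>',
#'   '<entry id="2" name="hsa:20" type="gene"/>',
#'   '<relation entry1="1" entry2="2" type="PPrel">',
#'   '<subtype name="activation" value="--&gt;"/></relation></pathway>'
#' )
#' parse_kgml(kgml)$edges
#' @export
parse_kgml <- function(x) {
  doc <- xml2::read_xml(x)
  if (xml2::xml_name(doc) != "pathway") {
    stop("not a KGML document: root element is <", xml2::xml_name(doc),
         ">, expected <pathway>")
  }
  pathway_id <- xml2::xml_attr(doc, "name")
  if (is.na(pathway_id)) pathway_id <- ""

  entries <- xml2::xml_find_all(doc, "./entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_split <- strsplit(xml2::xml_attr(entries, "name"), "\\s+")
  components <- lapply(entries, function(e) {
    xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id")
  })
  entry_type <- setNames(types, ids)

  # Gene identifiers named by an entry; groups recurse into their components.
  entry_genes <- function(id, depth = 0) {
    if (depth > 4 || !id %in% ids) return(character(0))
    i <- match(id, ids)
    if (identical(types[i], "gene")) {
      nm <- names_split[[i]]
      return(nm[nzchar(nm) & !is.na(nm)])
    }
    if (identical(types[i], "group")) {
      return(unique(unlist(lapply(components[[i]], entry_genes, depth + 1))))
    }
    character(0)
  }

  skipped <- c(other_relation_type = 0L, no_signed_subtype = 0L,
               unknown_entry = 0L, non_gene_entry = 0L)
  out <- list()
  for (rel in xml2::xml_find_all(doc, "./relation")) {
    rtype <- xml2::xml_attr(rel, "type")
    if (!rtype %in% c("PPrel", "GErel")) {
      skipped["other_relation_type"] <- skipped["other_relation_type"] + 1L
      next
    }
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    if (!e1 %in% ids || !e2 %in% ids) {
      skipped["unknown_entry"] <- skipped["unknown_entry"] + 1L
      next
    }
    subs <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"), "name")
    signed <- unique(subs[subs %in% names(RELATION_SIGNS)])
    if (!length(signed)) {
      skipped["no_signed_subtype"] <- skipped["no_signed_subtype"] + 1L
      next
    }
    g1 <- entry_genes(e1)
    g2 <- entry_genes(e2)
    if (!length(g1) || !length(g2)) {
      skipped["non_gene_entry"] <- skipped["non_gene_entry"] + 1L
      next
    }
    # one edge per sign: drop same-sign duplicates among the signed subtypes
    signed <- signed[!duplicated(RELATION_SIGNS[signed])]
    for (lab in signed) {
      grid <- expand.grid(source = g1, destination = g2,
                          stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- reg_edges(grid$source, grid$destination,
                                           lab, pathway_id)
    }
  }
  edges <- if (length(out)) do.call(rbind, out) else
    reg_edges(character(0), character(0), character(0))
  list(edges = edges, skipped = skipped)
}

#' Read a drug-target action table
#'
#' The TSV must have columns `drug_id`, `target`, `action` with actions in
#' `activation` / `upregulation` (positive, sign +1) or `inhibition` /
#' `downregulation` (negative, sign -1). Duplicate rows with identical action
#' are deduplicated; the same (drug, target) appearing with conflicting
#' actions is an error, never a silent override.
#'
#' @param path Path to the TSV (header row required; `#` comments ignored).
#' @return A named list of [drug_profile()] objects, one per distinct drug.
#' @export
read_drug_targets <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  need <- c("drug_id", "target", "action")
  if (!all(need %in% names(tab))) {
    stop("drug-target table must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(!tab$action %in% names(DRUG_ACTION_SIGNS))
  if (length(bad)) {
    stop("unknown action label ", sQuote(tab$action[bad[1]]), " in row ",
         bad[1], " (drug ", tab$drug_id[bad[1]], ", target ",
         tab$target[bad[1]], ")")
  }
  tab <- tab[!duplicated(tab[, need]), , drop = FALSE]
  dup <- duplicated(tab[, c("drug_id", "target")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("conflicting actions for drug ", tab$drug_id[i], ", target ",
         tab$target[i])
  }
  lapply(split(tab, tab$drug_id), function(d) {
    drug_profile(d$drug_id[1], setNames(d$action, d$target))
  })
}

#' A drug's immediate-target action profile
#'
#' @param drug_id Drug identifier (free text).
#' @param actions Named character vector mapping target identifiers to one of
#'   `activation`, `upregulation`, `inhibition`, `downregulation`.
#' @return An object of class `drug_profile`.
#' @examples
#' drug_profile("D1", c(EGFR = "inhibition", TP53 = "activation"))
#' @export
drug_profile <- function(drug_id, actions) {
  actions <- unlist(actions)
  if (is.null(names(actions)) || any(!nzchar(names(actions)))) {
    stop("actions must be a named vector (names are target identifiers)")
  }
  bad <- which(!actions %in% names(DRUG_ACTION_SIGNS))
  if (length(bad)) {
    stop("unknown action label ", sQuote(actions[bad[1]]), " for target ",
         names(actions)[bad[1]])
  }
  structure(list(drug_id = as.character(drug_id), actions = actions),
            class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat("Drug", x$drug_id, "acting on", length(x$actions), "targets\n")
  invisible(x)
}

#' Signed immediate actions of a drug profile
#'
#' @param profile A `drug_profile`.
#' @return Named integer vector (+1 activation/upregulation, -1
#'   inhibition/downregulation) keyed by target identifier.
#' @export
profile_signs <- function(profile) {
  stopifnot(inherits(profile, "drug_profile"))
  setNames(unname(DRUG_ACTION_SIGNS[profile$actions]), names(profile$actions))
}

#' Write drug-target profiles as TSV
#'
#' @param profiles A list of `drug_profile` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_targets <- function(profiles, path) {
  if (inherits(profiles, "drug_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(drug_id = p$drug_id, target = names(p$actions),
               action = unname(p$actions), stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a drug-pair label table
#'
#' The TSV must have columns `drug_a`, `drug_b`, `label`; labels are
#' normalized case-insensitively to `synergism` / `antagonism`. Pair order is
#' preserved as given; a self-pair (drug combined with itself) is accepted
#' with a warning.
#'
#' @param path Path to the TSV (header row required; `#` comments ignored).
#' @return A data frame with columns `drug_a`, `drug_b`, `label`.
#' @export
read_combinations <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  need <- c("drug_a", "drug_b", "label")
  if (!all(need %in% names(tab))) {
    stop("combination table must have columns ", paste(need, collapse = ", "))
  }
  lab <- tolower(tab$label)
  bad <- which(!lab %in% c("synergism", "antagonism"))
  if (length(bad)) {
    stop("unknown combination label ", sQuote(tab$label[bad[1]]),
         " in row ", bad[1])
  }
  tab$label <- lab
  self <- tab$drug_a == tab$drug_b
  if (any(self)) {
    warning(sum(self), " self-pair(s) in combination table (e.g. ",
            tab$drug_a[which(self)[1]], ")")
  }
  tab[, need]
}

#' Write a drug-pair label table as TSV
#'
#' @param records Data frame with columns `drug_a`, `drug_b`, `label`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_combinations <- function(records, path) {
  write.table(records[, c("drug_a", "drug_b", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
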