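test_that("parse_kgml extracts signed PPrel/GErel relations", {
  doc <- minimal_kgml(
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>')
  res <- parse_kgml(doc)
  expect_equal(nrow(res$edges), 1)
  expect_equal(res$edges$source, "hsa:10")
  expect_equal(res$edges$destination, "hsa:20")
  expect_equal(res$edges$sign, 1L)
  expect_equal(res$edges$pathway_id, "path:test01")
  expect_true(all(res$skipped == 0))
})

test_that("parse_kgml skips unsigned subtypes, other types, unknown entries", {
  doc <- minimal_kgml(c(
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="binding/association" value="---"/></relation>',
    '<relation entry1="1" entry2="2" type="ECrel"><subtype name="compound" value="c"/></relation>',
    '<relation entry1="1" entry2="99" type="GErel"><subtype name="expression" value="--&gt;"/></relation>'))
  res <- parse_kgml(doc)
  expect_equal(nrow(res$edges), 0)
  expect_equal(unname(res$skipped["no_signed_subtype"]), 1L)
  expect_equal(unname(res$skipped["other_relation_type"]), 1L)
  expect_equal(unname(res$skipped["unknown_entry"]), 1L)
})

test_that("parse_kgml expands multi-gene entries and groups combinatorially", {
  doc <- minimal_kgml(
    '<relation entry1="3" entry2="4" type="GErel"><subtype name="expression" value="--&gt;"/></relation>',
    entries = c('<entry id="3" name="hsa:1 hsa:2" type="gene"/>',
                '<entry id="4" name="hsa:3" type="gene"/>'))
  res <- parse_kgml(doc)
  expect_equal(nrow(res$edges), 2)
  expect_setequal(res$edges$source, c("hsa:1", "hsa:2"))
  expect_equal(unique(res$edges$destination), "hsa:3")
  expect_equal(unique(res$edges$sign), 1L)

  grp <- minimal_kgml(
    '<relation entry1="5" entry2="2" type="PPrel"><subtype name="inhibition" value="--|"/></relation>',
    entries = c('<entry id="1" name="hsa:10" type="gene"/>',
                '<entry id="2" name="hsa:20" type="gene"/>',
                '<entry id="4" name="hsa:40" type="gene"/>',
                '<entry id="5" name="undefined" type="group"><component id="1"/><component id="4"/></entry>'))
  res2 <- parse_kgml(grp)
  expect_setequal(res2$edges$source, c("hsa:10", "hsa:40"))
  expect_equal(unique(res2$edges$sign), -1L)
})

test_that("parse_kgml emits one edge per sign and ignores non-gene entries", {
  # signed subtype wins over unsigned companions; activation+inhibition -> 2
  doc <- minimal_kgml(
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--&gt;"/><subtype name="phosphorylation" value="+p"/><subtype name="inhibition" value="--|"/></relation>')
  res <- parse_kgml(doc)
  expect_equal(nrow(res$edges), 2)
  expect_setequal(res$edges$sign, c(1L, -1L))

  cpd <- minimal_kgml(
    '<relation entry1="1" entry2="6" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>',
    entries = c('<entry id="1" name="hsa:10" type="gene"/>',
                '<entry id="6" name="cpd:C00076" type="compound"/>'))
  res3 <- parse_kgml(cpd)
  expect_equal(nrow(res3$edges), 0)
  expect_equal(unname(res3$skipped["non_gene_entry"]), 1L)
})

test_that("parse_kgml output signs/labels are valid and round-trip as a network", {
  doc <- minimal_kgml(c(
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>',
    '<relation entry1="2" entry2="1" type="GErel"><subtype name="repression" value="--|"/></relation>'))
  res <- parse_kgml(doc)
  expect_true(all(res$edges$sign %in% c(-1L, 1L)))
  expect_true(all(res$edges$relation %in%
                    c("activation", "inhibition", "expression", "repression")))
  net <- build_network(res$edges)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_edge_list(net, path)
  expect_identical(read_edge_list(path)$edges, net$edges)
})

test_that("parse_kgml rejects malformed and non-KGML XML", {
  expect_error(parse_kgml("<pathway><entry"), class = "error")
  expect_error(parse_kgml("<notkgml/>"), "expected <pathway>")
})

test_that("read_drug_targets builds profiles, dedupes, and rejects conflicts", {
  write_tab <- function(lines) {
    p <- tempfile(fileext = ".tsv")
    writeLines(c("drug_id\ttarget\taction", lines), p)
    p
  }
  p1 <- write_tab("D1\tT1\tactivation")
  profs <- read_drug_targets(p1)
  expect_length(profs, 1)
  expect_equal(unname(profile_signs(profs$D1)["T1"]), 1L)

  p2 <- write_tab(c("D1\tT1\tinhibition", "D1\tT1\tinhibition",
                    "D2\tT1\tdownregulation"))
  profs2 <- read_drug_targets(p2)
  expect_length(profs2$D1$actions, 1)
  expect_equal(unname(profile_signs(profs2$D2)["T1"]), -1L)

  p3 <- write_tab(c("D1\tT1\tactivation", "D1\tT1\tinhibition"))
  expect_error(read_drug_targets(p3), "conflicting actions")
  p4 <- write_tab("D1\tT1\tbinds")
  expect_error(read_drug_targets(p4), "unknown action")
  unlink(c(p1, p2, p3, p4))
})

test_that("read_combinations normalizes labels and flags degenerate rows", {
  write_tab <- function(lines) {
    p <- tempfile(fileext = ".tsv")
    writeLines(c("drug_a\tdrug_b\tlabel", lines), p)
    p
  }
  p1 <- write_tab("D1\tD2\tSynergism")
  expect_equal(read_combinations(p1)$label, "synergism")

  p2 <- write_tab(character(0))
  expect_equal(nrow(read_combinations(p2)), 0)

  p3 <- write_tab("D1\tD1\tsynergism")
  expect_warning(rec <- read_combinations(p3), "self-pair")
  expect_equal(nrow(rec), 1)

  p4 <- write_tab("D1\tD2\tadditivity")
  expect_error(read_combinations(p4), "unknown combination label")
  unlink(c(p1, p2, p3, p4))
})
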