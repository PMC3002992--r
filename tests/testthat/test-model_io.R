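test_that("rule lines parse into activator/inhibitor sets; comments ignored", {
  net <- parse_rules(c("# a comment", "", "STAT6, -TBET -> GATA3"))
  expect_equal(length(net$rules), 1L)
  expect_equal(net$rules$GATA3$activators, "STAT6")
  expect_equal(net$rules$GATA3$inhibitors, "TBET")
  expect_false(net$rules$GATA3$act_const)
  expect_setequal(net$inputs, c("STAT6", "TBET"))
  expect_equal(length(parse_rules("# only comments\n\n")$rules), 0L)
})

test_that("malformed rule sets are rejected with informative errors", {
  expect_error(parse_rules(c("A -> C", "B -> C")), "duplicate.*C")
  expect_error(parse_rules("A, -A -> B"), "both activator and inhibitor")
  expect_error(parse_rules("-A -> B"), "empty activator")
  expect_error(parse_rules("A, -B -> B"), "inhibit itself")
  expect_error(parse_rules("A - B"), "malformed")
  # self-activation is legal (persisting-modality self-loops round-trip)
  expect_silent(parse_rules("A, B -> A"))
})

test_that("gene names normalize through the alias table", {
  expect_equal(normalize_gene(c("IFN-g", "il-4r", "PLCPG", "T-bet")),
               c("IFNG", "IL4R", "PLCG", "TBET"))
  expect_equal(normalize_gene("IFN-γ"), "IFNG")  # unicode gamma
  net <- th1th2_network()
  published <- c(unlist(th_gene_sets()), unlist(thx_states()),
                 inhibitory_pairs()$gene1, inhibitory_pairs()$gene2,
                 ko_reference()$gene)
  expect_true(all(published %in% net$genes))
})

test_that("packaged model variants have the documented structure", {
  cons <- th1th2_network("consensus")
  expect_equal(length(cons$rules), 43L)
  expect_equal(length(cons$genes), 51L)
  expect_setequal(cons$inputs,
                  c("ANTIGEN", "CD80", "CD86", "IFNA", "IL7", "IL12",
                    "IL18", "TNFSF4"))
  lit <- th1th2_network("literal")
  expect_equal(length(lit$rules), 43L)
  expect_equal(length(lit$genes), 50L)
  expect_setequal(lit$inputs,
                  c("ANTIGEN", "CD80", "CD86", "IL7", "IL12", "IL18",
                    "TNFSF4"))
  for (net in list(cons, lit)) {
    for (r in net$rules) {
      expect_gt(length(r$activators), 0L)
      expect_length(intersect(r$activators, r$inhibitors), 0L)
    }
  }
})

test_that("GML export writes one node per gene and one signed edge per regulator", {
  lit <- th1th2_network("literal")
  gml <- export_network(lit, "gml")
  n_nodes <- lengths(regmatches(gml, gregexpr("node \\[", gml)))
  n_edges <- lengths(regmatches(gml, gregexpr("edge \\[", gml)))
  expect_equal(n_nodes, 50L)
  # one edge per regulator occurrence across the 43 rules
  expected_edges <- sum(vapply(lit$rules, function(r)
    length(r$activators) + length(r$inhibitors), integer(1)))
  expect_equal(expected_edges, 83L)
  expect_equal(n_edges, expected_edges)
  n_neg <- lengths(regmatches(gml, gregexpr('sign "-"', gml)))
  expect_equal(n_neg, sum(vapply(lit$rules, function(r)
    length(r$inhibitors), integer(1))))

  tiny <- parse_rules("A -> B")
  g2 <- export_network(tiny, "gml")
  expect_equal(lengths(regmatches(g2, gregexpr("node \\[", g2))), 2L)
  expect_equal(lengths(regmatches(g2, gregexpr('edge \\[.*sign "\\+"', g2))), 1L)

  expect_error(export_network(tiny, "dot"), "gml, cnet, boolnet")
})

rule_sets <- function(net) {
  lapply(net$rules, function(r)
    list(a = sort(r$activators), i = sort(r$inhibitors),
         k = isTRUE(r$act_const)))
}

test_that("boolnet and cnet exports round-trip to the identical rule set", {
  for (variant in c("consensus", "literal")) {
    net <- th1th2_network(variant)
    for (fmt in c("boolnet", "cnet")) {
      back <- if (fmt == "boolnet") parse_boolnet(export_network(net, fmt))
              else parse_cnet(export_network(net, fmt))
      expect_equal(rule_sets(back)[sort(names(net$rules))],
                   rule_sets(net)[sort(names(net$rules))])
      expect_setequal(back$inputs, net$inputs)
    }
  }
  # persisting-modality self-loops survive the boolnet round-trip
  per <- apply_stimulation_modality(th1th2_network(), "persisting")
  back <- parse_boolnet(export_network(per, "boolnet"))
  expect_equal(rule_sets(back)[sort(names(per$rules))],
               rule_sets(per)[sort(names(per$rules))])
})

test_that("clamp knockouts keep the roster and are idempotent", {
  wt <- th1th2_network()
  ko <- apply_knockout(wt, "GATA3", method = "clamp")
  expect_true("GATA3" %in% ko$genes)
  expect_equal(ko$clamps[["GATA3"]], 0L)
  expect_equal(apply_knockout(ko, "GATA3", method = "clamp"), ko)
  # GATA3 still sits in TBET's inhibitor list, now permanently inactive
  expect_true("GATA3" %in% ko$rules$TBET$inhibitors)
  expect_error(apply_knockout(wt, "FOO"), "unknown gene")
  expect_error(apply_knockout(wt, "GAT3"), "GATA3")
})

test_that("deletion knockouts rewire sole-activator targets into inputs", {
  wt <- th1th2_network()
  ko <- apply_knockout(wt, "STAT6", method = "delete")
  expect_false("STAT6" %in% ko$genes)
  # MAF lost its only regulator and became rule-less (an input)
  expect_null(ko$rules$MAF)
  expect_true("MAF" %in% ko$inputs)
  # GATA3 kept its inhibitor with a vacuously-true activation clause
  expect_true(ko$rules$GATA3$act_const)
  expect_equal(ko$rules$GATA3$inhibitors, "TBET")
  ko2 <- apply_knockout(wt, "LCK", method = "delete")
  expect_true("VAV1" %in% ko2$inputs)
  # ZAP70 keeps its other activators
  expect_setequal(ko2$rules$ZAP70$activators, c("TCR", "CD3"))
})

test_that("stimulation modalities implement impulse decay and frozen inputs", {
  wt <- th1th2_network()
  tmp <- apply_stimulation_modality(wt, "temporary")
  s <- network_state(tmp, "ANTIGEN")
  expect_equal(step_state(tmp, s)[["ANTIGEN"]], 0L)
  per <- apply_stimulation_modality(wt, "persisting")
  s2 <- network_state(per, "IL-12")
  for (i in 1:3) s2 <- step_state(per, s2)
  expect_equal(s2[["IL12"]], 1L)
  # a network without rule-less genes is unchanged
  swap <- toy_swap()
  swap2 <- apply_stimulation_modality(swap, "persisting")
  expect_equal(swap2$rules, swap$rules)
})
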