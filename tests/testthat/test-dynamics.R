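test_that("synchronous step follows the one-activator-no-inhibitor rule", {
  tmp <- apply_stimulation_modality(th1th2_network(), "temporary")
  off <- network_state(tmp)
  expect_equal(step_state(tmp, off), off)  # quiescent fixed point
  s1 <- network_state(tmp, "STAT6")
  expect_equal(step_state(tmp, s1)[["GATA3"]], 1L)
  s2 <- network_state(tmp, c("STAT6", "TBET"))
  expect_equal(step_state(tmp, s2)[["GATA3"]], 0L)  # inhibitor veto
  swap <- toy_swap()
  a <- network_state(swap, "A")
  b <- step_state(swap, a)
  expect_equal(b[["A"]], 0L)
  expect_equal(b[["B"]], 1L)
  expect_equal(step_state(swap, b), a)  # period-2 loop
})

test_that("step is a pure function of the source state", {
  net <- th1th2_network()
  s <- network_state(net, c("STAT6", "IL-4"))
  expect_identical(step_state(net, s), step_state(net, s))
  expect_error(step_state(net, s[-1]), "width")
})

test_that("trajectory finds the cycle with its transient prefix", {
  tmp <- apply_stimulation_modality(th1th2_network(), "temporary")
  tr <- trajectory(tmp, network_state(tmp))
  expect_equal(nrow(tr$transient), 0L)
  expect_equal(nrow(tr$cycle), 1L)
  expect_true(all(tr$cycle == 0L))
  swap <- toy_swap()
  tr2 <- trajectory(swap, network_state(swap, "A"))
  expect_equal(nrow(tr2$cycle), 2L)
  expect_error(trajectory(swap, network_state(swap, "A"), max_steps = 1L),
               class = "bn_budget_exceeded")
})

test_that("trajectory cycles agree with the brute-force transition graph", {
  for (seed in 1:5) {
    net <- generate_random_network(10, mean_in_degree = 2,
                                   inhibitor_fraction = 0.3, seed = seed)
    oracle <- brute_attractor_keys(net)
    w <- 2^(seq_along(net$genes) - 1L)
    set.seed(seed + 100)
    for (s0 in sample(0:1023, 15)) {
      active <- net$genes[bitwAnd(bitwShiftR(s0, seq_along(net$genes) - 1L),
                                  1L) == 1L]
      tr <- trajectory(net, network_state(net, active))
      key <- paste(sort(apply(tr$cycle, 1, function(r) sum(w[r == 1L]))),
                   collapse = "|")
      expect_true(key %in% oracle)
    }
  }
})

test_that("temporary-modality reduction fixes the input and TCR cascade OFF", {
  tmp <- apply_stimulation_modality(th1th2_network(), "temporary")
  red <- reduce_network(tmp)
  cascade <- normalize_gene(c(
    "ANTIGEN", "CD80", "CD86", "IFN-a", "IL-7", "IL-12", "IL-18", "TNFSF4",
    "CD4", "TCR", "CD3", "CD45", "LCK", "ZAP70", "SLP76", "VAV1", "ITK",
    "PLC-g", "CTLA4", "SHP1", "CD28", "ICOS", "PI3K", "AKT1", "COT", "NIK",
    "IKBKB", "NFKB", "TNFRSF4", "IL-7R", "IL-18R", "IRAK", "IL-12R",
    "IFN-aR1"))
  expect_true(all(cascade %in% names(red$fixed)))
  expect_true(all(red$fixed[cascade] == 0L))
  expect_lte(length(red$free), 20L)
  # the two reduction-based enumerators agree on the packaged model
  keys_exh <- att_keys(enumerate_exhaustive(tmp), tmp$genes)
  keys_sym <- att_keys(enumerate_symbolic(tmp), tmp$genes)
  expect_equal(keys_exh, keys_sym)
})

test_that("reduction is exact on random networks", {
  for (seed in 1:20) {
    net <- generate_random_network(sample(6:12, 1), mean_in_degree = 2,
                                   inhibitor_fraction = 0.3,
                                   n_inputs = sample(0:2, 1), seed = seed)
    a_red <- enumerate_exhaustive(net, reduce = TRUE)
    a_full <- enumerate_exhaustive(net, reduce = FALSE)
    expect_equal(att_keys(a_red, net$genes), att_keys(a_full, net$genes))
  }
})

test_that("reduction never fixes recurrent self-loop genes and obeys clamps", {
  self <- toy_self()
  expect_length(reduce_network(self)$fixed, 0L)
  net <- parse_rules("I -> A")
  on <- net; on$clamps <- c(I = 1L)
  off <- net; off$clamps <- c(I = 0L)
  expect_equal(reduce_network(on)$fixed[["A"]], 1L)
  expect_equal(reduce_network(off)$fixed[["A"]], 0L)
})

test_that("under temporary stimulation every attractor state has inputs OFF", {
  wt <- th1th2_network()
  tmp <- apply_stimulation_modality(wt, "temporary")
  atts <- enumerate_symbolic(tmp)
  for (a in atts$attractors)
    for (st in a$states)
      expect_length(intersect(st, wt$inputs), 0L)
})
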