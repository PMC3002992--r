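make_matrix <- function(n_genes, n_per_group, shift_genes = integer(),
                        shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_group
  m <- matrix(rnorm(n_genes * n, 0, sd), n_genes, n,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  m[shift_genes, seq_len(n_per_group)] <-
    m[shift_genes, seq_len(n_per_group)] + shift
  m
}
grp <- function(n_per_group) rep(c("patient", "control"), each = n_per_group)

test_that("the DE step matches the classical pooled-variance t-test", {
  m <- make_matrix(50, 6, seed = 3)
  de <- differential_genes(m, grp(6), alpha = 0.05)
  p <- attr(de, "p.values")
  for (g in rownames(m)[c(1, 17, 42)]) {
    ref <- stats::t.test(m[g, 1:6], m[g, 7:12], var.equal = TRUE)$p.value
    expect_equal(unname(p[g]), ref, tolerance = 1e-12)
  }
})

test_that("under the null the DE rate matches alpha within sampling error", {
  m <- make_matrix(1000, 10, seed = 11)
  de <- differential_genes(m, grp(10), alpha = 0.05)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(length(de) / 1000 - 0.05), 2 * se + 1e-9)
})

test_that("extreme effects are always flagged; degenerate inputs handled", {
  m <- make_matrix(20, 10, shift_genes = 1:3, shift = 10, seed = 5)
  de <- differential_genes(m, grp(10), alpha = 1e-4)
  expect_true(all(rownames(m)[1:3] %in% de))
  expect_error(differential_genes(m[, 1:11], c(rep("patient", 1),
                                               rep("control", 10))),
               "at least 2")
  flat <- m
  flat[4, ] <- 1  # zero variance in both groups
  expect_warning(de2 <- differential_genes(flat, grp(10)), "undefined")
  expect_equal(attr(de2, "excluded"), rownames(m)[4])
})

test_that("attractor-gene ratios and their correlation behave as documented", {
  sets <- th_gene_sets()
  # deterministic construction: 3 of 5 Th1 genes strongly shifted -> 0.6
  genes <- c(sets$th1, sets$th2, sprintf("bg%02d", 1:10))
  mk <- function(th1_k, th2_k, seed) {
    m <- make_matrix(length(genes), 8, seed = seed, sd = 0.2)
    rownames(m) <- genes
    hot <- c(sets$th1[seq_len(th1_k)], sets$th2[seq_len(th2_k)])
    m[hot, 1:8] <- m[hot, 1:8] + 5
    m
  }
  ds <- list(
    list(id = "d1", disease = "a", expr = mk(3, 5, 1), groups = grp(8)),
    list(id = "d2", disease = "b", expr = mk(1, 2, 2), groups = grp(8)),
    list(id = "d3", disease = "c", expr = mk(5, 9, 3), groups = grp(8)))
  st <- expression_study(ds)
  res <- attractor_ratio_correlation(st, alpha = 1e-6)
  expect_equal(res$ratios$th1_ratio[1], 3 / 5)
  expect_equal(res$ratios$th2_ratio[1], 5 / 11)
  # concordant construction -> positive correlation
  expect_gt(res$estimate, 0)
  # invariant to disease order and positive rescaling of one dataset
  ds2 <- ds[c(3, 1, 2)]
  ds2[[2]]$expr <- ds2[[2]]$expr * 3.7
  res2 <- attractor_ratio_correlation(expression_study(ds2), alpha = 1e-6)
  expect_equal(res2$estimate, res$estimate, tolerance = 1e-9)
  # constant ratios -> undefined correlation, reported as NA
  ds3 <- lapply(1:3, function(i)
    list(id = paste0("c", i), disease = paste0("z", i),
         expr = mk(2, 2, 10 + i), groups = grp(8)))
  expect_message(res3 <- attractor_ratio_correlation(expression_study(ds3),
                                                     alpha = 1e-6),
                 "undefined")
  expect_true(is.na(res3$estimate))
  expect_error(attractor_ratio_correlation(expression_study(ds[1:2])),
               "at least 3")
})

test_that("inhibitory-pair correlations recover exact and sampled coupling", {
  pairs <- inhibitory_pairs()
  expect_equal(pairs$gene1[1], "GATA3")  # headline pair listed first
  expect_equal(pairs$gene2[1], "TBET")
  # exact anti-correlation: y = -x pooled over two datasets
  set.seed(42)
  mk <- function(id, n) {
    x <- rnorm(n)
    m <- rbind(GATA3 = x, TBET = -x,
               matrix(rnorm(2 * n), 2, n,
                      dimnames = list(c("SHP1", "JAK1"), NULL)))
    colnames(m) <- sprintf("%s_s%02d", id, seq_len(n))
    list(id = id, disease = "ctrl", expr = m,
         groups = rep(c("patient", "control"), c(5, n - 5)))
  }
  st <- expression_study(list(mk("p1", 12), mk("p2", 13)))
  res <- inhibitory_pair_correlations(st, pairs = pairs[1:2, ])
  expect_equal(res$r[res$gene1 == "GATA3"], -1)
  expect_equal(res$n[1], 15L)  # pooled controls only
  # sampled coupling 0.8 at n = 100 recovered within ~2 SE
  set.seed(7)
  z <- rnorm(100); e <- rnorm(100)
  x <- z; y <- 0.8 * z + sqrt(1 - 0.64) * e
  big <- rbind(GATA3 = c(x, rep(0, 5)), TBET = c(y, rep(0, 5)))
  colnames(big) <- sprintf("s%03d", 1:105)
  st2 <- expression_study(list(list(id = "big", disease = "d", expr = big,
                                    groups = rep(c("patient", "control"),
                                                 c(5, 100)))))
  res2 <- inhibitory_pair_correlations(st2, pairs = pairs[1, , drop = FALSE])
  expect_lt(abs(res2$r - 0.8), 0.12)
  expect_true(all(abs(res2$r) <= 1))
})

test_that("datasets missing a pair gene are excluded for that pair", {
  set.seed(9)
  full <- matrix(rnorm(3 * 10), 3, 10,
                 dimnames = list(c("GATA3", "TBET", "SHP1"), NULL))
  colnames(full) <- sprintf("a%02d", 1:10)
  part <- matrix(rnorm(2 * 10), 2, 10,
                 dimnames = list(c("GATA3", "SHP1"), NULL))
  colnames(part) <- sprintf("b%02d", 1:10)
  st <- expression_study(list(
    list(id = "full", disease = "x", expr = full,
         groups = rep(c("patient", "control"), each = 5)),
    list(id = "part", disease = "y", expr = part,
         groups = rep(c("patient", "control"), each = 5))))
  pairs <- inhibitory_pairs()[1, , drop = FALSE]
  expect_message(res <- inhibitory_pair_correlations(st, pairs = pairs),
                 "excluded")
  expect_equal(res$n, 5L)
})
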