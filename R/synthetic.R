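#' Generate a synthetic multi-disease expression study
#'
#' Emulates the structure of a collection of CD4+ T-cell microarray
#' case-control datasets: several diseases, at least 5 samples per group,
#' Gaussian log-scale expression with per-dataset baseline offsets, and
#' Th1/Th2 gene modules whose activation across diseases is coupled through
#' a latent per-disease severity factor.
#'
#' The generating model: for disease `d`, a bivariate standard-normal
#' severity pair `(s1_d, s2_d)` with correlation `coupling` drives the two
#' modules. A module gene `g` is truly differentially expressed in disease
#' `d` iff `s_d + e_gd > 0` with `e_gd ~ N(0, de_latent_sd)`; DE genes gain
#' `effect_size` (in residual-SD units) in patients. With
#' `de_latent_sd = 0` the DE pattern is fully determined by the sign of the
#' severity factor, so with `coupling = 1` the Th1 and Th2 DE-ratio vectors
#' coincide. Background (non-module) genes are never differentially
#' expressed. The sign of `coupling` is therefore the true sign of the
#' attractor-ratio correlation recovered by
#' [attractor_ratio_correlation()].
#'
#' @param n_diseases number of disease datasets (default 10).
#' @param n_per_group samples per group per dataset (>= 5; default 10).
#' @param genes gene roster; defaults to the packaged network roster, whose
#'   Th1/Th2 attractor genes form the modules.
#' @param coupling latent correlation between Th1- and Th2-module severity,
#'   in \[-1, 1\].
#' @param effect_size mean patient shift of DE genes, in units of
#'   `noise_sd` (default 2).
#' @param noise_sd residual SD (default 1; 0 gives the noiseless limit).
#' @param de_latent_sd SD of the per-gene DE threshold noise (default 0.5).
#' @param seed RNG seed (integer) for full reproducibility.
#' @return an `expression_study`; attribute `truth` carries the generating
#'   ground truth (`de` indicator matrix genes x diseases, severities,
#'   `coupling`).
#' @examples
#' st <- generate_expression_study(n_diseases = 4, seed = 1)
#' st
#' @export
generate_expression_study <- function(n_diseases = 10L, n_per_group = 10L,
                                      genes = NULL, coupling = 0.8,
                                      effect_size = 2, noise_sd = 1,
                                      de_latent_sd = 0.5, seed = NULL) {
  if (!is.numeric(coupling) || length(coupling) != 1L ||
      is.na(coupling) || coupling < -1 || coupling > 1)
    stop("coupling must be a number in [-1, 1]", call. = FALSE)
  if (n_per_group < 5L)
    stop("n_per_group must be at least 5", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sets <- th_gene_sets()
  if (is.null(genes)) genes <- th1th2_network()$genes
  genes <- unique(c(normalize_gene(genes), sets$th1, sets$th2))
  s1 <- stats::rnorm(n_diseases)
  s2 <- coupling * s1 + sqrt(1 - coupling^2) * stats::rnorm(n_diseases)
  de <- matrix(FALSE, length(genes), n_diseases,
               dimnames = list(genes, NULL))
  for (d in seq_len(n_diseases)) {
    e1 <- stats::rnorm(length(sets$th1), 0, de_latent_sd)
    e2 <- stats::rnorm(length(sets$th2), 0, de_latent_sd)
    de[sets$th1, d] <- s1[d] + e1 > 0
    de[sets$th2, d] <- s2[d] + e2 > 0
  }
  baseline <- stats::setNames(stats::rnorm(length(genes), 7, 1), genes)
  datasets <- lapply(seq_len(n_diseases), function(d) {
    n <- 2L * n_per_group
    offs <- stats::rnorm(length(genes), 0, 0.5)  # per-dataset batch offset
    mu <- baseline + offs
    mat <- matrix(stats::rnorm(length(genes) * n, 0, noise_sd),
                  length(genes), n, dimnames = list(
                    genes, sprintf("D%02d_S%02d", d, seq_len(n))))
    mat <- mat + mu
    patient <- seq_len(n_per_group)
    shift <- effect_size * if (noise_sd > 0) noise_sd else 1
    mat[de[, d], patient] <- mat[de[, d], patient] + shift
    list(id = sprintf("SYN%02d", d), disease = sprintf("disease_%02d", d),
         expr = mat,
         groups = rep(c("patient", "control"), each = n_per_group))
  })
  st <- expression_study(datasets)
  attr(st, "truth") <- list(de = de, s1 = s1, s2 = s2, coupling = coupling)
  st
}

#' Generate a random Boolean network
#'
#' Fuel for oracle-equivalence testing: each regulated gene receives a
#' random regulator set (at least one activator guaranteed, activators and
#' inhibitors disjoint, no self-regulation except the unavoidable
#' one-gene self-activator), and an optional number of genes is left
#' rule-less to act as inputs.
#'
#' @param n_genes total gene count (>= 1).
#' @param mean_in_degree average regulators per regulated gene (Poisson
#'   around this mean, truncated to \[1, n_genes - 1\]); must be below
#'   `n_genes` for multi-gene networks.
#' @param inhibitor_fraction probability that a regulator beyond the first
#'   is inhibitory.
#' @param n_inputs number of rule-less input genes.
#' @param seed RNG seed.
#' @return a `boolean_network` with genes `G01`, `G02`, ...
#' @examples
#' net <- generate_random_network(8, seed = 42)
#' length(net$rules)
#' @export
generate_random_network <- function(n_genes, mean_in_degree = 2,
                                    inhibitor_fraction = 0.3,
                                    n_inputs = 0L, seed = NULL) {
  stopifnot(n_genes >= 1L, n_inputs >= 0L, n_inputs < n_genes)
  if (n_genes > 1L && mean_in_degree >= n_genes)
    stop("mean_in_degree must be below n_genes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  if (n_genes == 1L) {
    # only possible regulator is the gene itself: the self-activator
    rules <- list(G01 = list(activators = "G01", inhibitors = character(),
                             act_const = FALSE))
    return(new_boolean_network(rules))
  }
  regulated <- genes[seq_len(n_genes - n_inputs)]
  rules <- list()
  for (g in regulated) {
    pool <- setdiff(genes, g)
    k <- min(length(pool), max(1L, stats::rpois(1L, mean_in_degree)))
    regs <- sample(pool, k)
    inh <- regs[-1][stats::runif(k - 1L) < inhibitor_fraction]
    rules[[g]] <- list(activators = setdiff(regs, inh), inhibitors = inh,
                       act_const = FALSE)
  }
  new_boolean_network(rules, extra_genes = genes)
}
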