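#' Assemble an expression study
#'
#' An expression study is a collection of per-disease expression datasets
#' (microarray-style, log-scale values), each a genes x samples matrix with
#' a patient/control group label per sample.
#'
#' @param datasets list; each element a list with `id` (dataset identifier),
#'   `disease` (label), `expr` (numeric matrix, rownames = gene symbols,
#'   colnames = sample ids) and `groups` (character vector per sample,
#'   `"patient"` or `"control"`).
#' @param min_per_group datasets are expected to carry at least this many
#'   samples per group (default 5, the study inclusion rule); fewer than 2
#'   is an error, fewer than `min_per_group` a warning.
#' @return an `expression_study`.
#' @export
expression_study <- function(datasets, min_per_group = 5L) {
  for (d in datasets) {
    stopifnot(is.matrix(d$expr), !is.null(rownames(d$expr)),
              length(d$groups) == ncol(d$expr))
    if (!all(d$groups %in% c("patient", "control")))
      stop(sprintf("dataset '%s': groups must be 'patient'/'control'", d$id),
           call. = FALSE)
    n <- table(factor(d$groups, c("patient", "control")))
    if (any(n < 2L))
      stop(sprintf("dataset '%s': need at least 2 samples per group", d$id),
           call. = FALSE)
    if (any(n < min_per_group))
      warning(sprintf("dataset '%s': fewer than %d samples in a group",
                      d$id, min_per_group), call. = FALSE)
  }
  structure(list(datasets = datasets), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study: %d dataset(s)\n", length(x$datasets)))
  for (d in x$datasets)
    cat(sprintf("  %s (%s): %d genes, %d patients / %d controls\n",
                d$id, d$disease, nrow(d$expr),
                sum(d$groups == "patient"), sum(d$groups == "control")))
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' `expr_path`: first column gene symbol, remaining columns samples.
#' `samples_path`: columns `sample_id`, `dataset_id`, `disease`, `group`.
#'
#' @param expr_path path to the expression TSV.
#' @param samples_path path to the sample sheet TSV.
#' @return an `expression_study`.
#' @export
read_expression_study <- function(expr_path, samples_path) {
  ex <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(ex[, -1, drop = FALSE])
  rownames(mat) <- ex[[1]]
  sh <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "dataset_id", "disease", "group")
  if (!all(need %in% names(sh)))
    stop("sample sheet must have columns sample_id, dataset_id, disease, group",
         call. = FALSE)
  miss <- setdiff(sh$sample_id, colnames(mat))
  if (length(miss))
    stop(sprintf("samples missing from expression matrix: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  datasets <- lapply(split(sh, sh$dataset_id), function(d)
    list(id = d$dataset_id[1], disease = d$disease[1],
         expr = mat[, d$sample_id, drop = FALSE], groups = d$group))
  expression_study(unname(datasets))
}

#' Write an expression study as TSV files
#'
#' @param study an `expression_study`.
#' @param dir output directory (created if absent); writes
#'   `expression.tsv` and `samples.tsv` in the format read by
#'   [read_expression_study()].
#' @return `dir`, invisibly.
#' @export
write_expression_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- lapply(study$datasets, `[[`, "expr")
  genes <- Reduce(union, lapply(mats, rownames))
  big <- do.call(cbind, lapply(mats, function(m) {
    out <- matrix(NA_real_, length(genes), ncol(m),
                  dimnames = list(genes, colnames(m)))
    out[rownames(m), ] <- m
    out
  }))
  utils::write.table(data.frame(gene = genes, big, check.names = FALSE),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sh <- do.call(rbind, lapply(study$datasets, function(d)
    data.frame(sample_id = colnames(d$expr), dataset_id = d$id,
               disease = d$disease, group = d$groups,
               stringsAsFactors = FALSE)))
  utils::write.table(sh, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Differentially expressed genes by unpaired t-test
#'
#' Two-sided unpaired Student's t-test (pooled variance) per gene; genes
#' with p below `alpha` are returned. No multiple-testing correction is
#' applied. Genes with zero variance in both groups and equal means have an
#' undefined statistic and are excluded with a warning (they are reported in
#' the `excluded` attribute and count as not differentially expressed).
#'
#' @param mat numeric matrix, genes x samples.
#' @param groups character vector per sample, `"patient"`/`"control"`.
#' @param alpha significance level in (0,1), default 0.05.
#' @return character vector of DE gene names, with attributes `p.values`
#'   (named numeric over testable genes) and `excluded`.
#' @export
differential_genes <- function(mat, groups, alpha = 0.05) {
  stopifnot(is.matrix(mat), length(groups) == ncol(mat))
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("alpha must be in (0, 1)", call. = FALSE)
  g1 <- groups == "patient"; g2 <- groups == "control"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  v1 <- apply(mat[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, g2, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  bad <- is.nan(p) | is.na(p)
  if (any(bad))
    warning(sprintf("%d gene(s) with undefined t statistic excluded",
                    sum(bad)), call. = FALSE)
  de <- rownames(mat)[!bad & p < alpha]
  structure(de, p.values = p[!bad], excluded = rownames(mat)[bad])
}

#' Correlation of Th1 and Th2 attractor-gene DE ratios across diseases
#'
#' For each disease dataset, the fraction of the Th1 attractor genes that
#' are differentially expressed (patients vs controls) and likewise for the
#' Th2 attractor genes; then the Pearson correlation between the two ratio
#' vectors across diseases. A negative correlation would support
#' counter-regulation of the two programs; a positive one, concordant
#' activation. Ratios use only the genes actually measured in each dataset
#' (a message reports any unmeasured ones). If either ratio vector is
#' constant across diseases the correlation is undefined and returned as
#' `NA`.
#'
#' @param study an `expression_study` with at least 3 datasets.
#' @param sets list with `th1` and `th2` gene sets ([th_gene_sets()]).
#' @param alpha DE significance level.
#' @return list with `ratios` (data.frame: dataset, disease, th1_ratio,
#'   th2_ratio), `estimate` (Pearson r), `p.value`.
#' @export
attractor_ratio_correlation <- function(study, sets = th_gene_sets(),
                                        alpha = 0.05) {
  if (length(study$datasets) < 3L)
    stop("need at least 3 disease datasets for a correlation", call. = FALSE)
  th1 <- normalize_gene(sets$th1); th2 <- normalize_gene(sets$th2)
  rows <- lapply(study$datasets, function(d) {
    rn <- normalize_gene(rownames(d$expr))
    mat <- d$expr; rownames(mat) <- rn
    miss <- setdiff(c(th1, th2), rn)
    if (length(miss))
      message(sprintf("dataset '%s': unmeasured attractor gene(s): %s",
                      d$id, paste(miss, collapse = ", ")))
    de <- suppressWarnings(differential_genes(mat, d$groups, alpha))
    t1 <- intersect(th1, rn); t2 <- intersect(th2, rn)
    data.frame(dataset = d$id, disease = d$disease,
               th1_ratio = length(intersect(de, t1)) / length(t1),
               th2_ratio = length(intersect(de, t2)) / length(t2),
               stringsAsFactors = FALSE)
  })
  ratios <- do.call(rbind, rows)
  if (stats::sd(ratios$th1_ratio) == 0 || stats::sd(ratios$th2_ratio) == 0) {
    message("ratio vector constant across diseases; correlation undefined")
    return(list(ratios = ratios, estimate = NA_real_, p.value = NA_real_))
  }
  ct <- stats::cor.test(ratios$th1_ratio, ratios$th2_ratio,
                        method = "pearson")
  list(ratios = ratios, estimate = unname(ct$estimate), p.value = ct$p.value)
}

#' The packaged counter-regulatory gene pairs
#'
#' Seven gene pairs with literature-annotated mutual/one-way inhibition,
#' headed by the GATA3--TBET master-regulator pair.
#'
#' @return data.frame with `gene1`, `gene2` (normalized) and display labels.
#' @export
inhibitory_pairs <- function() {
  path <- system.file("extdata", "inhibitory_pairs.tsv", package = "thboolnet")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$gene1 <- normalize_gene(tab$label1)
  tab$gene2 <- normalize_gene(tab$label2)
  tab
}

#' Pearson correlations of inhibitory gene pairs over pooled controls
#'
#' Control samples are pooled across datasets; by default each gene is
#' z-scored within each dataset's controls first, so that platform/batch
#' offsets between datasets do not masquerade as correlation
#' (`standardize = FALSE` restores naive pooling). Pairs are tested with a
#' two-sided Pearson correlation test. Datasets in which either gene is
#' unmeasured are excluded for that pair (reported via a message).
#'
#' @param study an `expression_study`.
#' @param pairs data.frame with `gene1`, `gene2` ([inhibitory_pairs()]).
#' @param standardize z-score per gene within each dataset's controls before
#'   pooling.
#' @return data.frame with `gene1`, `gene2`, `n` (pooled control samples),
#'   `r`, `p.value`.
#' @export
inhibitory_pair_correlations <- function(study, pairs = inhibitory_pairs(),
                                         standardize = TRUE) {
  ctrl <- lapply(study$datasets, function(d) {
    m <- d$expr[, d$groups == "control", drop = FALSE]
    rownames(m) <- normalize_gene(rownames(m))
    if (standardize && ncol(m) > 1L) {
      mu <- rowMeans(m)
      sd <- apply(m, 1, stats::sd)
      sd[sd == 0] <- 1
      m <- (m - mu) / sd
    }
    m
  })
  n_ctrl <- sum(vapply(ctrl, ncol, integer(1)))
  if (n_ctrl < 4L)
    stop("need at least 4 pooled control samples", call. = FALSE)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    has <- vapply(ctrl, function(m) all(c(g1, g2) %in% rownames(m)),
                  logical(1))
    if (any(!has))
      message(sprintf("pair %s-%s: %d dataset(s) excluded (gene unmeasured)",
                      g1, g2, sum(!has)))
    x <- unlist(lapply(ctrl[has], function(m) m[g1, ]))
    y <- unlist(lapply(ctrl[has], function(m) m[g2, ]))
    if (length(x) < 4L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(gene1 = g1, gene2 = g2, n = length(x),
                        r = NA_real_, p.value = NA_real_))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(gene1 = g1, gene2 = g2, n = length(x),
               r = unname(ct$estimate), p.value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
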