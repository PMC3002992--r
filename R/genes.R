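#' Normalize a gene symbol
#'
#' Gene names are compared internally in a normalized form: upper case, with
#' hyphens, spaces and dots removed, Greek letters transliterated, and a small
#' alias table applied afterwards (so that, e.g., the phospholipase written
#' `PLCPG` in some sources resolves to the canonical `PLCG`). Display names
#' are preserved separately by [parse_rules()].
#'
#' @param x character vector of gene symbols.
#' @param aliases named character vector mapping normalized aliases to
#'   canonical normalized names; defaults to [gene_aliases()].
#' @return character vector of normalized symbols.
#' @examples
#' normalize_gene(c("IFN-g", "IL-4R", "plcpg"))
#' @export
normalize_gene <- function(x, aliases = gene_aliases()) {
  y <- toupper(x)
  y <- gsub("γ|Γ", "G", y)  # gamma
  y <- gsub("α|Α", "A", y)  # alpha
  y <- gsub("[-. ]", "", y)
  hit <- match(y, names(aliases))
  y[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  y
}

#' Alias table for gene-name normalization
#'
#' Read from the packaged `gene_aliases.tsv`. Aliases are already in
#' mechanically normalized form (upper case, separators stripped); the table
#' only carries renamings that normalization alone cannot produce.
#'
#' @return named character vector (alias -> canonical).
#' @export
gene_aliases <- function() {
  path <- system.file("extdata", "gene_aliases.tsv", package = "thboolnet")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$canonical, tab$alias)
}

# nearest roster name, for error messages
.suggest_gene <- function(gene, roster) {
  d <- utils::adist(gene, roster, ignore.case = TRUE)
  roster[which.min(d)]
}

.check_gene <- function(net, gene) {
  g <- normalize_gene(gene)
  if (length(g) != 1L || is.na(g) || !nzchar(g))
    stop("expected a single gene name", call. = FALSE)
  if (!g %in% net$genes)
    stop(sprintf("unknown gene '%s'; did you mean '%s'?", gene,
                 .display_name(net, .suggest_gene(g, net$genes))),
         call. = FALSE)
  g
}

.display_name <- function(net, g) {
  d <- net$display[g]
  ifelse(is.na(d), g, unname(d))
}
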