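#' Default knockout screen roster
#'
#' The 24 intracellular genes screened in the packaged Th1/Th2 model
#' (signaling kinases and transcription factors; inputs, receptors and
#' effector cytokines excluded).
#'
#' @return character vector of 24 normalized gene names.
#' @export
screen_genes <- function() {
  c("COT", "GATA3", "IKBKB", "IRAK", "IRF4", "ITK", "JAK1", "JAK3", "LCK",
    "MAF", "NFAT", "NFKB", "NIK", "PI3K", "PLCG", "SHP1", "SLP76", "SOCS1",
    "STAT1", "STAT4", "STAT6", "TBET", "VAV1", "ZAP70")
}

#' Run a systematic single-gene knockout screen
#'
#' For every (gene, modality) pair: knock the gene out
#' ([apply_knockout()]), apply the stimulation modality (so that any
#' knockout-created rule-less gene is treated exactly like a native input),
#' enumerate all attractors ([enumerate_symbolic()]), and record the total,
#' static/dynamical split, maximum cycle length and the IL-4/IFN-gamma
#' profile.
#'
#' @param net a `boolean_network` (typically [th1th2_network()]).
#' @param genes genes to knock out; defaults to [screen_genes()].
#' @param modalities subset of `c("temporary", "persisting")`.
#' @param knockout knockout semantics, `"delete"` (default) or `"clamp"`;
#'   see [apply_knockout()].
#' @param max_bits per-context enumeration budget.
#' @return a `knockout_screen`: data.frame with columns `gene`, `modality`,
#'   `attractors`, `static`, `dynamical`, `max_length`, plus attributes
#'   `profiles` (named list of cytokine profiles) and `knockout`.
#' @examples
#' \donttest{
#' rep <- run_screen(th1th2_network(), genes = "GATA3",
#'                   modalities = "temporary")
#' rep$attractors  # 3
#' }
#' @export
run_screen <- function(net, genes = screen_genes(),
                       modalities = c("temporary", "persisting"),
                       knockout = c("delete", "clamp"), max_bits = 24L) {
  knockout <- match.arg(knockout)
  modalities <- match.arg(modalities, c("temporary", "persisting"),
                          several.ok = TRUE)
  genes <- normalize_gene(genes)
  rows <- list()
  profiles <- list()
  for (g in genes) {
    ko <- tryCatch(apply_knockout(net, g, method = knockout),
                   error = function(e) stop(sprintf(
                     "knockout of '%s' failed: %s", g, conditionMessage(e)),
                     call. = FALSE))
    for (mod in modalities) {
      atts <- tryCatch(
        enumerate_symbolic(apply_stimulation_modality(ko, mod),
                           max_bits = max_bits),
        error = function(e) stop(sprintf(
          "enumeration failed for knockout '%s' under %s stimulation: %s",
          g, mod, conditionMessage(e)), call. = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, modality = mod,
        attractors = atts$counts$total, static = atts$counts$static,
        dynamical = atts$counts$dynamical, max_length = atts$max_length,
        stringsAsFactors = FALSE)
      profiles[[paste(g, mod, sep = ".")]] <- cytokine_profile(atts)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), modality = character(),
               attractors = integer(), static = integer(),
               dynamical = integer(), max_length = integer())
  structure(out, profiles = profiles, knockout = knockout,
            class = c("knockout_screen", "data.frame"))
}

#' Per-modality medians and ranges of a screen
#'
#' The median uses the usual even-count convention (mean of the two middle
#' values). An empty screen yields no rows.
#'
#' @param report a `knockout_screen` (or any data.frame with `modality` and
#'   `attractors` columns).
#' @return data.frame with `modality`, `median`, `min`, `max`, `n`.
#' @export
screen_summary <- function(report) {
  if (nrow(report) == 0L)
    return(data.frame(modality = character(), median = numeric(),
                      min = integer(), max = integer(), n = integer()))
  do.call(rbind, lapply(split(report, report$modality), function(d)
    data.frame(modality = d$modality[1],
               median = stats::median(d$attractors),
               min = min(d$attractors), max = max(d$attractors),
               n = nrow(d), row.names = NULL)))
}

#' @export
print.knockout_screen <- function(x, ...) {
  cat(sprintf("Knockout screen: %d rows (%s knockouts)\n",
              nrow(x), attr(x, "knockout")))
  print.data.frame(x, row.names = FALSE, ...)
  s <- screen_summary(x)
  if (nrow(s)) {
    cat("\n")
    print.data.frame(s, row.names = FALSE)
  }
  invisible(x)
}

#' Published reference counts for the knockout screen
#'
#' The packaged transcription of the published single-gene knockout
#' attractor counts for the Th1/Th2 model: 24 genes x 2 stimulation
#' modalities, with total, static, dynamical and maximum cycle length.
#' Gene labels in the file are resolved through the alias table.
#'
#' @return data.frame with `gene`, `modality`, `attractors`, `static`,
#'   `dynamical`, `max_length`.
#' @export
ko_reference <- function() {
  path <- system.file("extdata", "ko_reference.tsv", package = "thboolnet")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$gene <- normalize_gene(tab$gene)
  tab
}

#' Compare a screen against the packaged reference counts
#'
#' @param report a `knockout_screen`.
#' @param reference reference table, as from [ko_reference()].
#' @return data.frame of per-row deltas (`d_attractors`, `d_static`,
#'   `d_dynamical`, `d_max_length`) for every (gene, modality) present in
#'   both; attribute `all_match` is `TRUE` iff every delta is zero.
#' @export
compare_to_reference <- function(report, reference = ko_reference()) {
  m <- merge(as.data.frame(report), reference,
             by = c("gene", "modality"), suffixes = c("", ".ref"))
  out <- data.frame(
    gene = m$gene, modality = m$modality,
    d_attractors = m$attractors - m$attractors.ref,
    d_static = m$static - m$static.ref,
    d_dynamical = m$dynamical - m$dynamical.ref,
    d_max_length = m$max_length - m$max_length.ref,
    stringsAsFactors = FALSE)
  structure(out, all_match = nrow(out) > 0L &&
              all(out$d_attractors == 0L & out$d_static == 0L &
                    out$d_dynamical == 0L & out$d_max_length == 0L))
}
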