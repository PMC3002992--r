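#' Parse a signed regulatory rule file
#'
#' Each non-blank, non-comment (`#`) line declares the update rule of one
#' target gene in the form `act1, act2, -inh1 -> target`: a comma-separated
#' regulator list, inhibitors prefixed with a minus sign, then `->` and the
#' target. Under the network's update semantics a gene switches on exactly
#' when at least one of its activators is on and none of its inhibitors is.
#' Genes that appear only as regulators and never as targets carry no rule
#' and are recorded as input nodes.
#'
#' Validation: a second rule for the same target, a token listed both as
#' activator and inhibitor of one rule, an empty activator list, or a gene
#' inhibiting itself are hard errors. A gene *activating* itself is accepted
#' (such self-loops are what [apply_stimulation_modality()] injects for
#' persisting stimulation, and they round-trip through [export_network()]).
#'
#' @param text character: rule-file content (single string or vector of
#'   lines).
#' @return a `boolean_network`: list with elements `genes` (roster, fixed
#'   order: regulated genes in rule order, then inputs), `rules` (named list
#'   of `list(activators, inhibitors, act_const)`), `inputs`, `clamps`
#'   (named 0/1 integer vector) and `display` (normalized -> display name).
#' @seealso [read_rules()], [th1th2_network()], [export_network()]
#' @examples
#' net <- parse_rules("STAT6, -TBET -> GATA3")
#' net$rules$GATA3
#' @export
parse_rules <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rules <- list()
  display <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("malformed rule line (expected 'regulators -> target'): '%s'", ln),
           call. = FALSE)
    target_raw <- trimws(parts[2])
    target <- normalize_gene(target_raw)
    if (!nzchar(target)) stop(sprintf("empty target in line '%s'", ln), call. = FALSE)
    toks <- trimws(strsplit(parts[1], ",", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L)
      stop(sprintf("rule for '%s' has no regulators", target_raw), call. = FALSE)
    neg <- startsWith(toks, "-")
    raw <- ifelse(neg, substring(toks, 2), toks)
    norm <- normalize_gene(raw)
    if (any(!nzchar(norm)))
      stop(sprintf("empty regulator token in line '%s'", ln), call. = FALSE)
    act <- unique(norm[!neg])
    inh <- unique(norm[neg])
    if (length(act) == 0L)
      stop(sprintf("rule for '%s' has an empty activator list", target_raw),
           call. = FALSE)
    both <- intersect(act, inh)
    if (length(both))
      stop(sprintf("gene(s) %s are both activator and inhibitor of '%s'",
                   paste(both, collapse = ", "), target_raw), call. = FALSE)
    if (target %in% inh)
      stop(sprintf("'%s' cannot inhibit itself", target_raw), call. = FALSE)
    if (!is.null(rules[[target]]))
      stop(sprintf("duplicate rule for target '%s'", target_raw), call. = FALSE)
    rules[[target]] <- list(activators = act, inhibitors = inh, act_const = FALSE)
    for (k in seq_along(raw)) {
      if (is.na(display[norm[k]])) display[norm[k]] <- raw[k]
    }
    if (is.na(display[target]) || display[target] == target)
      display[target] <- target_raw
  }
  new_boolean_network(rules, display = display)
}

#' @rdname parse_rules
#' @param path path to a UTF-8 rule file.
#' @export
read_rules <- function(path) {
  parse_rules(readLines(path, encoding = "UTF-8", warn = FALSE))
}

# low-level constructor + validator
new_boolean_network <- function(rules, display = character(),
                                clamps = integer(), extra_genes = character()) {
  regulated <- names(rules)
  regulators <- unique(unlist(lapply(rules, function(r)
    c(r$activators, r$inhibitors)), use.names = FALSE))
  inputs <- setdiff(c(regulators, extra_genes), regulated)
  genes <- c(regulated, sort(inputs))
  net <- structure(list(genes = genes, rules = rules, inputs = sort(inputs),
                        clamps = clamps, display = display),
                   class = "boolean_network")
  validate_network(net)
  net
}

#' Validate a boolean_network's structural invariants
#'
#' Checks roster uniqueness, one rule per regulated gene, disjoint
#' activator/inhibitor sets, that inputs carry no rule, and that clamped
#' genes are on the roster. Called by the constructors; exported for tests
#' and for networks assembled manually.
#'
#' @param net a `boolean_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  if (anyDuplicated(net$genes))
    stop("duplicate gene in roster", call. = FALSE)
  if (any(!nzchar(net$genes))) stop("empty gene name in roster", call. = FALSE)
  for (g in names(net$rules)) {
    r <- net$rules[[g]]
    if (length(intersect(r$activators, r$inhibitors)))
      stop(sprintf("rule for '%s': activators and inhibitors overlap", g),
           call. = FALSE)
    if (length(r$activators) == 0L && !isTRUE(r$act_const) &&
        length(r$inhibitors) > 0L)
      stop(sprintf("rule for '%s': inhibitors without activation clause", g),
           call. = FALSE)
    if (g %in% r$inhibitors)
      stop(sprintf("'%s' inhibits itself", g), call. = FALSE)
    miss <- setdiff(c(r$activators, r$inhibitors), net$genes)
    if (length(miss))
      stop(sprintf("rule for '%s' references unknown gene(s) %s", g,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (length(net$clamps)) {
    if (!all(names(net$clamps) %in% net$genes))
      stop("clamped gene not in roster", call. = FALSE)
    if (!all(net$clamps %in% c(0L, 1L)))
      stop("clamp values must be 0 or 1", call. = FALSE)
  }
  invisible(net)
}

#' The packaged Th1/Th2 differentiation network
#'
#' Loads the 43-rule regulatory network of human Th1/Th2 cell
#' differentiation shipped with the package, in one of two transcription
#' variants:
#'
#' * `"consensus"` (default): the curated reading in which the glyph-damaged
#'   receptor symbol is the type-I interferon receptor chain (`IFN-aR1`,
#'   ligand `IFN-a`, an eighth input node). Under this reading the wild-type
#'   temporary-stimulation dynamics has exactly four attractors whose active
#'   gene sets are the published Th0/Th1/Th2/ThX phenotypes, gene for gene.
#'   51 genes, 8 inputs.
#' * `"literal"`: the rule table exactly as transcribed from the source
#'   table, with `IFN-gR1` driven by `IFN-g`. 50 genes, 7 inputs. This
#'   variant does *not* reproduce the published attractor landscape (it has
#'   six wild-type attractors); it is shipped so the discrepancy can be
#'   inspected rather than silently patched.
#'
#' The two variants differ only in the four rules that mention the damaged
#' receptor symbol; see the package vignette for the full argument behind
#' the consensus reading.
#'
#' @param variant `"consensus"` or `"literal"`.
#' @return a `boolean_network` with 43 rules.
#' @examples
#' net <- th1th2_network()
#' length(net$rules)  # 43
#' net$inputs
#' @export
th1th2_network <- function(variant = c("consensus", "literal")) {
  variant <- match.arg(variant)
  fname <- if (variant == "consensus") "th1th2_rules.txt" else
    "th1th2_rules_literal.txt"
  read_rules(system.file("extdata", fname, package = "thboolnet"))
}

#' Export a network to GML, BoolNet or CNET text
#'
#' * `gml`: one node per gene, one directed edge per (regulator, target)
#'   occurrence with a `sign` attribute (`"+"` activation, `"-"`
#'   inhibition).
#' * `boolnet`: a `targets, factors` table with the full per-node update
#'   expression (`(A | B) & !C` form), honoring clamps (clamped genes export
#'   as constants). Input nodes are listed in a header comment and carry no
#'   line; [parse_boolnet()] restores them.
#' * `cnet`: a truth-table format: per regulated node, its regulator indices
#'   and the full truth table of its update function.
#'
#' `parse_rules(export_network(net, "boolnet"))`-style round-trips recover
#' the rule set exactly (see [parse_boolnet()] and [parse_cnet()]).
#'
#' @param net a `boolean_network`.
#' @param format `"gml"`, `"cnet"` or `"boolnet"`.
#' @return a single character string.
#' @export
export_network <- function(net, format = c("gml", "cnet", "boolnet")) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("gml", "cnet", "boolnet")) {
    if (length(format) > 1L) format <- match.arg(format) else
      stop(sprintf("unknown format '%s'; supported formats: gml, cnet, boolnet",
                   paste(format, collapse = ",")), call. = FALSE)
  }
  switch(format,
         gml = .export_gml(net),
         boolnet = .export_boolnet(net),
         cnet = .export_cnet(net))
}

.export_gml <- function(net) {
  ids <- stats::setNames(seq_along(net$genes) - 1L, net$genes)
  nodes <- sprintf('  node [ id %d label "%s" ]', ids,
                   .display_name(net, net$genes))
  edges <- character()
  for (g in names(net$rules)) {
    r <- net$rules[[g]]
    for (a in r$activators)
      edges <- c(edges, sprintf('  edge [ source %d target %d sign "+" ]',
                                ids[[a]], ids[[g]]))
    for (i in r$inhibitors)
      edges <- c(edges, sprintf('  edge [ source %d target %d sign "-" ]',
                                ids[[i]], ids[[g]]))
  }
  paste(c("graph [", "  directed 1", nodes, edges, "]"), collapse = "\n")
}

.bool_expr <- function(net, g) {
  if (g %in% names(net$clamps)) return(as.character(net$clamps[[g]]))
  r <- net$rules[[g]]
  act <- if (isTRUE(r$act_const)) "1" else if (length(r$activators))
    paste(r$activators, collapse = " | ") else "0"
  if (length(r$inhibitors)) {
    inh <- paste(sprintf("!%s", r$inhibitors), collapse = " & ")
    sprintf("(%s) & %s", act, inh)
  } else act
}

.export_boolnet <- function(net) {
  hdr <- c("targets, factors")
  cmt <- if (length(net$inputs))
    sprintf("# inputs: %s", paste(net$inputs, collapse = ", ")) else character()
  body <- vapply(names(net$rules), function(g)
    sprintf("%s, %s", g, .bool_expr(net, g)), character(1))
  paste(c(cmt, hdr, body), collapse = "\n")
}

.export_cnet <- function(net) {
  ids <- stats::setNames(seq_along(net$genes), net$genes)
  out <- c(sprintf("# cnet-style truth tables, %d nodes", length(net$genes)),
           sprintf(".v %d", length(net$genes)))
  for (g in net$genes) {
    r <- net$rules[[g]]
    if (is.null(r)) {
      out <- c(out, sprintf("# %s (input)", g), sprintf(".n %d 0", ids[[g]]))
      next
    }
    regs <- c(r$activators, r$inhibitors)
    k <- length(regs)
    out <- c(out, sprintf("# %s <- %s", g, paste(regs, collapse = " ")),
             sprintf(".n %d %d %s", ids[[g]], k,
                     paste(ids[regs], collapse = " ")))
    if (k == 0L) {
      out <- c(out, as.character(as.integer(isTRUE(r$act_const))))
      next
    }
    for (row in 0:(2^k - 1)) {
      bits <- as.integer(intToBits(row))[seq_len(k)]
      a_on <- isTRUE(r$act_const) ||
        any(bits[seq_along(r$activators)] == 1L)
      i_on <- length(r$inhibitors) > 0L &&
        any(bits[length(r$activators) + seq_along(r$inhibitors)] == 1L)
      out <- c(out, sprintf("%s %d", paste(bits, collapse = ""),
                            as.integer(a_on && !i_on)))
    }
  }
  paste(out, collapse = "\n")
}

#' Re-parse exported BoolNet text
#'
#' Accepts the `targets, factors` output of [export_network()]: expressions
#' of the form `(A | B) & !C & !D`, plus `0`/`1` constants for clamped
#' genes. Genes mentioned only inside factors become input nodes.
#'
#' @param text character: BoolNet-format content.
#' @return a `boolean_network`.
#' @export
parse_boolnet <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^targets\\s*,\\s*factors$", lines, ignore.case = TRUE)]
  rules <- list(); clamps <- integer()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^,]+),(.*)$", ln))[[1]]
    if (length(m) != 3L) stop(sprintf("malformed boolnet line '%s'", ln),
                              call. = FALSE)
    target <- normalize_gene(trimws(m[2]))
    expr <- gsub("[() ]", "", m[3])
    if (expr %in% c("0", "1")) { clamps[target] <- as.integer(expr); next }
    toks <- strsplit(expr, "&", fixed = TRUE)[[1]]
    act <- character(); inh <- character()
    for (tk in toks) {
      if (startsWith(tk, "!")) inh <- c(inh, normalize_gene(substring(tk, 2)))
      else act <- c(act, normalize_gene(strsplit(tk, "|", fixed = TRUE)[[1]]))
    }
    act_const <- "1" %in% act
    act <- setdiff(act, "1")
    if (!is.null(rules[[target]]))
      stop(sprintf("duplicate rule for target '%s'", target), call. = FALSE)
    rules[[target]] <- list(activators = unique(act),
                            inhibitors = unique(inh),
                            act_const = act_const)
  }
  new_boolean_network(rules, clamps = clamps, extra_genes = names(clamps))
}

#' Re-parse exported CNET text
#'
#' Inverts the truth tables written by `export_network(net, "cnet")` back to
#' activator/inhibitor sets, assuming each table was generated by the
#' "at least one activator and no inhibitors" semantics: a regulator is an
#' activator iff switching it on alone turns the target on, and an
#' inhibitor iff it vetoes an active activator.
#'
#' @param text character: CNET-format content.
#' @return a `boolean_network`.
#' @export
parse_cnet <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  names_by_id <- character()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^# (\\S+) (?:<-|\\(input\\))", ln))[[1]]
    if (length(m) == 2L) names_by_id <- c(names_by_id, m[2])
  }
  lines <- trimws(lines)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  nv <- as.integer(sub("^\\.v\\s+", "", body[grepl("^\\.v", body)]))
  if (length(names_by_id) != nv)
    stop("cnet header/annotation mismatch", call. = FALSE)
  rules <- list()
  i <- 1L
  pos <- which(grepl("^\\.n", body))
  for (p in pos) {
    hdr <- as.integer(strsplit(sub("^\\.n\\s+", "", body[p]), "\\s+")[[1]])
    id <- hdr[1]; k <- hdr[2]
    target <- names_by_id[id]
    if (k == 0L && length(hdr) == 2L) {
      nxt <- if (p < length(body)) body[p + 1L] else ""
      if (grepl("^[01]$", nxt)) {
        rules[[target]] <- list(activators = character(),
                                inhibitors = character(),
                                act_const = nxt == "1")
      }
      next  # plain input node: no rule
    }
    regs <- names_by_id[hdr[-(1:2)]]
    tab <- body[(p + 1L):(p + 2L^k)]
    f <- function(bits) {  # evaluate stored truth table
      key <- paste(bits, collapse = "")
      row <- tab[startsWith(tab, paste0(key, " "))]
      as.integer(sub("^\\S+\\s+", "", row))
    }
    act <- character(); inh <- character()
    for (j in seq_len(k)) {
      e <- integer(k); e[j] <- 1L
      if (f(e) == 1L) act <- c(act, regs[j])
    }
    if (length(act)) {
      base <- integer(k); base[match(act[1], regs)] <- 1L
      for (j in seq_len(k)) {
        if (regs[j] %in% act) next
        e <- base; e[j] <- 1L
        if (f(e) == 0L) inh <- c(inh, regs[j])
      }
    } else if (f(integer(k)) == 1L) {
      # vacuous activation: on unless an inhibitor fires
      for (j in seq_len(k)) {
        e <- integer(k); e[j] <- 1L
        if (f(e) == 0L) inh <- c(inh, regs[j])
      }
      rules[[target]] <- list(activators = character(), inhibitors = inh,
                              act_const = TRUE)
      next
    } else stop(sprintf("cnet table for '%s' is not of activator/inhibitor form",
                        target), call. = FALSE)
    rules[[target]] <- list(activators = act, inhibitors = inh,
                            act_const = FALSE)
  }
  new_boolean_network(rules, extra_genes = names_by_id)
}

#' Knock a gene out of a network
#'
#' Two knockout semantics are provided:
#'
#' * `"delete"` (default, and the semantics used by [run_screen()]): the
#'   gene is removed from the roster, its rule is dropped, and it is erased
#'   from every regulator list. A target whose regulator list becomes empty
#'   is left rule-less and thereby becomes an input node (so it decays under
#'   temporary stimulation and is frozen under persisting stimulation,
#'   exactly like the network's native inputs). A target left with
#'   inhibitors only keeps a rule whose activation clause is vacuously
#'   satisfied (`next = !any(inhibitors)`).
#' * `"clamp"`: the gene is clamped to constant OFF; it keeps its roster
#'   position so state vectors keep their shape, and its own rule becomes
#'   inert.
#'
#' The two differ dynamically whenever the deleted gene was the sole
#' activator of some target; the vignette discusses why the deletion
#' reading is the one under which the packaged network reproduces its
#' published knockout landscape.
#'
#' @param net a `boolean_network`.
#' @param gene gene to knock out (any alias; resolved via [normalize_gene()]).
#' @param method `"delete"` or `"clamp"`.
#' @return a modified `boolean_network`.
#' @examples
#' wt <- th1th2_network()
#' ko <- apply_knockout(wt, "GATA3")
#' @export
apply_knockout <- function(net, gene, method = c("delete", "clamp")) {
  method <- match.arg(method)
  g <- .check_gene(net, gene)
  if (method == "clamp") {
    net$clamps[g] <- 0L
    return(validate_network(net))
  }
  rules <- net$rules[setdiff(names(net$rules), g)]
  for (t in names(rules)) {
    r <- rules[[t]]
    r$activators <- setdiff(r$activators, g)
    r$inhibitors <- setdiff(r$inhibitors, g)
    if (length(r$activators) == 0L && !isTRUE(r$act_const)) {
      if (length(r$inhibitors) == 0L) { rules[[t]] <- NULL; next }
      r$act_const <- TRUE  # activation clause vacuously satisfied
    }
    rules[[t]] <- r
  }
  keep <- setdiff(net$genes, g)
  clamps <- net$clamps[setdiff(names(net$clamps), g)]
  new_boolean_network(rules, display = net$display[names(net$display) != g],
                      clamps = clamps, extra_genes = keep)
}

#' Apply an input-stimulation modality
#'
#' Input nodes (rule-less genes) model extracellular stimuli. Under
#' *temporary* stimulation an input is active only as an initial impulse:
#' its update function becomes constant OFF (an empty activator list), so
#' any initial activity decays after one synchronous step. Under
#' *persisting* stimulation each input receives a pure self-activation
#' rule, turning it into a frozen bit that holds its initial value forever.
#' Clamped genes are left untouched. A network without rule-less genes is
#' returned unchanged.
#'
#' @param net a `boolean_network`.
#' @param modality `"temporary"` or `"persisting"`.
#' @return a `boolean_network` with an attribute `modality`.
#' @export
apply_stimulation_modality <- function(net, modality = c("temporary", "persisting")) {
  modality <- match.arg(modality)
  free_inputs <- setdiff(net$inputs, names(net$clamps))
  for (g in free_inputs) {
    net$rules[[g]] <- if (modality == "temporary")
      list(activators = character(), inhibitors = character(), act_const = FALSE)
    else
      list(activators = g, inhibitors = character(), act_const = FALSE)
  }
  net$inputs <- setdiff(net$inputs, free_inputs)
  attr(net, "modality") <- modality
  validate_network(net)
  net
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d genes (%d regulated, %d inputs)\n",
              length(x$genes), length(x$rules), length(x$inputs)))
  if (length(x$inputs))
    cat("  inputs:", paste(.display_name(x, x$inputs), collapse = ", "), "\n")
  if (length(x$clamps))
    cat("  clamps:", paste(sprintf("%s=%d", names(x$clamps), x$clamps),
                           collapse = ", "), "\n")
  if (!is.null(attr(x, "modality")))
    cat("  stimulation modality:", attr(x, "modality"), "\n")
  invisible(x)
}

#' @export
summary.boolean_network <- function(object, ...) {
  k <- vapply(object$rules, function(r)
    length(r$activators) + length(r$inhibitors), integer(1))
  cat(sprintf("Boolean network: %d genes, %d rules, %d inputs\n",
              length(object$genes), length(object$rules),
              length(object$inputs)))
  cat(sprintf("  in-degree: mean %.2f, max %d\n",
              if (length(k)) mean(k) else 0, if (length(k)) max(k) else 0L))
  n_inh <- sum(vapply(object$rules, function(r) length(r$inhibitors), integer(1)))
  cat(sprintf("  regulator occurrences: %d (%d inhibitory)\n", sum(k), n_inh))
  invisible(object)
}
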