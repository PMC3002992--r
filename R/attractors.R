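#' @useDynLib thboolnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal helpers -------------------------------------------------------

# successor table built in pure R, vectorized over all 2^m states; used by
# the exhaustive route so that the two enumerators share no compilation path
.succ_r <- function(free, rules) {
  m <- length(free)
  N <- bitwShiftL(1L, m)
  s <- 0:(N - 1L)
  pos <- stats::setNames(seq_len(m), free)
  ns <- integer(N)
  for (g in seq_len(m)) {
    r <- rules[[free[g]]]
    a_on <- rep(isTRUE(r$act_const), N)
    for (a in r$activators)
      a_on <- a_on | bitwAnd(s, bitwShiftL(1L, pos[[a]] - 1L)) > 0L
    i_on <- rep(FALSE, N)
    for (i in r$inhibitors)
      i_on <- i_on | bitwAnd(s, bitwShiftL(1L, pos[[i]] - 1L)) > 0L
    ns <- ns + bitwShiftL(1L, g - 1L) * as.integer(a_on & !i_on)
  }
  ns
}

# successor table via the compiled bitmask route (symbolic enumerator)
.succ_cpp <- function(free, rules) {
  m <- length(free)
  pos <- stats::setNames(seq_len(m) - 1L, free)
  act_mask <- inh_mask <- integer(m)
  act_const <- logical(m)
  for (g in seq_len(m)) {
    r <- rules[[free[g]]]
    am <- 0L
    for (a in r$activators) am <- bitwOr(am, bitwShiftL(1L, pos[[a]]))
    im <- 0L
    for (i in r$inhibitors) im <- bitwOr(im, bitwShiftL(1L, pos[[i]]))
    act_mask[g] <- am; inh_mask[g] <- im
    act_const[g] <- isTRUE(r$act_const)
  }
  bn_succ_table(m, act_mask, inh_mask, act_const)
}

# decode integer cycle states into attractor objects on the full roster
.lift_cycles <- function(cycles, free, fixed_on, net) {
  lapply(cycles, function(cyc) {
    states <- lapply(cyc, function(s) {
      on_free <- free[bitwAnd(bitwShiftR(s, seq_along(free) - 1L), 1L) == 1L]
      net$genes[net$genes %in% c(fixed_on, on_free)]
    })
    new_attractor(states, net)
  })
}

new_attractor <- function(states, net) {
  structure(list(states = states,
                 length = length(states),
                 kind = if (length(states) == 1L) "static" else "dynamical",
                 active_union = Reduce(union, states, character())),
            class = "bn_attractor")
}

.budget_error <- function(m, max_bits) {
  stop(errorCondition(
    sprintf(paste0("state space of %d free genes exceeds the %d-bit budget; ",
                   "use enumerate_symbolic()"), m, max_bits),
    class = c("bn_budget_exceeded", "error", "condition")))
}

new_attractor_set <- function(attractors, net) {
  len <- vapply(attractors, `[[`, integer(1), "length")
  structure(list(attractors = attractors,
                 counts = list(total = length(attractors),
                               static = sum(len == 1L),
                               dynamical = sum(len > 1L)),
                 max_length = if (length(len)) max(len) else 0L,
                 genes = net$genes),
            class = "bn_attractor_set")
}

# ---- enumerators ------------------------------------------------------------

#' Enumerate all attractors exhaustively
#'
#' Builds the full successor map over the free genes (after optional exact
#' reduction) and extracts every limit cycle by pointer-chasing with
#' colouring, visiting each state at most twice. Exact and complete; serves
#' as the oracle for [enumerate_symbolic()]. Refuses (with a
#' `bn_budget_exceeded` condition) when the free core exceeds `max_bits`
#' bits — as happens under persisting stimulation, where the frozen inputs
#' stay free; use [enumerate_symbolic()] there.
#'
#' @param net a `boolean_network` (knockouts/modality already applied).
#' @param max_bits largest admissible free-gene count (default 24).
#' @param reduce apply [reduce_network()] first (default). With
#'   `reduce = FALSE` the map is built over the entire roster, which is what
#'   the reduction-exactness tests compare against.
#' @return a `bn_attractor_set`.
#' @examples
#' net <- parse_rules(c("A -> B", "B -> A"))
#' enumerate_exhaustive(net)$counts$total  # 3
#' @export
enumerate_exhaustive <- function(net, max_bits = 24L, reduce = TRUE) {
  if (reduce) {
    red <- reduce_network(net)
    free <- red$free; rules <- red$rules
    fixed_on <- names(red$fixed)[red$fixed == 1L]
  } else {
    free <- net$genes
    rules <- lapply(stats::setNames(free, free), function(g) {
      if (g %in% names(net$clamps))
        list(activators = character(), inhibitors = character(),
             act_const = net$clamps[[g]] == 1L)
      else if (!is.null(net$rules[[g]])) net$rules[[g]]
      else list(activators = character(), inhibitors = character(),
                act_const = FALSE)
    })
    fixed_on <- character()
  }
  m <- length(free)
  if (m > max_bits) .budget_error(m, max_bits)
  cycles <- bn_cycles_chase(.succ_r(free, rules))
  new_attractor_set(.lift_cycles(cycles, free, fixed_on, net), net)
}

#' Enumerate all attractors scalably
#'
#' Exact and complete enumeration designed for networks whose frozen bits
#' (pure self-activation genes, e.g. persisting-stimulation inputs) push the
#' free core past the exhaustive budget. The network is reduced by constant
#' propagation; every assignment of the frozen bits defines a context, which
#' is re-reduced and enumerated from a compiled bitmask successor table by a
#' set-based image-fixpoint (the eventual image of the full state set is
#' exactly the union of the limit cycles). Attractor sets from all contexts
#' are disjoint and are concatenated. Agrees with [enumerate_exhaustive()]
#' wherever both run.
#'
#' @param net a `boolean_network`.
#' @param max_bits largest admissible per-context free-gene count.
#' @return a `bn_attractor_set`.
#' @examples
#' net <- apply_stimulation_modality(th1th2_network(), "persisting")
#' \donttest{enumerate_symbolic(net)$counts$total}
#' @export
enumerate_symbolic <- function(net, max_bits = 24L) {
  red <- reduce_network(net)
  frozen <- red$free[vapply(red$free, function(g) {
    r <- red$rules[[g]]
    identical(r$activators, g) && length(r$inhibitors) == 0L &&
      !isTRUE(r$act_const)
  }, logical(1))]
  k <- length(frozen)
  if (k > 16L)
    stop(sprintf("%d frozen bits is beyond the supported context budget", k),
         call. = FALSE)
  base_fixed <- stats::setNames(rep(NA_integer_, length(red$free)), red$free)
  attractors <- list()
  for (ctx in 0:(bitwShiftL(1L, k) - 1L)) {
    fixed <- base_fixed
    if (k > 0L)
      fixed[frozen] <- bitwAnd(bitwShiftR(ctx, seq_len(k) - 1L), 1L)
    rules <- red$rules[setdiff(names(red$rules), frozen)]
    fixed <- .propagate(rules, fixed)
    free <- red$free[is.na(fixed[red$free])]
    m <- length(free)
    if (m > max_bits) .budget_error(m, max_bits)
    res <- .residual_rules(rules, fixed)
    cycles <- bn_cycles_image(.succ_cpp(free, res))
    fixed_on <- c(names(red$fixed)[red$fixed == 1L],
                  names(fixed)[!is.na(fixed) & fixed == 1L])
    attractors <- c(attractors, .lift_cycles(cycles, free, fixed_on, net))
  }
  new_attractor_set(attractors, net)
}

#' Enumerate attractors (dispatcher)
#'
#' @param net a `boolean_network`.
#' @param method `"symbolic"` (default; handles frozen-bit contexts) or
#'   `"exhaustive"` (single full successor map, oracle).
#' @param max_bits free-gene budget per successor table.
#' @param ... passed to the chosen enumerator.
#' @return a `bn_attractor_set`.
#' @export
enumerate_attractors <- function(net, method = c("symbolic", "exhaustive"),
                                 max_bits = 24L, ...) {
  method <- match.arg(method)
  if (method == "symbolic") enumerate_symbolic(net, max_bits = max_bits, ...)
  else enumerate_exhaustive(net, max_bits = max_bits, ...)
}

# canonical string key of an attractor (for set comparisons in tests)
attractor_key <- function(att, genes) {
  enc <- vapply(att$states, function(st)
    paste(as.integer(genes %in% st), collapse = ""), character(1))
  rot <- which.min(enc)  # lexicographic == numeric for fixed width
  paste(enc[c(rot:length(enc), seq_len(rot - 1L))], collapse = "|")
}

# ---- phenotype classification ----------------------------------------------

#' Th1/Th2 phenotype gene sets
#'
#' The active-gene sets of the Th1 and Th2 fixed points of the packaged
#' network's wild-type temporary-stimulation dynamics (normalized names).
#'
#' @return list with `th1` (5 genes) and `th2` (11 genes).
#' @export
th_gene_sets <- function() {
  list(th1 = c("IFNG", "IFNGR", "SOCS1", "STAT1", "TBET"),
       th2 = c("GATA3", "IL13", "IL4", "IL4R", "IL5", "IRF4", "JAK1",
               "JAK3", "MAF", "NFAT", "STAT6"))
}

#' The three states of the mixed ThX cycle
#'
#' @return list of three character vectors (active genes per state).
#' @export
thx_states <- function() {
  list(c("IFNG", "IL13", "IL4", "IL5", "JAK3", "NFAT", "SOCS1"),
       c("IFNGR", "IL13", "IL4", "IL5", "STAT6"),
       c("GATA3", "IL4R", "IRF4", "MAF", "SOCS1", "STAT1", "TBET"))
}

#' Classify an attractor into a Th phenotype
#'
#' Exact active-set matching: `Th0` iff a fixed point with nothing active;
#' `Th1`/`Th2` iff a fixed point whose active set equals the respective
#' phenotype set; `ThX` iff a 3-cycle whose per-state active sets match the
#' mixed-cycle states as sets, under any rotation; `other` otherwise.
#'
#' @param att a `bn_attractor`.
#' @param sets phenotype sets, as from [th_gene_sets()].
#' @param thx the ThX states, as from [thx_states()].
#' @return one of `"Th0"`, `"Th1"`, `"Th2"`, `"ThX"`, `"other"`.
#' @export
classify_attractor <- function(att, sets = th_gene_sets(), thx = thx_states()) {
  setsame <- function(a, b) length(a) == length(b) && setequal(a, b)
  if (att$length == 1L) {
    a <- att$states[[1]]
    if (length(a) == 0L) return("Th0")
    if (setsame(a, sets$th1)) return("Th1")
    if (setsame(a, sets$th2)) return("Th2")
    return("other")
  }
  if (att$length == 3L) {
    ok <- vapply(att$states, function(st)
      any(vapply(thx, setsame, logical(1), a = st)), logical(1))
    used <- vapply(thx, function(ps)
      any(vapply(att$states, setsame, logical(1), a = ps)), logical(1))
    if (all(ok) && all(used)) return("ThX")
  }
  "other"
}

#' IL-4 / IFN-gamma expression profile of an attractor set
#'
#' Partitions attractors into four bins by whether IL-4 and/or IFN-gamma
#' belong to the attractor's active-gene union ("expressed somewhere along
#' the cycle").
#'
#' @param atts a `bn_attractor_set`.
#' @return data.frame with `bin`, `count`, `percent`.
#' @export
cytokine_profile <- function(atts) {
  il4 <- vapply(atts$attractors, function(a) "IL4" %in% a$active_union,
                logical(1))
  ifng <- vapply(atts$attractors, function(a) "IFNG" %in% a$active_union,
                 logical(1))
  n <- length(il4)
  cnt <- c("IL-4 only" = sum(il4 & !ifng),
           "IFN-g only" = sum(!il4 & ifng),
           "both" = sum(il4 & ifng),
           "neither" = sum(!il4 & !ifng))
  data.frame(bin = names(cnt), count = as.integer(cnt),
             percent = if (n) 100 * as.integer(cnt) / n else rep(NA_real_, 4),
             row.names = NULL)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.bn_attractor <- function(x, ...) {
  cat(sprintf("Attractor: length %d (%s)\n", x$length, x$kind))
  for (i in seq_along(x$states)) {
    st <- x$states[[i]]
    cat(sprintf("  state %d: %s\n", i,
                if (length(st)) paste(st, collapse = ", ") else "(all off)"))
  }
  invisible(x)
}

#' @export
print.bn_attractor_set <- function(x, ...) {
  cat(sprintf("Attractor set: %d attractors (%d static / %d dynamical), max length %d\n",
              x$counts$total, x$counts$static, x$counts$dynamical,
              x$max_length))
  invisible(x)
}

#' @export
summary.bn_attractor_set <- function(object, ...) {
  print(object)
  df <- as.data.frame(object)
  lab <- table(df$label)
  cat("  phenotypes:", paste(sprintf("%s=%d", names(lab), lab),
                             collapse = ", "), "\n")
  invisible(df)
}

#' @export
as.data.frame.bn_attractor_set <- function(x, ...) {
  data.frame(
    id = seq_along(x$attractors),
    length = vapply(x$attractors, `[[`, integer(1), "length"),
    kind = vapply(x$attractors, `[[`, character(1), "kind"),
    label = vapply(x$attractors, classify_attractor, character(1)),
    active = vapply(x$attractors, function(a)
      paste(a$active_union, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' @export
plot.bn_attractor_set <- function(x, ...) {
  pr <- cytokine_profile(x)
  graphics::barplot(pr$percent, names.arg = pr$bin,
                    ylab = "% of attractors",
                    main = "IL-4 / IFN-g expression across attractors", ...)
  invisible(pr)
}

#' Export an attractor set as JSON-like report or TSV summary
#'
#' @param atts a `bn_attractor_set`.
#' @param path output path.
#' @param format `"json"` (one record per attractor with per-state active
#'   gene lists) or `"tsv"` (one summary row per attractor).
#' @return `path`, invisibly.
#' @export
write_attractors <- function(atts, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(atts), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  esc <- function(v) paste0('"', v, '"')
  recs <- vapply(seq_along(atts$attractors), function(i) {
    a <- atts$attractors[[i]]
    states <- paste(vapply(a$states, function(st)
      paste0("[", paste(esc(st), collapse = ","), "]"), character(1)),
      collapse = ",")
    sprintf('{"id":%d,"length":%d,"kind":"%s","label":"%s","states":[%s]}',
            i, a$length, a$kind, classify_attractor(a), states)
  }, character(1))
  writeLines(paste0("[", paste(recs, collapse = ","), "]"), path)
  invisible(path)
}
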