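#' Construct a network state
#'
#' A state is a named 0/1 integer vector over the network roster, in roster
#' order (the roster order defines the bit positions of the encoded state,
#' gene 1 = least significant bit, and is stable across runs).
#'
#' @param net a `boolean_network`.
#' @param active character vector of genes that are ON (aliases allowed).
#' @return named integer vector of 0/1 over `net$genes`.
#' @examples
#' net <- th1th2_network()
#' s <- network_state(net, c("STAT6"))
#' @export
network_state <- function(net, active = character()) {
  a <- normalize_gene(active)
  bad <- setdiff(a, net$genes)
  if (length(bad))
    stop(sprintf("unknown gene(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  stats::setNames(as.integer(net$genes %in% a), net$genes)
}

# compile a network into index form for fast evaluation
.compile_net <- function(net) {
  genes <- net$genes
  idx <- stats::setNames(seq_along(genes), genes)
  clamp <- rep(NA_integer_, length(genes))
  clamp[idx[names(net$clamps)]] <- net$clamps
  act <- vector("list", length(genes))
  inh <- vector("list", length(genes))
  act_const <- logical(length(genes))
  has_rule <- logical(length(genes))
  for (g in names(net$rules)) {
    r <- net$rules[[g]]
    i <- idx[[g]]
    has_rule[i] <- TRUE
    act[[i]] <- unname(idx[r$activators])
    inh[[i]] <- unname(idx[r$inhibitors])
    act_const[i] <- isTRUE(r$act_const)
  }
  list(genes = genes, idx = idx, clamp = clamp, act = act, inh = inh,
       act_const = act_const, has_rule = has_rule)
}

.step_compiled <- function(cn, s) {
  ns <- integer(length(s))
  for (i in seq_along(s)) {
    if (!is.na(cn$clamp[i])) { ns[i] <- cn$clamp[i]; next }
    if (!cn$has_rule[i]) { ns[i] <- 0L; next }  # rule-less genes decay
    a_on <- cn$act_const[i] || any(s[cn$act[[i]]] == 1L)
    i_on <- length(cn$inh[[i]]) > 0L && any(s[cn$inh[[i]]] == 1L)
    ns[i] <- as.integer(a_on && !i_on)
  }
  ns
}

#' One synchronous update step
#'
#' Every gene recomputes its next value from the *same* source state: a
#' regulated gene switches on iff at least one of its activators is on and
#' none of its inhibitors is; genes with an empty activator list (e.g.
#' temporary-modality inputs) evaluate to OFF; clamped genes keep their
#' clamped value; rule-less genes decay to OFF.
#'
#' @param net a `boolean_network`.
#' @param state a state as returned by [network_state()].
#' @return the successor state (same shape).
#' @export
step_state <- function(net, state) {
  if (length(state) != length(net$genes) ||
      !identical(names(state), net$genes))
    stop("state width/names do not match the network roster", call. = FALSE)
  cn <- .compile_net(net)
  stats::setNames(.step_compiled(cn, as.integer(state)), net$genes)
}

#' Simulate a trajectory to its attractor
#'
#' Iterates the synchronous update from `s0`, memoizing visited states,
#' until a state repeats. The deterministic dynamics guarantees that the
#' first repeat closes the unique limit cycle reachable from `s0`.
#'
#' @param net a `boolean_network`.
#' @param s0 initial state ([network_state()]).
#' @param max_steps maximum number of steps before giving up; exceeding it
#'   raises a condition of class `bn_budget_exceeded`.
#' @return list with `transient` (matrix of states before the cycle, possibly
#'   0-row) and `cycle` (matrix of the cycle states, in visit order), both
#'   with one column per gene; class `bn_trajectory`.
#' @examples
#' net <- parse_rules(c("A -> B", "B -> A"))
#' tr <- trajectory(net, network_state(net, "A"))
#' nrow(tr$cycle)  # 2
#' @export
trajectory <- function(net, s0, max_steps = 10000L) {
  stopifnot(max_steps >= 1L)
  if (length(s0) != length(net$genes) || !identical(names(s0), net$genes))
    stop("state width/names do not match the network roster", call. = FALSE)
  cn <- .compile_net(net)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- list()
  s <- as.integer(s0)
  for (k in seq_len(max_steps + 1L)) {
    key <- paste(s, collapse = "")
    hit <- seen[[key]]
    if (!is.null(hit)) {
      states <- do.call(rbind, path)
      colnames(states) <- net$genes
      out <- list(transient = states[seq_len(hit - 1L), , drop = FALSE],
                  cycle = states[hit:length(path), , drop = FALSE])
      return(structure(out, class = "bn_trajectory"))
    }
    seen[[key]] <- k
    path[[k]] <- s
    s <- .step_compiled(cn, s)
  }
  stop(errorCondition(
    sprintf("no cycle closed within %d steps", max_steps),
    class = c("bn_budget_exceeded", "error", "condition")))
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d transient step(s), cycle of length %d\n",
              nrow(x$transient), nrow(x$cycle)))
  on <- colnames(x$cycle)[colSums(x$cycle) > 0]
  cat("  genes active in cycle:",
      if (length(on)) paste(on, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write a trajectory as TSV
#'
#' One row per step (transient then cycle), with a step index, a `phase`
#' column and one 0/1 column per gene.
#'
#' @param tr a `bn_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  m <- rbind(tr$transient, tr$cycle)
  df <- data.frame(step = seq_len(nrow(m)) - 1L,
                   phase = rep(c("transient", "cycle"),
                               c(nrow(tr$transient), nrow(tr$cycle))),
                   m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# constant propagation over index-form rules. `fixed` is a named integer
# vector; returns the completed fixed set.
.propagate <- function(rules, fixed) {
  repeat {
    changed <- FALSE
    for (g in names(rules)) {
      if (!is.na(fixed[g])) next
      r <- rules[[g]]
      fa <- fixed[r$activators]
      fi <- fixed[r$inhibitors]
      v <- NA_integer_
      all_off <- function(x) length(x) == 0L || (!anyNA(x) && all(x == 0L))
      if (length(fi) && any(fi == 1L, na.rm = TRUE)) v <- 0L
      else if (!isTRUE(r$act_const) && length(fa) == 0L) v <- 0L
      else if (!isTRUE(r$act_const) && !anyNA(fa) && all(fa == 0L)) v <- 0L
      else if ((isTRUE(r$act_const) || any(fa == 1L, na.rm = TRUE)) &&
               all_off(fi)) v <- 1L
      if (!is.na(v)) { fixed[g] <- v; changed <- TRUE }
    }
    if (!changed) break
  }
  fixed
}

# rewrite rules over the free genes given a completed fixed assignment
.residual_rules <- function(rules, fixed) {
  free <- names(fixed)[is.na(fixed)]
  out <- list()
  for (g in free) {
    r <- rules[[g]]
    on_act <- any(fixed[r$activators] == 1L, na.rm = TRUE)
    act <- r$activators[is.na(fixed[r$activators])]
    inh <- r$inhibitors[is.na(fixed[r$inhibitors])]
    out[[g]] <- list(activators = act, inhibitors = inh,
                     act_const = isTRUE(r$act_const) || on_act)
  }
  out
}

#' Reduce a network by exact constant propagation
#'
#' Iteratively fixes genes whose value is forced: rule-less genes are OFF,
#' clamps hold, a gene with all activators fixed OFF (and no vacuous
#' activation clause) is OFF, a gene with a fixed-ON inhibitor is OFF, and a
#' gene with an active activation clause and all inhibitors fixed OFF is ON.
#' The rewriting is exact: restricted to the free genes, the reduced
#' network has the same attractors as the original, with fixed genes at
#' their proven constants. Pure self-activation rules (persisting-modality
#' inputs) are never fixed — both of their values are recurrent.
#'
#' @param net a `boolean_network` (clamps and stimulation modality already
#'   applied).
#' @return a `reduced_network`: list with `fixed` (named 0/1 vector), `free`
#'   (character, roster order), `rules` (residual rules over free genes) and
#'   `net` (the original network).
#' @examples
#' net <- apply_stimulation_modality(th1th2_network(), "temporary")
#' red <- reduce_network(net)
#' length(red$free)
#' @export
reduce_network <- function(net) {
  fixed <- stats::setNames(rep(NA_integer_, length(net$genes)), net$genes)
  fixed[names(net$clamps)] <- net$clamps
  ruleless <- setdiff(net$genes, c(names(net$rules), names(net$clamps)))
  fixed[ruleless] <- 0L
  # clamped genes keep their clamp even if regulated
  rules <- net$rules[setdiff(names(net$rules), names(net$clamps))]
  fixed <- .propagate(rules, fixed)
  free <- net$genes[is.na(fixed[net$genes])]
  structure(list(fixed = fixed[!is.na(fixed)], free = free,
                 rules = .residual_rules(rules, fixed), net = net),
            class = "reduced_network")
}

#' @export
print.reduced_network <- function(x, ...) {
  cat(sprintf("Reduced network: %d genes fixed, %d free\n",
              length(x$fixed), length(x$free)))
  if (length(x$fixed)) {
    on <- names(x$fixed)[x$fixed == 1L]
    cat(sprintf("  fixed ON: %s\n",
                if (length(on)) paste(on, collapse = ", ") else "(none)"))
  }
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}
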