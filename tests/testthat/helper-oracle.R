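# Independent brute-force attractor oracle. Re-implements the update
# semantics from scratch (no package internals beyond the network list
# structure) and walks the full transition graph state by state.

brute_succ <- function(net) {
  genes <- net$genes
  n <- length(genes)
  stopifnot(n <= 16L)
  N <- 2L^n
  succ <- integer(N)
  for (s in 0:(N - 1L)) {
    x <- stats::setNames(as.integer(bitwAnd(bitwShiftR(s, 0:(n - 1L)), 1L)),
                         genes)
    nx <- integer(n)
    for (i in seq_len(n)) {
      g <- genes[i]
      if (g %in% names(net$clamps)) { nx[i] <- net$clamps[[g]]; next }
      r <- net$rules[[g]]
      if (is.null(r)) { nx[i] <- 0L; next }
      a_on <- isTRUE(r$act_const) || any(x[r$activators] == 1L)
      i_on <- length(r$inhibitors) > 0L && any(x[r$inhibitors] == 1L)
      nx[i] <- as.integer(a_on && !i_on)
    }
    succ[s + 1L] <- sum(nx * 2L^(0:(n - 1L)))
  }
  succ
}

# all cycles of a successor map, as a sorted character vector of canonical
# keys; each key is the sorted set of member state encodings
brute_attractor_keys <- function(net) {
  succ <- brute_succ(net)
  N <- length(succ)
  color <- integer(N)
  keys <- character()
  comp <- 0L
  for (s0 in seq_len(N)) {
    if (color[s0] > 0L) next
    comp <- comp + 1L
    path <- integer()
    s <- s0
    while (color[s] == 0L) {
      color[s] <- comp
      path <- c(path, s)
      s <- succ[s] + 1L
    }
    if (color[s] == comp) {
      j <- match(s, path)
      keys <- c(keys, paste(sort(path[j:length(path)] - 1L), collapse = "|"))
    }
  }
  sort(keys)
}

# canonical keys of a bn_attractor_set over a fixed roster: each attractor
# becomes the sorted set of its state bit-strings (rotation-independent)
att_keys <- function(atts, genes) {
  sort(vapply(atts$attractors, function(a) {
    enc <- vapply(a$states, function(st)
      paste(as.integer(genes %in% st), collapse = ""), character(1))
    paste(sort(enc), collapse = "|")
  }, character(1)))
}

# integer-encoded keys compatible with brute_attractor_keys (gene 1 = LSB)
att_keys_int <- function(atts, genes) {
  w <- 2^(seq_along(genes) - 1L)
  sort(vapply(atts$attractors, function(a) {
    enc <- vapply(a$states, function(st)
      sum(w[genes %in% st]), numeric(1))
    paste(sort(enc), collapse = "|")
  }, character(1)))
}

# small named toy networks
toy_swap <- function() parse_rules(c("A -> B", "B -> A"))
toy_self <- function() parse_rules("A -> A")
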