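# Independent brute-force oracle for microhomology enumeration: tests every
# (left, right, arm-length) triple directly, with no k-mer grouping, and a
# separately coded junction-collapse step.  Deliberately kept structurally
# different from the package kernel.

oracle_enumerate <- function(context, dsb, min_arm = 2L, max_arm = 25L) {
  n <- nchar(context)
  found <- list()
  for (L in seq.int(min_arm, max_arm)) {
    if (2L * L > n) break
    g <- expand.grid(i = 0:(n - L), j = 0:(n - L))
    g <- g[g$i < dsb & g$j + L > dsb & g$j - g$i >= L, , drop = FALSE]
    if (!nrow(g)) next
    eq <- substring(context, g$i + 1L, g$i + L) ==
      substring(context, g$j + 1L, g$j + L)
    g <- g[eq, , drop = FALSE]
    if (!nrow(g)) next
    g$L <- L
    found[[length(found) + 1L]] <- g
  }
  if (!length(found)) {
    return(data.frame(i = integer(), j = integer(), L = integer()))
  }
  out <- do.call(rbind, found)
  out[order(out$i, out$j, out$L), , drop = FALSE]
}

oracle_dedupe <- function(pats, context) {
  if (!nrow(pats)) return(pats)
  prods <- paste0(substr(rep(context, nrow(pats)), 1, pats$i),
                  substring(context, pats$j + 1))
  kept <- do.call(rbind, lapply(split(pats, prods), function(grp) {
    grp <- grp[grp$L == max(grp$L), , drop = FALSE]
    grp[which.min(grp$i), , drop = FALSE]
  }))
  kept[order(kept$i, kept$j, kept$L), , drop = FALSE]
}

# Canonical (i, j, L) triple view of a package pattern table, for comparison.
triples <- function(pats) {
  canon_triples(data.frame(i = pats$left_start, j = pats$right_start,
                           L = pats$arm_length))
}

canon_triples <- function(df) {
  df <- as.data.frame(lapply(df[, c("i", "j", "L")], as.integer))
  df <- df[order(df$i, df$j, df$L), , drop = FALSE]
  rownames(df) <- NULL
  df
}

triples_from_oracle <- function(context, dsb, min_arm = 2L, max_arm = 25L) {
  canon_triples(oracle_enumerate(context, dsb, min_arm, max_arm))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
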