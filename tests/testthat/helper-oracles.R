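# Independent oracles and small fixture builders used across test files.

# Exhaustive antiparallel alignment score by plain recursion over all
# alignments: every invader base is paired or bulged; substrate is consumed
# from its 3' end; leftover substrate at the 5' (hairpin-base) end is free.
brute_force_score <- function(invader, substrate, params = align_params()) {
  inv <- strsplit(invader, "")[[1]]
  srev <- rev(strsplit(substrate, "")[[1]])
  m <- length(inv); n <- length(srev)
  pair_score <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("AU", "UA", "GC", "CG")) return(params$match_wc)
    if (p %in% c("GU", "UG")) return(params$match_wobble)
    params$mismatch
  }
  rec <- function(i, j) {
    if (i > m) return(0)           # remaining substrate tail is free
    best <- rec(i + 1L, j) + params$gap   # bulge the invader base
    if (j <= n) {
      best <- max(best, rec(i + 1L, j + 1L) + pair_score(inv[i], srev[j]))
      best <- max(best, rec(i, j + 1L) + params$gap)  # bulge the substrate base
    }
    best
  }
  rec(1L, 1L)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Welch statistics straight from the textbook formulas
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# toy hairpin construct: 4-bp stem, 4-nt loop, poly-U downstream
#   substrate GCGC [3,6], loop GAAA [7,10], invader GCGC [11,14], polyU [15,20]
toy_hairpin <- function(id = "toy") {
  load_construct(
    "AAGCGCGAAAGCGCUUUUUUAA",
    list(P3 = c(3, 6), loop = c(7, 10), invader = c(11, 14), polyU = c(15, 20)),
    id = id
  )
}
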