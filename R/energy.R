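# Reduced nearest-neighbor parameter set (kcal/mol at 37 C).
# Watson-Crick stack values follow the standard RNA nearest-neighbor table;
# wobble-containing stacks and loop penalties are a coarse reduction: the
# model is used to rank hairpin variants, not to reproduce folding ensembles.

# key = 5'->3' dinucleotide on the invader (loop-proximal first); the
# substrate strand is the antiparallel WC complement.
NN_WC_STACK <- c(
  AA = -0.93, AC = -2.24, AG = -2.08, AU = -1.10,
  CA = -2.11, CC = -3.26, CG = -2.36, CU = -2.08,
  GA = -2.35, GC = -3.42, GG = -3.26, GU = -2.24,
  UA = -1.33, UC = -2.35, UG = -2.11, UU = -0.93
)

# stacks involving G:U wobbles, keyed by how many of the two pairs are
# wobbles and the strength of the flanking WC pair
WOBBLE_STACK <- c(one_gc = -1.5, one_au = -1.0, two = -0.5)

# hairpin loop initiation by loop length (3..9); longer loops extrapolated
HAIRPIN_INIT <- c(`3` = 5.4, `4` = 5.6, `5` = 5.7, `6` = 5.4,
                  `7` = 6.0, `8` = 5.5, `9` = 6.4)

BULGE_PENALTY <- c(`1` = 3.8, `2` = 2.8, `3` = 3.2)
LOOP_EXTRAP_COEF <- 1.07  # ~1.75 * R * T at 37 C

hairpin_init_dg <- function(len) {
  if (len < 3L) return(HAIRPIN_INIT[["3"]])
  if (len <= 9L) return(HAIRPIN_INIT[[as.character(len)]])
  HAIRPIN_INIT[["9"]] + LOOP_EXTRAP_COEF * log(len / 9)
}

bulge_dg <- function(len) {
  if (len <= 3L) return(BULGE_PENALTY[[as.character(len)]])
  BULGE_PENALTY[["3"]] + LOOP_EXTRAP_COEF * log(len / 3)
}

internal_loop_dg <- function(unpaired) {
  # generic internal-loop initiation; a 1x1 mismatch counts 2 unpaired nt
  1.7 + LOOP_EXTRAP_COEF * max(0, log(unpaired / 2))
}

stack_dg <- function(inv1, sub1, inv2, sub2) {
  k1 <- pair_kind(inv1, sub1)
  k2 <- pair_kind(inv2, sub2)
  if (k1 == "WC" && k2 == "WC") {
    return(NN_WC_STACK[[paste0(inv1, inv2)]])
  }
  wob <- sum(c(k1, k2) == "WOBBLE")
  if (wob == 2L) return(WOBBLE_STACK[["two"]])
  wc_pair <- if (k1 == "WC") paste0(inv1, sub1) else paste0(inv2, sub2)
  if (wc_pair %in% c("GC", "CG")) WOBBLE_STACK[["one_gc"]] else WOBBLE_STACK[["one_au"]]
}

#' Hairpin free energy from a duplex alignment
#'
#' Sums nearest-neighbor stack terms over consecutive paired columns
#' (Watson-Crick or wobble), a hairpin-loop initiation term for the apical
#' loop, and bulge/internal-loop penalties for noncomplementary elements,
#' using the reduced parameter table shipped with the package. Mismatched or
#' bulged columns interrupt stacking. The value ranks stem variants; it is
#' not an ensemble free energy.
#'
#' @param alignment a `duplex_alignment` (columns ordered from the
#'   nucleation site, i.e. loop-proximal end, toward the hairpin base).
#' @param loop_seq apical loop sequence (determines the initiation term).
#' @return a list of class `hairpin_energy` with element `delta_g`
#'   (kcal/mol at 37 C) and a `terms` breakdown.
#' @export
hairpin_delta_g <- function(alignment, loop_seq) {
  cols <- alignment$columns
  if (nrow(cols) == 0L) stop("empty alignment", call. = FALSE)
  loop_seq <- as_rna(loop_seq, "loop")
  terms <- c(hairpin_init = hairpin_init_dg(nchar(loop_seq)))

  paired <- cols$kind %in% c("WC", "WOBBLE")
  # stacks between consecutive paired columns with no interruption
  stack_total <- 0
  for (i in seq_len(nrow(cols) - 1L)) {
    if (paired[i] && paired[i + 1L]) {
      stack_total <- stack_total + stack_dg(
        cols$invader_base[i], cols$substrate_base[i],
        cols$invader_base[i + 1L], cols$substrate_base[i + 1L]
      )
    }
  }
  terms <- c(terms, stacks = stack_total)

  # penalties for maximal runs of non-WC-or-wobble columns
  kind_run <- rle(cols$kind)
  pen <- 0
  for (i in seq_along(kind_run$lengths)) {
    k <- kind_run$values[i]
    len <- kind_run$lengths[i]
    if (k %in% c("BULGE_INVADER", "BULGE_SUBSTRATE")) {
      pen <- pen + bulge_dg(len)
    } else if (k == "MISMATCH") {
      pen <- pen + internal_loop_dg(2L * len)
    }
  }
  terms <- c(terms, loops = pen)

  structure(
    list(delta_g = unname(sum(terms)), terms = terms),
    class = "hairpin_energy"
  )
}

#' @export
print.hairpin_energy <- function(x, ...) {
  cat(sprintf("<hairpin_energy> dG = %.2f kcal/mol\n", x$delta_g))
  invisible(x)
}
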