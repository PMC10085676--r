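#' Synthetic wild-type ZTP riboswitch reference construct
#'
#' A 140-nt synthetic reference construct that reproduces the published
#' structural anatomy of the Clostridium beijerinckii pfl ZTP riboswitch
#' terminator: the terminator nucleating base pair C100:G108, an invader
#' spanning residues 108-126 that carries three wobble pairs (G97:U111,
#' U96:G112 and G90:U120) and two single-nucleotide bulges (U115 and C118),
#' a 7-nt apical loop, and a poly-U tract of 8 Us starting at residue 127.
#'
#' This is NOT the organism's genomic sequence: residues outside the
#' terminator duplex window (aptamer P1/J12/P2, pseudoknot, linker) are
#' arbitrary filler chosen to satisfy the construct invariants, and the third
#' wobble position is a synthetic choice. It exists so that every
#' structure-dependent operation in the package has a fully annotated,
#' self-contained reference whose duplex annotation matches the published
#' architecture (five noncomplementary elements: three wobbles, two bulges).
#'
#' @return `ztp_wt_synthetic()`: a `construct`; `ztp_wt_regions()`: the
#'   region config used to annotate it.
#' @examples
#' wt <- ztp_wt_synthetic()
#' substr(wt$sequence, 100, 100)  # "C", substrate side of the nucleating pair
#' substr(wt$sequence, 108, 108)  # "G", invader side
#' @export
ztp_wt_synthetic <- function() {
  seq <- paste0(
    "GGAGCGACUAGCAGGCAAGGC",          #   1- 21  P1/J12/P2 (filler)
    "GCGAACGGC",                       #  22- 30  pseudoknot span (A26)
    "AACCGAUAGGCUAAGCUGAGCCAGUCAGCG",  #  31- 60  linker (filler)
    "GGCACGCAAAGCA",                   #  61- 73  filler
    "GUCCAGAGCG",                      #  74- 83  P3 5' arm (filler)
    "GAUCGCGACGUCUGGAC",               #  84-100  substrate: P3 3' arm + PK span
    "GAAAGCA",                         # 101-107  apical loop
    "GUCUGGAUCGCUUGCGAUC",             # 108-126  invader
    "UUUUUUUU",                        # 127-134  poly-U tract
    "AGCAUC"                           # 135-140  downstream filler
  )
  load_construct(seq, ztp_wt_regions(), id = "ZTP_WT_synthetic")
}

#' @rdname ztp_wt_synthetic
#' @export
ztp_wt_regions <- function() {
  list(
    P1      = c(1L, 8L),
    J12     = c(9L, 14L),
    P2      = c(15L, 21L),
    PK      = c(22L, 30L),
    linker  = c(31L, 60L),
    P3      = c(84L, 100L),
    loop    = c(101L, 107L),
    invader = c(108L, 126L),
    polyU   = c(127L, 134L)
  )
}
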