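WC_PAIRS <- c("AU", "UA", "GC", "CG")
WOBBLE_PAIRS <- c("GU", "UG")

pair_kind <- function(a, b) {
  p <- paste0(a, b)
  ifelse(p %in% WC_PAIRS, "WC", ifelse(p %in% WOBBLE_PAIRS, "WOBBLE", "MISMATCH"))
}

#' Alignment parameters for invader/substrate duplex annotation
#'
#' Package-default scoring: Watson-Crick pair +3, wobble +1, mismatch -2,
#' gap -4 per bulged nucleotide. These are annotation parameters, not
#' thermodynamic values; any setting that reproduces the reference
#' architecture is acceptable. `window_slack` widens the substrate window
#' beyond the invader length so bulged invaders can still reach the hairpin
#' base; `min_stem`, `loop_range` and `max_polyU_gap` are the architecture
#' classification thresholds.
#'
#' @param match_wc,match_wobble,mismatch,gap column scores.
#' @param window_slack extra substrate nucleotides in the alignment window.
#' @param min_stem minimum number of base-paired columns for the
#'   loop + invader architecture call.
#' @param loop_range admissible apical loop lengths (closed interval).
#' @param max_polyU_gap maximum spacer between invader 3' end and poly-U.
#' @return a named list of parameters.
#' @export
align_params <- function(match_wc = 3, match_wobble = 1, mismatch = -2, gap = -4,
                         window_slack = 4L, min_stem = 8L,
                         loop_range = c(3L, 12L), max_polyU_gap = 2L) {
  list(match_wc = match_wc, match_wobble = match_wobble, mismatch = mismatch,
       gap = gap, window_slack = as.integer(window_slack),
       min_stem = as.integer(min_stem), loop_range = as.integer(loop_range),
       max_polyU_gap = as.integer(max_polyU_gap))
}

column_score <- function(kind, params) {
  unname(c(WC = params$match_wc, WOBBLE = params$match_wobble,
           MISMATCH = params$mismatch)[kind])
}

#' Align a terminator invader against its substrate
#'
#' Antiparallel global alignment of the invader (5'->3') against the
#' substrate (given 5'->3'), anchored at the strand-displacement nucleation
#' site: the invader's 5' end is aligned against the substrate's 3' end, and
#' any unused substrate at the far (5', hairpin-base) end is left unaligned
#' free of charge. Every invader nucleotide is consumed: paired (WC, wobble
#' or mismatch column) or bulged. The optimum is found by dynamic
#' programming; ties are broken deterministically by preferring pairing over
#' gaps and pushing bulges toward the nucleation end.
#'
#' @param invader,substrate RNA sequences, both 5'->3'.
#' @param params scoring parameters from [align_params()].
#' @return a `duplex_alignment`: a list with `columns` (tibble of `kind`,
#'   `invader_pos`, `substrate_pos`, `invader_base`, `substrate_base`,
#'   ordered from the nucleation site toward the hairpin base; positions are
#'   1-based within the input strings, `NA` for bulged sides) and `score`.
#' @examples
#' align_duplex("GCGC", "GCGC")$score  # 4 WC columns, score 12
#' @export
align_duplex <- function(invader, substrate, params = align_params()) {
  invader <- as_rna(invader, "invader")
  substrate <- as_rna(substrate, "substrate")
  inv <- strsplit(invader, "")[[1L]]
  sub <- strsplit(substrate, "")[[1L]]
  srev <- rev(sub)  # srev[j] = substrate position length-j+1
  m <- length(inv); n <- length(srev)
  gap <- params$gap

  kind_ij <- matrix(pair_kind(rep(inv, times = n), rep(srev, each = m)),
                    nrow = m, ncol = n)
  score_ij <- matrix(column_score(kind_ij, params), nrow = m, ncol = n)

  D <- matrix(-Inf, nrow = m + 1L, ncol = n + 1L)
  D[1L, ] <- (0:n) * gap
  D[, 1L] <- (0:m) * gap
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1L, j + 1L] <- max(
        D[i, j] + score_ij[i, j],
        D[i, j + 1L] + gap,
        D[i + 1L, j] + gap
      )
    }
  }
  # free trailing substrate (hairpin-base side): stop at the best j
  best_j <- which(D[m + 1L, ] == max(D[m + 1L, ]))[1L] - 1L
  score <- D[m + 1L, best_j + 1L]

  # traceback; preference order places bulges nucleation-proximal
  i <- m; j <- best_j
  rows <- vector("list", m + n)
  k <- 0L
  push <- function(kind, ip, jp) {
    k <<- k + 1L
    rows[[k]] <<- list(
      kind = kind,
      invader_pos = if (is.na(ip)) NA_integer_ else ip,
      substrate_pos = if (is.na(jp)) NA_integer_ else length(sub) - jp + 1L,
      invader_base = if (is.na(ip)) NA_character_ else inv[ip],
      substrate_base = if (is.na(jp)) NA_character_ else srev[jp]
    )
  }
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + score_ij[i, j]) {
      push(kind_ij[i, j], i, j)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + gap) {
      push("BULGE_INVADER", i, NA)
      i <- i - 1L
    } else {
      push("BULGE_SUBSTRATE", NA, j)
      j <- j - 1L
    }
  }
  cols <- dplyr::bind_rows(lapply(rev(rows[seq_len(k)]), tibble::as_tibble))
  structure(
    list(columns = cols, score = score, params = params,
         invader = invader, substrate = substrate),
    class = "duplex_alignment"
  )
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex_alignment> %d columns, score %g\n",
              nrow(x$columns), x$score))
  tab <- table(x$columns$kind)
  cat(" ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Align a construct's invader against its substrate window
#'
#' Extracts the annotated invader and the substrate window ending at the P3
#' 3' terminus (length = invader length + `window_slack`, reflecting that
#' invasion proceeds from the P3 3' end through the pseudoknot), runs
#' [align_duplex()], and rewrites column positions into absolute construct
#' coordinates so that barrier indices can be attached.
#'
#' @param construct a `construct` with `P3` and `invader` regions.
#' @param params scoring parameters from [align_params()].
#' @return a `duplex_alignment` with absolute `invader_pos`/`substrate_pos`.
#' @export
align_construct <- function(construct, params = align_params()) {
  inv <- region_of(construct, "invader")
  p3 <- region_of(construct, "P3")
  if (is.null(inv) || is.null(p3)) {
    stop("construct '", construct$id, "' must have invader and P3 regions",
         call. = FALSE)
  }
  inv_len <- inv$end - inv$start + 1L
  win_start <- max(1L, p3$end - (inv_len + params$window_slack) + 1L)
  aln <- align_duplex(
    substr(construct$sequence, inv$start, inv$end),
    substr(construct$sequence, win_start, p3$end),
    params
  )
  aln$columns$invader_pos <- aln$columns$invader_pos + inv$start - 1L
  aln$columns$substrate_pos <- aln$columns$substrate_pos + win_start - 1L
  aln$construct_id <- construct$id
  aln
}

#' Nucleating base pair of a duplex alignment
#'
#' @param alignment a `duplex_alignment`.
#' @return named integer vector `c(substrate_pos, invader_pos)` of the first
#'   paired (non-bulge) column from the nucleation end.
#' @export
nucleating_pair <- function(alignment) {
  cols <- alignment$columns
  i <- which(cols$kind %in% c("WC", "WOBBLE", "MISMATCH"))
  if (length(i) == 0L) {
    stop("degenerate alignment: no paired column", call. = FALSE)
  }
  i <- i[1L]
  c(substrate_pos = cols$substrate_pos[i], invader_pos = cols$invader_pos[i])
}

#' Annotate noncomplementary elements of a duplex
#'
#' Collapses maximal runs of adjacent same-kind non-WC columns into elements
#' (a 2-nt bulge is one element of span 2); wobble columns are exempt from
#' merging since adjacent wobble pairs remain two distinct base pairs rather
#' than one larger loop. Attaches the kinetic-barrier
#' index r of each element's 5'-most invader-side column (for substrate
#' bulges, of the nearest flanking invader position), and labels each
#' element with its phenomenological tunebox: elements at r <= 5 sit in the
#' ON-state tunebox, elements within 6 nt of the hairpin base in the leak
#' tunebox, the remainder in the variable region. Labels are annotations
#' only and enter no computation.
#'
#' @param alignment a `duplex_alignment` from [align_construct()].
#' @param construct the construct the alignment was computed from.
#' @return a tibble of elements, sorted by `r` ascending, with columns
#'   `kind`, `r`, `length`, `invader_pos`, `substrate_pos`, `tunebox`.
#' @export
annotate_elements <- function(alignment, construct) {
  cols <- alignment$columns
  cols$column <- seq_len(nrow(cols))
  nc <- cols[cols$kind != "WC", , drop = FALSE]
  empty <- tibble::tibble(
    kind = character(), r = integer(), length = integer(),
    invader_pos = character(), substrate_pos = character(), tunebox = character()
  )
  if (nrow(nc) == 0L) return(empty)

  run <- cumsum(c(TRUE, diff(nc$column) != 1L |
                    nc$kind[-1L] != nc$kind[-nrow(nc)] |
                    nc$kind[-1L] == "WOBBLE"))
  r_base <- max(
    vapply(cols$invader_pos[!is.na(cols$invader_pos)],
           function(p) barrier_index(construct, p), integer(1))
  )
  out <- lapply(split(nc, run), function(e) {
    ip <- e$invader_pos[!is.na(e$invader_pos)]
    if (length(ip)) {
      anchor <- min(ip)
    } else {
      # substrate bulge: nearest flanking invader-side column
      first_col <- min(e$column)
      before <- cols$invader_pos[cols$column < first_col]
      before <- before[!is.na(before)]
      after <- cols$invader_pos[cols$column > max(e$column)]
      after <- after[!is.na(after)]
      anchor <- if (length(before)) max(before) else min(after)
    }
    r <- barrier_index(construct, anchor)
    tibble::tibble(
      kind = e$kind[1L],
      r = r,
      length = nrow(e),
      invader_pos = paste(ip, collapse = ","),
      substrate_pos = paste(e$substrate_pos[!is.na(e$substrate_pos)], collapse = ","),
      tunebox = if (r <= 5L) "ON-state tunebox"
                else if (r >= r_base - 5L) "leak tunebox"
                else "variable region"
    )
  })
  out <- dplyr::bind_rows(out)
  out[order(out$r), ]
}

#' Find poly-U tracts
#'
#' Maximal runs of U of at least `min_len` nucleotides, reported in order of
#' occurrence. The default threshold of 5 Us is the curation cutoff for a
#' putative intrinsic-terminator poly-U tract.
#'
#' @param sequence an RNA sequence.
#' @param min_len minimum run length (>= 1).
#' @return a tibble with columns `start`, `end` (1-based closed intervals).
#' @examples
#' find_polyU("AAUUUUUA")  # one run, [3, 7]
#' @export
find_polyU <- function(sequence, min_len = 5L) {
  sequence <- as_rna(sequence)
  stopifnot(min_len >= 1L)
  m <- gregexpr(sprintf("U{%d,}", as.integer(min_len)), sequence)[[1L]]
  if (m[1L] == -1L) return(tibble::tibble(start = integer(), end = integer()))
  tibble::tibble(
    start = as.integer(m),
    end = as.integer(m) + attr(m, "match.length") - 1L
  )
}

#' Classify terminator architecture
#'
#' A construct has the reference loop + invader architecture when (i) its
#' invader forms at least `min_stem` base-paired columns (WC or wobble) with
#' the substrate window, (ii) the apical loop between the P3 3' terminus and
#' the invader 5' end has length within `loop_range`, and (iii) the poly-U
#' tract starts within `max_polyU_gap` nucleotides of the invader 3' end.
#'
#' @param construct a `construct` with `P3`, `invader` and `polyU` regions.
#' @param params parameters from [align_params()].
#' @return `"LOOP_PLUS_INVADER"` or `"OTHER"`.
#' @export
classify_architecture <- function(construct, params = align_params()) {
  inv <- region_of(construct, "invader")
  pu <- region_of(construct, "polyU")
  p3 <- region_of(construct, "P3")
  if (is.null(inv) || is.null(pu) || is.null(p3)) {
    stop("construct '", construct$id,
         "' must have P3, invader and polyU regions", call. = FALSE)
  }
  aln <- align_construct(construct, params)
  n_paired <- sum(aln$columns$kind %in% c("WC", "WOBBLE"))
  loop_len <- inv$start - p3$end - 1L
  gap <- pu$start - inv$end - 1L
  ok <- n_paired >= params$min_stem &&
    loop_len >= params$loop_range[1L] && loop_len <= params$loop_range[2L] &&
    gap <= params$max_polyU_gap
  if (ok) "LOOP_PLUS_INVADER" else "OTHER"
}
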