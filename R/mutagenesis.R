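DELTA <- "Δ"

#' Create a mutation specification
#'
#' Mutations are specified in reference (not mutant) numbering. For
#' insertions, `position` is the residue immediately 5' of the inserted
#' bases ("a bulge at position 3 denotes an insertion between C110 and
#' C111" when the invader starts at residue 108).
#'
#' @param kind `"SUBSTITUTION"`, `"DELETION"` or `"INSERTION"`.
#' @param position 1-based reference position.
#' @param alt substituted/inserted residues; must be empty for deletions,
#'   a single base for substitutions.
#' @return an object of class `mutation_spec`.
#' @export
mutation_spec <- function(kind = c("SUBSTITUTION", "DELETION", "INSERTION"),
                          position, alt = "") {
  kind <- match.arg(kind)
  position <- as.integer(position)
  stopifnot(length(position) == 1L, !is.na(position), position >= 1L)
  if (kind == "SUBSTITUTION") {
    alt <- as_rna(alt, "substitution alt")
    if (nchar(alt) != 1L) stop("substitution alt must be one base", call. = FALSE)
  } else if (kind == "INSERTION") {
    alt <- as_rna(alt, "insertion alt")
  } else if (nzchar(alt)) {
    stop("deletion spec must have empty alt", call. = FALSE)
  }
  structure(list(kind = kind, position = position, alt = alt),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("<mutation_spec> %s at %d%s\n", x$kind, x$position,
              if (nzchar(x$alt)) paste0(" -> ", x$alt) else ""))
  invisible(x)
}

shift_regions <- function(regions, pos, kind, ins_len = 0L) {
  if (nrow(regions) == 0L) return(regions)
  if (kind == "DELETION") {
    drop <- regions$start == pos & regions$end == pos
    regions$start <- ifelse(regions$start > pos, regions$start - 1L, regions$start)
    regions$end <- ifelse(regions$end >= pos, regions$end - 1L, regions$end)
    regions <- regions[!drop, , drop = FALSE]
  } else if (kind == "INSERTION") {
    regions$start <- ifelse(regions$start > pos, regions$start + ins_len, regions$start)
    regions$end <- ifelse(regions$end > pos, regions$end + ins_len, regions$end)
  }
  regions
}

#' Apply mutations to a construct
#'
#' Edits the sequence and shifts all region coordinates 3' of the edit by
#' the length change, so invader/poly-U annotations remain valid on the
#' mutant. `apply_mutations()` applies a list of specs given in reference
#' numbering (they are applied 3'-to-5' so earlier edits cannot displace
#' later ones).
#'
#' @param construct a `construct`.
#' @param spec a `mutation_spec`.
#' @param specs a list of `mutation_spec`s in reference numbering.
#' @param id id for the mutant construct; default appends the mutation name.
#' @return the mutated `construct`.
#' @export
apply_mutation <- function(construct, spec, id = NULL) {
  stopifnot(inherits(spec, "mutation_spec"))
  s <- construct$sequence
  n <- nchar(s)
  p <- spec$position
  if (p > n) stop("position ", p, " beyond sequence length ", n, call. = FALSE)
  ref_base <- substr(s, p, p)
  if (spec$kind == "SUBSTITUTION") {
    if (spec$alt == ref_base) {
      stop("no-op substitution at ", p, " (reference base already ", ref_base, ")",
           call. = FALSE)
    }
    new_seq <- paste0(substr(s, 1L, p - 1L), spec$alt, substr(s, p + 1L, n))
    regions <- construct$regions
  } else if (spec$kind == "DELETION") {
    new_seq <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, n))
    regions <- shift_regions(construct$regions, p, "DELETION")
  } else {
    new_seq <- paste0(substr(s, 1L, p), spec$alt, substr(s, p + 1L, n))
    regions <- shift_regions(construct$regions, p, "INSERTION", nchar(spec$alt))
  }
  if (is.null(id)) id <- paste0(construct$id, "_", name_mutation(spec, construct))
  construct(id, new_seq, regions)
}

#' @rdname apply_mutation
#' @export
apply_mutations <- function(construct, specs, id = NULL) {
  stopifnot(is.list(specs))
  if (is.null(id)) {
    id <- paste0(construct$id, "_",
                 paste(vapply(specs, name_mutation, character(1),
                              reference = construct), collapse = "+"))
  }
  ord <- order(vapply(specs, function(x) x$position, integer(1)),
               decreasing = TRUE)
  out <- construct
  for (sp in specs[ord]) out <- apply_mutation(out, sp, id = id)
  out
}

#' Name a mutation, or parse a mutation name
#'
#' The naming grammar follows the field's convention, always in reference
#' numbering: substitution `"<ref><pos><alt>"` (G108C), deletion
#' `"<ref><pos>Δ"` (G108Δ; ASCII alias `"G108del"`), insertion
#' `"<pos>ins<seq>"` (108insAAA; alias bracketing the flanking residues,
#' `"G108-C109insAAA"`). `parse_mutation_name()` checks the stated reference
#' base against the reference construct and errors on mismatch;
#' `name_mutation(parse_mutation_name(x)) == x` for canonical names.
#'
#' @param spec a `mutation_spec`.
#' @param name a mutation name string.
#' @param reference the reference `construct`.
#' @return `name_mutation()`: a string; `parse_mutation_name()`: a
#'   `mutation_spec`.
#' @export
name_mutation <- function(spec, reference) {
  ref_base <- substr(reference$sequence, spec$position, spec$position)
  switch(spec$kind,
    SUBSTITUTION = paste0(ref_base, spec$position, spec$alt),
    DELETION = paste0(ref_base, spec$position, DELTA),
    INSERTION = paste0(spec$position, "ins", spec$alt)
  )
}

#' @rdname name_mutation
#' @export
parse_mutation_name <- function(name, reference) {
  stopifnot(is.character(name), length(name) == 1L)
  check_ref <- function(pos, stated) {
    actual <- substr(reference$sequence, pos, pos)
    if (actual != stated) {
      stop(sprintf("name '%s' states reference base %s at %d but reference has %s",
                   name, stated, pos, actual), call. = FALSE)
    }
  }
  # insertion, flanking-pair alias: G108-C109insAAA
  m <- regmatches(name, regexec("^([ACGUT])(\\d+)-([ACGUT])(\\d+)ins([ACGUT]+)$", name))[[1L]]
  if (length(m)) {
    p1 <- as.integer(m[3L]); p2 <- as.integer(m[5L])
    if (p2 != p1 + 1L) stop("insertion flanks must be adjacent: ", name, call. = FALSE)
    check_ref(p1, chartr("T", "U", m[2L]))
    check_ref(p2, chartr("T", "U", m[4L]))
    return(mutation_spec("INSERTION", p1, m[6L]))
  }
  # insertion: 108insAAA
  m <- regmatches(name, regexec("^(\\d+)ins([ACGUT]+)$", name))[[1L]]
  if (length(m)) {
    return(mutation_spec("INSERTION", as.integer(m[2L]), m[3L]))
  }
  # deletion: G108<delta> or G108del
  m <- regmatches(name, regexec(paste0("^([ACGUT])(\\d+)(", DELTA, "|del)$"), name))[[1L]]
  if (length(m)) {
    pos <- as.integer(m[3L])
    check_ref(pos, chartr("T", "U", m[2L]))
    return(mutation_spec("DELETION", pos))
  }
  # substitution: G108C
  m <- regmatches(name, regexec("^([ACGUT])(\\d+)([ACGUT])$", name))[[1L]]
  if (length(m)) {
    pos <- as.integer(m[3L])
    check_ref(pos, chartr("T", "U", m[2L]))
    return(mutation_spec("SUBSTITUTION", pos, m[4L]))
  }
  stop("cannot parse mutation name: ", name, call. = FALSE)
}

new_mutant_library <- function(name, reference, names, specs, constructs,
                               r, kind_created, note = NULL) {
  seqs <- vapply(constructs, function(x) x$sequence, character(1))
  keep <- !duplicated(seqs)  # homopolymer-equivalent edits collapse to the 5'-most
  tbl <- tibble::tibble(
    name = names[keep],
    r = r[keep],
    kind_created = kind_created[keep],
    spec = specs[keep],
    construct = constructs[keep]
  )
  if (!is.null(note)) tbl$note <- note[keep]
  structure(list(name = name, reference = reference, mutants = tbl),
            class = "mutant_library")
}

#' @export
print.mutant_library <- function(x, ...) {
  cat(sprintf("<mutant_library> %s: %d mutants of %s\n",
              x$name, nrow(x$mutants), x$reference$id))
  invisible(x)
}

#' Mutational scans of the terminator invader
#'
#' Generate the standard barrier-scan libraries against an annotated
#' reference construct:
#' * `scan_mismatch()` - one mutant per paired invader position,
#'   substituting the invader base with its own Watson-Crick complement
#'   (G<->C, A<->U), which breaks the pair regardless of substrate identity.
#' * `scan_deletion()` - one mutant per invader position.
#' * `scan_bulge()` - a poly-`base` insertion of length `n` immediately
#'   after each invader index (indices 1 to invader length - 1; an
#'   insertion after the last invader residue would fall outside the stem).
#' * `scan_wobble()` - C->U at G:C pairs (creating G:U) and, when
#'   `include_reversed`, A->G at U:A pairs (creating U:G; these are flagged
#'   `"wobble-to-WC direction reversed"` since such wobbles can increase
#'   strand-displacement efficiency).
#'
#' Mutants are named with [name_mutation()]; libraries are duplicate-free
#' (edits that are sequence-equivalent within homopolymer runs collapse to
#' their 5'-most representative).
#'
#' @param construct the reference `construct` (invader and P3 annotated).
#' @param params alignment parameters from [align_params()].
#' @param n bulge length, 1-3.
#' @param base bulge base (default `"A"`).
#' @param include_reversed include U:A -> U:G wobble mutants (flagged).
#' @return a `mutant_library`; `$mutants` is a tibble with columns `name`,
#'   `r`, `kind_created`, `spec` (list of `mutation_spec`), `construct`
#'   (list of `construct`).
#' @export
scan_mismatch <- function(construct, params = align_params()) {
  aln <- align_construct(construct, params)
  cols <- aln$columns
  paired <- cols[cols$kind %in% c("WC", "WOBBLE"), , drop = FALSE]
  specs <- lapply(seq_len(nrow(paired)), function(i) {
    mutation_spec("SUBSTITUTION", paired$invader_pos[i],
                  RNA_COMPLEMENT[[paired$invader_base[i]]])
  })
  build_scan(construct, "mismatch", specs, kind_created = "MISMATCH")
}

#' @rdname scan_mismatch
#' @export
scan_deletion <- function(construct, params = align_params()) {
  inv <- region_of(construct, "invader")
  if (is.null(inv)) stop("construct has no invader region", call. = FALSE)
  specs <- lapply(seq.int(inv$start, inv$end),
                  function(p) mutation_spec("DELETION", p))
  build_scan(construct, "deletion", specs, kind_created = "DELETION")
}

#' @rdname scan_mismatch
#' @export
scan_bulge <- function(construct, n = 1L, base = "A", params = align_params()) {
  n <- as.integer(n)
  if (!n %in% 1:3) stop("bulge length n must be 1, 2 or 3", call. = FALSE)
  inv <- region_of(construct, "invader")
  if (is.null(inv)) stop("construct has no invader region", call. = FALSE)
  specs <- lapply(seq.int(inv$start, inv$end - 1L),
                  function(p) mutation_spec("INSERTION", p, strrep(base, n)))
  build_scan(construct, paste0("bulge", n), specs,
             kind_created = paste0("BULGE", n))
}

#' @rdname scan_mismatch
#' @export
scan_wobble <- function(construct, include_reversed = TRUE,
                        params = align_params()) {
  aln <- align_construct(construct, params)
  cols <- aln$columns
  wc <- cols[cols$kind == "WC", , drop = FALSE]
  specs <- list(); note <- character()
  for (i in seq_len(nrow(wc))) {
    if (wc$invader_base[i] == "C" && wc$substrate_base[i] == "G") {
      specs <- c(specs, list(mutation_spec("SUBSTITUTION", wc$invader_pos[i], "U")))
      note <- c(note, "")
    } else if (include_reversed &&
               wc$invader_base[i] == "A" && wc$substrate_base[i] == "U") {
      specs <- c(specs, list(mutation_spec("SUBSTITUTION", wc$invader_pos[i], "G")))
      note <- c(note, "wobble-to-WC direction reversed")
    }
  }
  build_scan(construct, "wobble", specs, kind_created = "WOBBLE", note = note)
}

build_scan <- function(construct, scan_name, specs, kind_created, note = NULL) {
  names <- vapply(specs, name_mutation, character(1), reference = construct)
  constructs <- lapply(seq_along(specs), function(i) {
    apply_mutation(construct, specs[[i]], id = names[i])
  })
  r <- vapply(specs, function(sp) barrier_index(construct, sp$position), integer(1))
  new_mutant_library(scan_name, construct, names, specs, constructs,
                     r, rep(kind_created, length(specs)), note = note)
}

#' Correct an invader to perfect complementarity
#'
#' Removes every noncomplementary element of the reference duplex: wobble
#' pairs are corrected by substituting the invader base with the
#' Watson-Crick complement of the substrate base, invader bulges are
#' deleted, substrate bulges are filled by inserting the complement of the
#' bulged substrate base, and (with a warning, since the reference
#' architecture has none) mismatches are substituted to complement the
#' substrate. Applying the operation twice is idempotent: the corrected
#' construct's duplex has zero noncomplementary elements.
#'
#' @param construct the reference `construct`.
#' @param params alignment parameters from [align_params()].
#' @return a list with `construct` (the corrected construct) and `specs`
#'   (the corrective `mutation_spec`s in reference numbering).
#' @export
perfect_invader <- function(construct, params = align_params()) {
  aln <- align_construct(construct, params)
  cols <- aln$columns
  specs <- list()
  for (i in seq_len(nrow(cols))) {
    k <- cols$kind[i]
    if (k == "WC") next
    if (k == "WOBBLE") {
      specs <- c(specs, list(mutation_spec(
        "SUBSTITUTION", cols$invader_pos[i],
        RNA_COMPLEMENT[[cols$substrate_base[i]]]
      )))
    } else if (k == "BULGE_INVADER") {
      specs <- c(specs, list(mutation_spec("DELETION", cols$invader_pos[i])))
    } else if (k == "BULGE_SUBSTRATE") {
      prev <- cols$invader_pos[seq_len(i - 1L)]
      prev <- prev[!is.na(prev)]
      anchor <- if (length(prev)) max(prev) else region_of(construct, "invader")$start - 1L
      specs <- c(specs, list(mutation_spec(
        "INSERTION", anchor, RNA_COMPLEMENT[[cols$substrate_base[i]]]
      )))
    } else {
      warning("reference duplex contains a MISMATCH element; correcting it",
              call. = FALSE)
      specs <- c(specs, list(mutation_spec(
        "SUBSTITUTION", cols$invader_pos[i],
        RNA_COMPLEMENT[[cols$substrate_base[i]]]
      )))
    }
  }
  if (length(specs) == 0L) {
    out <- construct
  } else {
    out <- apply_mutations(construct, specs, id = paste0(construct$id, "_perfect"))
  }
  list(construct = out, specs = specs)
}

# single-edit diff against a reference; edits are left-aligned so that
# homopolymer-ambiguous indels report their 5'-most representative
infer_mutation <- function(ref_seq, mut_seq) {
  if (ref_seq == mut_seq) return(NULL)
  r <- strsplit(ref_seq, "")[[1L]]
  m <- strsplit(mut_seq, "")[[1L]]
  if (length(r) == length(m)) {
    d <- which(r != m)
    if (length(d) != 1L) stop("not a single substitution", call. = FALSE)
    return(mutation_spec("SUBSTITUTION", d, m[d]))
  }
  L <- abs(length(m) - length(r))
  i <- 1L
  while (i <= min(length(r), length(m)) && r[i] == m[i]) i <- i + 1L
  if (length(r) > length(m)) {  # deletion of r[i..i+L-1]
    pos <- i
    while (pos > 1L && r[pos - 1L] == r[pos + L - 1L]) pos <- pos - 1L
    if (L != 1L) stop("not a single-base deletion", call. = FALSE)
    return(mutation_spec("DELETION", pos))
  }
  ins <- m[seq.int(i, i + L - 1L)]  # insertion after r[i-1]
  pos <- i - 1L
  while (pos > 1L && r[pos] == ins[L]) {
    ins <- c(r[pos], ins[-L])
    pos <- pos - 1L
  }
  mutation_spec("INSERTION", pos, paste(ins, collapse = ""))
}
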