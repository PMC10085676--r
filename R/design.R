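#' Curate candidate expression platforms
#'
#' Applies, in order, the three curation filters used to narrow candidate
#' ZTP expression platforms: (i) presence of a putative terminator poly-U
#' tract of at least `min_polyU` Us within the expression platform (the
#' span 3' of P3), (ii) exact string identity of the candidate's P3 region
#' to the reference P3 (gapped near-identity is rejected), and (iii) the
#' loop + invader terminator architecture per [classify_architecture()].
#' Candidates lacking the required region annotations fail the affected
#' filters; no error is raised per candidate. Verdicts are independent of
#' candidate order.
#'
#' @param candidates list of `construct`s.
#' @param reference reference `construct` with an annotated P3.
#' @param min_polyU poly-U filter threshold (default 5).
#' @param params alignment/architecture parameters from [align_params()].
#' @return a `curation_report`: list with `verdicts` (tibble of `id`,
#'   `polyU_pass`, `P3_identical_pass`, `architecture_pass`, `pass`) and
#'   `surviving` (the passing constructs, input order preserved).
#' @export
curate_eps <- function(candidates, reference, min_polyU = 5L,
                       params = align_params()) {
  stopifnot(is.list(candidates))
  ref_p3 <- region_seq(reference, "P3")
  verdicts <- lapply(candidates, function(cand) {
    p3 <- region_of(cand, "P3")
    ep_start <- if (!is.null(p3)) p3$end + 1L else NA_integer_
    polyU_pass <- if (!is.na(ep_start) && ep_start <= construct_length(cand)) {
      nrow(find_polyU(substr(cand$sequence, ep_start, construct_length(cand)),
                      min_len = min_polyU)) > 0L
    } else FALSE
    p3_pass <- !is.null(p3) && substr(cand$sequence, p3$start, p3$end) == ref_p3
    arch_pass <- tryCatch(
      classify_architecture(cand, params) == "LOOP_PLUS_INVADER",
      error = function(e) FALSE
    )
    tibble::tibble(
      id = cand$id,
      polyU_pass = polyU_pass,
      P3_identical_pass = p3_pass,
      architecture_pass = arch_pass,
      pass = polyU_pass && p3_pass && arch_pass
    )
  })
  verdicts <- dplyr::bind_rows(verdicts)
  structure(
    list(verdicts = verdicts, surviving = candidates[verdicts$pass]),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> %d/%d candidates pass all filters\n",
              sum(x$verdicts$pass), nrow(x$verdicts)))
  print(x$verdicts)
  invisible(x)
}

#' Build an aptamer-invader chimera
#'
#' Fuses the reference riboswitch aptamer (everything 5' of its invader,
#' including the shared P3 sequence) with a foreign invader, keeping the
#' reference poly-U tract and downstream sequence. Regions are
#' re-annotated: the invader spans the foreign sequence and downstream
#' coordinates shift by the length difference.
#'
#' @param reference reference `construct` with invader and polyU regions.
#' @param foreign_invader RNA sequence of the replacement invader.
#' @param id id for the chimera.
#' @return a `construct`. Extracting its invader returns `foreign_invader`
#'   unchanged; its P3 is identical to the reference P3.
#' @export
build_chimera <- function(reference, foreign_invader, id = NULL) {
  foreign_invader <- as_rna(foreign_invader, "foreign invader")
  inv <- region_of(reference, "invader")
  pu <- region_of(reference, "polyU")
  if (is.null(inv) || is.null(pu)) {
    stop("reference must have invader and polyU regions", call. = FALSE)
  }
  if (is.null(id)) id <- paste0(reference$id, "_chimera")
  seq <- paste0(
    substr(reference$sequence, 1L, inv$start - 1L),
    foreign_invader,
    substr(reference$sequence, pu$start, construct_length(reference))
  )
  shift <- nchar(foreign_invader) - (inv$end - inv$start + 1L) -
    (pu$start - inv$end - 1L)
  regions <- reference$regions
  for (i in seq_len(nrow(regions))) {
    if (regions$name[i] == "invader") {
      regions$end[i] <- inv$start + nchar(foreign_invader) - 1L
    } else if (regions$start[i] > inv$end) {
      regions$start[i] <- regions$start[i] + shift
      regions$end[i] <- regions$end[i] + shift
    }
  }
  construct(id, seq, regions)
}

#' Design a flipped-logic OFF-switch
#'
#' Inverts the regulatory logic of a terminator-forming ON-switch by
#' inserting a "flipping domain" between the 3' end of the terminator
#' hairpin stem and the poly-U tract. Ligand-free, the domain acts as a
#' spacer that ablates intrinsic termination (ON); ligand-bound, it pairs
#' with the leftover 3' portion of the invader after failed strand
#' displacement, forming a synthetic terminator adjacent to the poly-U
#' tract (OFF). The default domain is the reverse complement of the
#' `domain_len`-nt 3' suffix of the invader, giving a perfect synthetic
#' stem; an explicit `domain` overrides it.
#'
#' @param parent a `construct` with invader and polyU annotated.
#' @param domain_len flipping-domain length (default 8).
#' @param domain explicit flipping-domain sequence (overrides the default).
#' @param spacer_threshold minimum apo spacer length at which apo
#'   termination is flagged ablated (heuristic annotation only).
#' @return a `flip_design`: list with `parent`, `construct` (the designed
#'   sequence with a `flipping_domain` region), `flipping_domain`,
#'   `insertion_point`, `apo_spacer_len`, `holo_stem` (a
#'   `duplex_alignment` of the domain against the invader suffix),
#'   `apo_termination_ablated`, and `barrier` (`NULL` until [tune_flip()]).
#' @export
design_flip <- function(parent, domain_len = 8L, domain = NULL,
                        spacer_threshold = 8L) {
  inv <- region_of(parent, "invader")
  pu <- region_of(parent, "polyU")
  if (is.null(inv) || is.null(pu)) {
    stop("parent must have invader and polyU regions", call. = FALSE)
  }
  domain_len <- as.integer(domain_len)
  inv_len <- inv$end - inv$start + 1L
  if (domain_len < 1L) stop("degenerate design: domain_len must be >= 1", call. = FALSE)
  if (domain_len > inv_len) {
    stop("domain_len ", domain_len, " exceeds invader length ", inv_len, call. = FALSE)
  }
  suffix <- substr(parent$sequence, inv$end - domain_len + 1L, inv$end)
  if (is.null(domain)) domain <- rna_revcomp(suffix) else domain <- as_rna(domain)

  insertion_point <- inv$end + 1L
  seq <- paste0(
    substr(parent$sequence, 1L, inv$end),
    domain,
    substr(parent$sequence, inv$end + 1L, construct_length(parent))
  )
  regions <- shift_regions(parent$regions, inv$end, "INSERTION", nchar(domain))
  regions <- dplyr::bind_rows(
    regions,
    region("flipping_domain", inv$end + 1L, inv$end + nchar(domain))
  )
  holo_stem <- align_duplex(domain, suffix)
  structure(
    list(
      parent = parent,
      construct = construct(paste0(parent$id, "_flip"), seq, regions),
      flipping_domain = domain,
      insertion_point = insertion_point,
      apo_spacer_len = nchar(domain) + (pu$start - inv$end - 1L),
      holo_stem = holo_stem,
      apo_termination_ablated =
        nchar(domain) + (pu$start - inv$end - 1L) >= spacer_threshold,
      barrier = NULL
    ),
    class = "flip_design"
  )
}

#' @export
print.flip_design <- function(x, ...) {
  cat(sprintf("<flip_design> %s: %d-nt flipping domain %s at %d\n",
              x$construct$id, nchar(x$flipping_domain), x$flipping_domain,
              x$insertion_point))
  cat(sprintf("  apo spacer %d nt (termination %s)\n", x$apo_spacer_len,
              if (x$apo_termination_ablated) "ablated" else "intact"))
  if (!is.null(x$barrier)) {
    cat(sprintf("  barrier: %s at r = %d\n", x$barrier$name, x$barrier$r))
  }
  invisible(x)
}

#' Add a kinetic barrier to a flipped-logic design
#'
#' Applies a barrier mutation (deletion, bulge insertion, ...) to the
#' parent invader before re-deriving the flip design, and records the
#' barrier kind and its index r. Barriers slow strand displacement of the
#' aptamer and so reduce the OFF-state leak of the flipped switch. The
#' barrier must target the parent invader; mutations inside the flipping
#' domain are rejected.
#'
#' @param design a `flip_design`.
#' @param barrier_spec a `mutation_spec` in parent numbering.
#' @param domain optional explicit flipping domain for the re-design.
#' @return a new `flip_design` with `barrier` recorded.
#' @export
tune_flip <- function(design, barrier_spec, domain = NULL) {
  stopifnot(inherits(design, "flip_design"), inherits(barrier_spec, "mutation_spec"))
  parent <- design$parent
  inv <- region_of(parent, "invader")
  if (barrier_spec$position < inv$start || barrier_spec$position > inv$end) {
    fd <- region_of(design$construct, "flipping_domain")
    if (!is.null(fd) && barrier_spec$position >= fd$start &&
        barrier_spec$position <= fd$end) {
      stop("barrier targets the flipping domain, not the invader", call. = FALSE)
    }
    stop("barrier position ", barrier_spec$position,
         " outside the parent invader", call. = FALSE)
  }
  r <- barrier_index(parent, barrier_spec$position)
  mutated <- apply_mutation(parent, barrier_spec)
  if (is.null(domain)) domain <- design$flipping_domain
  out <- design_flip(mutated, domain_len = nchar(design$flipping_domain),
                     domain = domain)
  out$barrier <- list(
    name = name_mutation(barrier_spec, parent),
    kind = barrier_spec$kind,
    size = if (barrier_spec$kind == "INSERTION") nchar(barrier_spec$alt) else 1L,
    r = r
  )
  out
}
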