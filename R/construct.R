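REGION_NAMES <- c("P1", "J12", "P2", "PK", "linker", "P3", "loop",
                  "invader", "polyU", "flipping_domain", "other")

#' Create a named sequence region
#'
#' Regions are 1-based closed intervals on a construct sequence, numbered
#' from the first transcribed nucleotide so that residue labels match the
#' field's mutation names (e.g. A26, C100, G108).
#'
#' @param name one of `P1, J12, P2, PK, linker, P3, loop, invader, polyU,
#'   flipping_domain, other`.
#' @param start,end 1-based closed interval bounds, `start <= end`.
#' @return a one-row tibble with columns `name`, `start`, `end`.
#' @export
region <- function(name, start, end) {
  name <- match.arg(name, REGION_NAMES)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid region interval [", start, ", ", end, "]", call. = FALSE)
  }
  tibble::tibble(name = name, start = start, end = end)
}

#' Build an annotated riboswitch construct
#'
#' A construct is an RNA sequence plus named regions (aptamer stems,
#' pseudoknot, terminator invader, poly-U tract, ...). Invariants enforced:
#' regions lie within the sequence; `P3`, `invader` and `polyU` each occur at
#' most once; when all three are present the invader lies 3' of P3 and the
#' poly-U tract 3' of the invader; regions other than `other` do not overlap.
#'
#' @param id construct identifier.
#' @param sequence RNA (or DNA) sequence; coerced with [as_rna()].
#' @param regions a tibble/data.frame of regions (rows as from [region()]),
#'   or `NULL` for none.
#' @return an object of class `construct`.
#' @seealso [load_construct()] for building from a region config.
#' @export
construct <- function(id, sequence, regions = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  sequence <- as_rna(sequence, what = sprintf("construct '%s' sequence", id))
  if (is.null(regions)) {
    regions <- tibble::tibble(name = character(), start = integer(), end = integer())
  }
  regions <- tibble::as_tibble(regions)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  x <- structure(
    list(id = id, sequence = sequence, regions = regions),
    class = "construct"
  )
  validate_construct(x)
  x
}

validate_construct <- function(x) {
  n <- nchar(x$sequence)
  r <- x$regions
  if (nrow(r) == 0L) return(invisible(x))
  if (!all(r$name %in% REGION_NAMES)) {
    stop("unknown region name(s): ",
         paste(setdiff(r$name, REGION_NAMES), collapse = ", "), call. = FALSE)
  }
  bad <- r$start < 1L | r$start > r$end | r$end > n
  if (any(bad)) {
    b <- r[which(bad)[1L], ]
    stop(sprintf("region %s [%d, %d] out of bounds for sequence of length %d",
                 b$name, b$start, b$end, n), call. = FALSE)
  }
  for (nm in c("P3", "invader", "polyU")) {
    if (sum(r$name == nm) > 1L) stop("region ", nm, " annotated more than once", call. = FALSE)
  }
  p3 <- region_of(x, "P3"); inv <- region_of(x, "invader"); pu <- region_of(x, "polyU")
  if (!is.null(p3) && !is.null(inv) && p3$end >= inv$start) {
    stop("invader must lie 3' of P3 (P3 ends at ", p3$end,
         ", invader starts at ", inv$start, ")", call. = FALSE)
  }
  if (!is.null(inv) && !is.null(pu) && inv$end >= pu$start) {
    stop("polyU must lie 3' of the invader", call. = FALSE)
  }
  # pairwise overlap among non-'other' regions
  rr <- r[r$name != "other", , drop = FALSE]
  if (nrow(rr) > 1L) {
    o <- order(rr$start, rr$end)
    rr <- rr[o, ]
    for (i in seq_len(nrow(rr) - 1L)) {
      if (rr$end[i] >= rr$start[i + 1L]) {
        stop(sprintf("regions %s and %s overlap", rr$name[i], rr$name[i + 1L]),
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' @export
print.construct <- function(x, ...) {
  cat(sprintf("<construct> %s (%d nt)\n", x$id, nchar(x$sequence)))
  if (nrow(x$regions)) {
    for (i in seq_len(nrow(x$regions))) {
      cat(sprintf("  %-16s [%d, %d]\n",
                  x$regions$name[i], x$regions$start[i], x$regions$end[i]))
    }
  } else {
    cat("  (no regions annotated)\n")
  }
  invisible(x)
}

#' Look up a region, its sequence, or the construct length
#'
#' @param x a `construct`.
#' @param name region name.
#' @return `region_of()`: a one-row tibble or `NULL` if absent;
#'   `region_seq()`: the region's sequence; `construct_length()`: integer.
#' @export
region_of <- function(x, name) {
  i <- which(x$regions$name == name)
  if (length(i) == 0L) return(NULL)
  x$regions[i[1L], ]
}

#' @rdname region_of
#' @export
region_seq <- function(x, name) {
  r <- region_of(x, name)
  if (is.null(r)) stop("construct '", x$id, "' has no ", name, " region", call. = FALSE)
  substr(x$sequence, r$start, r$end)
}

#' @rdname region_of
#' @export
construct_length <- function(x) nchar(x$sequence)

#' Build a construct from a sequence and a region-annotation config
#'
#' The region config is a named list (or a YAML file read with
#' [read_region_config()]) mapping region names to `c(start, end)` 1-based
#' closed intervals. Regions not mentioned are simply omitted; numbering is
#' defined operationally by the supplied sequence, so the config travels with
#' each construct.
#'
#' @param sequence RNA/DNA sequence.
#' @param region_config named list of 2-vectors `c(start, end)`.
#' @param id construct identifier.
#' @return a `construct`.
#' @examples
#' load_construct("GGGCAUUUUU", list(invader = c(1, 4), polyU = c(6, 10)), id = "toy")
#' @export
load_construct <- function(sequence, region_config = list(), id = "construct") {
  regions <- NULL
  if (length(region_config)) {
    stopifnot(!is.null(names(region_config)))
    regions <- do.call(rbind, lapply(names(region_config), function(nm) {
      iv <- region_config[[nm]]
      if (length(iv) != 2L) stop("region ", nm, " must be c(start, end)", call. = FALSE)
      region(nm, iv[[1L]], iv[[2L]])
    }))
  }
  construct(id, sequence, regions)
}

#' @rdname load_construct
#' @param path path to a YAML region config (`region: [start, end]` entries).
#' @export
read_region_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(iv) as.integer(unlist(iv)))
}

#' Map between residue positions and the kinetic-barrier index r
#'
#' The barrier index r counts nucleotides from the strand-displacement
#' nucleation site (the terminator loop end of the stem): the 5'-most invader
#' nucleotide, which forms the nucleating base pair with the 3'-most
#' substrate nucleotide, has r = 1. A bulge inserted after the invader
#' nucleotide at index k is indexed r = k (so a bulge "at position 3" sits
#' between residues 110 and 111 in the reference numbering, where the
#' invader starts at 108).
#'
#' @param construct a `construct` with an annotated invader.
#' @param position 1-based residue position in construct numbering.
#' @param r barrier index (positive integer).
#' @return `barrier_index()`: integer r; `position_of_index()`: integer
#'   residue position. The two are mutually inverse on the invader span.
#' @export
barrier_index <- function(construct, position) {
  inv <- region_of(construct, "invader")
  if (is.null(inv)) stop("construct has no invader region", call. = FALSE)
  position <- as.integer(position)
  if (position < inv$start || position > inv$end) {
    stop(sprintf("position %d lies outside the invader [%d, %d]",
                 position, inv$start, inv$end), call. = FALSE)
  }
  position - inv$start + 1L
}

#' @rdname barrier_index
#' @export
position_of_index <- function(construct, r) {
  inv <- region_of(construct, "invader")
  if (is.null(inv)) stop("construct has no invader region", call. = FALSE)
  r <- as.integer(r)
  if (r < 1L || r > inv$end - inv$start + 1L) {
    stop("barrier index ", r, " outside the invader span", call. = FALSE)
  }
  inv$start + r - 1L
}
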