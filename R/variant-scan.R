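# Clade-specific variant scanning of B3 multiple sequence alignments:
# classify alignment columns as clade-specific structural variants and
# derive pairwise-distinguishing position sets (e.g. the beta4-triad).

AMBIGUOUS_AA <- c("X", "B", "Z", "J", "U", "O", "*", ".")

# alignment input -> character matrix (rows = sequences), residues
# upper-cased; accepts a named character vector, AAStringSet or matrix
as_alignment_matrix <- function(aln) {
  if (inherits(aln, "AAStringSet") || inherits(aln, "XStringSet")) {
    aln <- setNames(as.character(aln), names(aln))
  }
  if (is.matrix(aln)) {
    mat <- toupper(aln)
  } else if (is.character(aln)) {
    if (is.null(names(aln))) stop_invalid("alignment sequences must be named")
    lens <- nchar(aln)
    if (length(unique(lens)) != 1L) {
      stop_invalid("all aligned sequences must have equal length")
    }
    mat <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(mat) <- names(aln)
  } else {
    stop_invalid("unsupported alignment representation")
  }
  mat
}

# clade assignment input -> named vector sequence_id -> clade
as_clade_vector <- function(clades) {
  if (is.data.frame(clades)) {
    if (!all(c("sequence_id", "clade") %in% names(clades))) {
      stop_invalid("clade table needs columns sequence_id, clade")
    }
    clades <- setNames(as.character(clades$clade),
                       as.character(clades$sequence_id))
  }
  if (is.null(names(clades))) stop_invalid("clade assignment must be named")
  clades
}

# per-clade consensus at one column: the single shared residue, or NA when
# the clade is polymorphic, partially gapped or carries an ambiguity code
clade_residue <- function(col, members) {
  res <- unique(col[members])
  if (length(res) != 1L) return(NA_character_)
  if (res %in% AMBIGUOUS_AA) return(NA_character_)
  # an all-gap clade participates with residue '-'
  res
}

validate_scan_inputs <- function(mat, clade_vec) {
  missing_ids <- setdiff(rownames(mat), names(clade_vec))
  if (length(missing_ids) > 0L) {
    stop_invalid("sequences without clade assignment: ",
                 paste(missing_ids, collapse = ", "))
  }
  clade_vec <- clade_vec[rownames(mat)]
  tab <- table(clade_vec)
  if (length(tab) < 2L) stop_invalid("need >= 2 clades")
  if (any(tab == 0L)) stop_invalid("empty clade in assignment")
  clade_vec
}

#' Find clade-specific variant positions in an alignment
#'
#' Classifies each alignment column against the clade-specific variant
#' rule: (i) the position carries an amino acid substitution in at least
#' one clade, and (ii) every substitution observed at the position is
#' strictly conserved within each clade. Operationally a column qualifies
#' when every clade is internally invariant (one residue per clade) and at
#' least two clades carry different residues; columns invariant across all
#' sequences are excluded. A clade containing a mix of gap and residue, or
#' any ambiguity code (X/B/Z/...), is treated as non-conserved; an all-gap
#' clade participates with residue `-`. Positions are 1-based uniform
#' alignment-column coordinates.
#'
#' @param aln Alignment: named character vector of equal-length aligned
#'   sequences, a `Biostrings::AAStringSet`, or a character matrix.
#' @param clades Clade assignment: data.frame (`sequence_id`, `clade`) or
#'   named character vector. Every sequence must be assigned; >= 2 clades,
#'   each non-empty.
#' @return A data.frame of class `clade_sites`, one row per clade-specific
#'   position, ordered by position: column `position` plus one residue
#'   column per clade.
#' @examples
#' fx <- b4_fixture_alignment(seed = 1)
#' find_clade_specific(fx$alignment, fx$clades)$position
#' @export
find_clade_specific <- function(aln, clades) {
  mat <- as_alignment_matrix(aln)
  clade_vec <- validate_scan_inputs(mat, as_clade_vector(clades))
  clade_names <- sort(unique(clade_vec))
  members <- lapply(clade_names, function(cl) which(clade_vec == cl))
  names(members) <- clade_names

  hits <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- vapply(members, function(m) clade_residue(col, m),
                  character(1))
    if (any(is.na(res))) next          # some clade not conserved
    if (length(unique(res)) < 2L) next # invariant across clades
    hits[[length(hits) + 1L]] <-
      c(list(position = j), as.list(res))
  }
  out <- if (length(hits) == 0L) {
    empty <- c(list(position = integer(0)),
               setNames(rep(list(character(0)), length(clade_names)),
                        clade_names))
    as.data.frame(empty, check.names = FALSE)
  } else {
    do.call(rbind, lapply(hits, as.data.frame))
  }
  rownames(out) <- NULL
  class(out) <- c("clade_sites", "data.frame")
  out
}

#' Positions distinguishing two clades
#'
#' Subset of clade-specific sites at which the two named clades carry
#' different residues. Symmetric in its clade arguments.
#'
#' @param sites A `clade_sites` data.frame from [find_clade_specific()].
#' @param cladeA,cladeB Clade labels (columns of `sites`).
#' @return Integer vector of positions (possibly empty).
#' @examples
#' fx <- b4_fixture_alignment(seed = 1)
#' sites <- find_clade_specific(fx$alignment, fx$clades)
#' pairwise_distinguishing(sites, "ABI3", "LEC2")
#' @export
pairwise_distinguishing <- function(sites, cladeA, cladeB) {
  stopifnot(is.data.frame(sites))
  clade_cols <- setdiff(names(sites), "position")
  for (cl in c(cladeA, cladeB)) {
    if (!cl %in% clade_cols) {
      stop_invalid("unknown clade label: ", cl, "; available: ",
                   paste(clade_cols, collapse = ", "))
    }
  }
  if (cladeA == cladeB || nrow(sites) == 0L) return(integer(0))
  sites$position[sites[[cladeA]] != sites[[cladeB]]]
}

#' Per-clade residues at selected positions
#'
#' Extracts the residue carried by each clade at the requested alignment
#' columns — by default the beta4-triad positions 64, 66 and 69. A clade
#' that is not internally conserved at a position is reported `NA` with a
#' warning; an all-gap clade is reported `-` with a warning.
#'
#' @param aln Alignment (see [find_clade_specific()]).
#' @param clades Clade assignment (see [find_clade_specific()]).
#' @param positions Integer positions, 1-based alignment coordinates.
#'   Default `c(64, 66, 69)`.
#' @return data.frame: one row per clade, columns `clade` then `pos<k>`
#'   for each requested position.
#' @examples
#' fx <- b4_fixture_alignment(seed = 1)
#' extract_triad(fx$alignment, fx$clades)
#' @export
extract_triad <- function(aln, clades, positions = c(64, 66, 69)) {
  mat <- as_alignment_matrix(aln)
  clade_vec <- validate_scan_inputs(mat, as_clade_vector(clades))
  if (any(positions < 1L) || any(positions > ncol(mat))) {
    stop_invalid("positions must lie in [1, ", ncol(mat), "]")
  }
  clade_names <- sort(unique(clade_vec))
  res <- sapply(positions, function(j) {
    col <- mat[, j]
    vapply(clade_names, function(cl) {
      r <- clade_residue(col, which(clade_vec == cl))
      if (is.na(r)) {
        warning("clade ", cl, " not conserved at position ", j,
                call. = FALSE)
      } else if (r == "-") {
        warning("clade ", cl, " is all-gap at position ", j, call. = FALSE)
      }
      r
    }, character(1))
  })
  res <- matrix(res, nrow = length(clade_names),
                dimnames = list(NULL, paste0("pos", positions)))
  out <- data.frame(clade = clade_names, res, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
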