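# Seeded generator for toy B3-style multiple sequence alignments with
# planted clade-specific variant columns.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specification of a toy alignment with planted clade-specific sites
#'
#' Builds an alignment of `n_clades * members_per_clade` sequences in which
#' exactly the planted columns satisfy the clade-specific variant rule
#' (within-clade invariant, >= 2 clades differing); all other columns are
#' either invariant across the whole alignment or scrambled so that at least
#' one clade is polymorphic.
#'
#' @param clades Character vector of clade labels (default the four B3
#'   clades ABI3, FUS3, LEC2, VAL1).
#' @param members_per_clade Sequences per clade, >= 1.
#' @param length Number of alignment columns.
#' @param planted_sites Named list: names are column positions (1-based),
#'   values are character vectors of per-clade residues named by clade.
#'   Each planted map must cover every clade and must not be identical
#'   across all clades.
#' @param n_scrambled Number of additional columns filled with i.i.d.
#'   residues (guaranteed within-clade polymorphic), to exercise rule
#'   violations. Default 0.
#' @param seed Integer seed.
#' @return An object of class `toy_alignment_spec`.
#' @export
toy_alignment_spec <- function(clades = c("ABI3", "FUS3", "LEC2", "VAL1"),
                               members_per_clade = 5L,
                               length = 110L,
                               planted_sites = list(),
                               n_scrambled = 0L,
                               seed = 1L) {
  if (length(clades) < 2L) stop_invalid("need >= 2 clades")
  if (members_per_clade < 1L) stop_invalid("members_per_clade must be >= 1")
  positions <- as.integer(names(planted_sites))
  if (length(planted_sites) > 0) {
    if (any(is.na(positions)) || any(positions < 1L) ||
        any(positions > length)) {
      stop_invalid("planted positions must lie within the alignment length")
    }
    for (pos in names(planted_sites)) {
      map <- planted_sites[[pos]]
      if (!all(clades %in% names(map))) {
        stop_invalid("planted site ", pos,
                     " must assign a residue to every clade")
      }
      if (length(unique(map[clades])) == 1L) {
        stop_invalid("planted site ", pos,
                     " is invariant across clades; not clade-specific")
      }
    }
  }
  structure(list(clades = clades,
                 members_per_clade = as.integer(members_per_clade),
                 length = as.integer(length),
                 planted_sites = planted_sites,
                 n_scrambled = as.integer(n_scrambled),
                 seed = as.integer(seed)),
            class = "toy_alignment_spec")
}

#' Generate a toy alignment with planted clade-specific sites
#'
#' @param spec A [toy_alignment_spec()].
#' @return A list with elements `alignment` (named character vector of
#'   aligned sequences) and `clades` (data.frame `sequence_id`, `clade`).
#' @examples
#' spec <- toy_alignment_spec(
#'   planted_sites = list(`64` = c(ABI3 = "R", FUS3 = "K",
#'                                 LEC2 = "K", VAL1 = "R")),
#'   seed = 11)
#' aln <- generate_toy_alignment(spec)
#' substr(aln$alignment[[1]], 64, 64)
#' @export
generate_toy_alignment <- function(spec) {
  stopifnot(inherits(spec, "toy_alignment_spec"))
  withr::with_seed(spec$seed, {
    n_seq <- length(spec$clades) * spec$members_per_clade
    clade_of <- rep(spec$clades, each = spec$members_per_clade)
    ids <- paste(clade_of,
                 rep(seq_len(spec$members_per_clade), length(spec$clades)),
                 sep = "_")
    # background: each column invariant across the whole alignment
    bg <- sample(AA20, spec$length, replace = TRUE)
    mat <- matrix(rep(bg, each = n_seq), nrow = n_seq)
    # plant clade-specific columns
    for (pos in names(spec$planted_sites)) {
      map <- spec$planted_sites[[pos]]
      mat[, as.integer(pos)] <- unname(map[clade_of])
    }
    # scrambled columns: i.i.d. residues, forced within-clade polymorphic
    free <- setdiff(seq_len(spec$length),
                    as.integer(names(spec$planted_sites)))
    if (spec$n_scrambled > 0L) {
      if (spec$members_per_clade < 2L) {
        stop_invalid("scrambled columns need >= 2 members per clade")
      }
      cols <- sample(free, spec$n_scrambled)
      for (j in cols) {
        mat[, j] <- sample(AA20, n_seq, replace = TRUE)
        # guarantee the first clade is polymorphic at this column
        r1 <- mat[1, j]
        mat[2, j] <- sample(setdiff(AA20, r1), 1)
      }
    }
    aln <- setNames(apply(mat, 1, paste, collapse = ""), ids)
    list(alignment = aln,
         clades = data.frame(sequence_id = ids, clade = clade_of))
  })
}

#' Faithful beta4-triad fixture alignment
#'
#' A toy four-clade B3 alignment planted with 16 clade-specific variant
#' columns arranged to mirror the published clade-specific variant map:
#' 8 positions distinguishing VAL1 from the three AFL clades, 6 positions
#' distinguishing FUS3 from ABI3, and 4 positions distinguishing ABI3 from
#' LEC2 — the latter including the beta4-triad at positions 64, 66, 69
#' (ABI3 R/R/P vs LEC2 K/K/S) and the L77V variant.
#'
#' @param members_per_clade Sequences per clade. Default 5.
#' @param seed Integer seed for the invariant background columns.
#' @return A list with elements `alignment`, `clades` and
#'   `planted_positions` (sorted integer vector of the 16 sites).
#' @examples
#' fx <- b4_fixture_alignment(seed = 2)
#' fx$planted_positions
#' @export
b4_fixture_alignment <- function(members_per_clade = 5L, seed = 1L) {
  site <- function(a, f, l, v) c(ABI3 = a, FUS3 = f, LEC2 = l, VAL1 = v)
  planted <- list(
    # VAL1 vs shared AFL residue (grey set, 8 sites)
    `5`  = site("T", "T", "T", "S"),
    `12` = site("I", "I", "I", "L"),
    `20` = site("E", "E", "E", "D"),
    `30` = site("Q", "Q", "Q", "E"),
    `40` = site("N", "N", "N", "D"),
    `50` = site("F", "F", "F", "Y"),
    `90` = site("S", "S", "S", "A"),
    `100` = site("K", "K", "K", "Q"),
    # FUS3-specific substitutions (4 sites; with 64 and 77 below,
    # FUS3 differs from ABI3 at 6 clade-specific positions)
    `26` = site("G", "R", "G", "G"),
    `33` = site("A", "S", "A", "A"),
    `45` = site("V", "I", "V", "V"),
    `55` = site("D", "E", "D", "D"),
    # positions distinguishing ABI3 and LEC2, incl. the beta4-triad
    `64` = site("R", "K", "K", "R"),
    `66` = site("R", "R", "K", "R"),
    `69` = site("P", "P", "S", "P"),
    `77` = site("L", "V", "V", "L"))
  spec <- toy_alignment_spec(members_per_clade = members_per_clade,
                             length = 110L, planted_sites = planted,
                             seed = seed)
  out <- generate_toy_alignment(spec)
  out$planted_positions <- sort(as.integer(names(planted)))
  out
}

#' Write / read alignments and clade maps
#'
#' Alignments are written as FASTA at 60 columns; clade assignments as a
#' two-column TSV (`sequence_id`, `clade`) without header.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param clades data.frame with columns `sequence_id`, `clade`.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the object.
#' @export
write_alignment_fasta <- function(alignment, path) {
  aa <- Biostrings::AAStringSet(alignment)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' @rdname write_alignment_fasta
#' @export
write_clade_map <- function(clades, path) {
  utils::write.table(clades[, c("sequence_id", "clade")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_clade_map <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sequence_id", "clade"))
  out
}
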