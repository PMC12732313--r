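# Reference-anchored residue-conservation census over a multiple
# sequence alignment: map reference positions (e.g. TxFKP G75, R79, K88,
# R597, D606, D767) to alignment columns, exclude rows that only align
# after a boundary position, score per-position conservation, and
# stratify the rows lacking residues by clade.

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA path.
#' @return a named character vector of gapped rows (validated for equal
#'   width and unique ids).
#' @export
read_alignment <- function(path) {
  aln <- read_protein_fasta(path)
  validate_alignment(aln)
  aln
}

validate_alignment <- function(aln) {
  stopifnot(is.character(aln), length(aln) >= 1, !is.null(names(aln)))
  if (anyDuplicated(names(aln)))
    stop("duplicate alignment row id(s)")
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows must all have the same width")
  invisible(aln)
}

# parse positions given as "G75" style strings or bare integers into a
# data.frame (position, expected); expected is NA for bare integers
parse_ref_positions <- function(positions) {
  if (is.numeric(positions)) {
    out <- data.frame(position = as.integer(positions),
                      expected = NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    m <- regmatches(positions,
                    regexec("^([A-Za-z])([0-9]+)$", positions))
    bad <- positions[vapply(m, length, 0L) != 3L]
    if (length(bad))
      stop("cannot parse position spec(s): ", paste(bad, collapse = ", "))
    out <- data.frame(
      position = as.integer(vapply(m, `[`, "", 3L)),
      expected = toupper(vapply(m, `[`, "", 2L)),
      stringsAsFactors = FALSE
    )
  }
  if (is.unsorted(out$position, strictly = TRUE))
    stop("reference positions must be strictly increasing")
  out
}

#' Map reference residue positions to alignment columns
#'
#' Resolves 1-based ungapped positions of the reference row to alignment
#' columns: the column for position `p` is the one at which the number
#' of non-gap reference characters in columns `1..c` first equals `p`.
#' If an expected residue is supplied (`"G75"` style), the reference row
#' must actually carry it at the resolved column.
#'
#' @param aln named character vector of gapped rows.
#' @param ref_id reference row id.
#' @param positions integer positions or `"G75"`-style strings.
#' @return a data.frame (`position`, `expected`, `column`) of class
#'   `ref_position_map`.
#' @examples
#' aln <- c(ref = "-A-C", other = "AAAC")
#' map_ref_positions(aln, "ref", 2)  # column 4
#' @export
map_ref_positions <- function(aln, ref_id, positions) {
  validate_alignment(aln)
  if (!ref_id %in% names(aln)) stop("reference row not found: ", ref_id)
  pos <- parse_ref_positions(positions)
  ref <- strsplit(aln[[ref_id]], "", fixed = TRUE)[[1L]]
  nongap <- ref != "-"
  ungapped_len <- sum(nongap)
  beyond <- pos$position[pos$position > ungapped_len]
  if (length(beyond))
    stop("position(s) beyond the reference ungapped length (",
         ungapped_len, "): ", paste(beyond, collapse = ", "))
  col_of <- which(nongap)
  pos$column <- col_of[pos$position]
  found <- toupper(ref[pos$column])
  has_exp <- !is.na(pos$expected)
  mismatch <- which(has_exp & found != pos$expected)
  if (length(mismatch))
    stop("reference residue mismatch at position ",
         paste0(pos$expected[mismatch], pos$position[mismatch],
                " (found ", found[mismatch], ")", collapse = ", "))
  pos$expected[!has_exp] <- found[!has_exp]
  class(pos) <- c("ref_position_map", class(pos))
  pos
}

#' Exclude rows that only align after a boundary position
#'
#' A row is excluded when it is gapped in *every* column corresponding
#' to reference positions `1..boundary` (the boundary position
#' included), i.e. its alignment to the reference begins strictly after
#' the boundary. The reference row is always retained.
#'
#' @param aln named character vector of gapped rows.
#' @param ref_id reference row id.
#' @param boundary reference position closing the prefix window.
#' @return character vector of retained row ids.
#' @export
apply_exclusion <- function(aln, ref_id, boundary) {
  validate_alignment(aln)
  if (!ref_id %in% names(aln)) stop("reference row not found: ", ref_id)
  stopifnot(is_count(boundary, positive = TRUE))
  ref <- strsplit(aln[[ref_id]], "", fixed = TRUE)[[1L]]
  col_of <- which(ref != "-")
  if (boundary > length(col_of))
    stop("boundary beyond the reference ungapped length")
  cols <- col_of[seq_len(boundary)]
  keep <- vapply(names(aln), function(id) {
    if (id == ref_id) return(TRUE)
    chars <- strsplit(aln[[id]], "", fixed = TRUE)[[1L]]
    any(chars[cols] != "-")
  }, NA)
  names(aln)[keep]
}

# per-row, per-position conservation (TRUE = identical residue,
# case-insensitive; gaps are non-conserved)
conservation_by_row <- function(aln, map, retained) {
  validate_alignment(aln)
  stopifnot(inherits(map, "ref_position_map"), length(retained) >= 1)
  missing <- setdiff(retained, names(aln))
  if (length(missing))
    stop("retained id(s) not in alignment: ",
         paste(missing, collapse = ", "))
  rows <- t(vapply(retained, function(id) {
    chars <- strsplit(aln[[id]], "", fixed = TRUE)[[1L]]
    toupper(chars[map$column]) == map$expected
  }, logical(nrow(map))))
  if (nrow(map) == 1L) rows <- matrix(rows, ncol = 1L,
                                      dimnames = list(retained, NULL))
  colnames(rows) <- paste0(map$expected, map$position)
  rows
}

#' Per-position conservation percentages
#'
#' For each mapped reference position, the percentage of retained rows
#' carrying the reference residue at the resolved column
#' (case-insensitive; a gap counts as non-conserved).
#'
#' @param aln named character vector of gapped rows.
#' @param map a [map_ref_positions()] result.
#' @param retained row ids to score (e.g. from [apply_exclusion()]).
#' @return a data.frame (`position`, `expected`, `column`,
#'   `pct_conserved`, `n_retained`).
#' @export
conservation_fraction <- function(aln, map, retained) {
  rows <- conservation_by_row(aln, map, retained)
  data.frame(position = map$position, expected = map$expected,
             column = map$column,
             pct_conserved = 100 * colMeans(rows),
             n_retained = length(retained),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratify residue-lacking rows by clade
#'
#' Among the rows non-conserved at one or more of the selected
#' positions, the fraction belonging to each clade (fractions sum to 1).
#'
#' @param row_conservation logical matrix from the census (rows x mapped
#'   positions), as produced internally by [conservation_fraction()];
#'   build it with `fkptools:::conservation_by_row()` or pass the same
#'   alignment/map/retained triple through `aln`, `map`, `retained`.
#' @param clades named clade labels covering every scored row.
#' @param positions optional column names (e.g. `c("G75","R79","K88")`)
#'   restricting the "lacking" test to a subset of positions.
#' @param aln,map,retained alternative input triple; used when
#'   `row_conservation` is `NULL`.
#' @return named numeric vector of per-clade fractions of lacking rows
#'   (empty, with a warning, when no row lacks anything).
#' @export
stratify_missing <- function(row_conservation = NULL, clades,
                             positions = NULL,
                             aln = NULL, map = NULL, retained = NULL) {
  if (is.null(row_conservation))
    row_conservation <- conservation_by_row(aln, map, retained)
  stopifnot(is.matrix(row_conservation), is.logical(row_conservation))
  ids <- rownames(row_conservation)
  unlabeled <- ids[!ids %in% names(clades)]
  if (length(unlabeled))
    stop("no clade label for row(s): ", paste(unlabeled, collapse = ", "))
  cols <- if (is.null(positions)) seq_len(ncol(row_conservation)) else {
    bad <- setdiff(positions, colnames(row_conservation))
    if (length(bad))
      stop("unknown position(s): ", paste(bad, collapse = ", "))
    positions
  }
  lacking <- ids[rowSums(!row_conservation[, cols, drop = FALSE]) > 0]
  if (length(lacking) == 0L) {
    warning("no rows lack any of the selected residues")
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- table(clades[lacking])
  frac <- as.numeric(tab) / length(lacking)
  stats::setNames(frac, names(tab))
}

#' Write a conservation census as TSV
#'
#' @param census data.frame from [conservation_fraction()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  utils::write.table(census, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
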