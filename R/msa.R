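#' Construct a multiple sequence alignment object
#'
#' An `msa` holds an aligned set of protein sequences as equal-length rows
#' over the 20 standard amino acids plus the gap character `-` and the
#' unknown-residue character `X`. Lowercase input is uppercased and the
#' alternative gap character `.` is normalized to `-`. Each record carries an
#' integer residue-numbering offset so that the first residue of a row is
#' numbered `offset + 1`; this emulates species-specific numbering schemes
#' that differ between homologs.
#'
#' @param seqs character vector of aligned rows (one string per sequence).
#' @param ids character vector of unique record identifiers; defaults to
#'   `names(seqs)`.
#' @param offsets integer residue-numbering offsets, recycled to the number
#'   of records. Default 0 (first residue numbered 1).
#' @return an object of class `msa` with fields `mat` (character matrix,
#'   rows = sequences), `ids`, `offsets`, `n`, `length`.
#' @seealso [read_alignment()], [derive_core_positions()]
#' @export
msa <- function(seqs, ids = names(seqs), offsets = 0L) {
  if (length(seqs) == 0L)
    cn_stop("alignment contains no sequences", "input_error")
  force(ids)  # resolve from `seqs` before it is normalized below
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    cn_stop("sequence ids must be unique", "input_error")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    cn_stop(sprintf("rows have unequal lengths (%s)",
                    paste(sort(unique(widths)), collapse = ", ")),
            "alignment_shape_error")
  if (widths[1] == 0L)
    cn_stop("alignment has zero columns", "alignment_shape_error")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  ok <- mat %in% c(AA_STANDARD, "-", "X")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow = nrow(mat)), arr.ind = TRUE)[1L, ]
    cn_stop(sprintf("illegal symbol '%s' in sequence '%s' at column %d",
                    mat[bad[1L], bad[2L]], ids[bad[1L]], bad[2L]),
            "alphabet_error")
  }
  rownames(mat) <- ids
  offsets <- as.integer(rep_len(offsets, length(ids)))
  names(offsets) <- ids
  structure(list(mat = mat, ids = ids, offsets = offsets,
                 n = nrow(mat), length = ncol(mat)),
            class = "msa")
}

#' Read an aligned FASTA file
#'
#' Reads an aligned protein FASTA file into an [msa()] object, validating
#' shape and alphabet. `.` gaps are normalized to `-` and lowercase letters
#' are uppercased.
#'
#' @param path path to an aligned FASTA file.
#' @param offsets per-sequence residue-numbering offsets (see [msa()]).
#' @return an `msa` object.
#' @export
read_alignment <- function(path, offsets = 0L) {
  if (!file.exists(path))
    cn_stop(sprintf("file not found: %s", path), "input_error")
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    cn_stop(sprintf("no sequences in %s", path), "input_error")
  ids <- sub("\\s.*$", "", names(set))
  msa(as.character(set), ids = ids, offsets = offsets)
}

#' Write an alignment to FASTA
#'
#' @param x an `msa` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  seqs <- apply(x$mat, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- x$ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns\n",
              x$n, x$length))
  gaps <- mean(x$mat == "-")
  cat(sprintf("  overall gap fraction: %.3f\n", gaps))
  invisible(x)
}

# Subset rows of an msa, preserving columns and offsets.
msa_rows <- function(x, idx) {
  mat <- x$mat[idx, , drop = FALSE]
  structure(list(mat = mat, ids = rownames(mat),
                 offsets = x$offsets[rownames(mat)],
                 n = nrow(mat), length = ncol(mat)),
            class = "msa")
}

#' Derive core alignment positions
#'
#' Core positions are the structurally conserved alignment columns on which
#' the super-family position numbering ("3D numbers") is defined; loop-like,
#' gap-rich columns are excluded. In the absence of structural superposition
#' the core is approximated by the per-column gap fraction: a column is core
#' when its fraction of `-`/`X` cells is at most `max_gap_frac`. The k-th
#' core column (in alignment order) receives 3D number k.
#'
#' @param x an `msa` object.
#' @param max_gap_frac maximum tolerated gap fraction per column (default
#'   0.3).
#' @return an integer vector of class `core_positions`: alignment column
#'   indices in increasing order, with attribute `gap_fraction`. The 3D
#'   number of a core column is its index in this vector.
#' @export
derive_core_positions <- function(x, max_gap_frac = 0.3) {
  stopifnot(inherits(x, "msa"), max_gap_frac >= 0, max_gap_frac <= 1)
  gap_frac <- colMeans(x$mat == "-" | x$mat == "X")
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) == 0L)
    cn_stop("no column satisfies the core gap-fraction threshold",
            "empty_core_error")
  structure(as.integer(keep), gap_fraction = unname(gap_frac[keep]),
            max_gap_frac = max_gap_frac, class = "core_positions")
}

#' @export
print.core_positions <- function(x, ...) {
  cat(sprintf("%d core positions (gap fraction <= %.2f) of alignment columns %d..%d\n",
              length(x), attr(x, "max_gap_frac"), min(x), max(x)))
  invisible(x)
}

#' Tabulate core positions
#'
#' @param x a `core_positions` object.
#' @param ... unused.
#' @return data frame with columns `d3_number`, `alignment_column`,
#'   `gap_fraction`.
#' @export
as.data.frame.core_positions <- function(x, ...) {
  data.frame(d3_number = seq_along(x),
             alignment_column = as.integer(x),
             gap_fraction = attr(x, "gap_fraction"))
}

#' Write the core-position table as TSV
#'
#' @param core a `core_positions` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_core_positions <- function(core, path) {
  write.table(as.data.frame(core), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Row index for a sequence id, with a classed error.
row_index <- function(x, seq_id) {
  i <- match(seq_id, x$ids)
  if (is.na(i))
    cn_stop(sprintf("unknown sequence id '%s'", seq_id), "unknown_id_error")
  i
}

#' Map a per-protein residue number to its 3D number
#'
#' Locates the alignment column holding the `residue_number`-th non-gap
#' symbol of the sequence (after subtracting the sequence's numbering
#' offset) and returns the 3D number of that column, or `NA` when the
#' column is not a core column. The alignment column is attached as the
#' `column` attribute either way, so non-core hits remain inspectable.
#'
#' @param x an `msa` object.
#' @param core a `core_positions` object for `x`.
#' @param seq_id sequence identifier.
#' @param residue_number residue number in the sequence's own numbering.
#' @return integer 3D number, or `NA` (not core), with attribute `column`.
#' @export
map_residue_to_3d <- function(x, core, seq_id, residue_number) {
  i <- row_index(x, seq_id)
  k <- as.integer(residue_number) - x$offsets[[seq_id]]
  row <- x$mat[i, ]
  nongap <- which(row != "-")
  if (k < 1L || k > length(nongap))
    cn_stop(sprintf("residue number %d out of range for '%s'",
                    residue_number, seq_id), "range_error")
  col <- nongap[k]
  d3 <- match(col, core)
  structure(if (is.na(d3)) NA_integer_ else as.integer(d3), column = col)
}

#' Map a 3D number to a sequence's residue number and amino acid
#'
#' Inverse of [map_residue_to_3d()] for non-gap cells. If the sequence is
#' gapped at the core column, the gap outcome is reported via
#' `residue_number = NA`, `aa = NA`, `gap = TRUE`.
#'
#' @param x an `msa` object.
#' @param core a `core_positions` object for `x`.
#' @param seq_id sequence identifier.
#' @param d3_number 3D number (1-based index into `core`).
#' @return list with `residue_number`, `aa`, `gap`, `column`.
#' @export
map_3d_to_residue <- function(x, core, seq_id, d3_number) {
  i <- row_index(x, seq_id)
  if (d3_number < 1L || d3_number > length(core))
    cn_stop(sprintf("3D number %d out of range (core has %d positions)",
                    d3_number, length(core)), "range_error")
  col <- core[[d3_number]]
  row <- x$mat[i, ]
  aa <- row[[col]]
  if (aa == "-")
    return(list(residue_number = NA_integer_, aa = NA_character_,
                gap = TRUE, column = col))
  resnum <- sum(row[seq_len(col)] != "-") + x$offsets[[seq_id]]
  list(residue_number = as.integer(resnum), aa = aa, gap = FALSE,
       column = col)
}

#' Residue distribution at a core position
#'
#' Counts the 20 standard amino acids at a core column over all rows or a
#' subset of rows. Gaps and `X` are excluded from the counts and reported
#' only through `n_nongap`.
#'
#' @param x an `msa` object.
#' @param core a `core_positions` object for `x`.
#' @param d3_number 3D number of the position.
#' @param subset_ids optional character vector of record ids to restrict to.
#' @return object of class `residue_distribution`: list with `position`,
#'   `counts` (named integer vector over the 20 amino acids), `n_nongap`.
#' @export
column_distribution <- function(x, core, d3_number, subset_ids = NULL) {
  stopifnot(inherits(x, "msa"))
  if (d3_number < 1L || d3_number > length(core))
    cn_stop("3D number out of range", "range_error")
  col <- core[[d3_number]]
  rows <- if (is.null(subset_ids)) seq_len(x$n)
          else vapply(subset_ids, row_index, integer(1L), x = x)
  if (length(rows) == 0L)
    cn_stop("empty sequence subset", "input_error")
  chars <- x$mat[rows, col]
  counts <- table(factor(chars, levels = AA_STANDARD))
  counts <- setNames(as.integer(counts), AA_STANDARD)
  structure(list(position = as.integer(d3_number), counts = counts,
                 n_nongap = sum(counts)),
            class = "residue_distribution")
}

#' @export
print.residue_distribution <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  nz <- nz[order(-nz, names(nz))]
  cat(sprintf("Residue distribution at 3D position %d (n = %d):\n",
              x$position, x$n_nongap))
  print(nz)
  invisible(x)
}

#' Relative residue frequencies of a distribution
#'
#' @param dist a `residue_distribution`.
#' @return named numeric vector summing to 1 over the observed residues.
#' @export
residue_frequencies <- function(dist) {
  stopifnot(inherits(dist, "residue_distribution"))
  if (dist$n_nongap == 0L)
    cn_stop("distribution has no non-gap residues", "input_error")
  dist$counts / dist$n_nongap
}
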