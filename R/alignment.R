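#' Construct a protein alignment from gapped sequences
#'
#' An alignment is a tibble with one row per sequence and columns `seq_id`,
#' `taxon_label` and `residues` (the gapped sequence). All rows must have
#' equal length; the gap character is `-`. The dialect gap characters `.`
#' and `*` are normalized to `-` on construction, and lower-case residues
#' are upper-cased. `X` is kept as an unknown residue.
#'
#' Alignment columns are numbered 1-based and spans are inclusive on both
#' ends, matching the convention used in all reports.
#'
#' @param sequences named character vector of gapped sequences; names are
#'   the sequence ids.
#' @param taxon_labels optional character vector of display labels, one per
#'   sequence (defaults to the ids).
#' @return a tibble of class `csi_alignment` with attribute `n_cols`.
#' @examples
#' aln <- alignment(c(a = "AC-D", b = "ACED"))
#' n_cols(aln)
#' @export
alignment <- function(sequences, taxon_labels = NULL) {
  if (length(sequences) < 2L) {
    abort("an alignment needs at least 2 sequences")
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort("`sequences` must be a named character vector (names are seq ids)")
  }
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate seq_id: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(unname(sequences))
  # '.' and '*' are gap dialects; normalize before validation
  seqs <- chartr(".*", "--", seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1L]][1L]
    abort(paste0(
      "alignment is not rectangular: row '", bad, "' has length ",
      nchar(seqs[ids == bad][1L]), " but row '", ids[1L], "' has length ",
      widths[1L]
    ))
  }
  ok <- c(AA_RESIDUES, "X", GAP)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad_at <- which(!chars %in% ok)
    if (length(bad_at)) {
      abort(paste0(
        "invalid character '", chars[bad_at[1L]], "' in row '", ids[i],
        "' at column ", bad_at[1L]
      ))
    }
  }
  labels <- taxon_labels %||% ids
  out <- tibble(
    seq_id = ids,
    taxon_label = as.character(labels),
    residues = seqs
  )
  new_alignment(out, n_cols = widths[1L])
}

new_alignment <- function(df, n_cols) {
  structure(
    as_tibble(df),
    n_cols = as.integer(n_cols),
    class = c("csi_alignment", class(tibble()))
  )
}

#' Number of columns in an alignment
#' @param alignment a `csi_alignment`.
#' @return integer alignment length in columns.
#' @export
n_cols <- function(alignment) {
  attr(alignment, "n_cols", exact = TRUE)
}

#' Read an aligned protein FASTA file
#'
#' Reads a pre-aligned FASTA file into a [alignment()] tibble. The FASTA id
#' (first whitespace-delimited token of the header) becomes `seq_id`; the
#' remainder of the header, if any, becomes `taxon_label`. Ragged rows,
#' empty files and non-amino-acid characters are errors; `.`/`*` gaps are
#' normalized to `-`.
#'
#' @param path path to an aligned FASTA file.
#' @return a `csi_alignment` tibble.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("alignment file is empty: ", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  labels <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    ids
  )
  seqs <- as.character(set)
  names(seqs) <- ids
  alignment(seqs, taxon_labels = labels)
}

#' Write an alignment to FASTA
#'
#' Inverse of [read_alignment()] for normalized alignments: headers are
#' `seq_id` followed by `taxon_label` when the label differs from the id.
#'
#' @param alignment a `csi_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  headers <- ifelse(
    alignment$taxon_label == alignment$seq_id,
    alignment$seq_id,
    paste(alignment$seq_id, alignment$taxon_label)
  )
  set <- Biostrings::BStringSet(alignment$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Map an alignment column to an ungapped residue position
#'
#' Returns the 1-based count of non-gap residues of `seq_id` in columns
#' `1..column`. If the residue at `column` is itself a gap, this is the
#' position of the nearest preceding residue (0 if there is none), which is
#' the convention used to anchor reports on a reference sequence.
#'
#' @param alignment a `csi_alignment`.
#' @param seq_id sequence id to index on.
#' @param column 1-based alignment column.
#' @return integer residue position (0 when no residue at or before
#'   `column`).
#' @export
ungapped_index <- function(alignment, seq_id, column) {
  row <- alignment$residues[alignment$seq_id == seq_id]
  if (length(row) != 1L) {
    abort(paste0("unknown seq_id: ", seq_id))
  }
  if (column < 1L || column > nchar(row)) {
    abort(paste0("column ", column, " outside alignment 1..", nchar(row)))
  }
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  sum(chars[seq_len(column)] != GAP)
}

#' Gap-free alignment length under complete deletion
#'
#' Number of columns containing no gap in any row — the column count that
#' survives the "complete deletion" treatment conventionally applied before
#' phylogenetic inference.
#'
#' @param alignment a `csi_alignment`.
#' @return integer count of gap-free columns.
#' @examples
#' complete_deletion_length(alignment(c(a = "AC-E", b = "ACDE")))
#' @export
complete_deletion_length <- function(alignment) {
  m <- aln_matrix(alignment)
  sum(colSums(m == GAP) == 0L)
}

#' @export
print.csi_alignment <- function(x, ...) {
  cat(
    "# Protein alignment: ", nrow(x), " sequences x ", n_cols(x),
    " columns\n",
    sep = ""
  )
  NextMethod()
}
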