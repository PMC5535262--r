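#' Find partition-discriminating indel candidates
#'
#' Scans alignment columns for the gap patterns that distinguish the
#' in-group from the out-group. A column is an insert-candidate column
#' when at least `outgroup_absence_fraction` of out-group rows are gapped
#' and at least one in-group row carries a residue; a deletion-candidate
#' column is the exact mirror (in-group gapped, out-group carrying), so
#' swapping the groups maps inserts to deletions with identical spans.
#'
#' Maximal runs of same-type candidate columns (optionally bridging up to
#' `merge_gap_cols` non-candidate columns) form candidate regions. A region
#' is kept only if the fraction of carrier-group rows holding at least one
#' residue anywhere in it reaches `ingroup_presence_fraction` (assessed on
#' the in-group for inserts, the out-group for deletions). Applying the
#' presence test region-wise rather than column-wise lets length-variable
#' indels — different in-group rows carrying, say, 43 or 44 residues —
#' surface as a single candidate spanning the full block.
#'
#' @inheritParams conservation_profile
#' @return tibble of candidates sorted by span start: `candidate_id`,
#'   `type` (`"insert"`/`"deletion"`), `col_start`, `col_end` (1-based,
#'   inclusive), and `per_row_lengths`, a list column of named integer
#'   vectors giving each partition row's non-gap residue count within the
#'   span.
#' @export
find_indel_candidates <- function(alignment, partition,
                                  config = scan_config()) {
  in_ids <- group_ids(alignment, partition, "ingroup")
  out_ids <- group_ids(alignment, partition, "outgroup")
  m <- aln_matrix(alignment)[c(in_ids, out_ids), , drop = FALSE]
  gap <- m == GAP
  in_gap <- gap[in_ids, , drop = FALSE]
  out_gap <- gap[out_ids, , drop = FALSE]

  q <- config$outgroup_absence_fraction
  ins_col <- colMeans(out_gap) >= q & colSums(!in_gap) > 0L
  del_col <- colMeans(in_gap) >= q & colSums(!out_gap) > 0L

  regions <- dplyr::bind_rows(
    candidate_runs(ins_col, config$merge_gap_cols, "insert"),
    candidate_runs(del_col, config$merge_gap_cols, "deletion")
  )
  if (nrow(regions) == 0L) {
    return(empty_candidates())
  }

  p <- config$ingroup_presence_fraction
  keep <- logical(nrow(regions))
  lengths <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    span <- regions$col_start[i]:regions$col_end[i]
    res_count <- rowSums(!gap[, span, drop = FALSE])
    carrier_ids <- if (regions$type[i] == "insert") in_ids else out_ids
    keep[i] <- mean(res_count[carrier_ids] > 0L) >= p
    lengths[[i]] <- res_count
  }
  regions$per_row_lengths <- lengths
  regions <- regions[keep, , drop = FALSE]
  regions <- dplyr::arrange(regions, .data$col_start, .data$type)
  regions$candidate_id <- seq_len(nrow(regions))
  dplyr::select(
    regions, "candidate_id", "type", "col_start", "col_end",
    "per_row_lengths"
  )
}

empty_candidates <- function() {
  tibble(
    candidate_id = integer(0),
    type = character(0),
    col_start = integer(0),
    col_end = integer(0),
    per_row_lengths = list()
  )
}

# maximal TRUE runs in `mask`, merging runs separated by <= bridge FALSEs
candidate_runs <- function(mask, bridge, type) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(
    col_start = starts[r$values],
    col_end = ends[r$values]
  )
  if (nrow(runs) > 1L && bridge > 0L) {
    merged_start <- runs$col_start[1L]
    out_s <- integer(0)
    out_e <- integer(0)
    cur_e <- runs$col_end[1L]
    for (i in seq_len(nrow(runs))[-1L]) {
      if (runs$col_start[i] - cur_e - 1L <= bridge) {
        cur_e <- runs$col_end[i]
      } else {
        out_s <- c(out_s, merged_start)
        out_e <- c(out_e, cur_e)
        merged_start <- runs$col_start[i]
        cur_e <- runs$col_end[i]
      }
    }
    runs <- tibble(
      col_start = c(out_s, merged_start),
      col_end = c(out_e, cur_e)
    )
  }
  if (nrow(runs)) runs$type <- type else runs$type <- character(0)
  runs
}
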