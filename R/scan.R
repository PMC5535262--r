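#' Count conserved flank columns around a candidate
#'
#' Walks outward from each side of the candidate span, column by column,
#' until `flank_window_aa` residues of the reference sequence have been
#' passed (or the alignment edge is reached), and counts how many of the
#' traversed columns are conserved. The neighborhood is measured in
#' reference residues, not raw columns, because the published criterion
#' counts amino acids.
#'
#' @param alignment a `csi_alignment`.
#' @param candidate one row of [find_indel_candidates()] output (or any
#'   list with `col_start`/`col_end`).
#' @param profile a [conservation_profile()].
#' @param config a [scan_config()].
#' @param reference_id the reference row whose residues delimit the
#'   window.
#' @return named integer vector `c(left = , right = )`.
#' @export
score_flanks <- function(alignment, candidate, profile, config,
                         reference_id) {
  row <- alignment$residues[alignment$seq_id == reference_id]
  if (length(row) != 1L) {
    abort(paste0("reference_id not in alignment: ", reference_id))
  }
  ref <- strsplit(row, "", fixed = TRUE)[[1L]]
  left_cols <- flank_columns(
    ref, candidate$col_start - 1L, -1L, config$flank_window_aa
  )
  right_cols <- flank_columns(
    ref, candidate$col_end + 1L, 1L, config$flank_window_aa
  )
  c(
    left = sum(profile$is_conserved[left_cols]),
    right = sum(profile$is_conserved[right_cols])
  )
}

# columns traversed walking from `from` in direction `step` until `window`
# reference residues have been seen (truncated at the alignment edge)
flank_columns <- function(ref, from, step, window) {
  cols <- integer(0)
  seen <- 0L
  j <- from
  while (j >= 1L && j <= length(ref) && seen < window) {
    cols <- c(cols, j)
    if (ref[j] != GAP) seen <- seen + 1L
    j <- j + step
  }
  cols
}

#' Classify the specificity of a candidate indel
#'
#' An insert is `exclusive` when every out-group row is fully gapped over
#' the span; out-group rows carrying one or more residues there are
#' exceptions and demote the call to `shared_with_exceptions`. For a
#' deletion the mirror applies: out-group rows that are also fully gapped
#' over the span share the deletion and are the exceptions. Exceptions are
#' always enumerated, never silently passed.
#'
#' @inheritParams score_flanks
#' @param partition a `csi_partition`.
#' @return list with `specificity` (`"exclusive"` or
#'   `"shared_with_exceptions"`) and `exception_ids` (character, in
#'   alignment row order).
#' @export
classify_specificity <- function(alignment, candidate, partition,
                                 config = scan_config()) {
  out_ids <- group_ids(alignment, partition, "outgroup")
  span <- candidate$col_start:candidate$col_end
  m <- aln_matrix(alignment)[out_ids, span, drop = FALSE]
  res_count <- rowSums(m != GAP)
  exceptions <- if (candidate$type == "insert") {
    out_ids[res_count > 0L]
  } else {
    out_ids[res_count == 0L]
  }
  list(
    specificity = if (length(exceptions)) "shared_with_exceptions" else
      "exclusive",
    exception_ids = exceptions
  )
}

#' Scan an alignment for conserved signature indels
#'
#' The full CSI procedure: build the column conservation profile, find
#' partition-discriminating indel candidates, discard candidates lacking
#' at least `min_flank_conserved` conserved columns on either side within
#' the flank window, classify the survivors' specificity, and anchor each
#' call on the reference sequence. Zero calls is a normal outcome.
#'
#' @inheritParams conservation_profile
#' @param reference_id reference row for flank windows and reported
#'   positions; defaults to the first in-group row present in the
#'   alignment.
#' @return a tibble of class `csi_scan`, one row per reported CSI, sorted
#'   by span start: `call_id`, `type`, `col_start`, `col_end`,
#'   `reference_id`, `reference_position` (1-based ungapped residue
#'   immediately preceding the span; 0 at the alignment start),
#'   `length_min`/`length_max` (indel length over carrier rows, e.g.
#'   "43 or 44"), `left_flank_conserved`, `right_flank_conserved`,
#'   `specificity`, `exception_ids` and `per_row_lengths` (list columns).
#'   Candidates rejected by the flank filter are recorded in
#'   `attr(, "rejected")`; see also [glance.csi_scan()].
#' @export
scan_csi <- function(alignment, partition, config = scan_config(),
                     reference_id = NULL) {
  in_ids <- group_ids(alignment, partition, "ingroup")
  reference_id <- reference_id %||% in_ids[1L]
  if (!reference_id %in% alignment$seq_id) {
    abort(paste0("reference_id not in alignment: ", reference_id))
  }
  profile <- conservation_profile(alignment, partition, config)
  candidates <- find_indel_candidates(alignment, partition, config)
  out_ids <- group_ids(alignment, partition, "outgroup")

  calls <- list()
  rejected <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    flanks <- score_flanks(alignment, cand, profile, config, reference_id)
    if (any(flanks < config$min_flank_conserved)) {
      rejected[[length(rejected) + 1L]] <- tibble(
        type = cand$type, col_start = cand$col_start,
        col_end = cand$col_end,
        left_flank_conserved = flanks[["left"]],
        right_flank_conserved = flanks[["right"]]
      )
      next
    }
    spec <- classify_specificity(alignment, cand, partition, config)
    lens <- cand$per_row_lengths[[1L]]
    carrier_ids <- if (cand$type == "insert") in_ids else out_ids
    carrier_lens <- lens[carrier_ids]
    carrier_lens <- carrier_lens[carrier_lens > 0L]
    if (length(carrier_lens) == 0L) carrier_lens <- 0L
    ref_pos <- if (cand$col_start == 1L) 0L else {
      ungapped_index(alignment, reference_id, cand$col_start - 1L)
    }
    calls[[length(calls) + 1L]] <- tibble(
      type = cand$type,
      col_start = cand$col_start,
      col_end = cand$col_end,
      reference_id = reference_id,
      reference_position = ref_pos,
      length_min = as.integer(min(carrier_lens)),
      length_max = as.integer(max(carrier_lens)),
      left_flank_conserved = flanks[["left"]],
      right_flank_conserved = flanks[["right"]],
      specificity = spec$specificity,
      exception_ids = list(spec$exception_ids),
      per_row_lengths = list(lens)
    )
  }
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0L) calls <- empty_calls()
  calls <- dplyr::arrange(calls, .data$col_start, .data$type)
  calls$call_id <- seq_len(nrow(calls))
  calls <- dplyr::relocate(calls, "call_id")
  structure(
    calls,
    rejected = dplyr::bind_rows(rejected),
    reference_id = reference_id,
    n_candidates = nrow(candidates),
    n_cols = n_cols(alignment),
    config = config,
    class = c("csi_scan", class(tibble()))
  )
}

empty_calls <- function() {
  tibble(
    type = character(0), col_start = integer(0), col_end = integer(0),
    reference_id = character(0), reference_position = integer(0),
    length_min = integer(0), length_max = integer(0),
    left_flank_conserved = integer(0), right_flank_conserved = integer(0),
    specificity = character(0), exception_ids = list(),
    per_row_lengths = list()
  )
}

#' @export
print.csi_scan <- function(x, ...) {
  rej <- attr(x, "rejected", exact = TRUE)
  cat(
    "# CSI scan: ", nrow(x), " call(s) from ",
    attr(x, "n_candidates", exact = TRUE), " candidate(s), ",
    if (is.null(rej)) 0L else nrow(rej), " rejected by flank filter\n",
    sep = ""
  )
  NextMethod()
}

#' Tidy a CSI scan result
#'
#' @param x a `csi_scan`.
#' @param ... unused.
#' @return a plain tibble with one row per call, list columns flattened
#'   (`exception_ids` semicolon-joined, `per_row_lengths` dropped).
#' @method tidy csi_scan
#' @export
tidy.csi_scan <- function(x, ...) {
  as_tibble(x) |>
    dplyr::mutate(
      exception_ids = map_chr(
        .data$exception_ids, paste, collapse = ";"
      )
    ) |>
    dplyr::select(-"per_row_lengths")
}

#' One-line summary of a CSI scan
#'
#' @param x a `csi_scan`.
#' @param ... unused.
#' @return one-row tibble: candidates found, rejected by the flank filter,
#'   calls emitted, and the split by specificity class.
#' @method glance csi_scan
#' @export
glance.csi_scan <- function(x, ...) {
  rej <- attr(x, "rejected", exact = TRUE)
  tibble(
    n_candidates = attr(x, "n_candidates", exact = TRUE),
    n_rejected_flanks = if (is.null(rej)) 0L else nrow(rej),
    n_calls = nrow(x),
    n_exclusive = sum(x$specificity == "exclusive"),
    n_shared_with_exceptions =
      sum(x$specificity == "shared_with_exceptions")
  )
}

#' Plot CSI calls along the alignment
#'
#' @param object a `csi_scan`.
#' @param ... unused.
#' @return a ggplot showing each call's span as a segment along the
#'   alignment, colored by indel type and shaped by specificity.
#' @method autoplot csi_scan
#' @export
autoplot.csi_scan <- function(object, ...) {
  df <- tidy.csi_scan(object)
  nc <- attr(object, "n_cols", exact = TRUE)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      y = factor(.data$call_id), yend = factor(.data$call_id),
      x = .data$col_start, xend = .data$col_end, color = .data$type
    )
  ) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::geom_point(
      ggplot2::aes(shape = .data$specificity), size = 3
    ) +
    ggplot2::xlim(1, nc) +
    ggplot2::labs(
      x = "alignment column", y = "CSI call",
      title = "Conserved signature indels"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
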