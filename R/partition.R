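#' Define an in-group / out-group taxon partition
#'
#' The partition names the clade whose signatures are sought (in-group)
#' and the reference taxa used to establish exclusivity (out-group). Ids
#' assigned to both groups are an error. Ids absent from the alignment are
#' tolerated — they mirror species that lack the homolog — and are recorded
#' in the `missing` attribute rather than raised.
#'
#' @param ingroup character vector of in-group seq ids.
#' @param outgroup character vector of out-group seq ids.
#' @param alignment optional `csi_alignment` to validate against.
#' @return a tibble of class `csi_partition` with columns `seq_id`,
#'   `group` and attribute `missing`.
#' @export
taxon_partition <- function(ingroup, outgroup, alignment = NULL) {
  ingroup <- unique(as.character(ingroup))
  outgroup <- unique(as.character(outgroup))
  if (length(ingroup) == 0L) abort("in-group is empty")
  if (length(outgroup) == 0L) abort("out-group is empty")
  both <- intersect(ingroup, outgroup)
  if (length(both)) {
    abort(paste0(
      "id(s) assigned to both groups: ", paste(both, collapse = ", ")
    ))
  }
  missing <- character(0)
  if (!is.null(alignment)) {
    missing <- setdiff(c(ingroup, outgroup), alignment$seq_id)
    if (length(setdiff(ingroup, missing)) == 0L) {
      abort("no in-group id is present in the alignment")
    }
    if (length(setdiff(outgroup, missing)) == 0L) {
      abort("no out-group id is present in the alignment")
    }
  }
  out <- tibble(
    seq_id = c(ingroup, outgroup),
    group = rep(c("ingroup", "outgroup"), c(length(ingroup), length(outgroup)))
  )
  structure(
    out,
    missing = missing,
    class = c("csi_partition", class(tibble()))
  )
}

#' Read a taxon partition file
#'
#' Reads either a two-column TSV (`seq_id<TAB>group`, group one of
#' `ingroup`/`outgroup`) or, when `outgroup_path` is given, two plain id
#' lists (one id per line: `path` holds the in-group, `outgroup_path` the
#' out-group).
#'
#' @param path TSV partition file, or in-group id list.
#' @param alignment the `csi_alignment` the partition applies to.
#' @param outgroup_path optional out-group id list file.
#' @return a `csi_partition`; ids missing from the alignment are collected
#'   in `attr(, "missing")` (see [missing_homologs()]).
#' @export
read_partition <- function(path, alignment, outgroup_path = NULL) {
  if (!file.exists(path)) abort(paste0("partition file not found: ", path))
  if (!is.null(outgroup_path)) {
    ing <- readLines(path, warn = FALSE)
    out <- readLines(outgroup_path, warn = FALSE)
    return(taxon_partition(
      trimws(ing[nzchar(trimws(ing))]),
      trimws(out[nzchar(trimws(out))]),
      alignment
    ))
  }
  df <- utils::read.table(
    path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    col.names = c("seq_id", "group"), comment.char = "#",
    strip.white = TRUE
  )
  bad <- setdiff(unique(df$group), c("ingroup", "outgroup"))
  if (length(bad)) {
    abort(paste0(
      "unknown group label(s): ", paste(bad, collapse = ", "),
      " (expected 'ingroup' or 'outgroup')"
    ))
  }
  dup <- df |>
    dplyr::distinct(.data$seq_id, .data$group) |>
    dplyr::count(.data$seq_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(paste0(
      "id(s) assigned to both groups: ", paste(dup$seq_id, collapse = ", ")
    ))
  }
  taxon_partition(
    df$seq_id[df$group == "ingroup"],
    df$seq_id[df$group == "outgroup"],
    alignment
  )
}

#' Partition ids with no homolog in the alignment
#'
#' @param partition a `csi_partition` built against an alignment.
#' @return character vector of ids that were assigned to a group but are
#'   absent from the alignment (e.g. species lacking the homolog).
#' @export
missing_homologs <- function(partition) {
  attr(partition, "missing", exact = TRUE) %||% character(0)
}

# ids of a group that are actually present in the alignment, in row order
group_ids <- function(alignment, partition, group) {
  wanted <- partition$seq_id[partition$group == group]
  alignment$seq_id[alignment$seq_id %in% wanted]
}
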