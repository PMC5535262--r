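#' Scan configuration
#'
#' All thresholds of the CSI scan in one object. The defaults implement the
#' strict published criteria: an indel must be present in every in-group
#' homolog, absent from every out-group homolog, and flanked on both sides
#' by at least 5 conserved residues within the neighboring 40 residues of
#' the reference sequence.
#'
#' @param flank_window_aa residues of the reference sequence on each side
#'   of a candidate within which conserved columns are counted (default 40;
#'   30 is the other conventional choice).
#' @param min_flank_conserved minimum conserved columns required on each
#'   side for a candidate to be reported (default 5; the bound is
#'   inclusive).
#' @param conservation_fraction minimum share of all partition rows that
#'   must carry a column's majority residue for the column to count as
#'   conserved (default 0.8; 1.0 demands strict identity). Gaps and `X`
#'   count in the denominator, never as matches.
#' @param ingroup_presence_fraction minimum share of in-group rows that
#'   must carry at least one residue inside an insert region (default 1.0
#'   = "exclusively found"; mirrored to the out-group for deletions).
#' @param outgroup_absence_fraction minimum per-column share of out-group
#'   rows that must be gapped inside an insert region (default 1.0;
#'   mirrored to the in-group for deletions).
#' @param merge_gap_cols maximum run of non-discriminating columns bridged
#'   when merging adjacent candidate columns of the same type (default 0).
#' @return a list of class `csi_scan_config`.
#' @export
scan_config <- function(flank_window_aa = 40L,
                        min_flank_conserved = 5L,
                        conservation_fraction = 0.8,
                        ingroup_presence_fraction = 1.0,
                        outgroup_absence_fraction = 1.0,
                        merge_gap_cols = 0L) {
  cfg <- list(
    flank_window_aa = as.integer(flank_window_aa),
    min_flank_conserved = as.integer(min_flank_conserved),
    conservation_fraction = as.numeric(conservation_fraction),
    ingroup_presence_fraction = as.numeric(ingroup_presence_fraction),
    outgroup_absence_fraction = as.numeric(outgroup_absence_fraction),
    merge_gap_cols = as.integer(merge_gap_cols)
  )
  if (cfg$flank_window_aa < 0L) abort("flank_window_aa must be >= 0")
  if (cfg$min_flank_conserved < 0L) abort("min_flank_conserved must be >= 0")
  if (cfg$min_flank_conserved > cfg$flank_window_aa) {
    abort("min_flank_conserved must be <= flank_window_aa")
  }
  for (f in c(
    "conservation_fraction", "ingroup_presence_fraction",
    "outgroup_absence_fraction"
  )) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) {
      abort(paste0(f, " must be in (0, 1]"))
    }
  }
  if (cfg$merge_gap_cols < 0L) abort("merge_gap_cols must be >= 0")
  structure(cfg, class = "csi_scan_config")
}

#' Read a scan configuration from YAML
#'
#' Unknown keys are an error; omitted keys take the [scan_config()]
#' defaults.
#'
#' @param path YAML file with any subset of the [scan_config()] fields.
#' @return a `csi_scan_config`.
#' @export
read_scan_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(scan_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  do.call(scan_config, vals)
}

#' @export
print.csi_scan_config <- function(x, ...) {
  cat("# CSI scan configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
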