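#' Run the full CSI discovery pipeline
#'
#' Reads an aligned FASTA and a taxon partition, scans for conserved
#' signature indels, and writes `calls.tsv`, `calls.json`, `report.txt`
#' (signature renderings) and `manifest.json` into `out_dir`. The run is
#' fully deterministic — no pipeline stage consumes randomness — so
#' identical inputs produce byte-identical outputs. Zero calls is a normal,
#' successful outcome. Every candidate rejected by the flank filter is
#' logged to the console with its conserved-flank counts unless `quiet`.
#'
#' @param alignment_path aligned protein FASTA.
#' @param partition_path TSV partition file (`seq_id<TAB>group`).
#' @param out_dir output directory (created if needed).
#' @param config a [scan_config()], or the path of a YAML config file.
#' @param reference_id reference row; defaults to the first in-group row.
#' @param flank_context_aa context residues in the text report.
#' @param quiet suppress progress/rejection messages (never results).
#' @return the run manifest (list of class `csi_manifest`), invisibly:
#'   input digests, resolved config, tool version, and the count ledger
#'   `candidates_found = rejected_by_flanks + calls_emitted`.
#' @export
run_pipeline <- function(alignment_path, partition_path, out_dir,
                         config = scan_config(), reference_id = NULL,
                         flank_context_aa = 40L, quiet = FALSE) {
  if (is.character(config)) config <- read_scan_config(config)
  aln <- read_alignment(alignment_path)
  part <- read_partition(partition_path, aln)
  miss <- missing_homologs(part)
  if (length(miss) && !quiet) {
    message(
      "note: ", length(miss),
      " partition id(s) have no homolog in the alignment: ",
      paste(miss, collapse = ", ")
    )
  }
  scan <- scan_csi(aln, part, config, reference_id)
  rejected <- attr(scan, "rejected", exact = TRUE)
  if (!quiet && nrow(rejected)) {
    for (i in seq_len(nrow(rejected))) {
      message(sprintf(
        "rejected %s at columns %d-%d: conserved flanks left=%d right=%d (< %d)",
        rejected$type[i], rejected$col_start[i], rejected$col_end[i],
        rejected$left_flank_conserved[i], rejected$right_flank_conserved[i],
        config$min_flank_conserved
      ))
    }
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  export_calls(scan, "tsv", file.path(out_dir, "calls.tsv"))
  export_calls(scan, "json", file.path(out_dir, "calls.json"))
  export_calls(
    scan, "text", file.path(out_dir, "report.txt"),
    alignment = aln, flank_context_aa = flank_context_aa
  )

  g <- glance.csi_scan(scan)
  manifest <- list(
    tool = "csiscan",
    version = as.character(utils::packageVersion("csiscan")),
    inputs = list(
      alignment = list(
        path = alignment_path,
        md5 = unname(tools::md5sum(alignment_path))
      ),
      partition = list(
        path = partition_path,
        md5 = unname(tools::md5sum(partition_path))
      )
    ),
    config = unclass(config),
    reference_id = attr(scan, "reference_id", exact = TRUE),
    missing_homologs = as.list(miss),
    counts = list(
      candidates_found = g$n_candidates,
      rejected_by_flanks = g$n_rejected_flanks,
      calls_emitted = g$n_calls,
      exclusive = g$n_exclusive,
      shared_with_exceptions = g$n_shared_with_exceptions
    )
  )
  json <- jsonlite::toJSON(
    manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  con <- file(file.path(out_dir, "manifest.json"), open = "wb")
  writeBin(charToRaw(paste0(as.character(json), "\n")), con)
  close(con)
  if (!quiet) {
    message(sprintf(
      "%d candidate(s), %d rejected by flank filter, %d CSI call(s) written to %s",
      g$n_candidates, g$n_rejected_flanks, g$n_calls, out_dir
    ))
  }
  invisible(structure(manifest, class = "csi_manifest"))
}

#' @export
print.csi_manifest <- function(x, ...) {
  cat("# csiscan run manifest (v", x$version, ")\n", sep = "")
  cat("  alignment: ", x$inputs$alignment$path, "\n", sep = "")
  cat("  partition: ", x$inputs$partition$path, "\n", sep = "")
  cat(
    "  candidates ", x$counts$candidates_found,
    " | rejected ", x$counts$rejected_by_flanks,
    " | calls ", x$counts$calls_emitted, "\n",
    sep = ""
  )
  invisible(x)
}
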