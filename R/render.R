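#' Render a CSI as a publication-style partial alignment
#'
#' Follows the field's signature-figure convention: the top sequence is
#' shown verbatim, and every other row shows a dash where its residue is
#' identical to the top line's residue, its own residue where it differs,
#' and a distinct gap character where it is gapped. Because `-` is reserved
#' for identity, alignment gaps are displayed as `␣` by default
#' (configurable, e.g. to `.`), which keeps the rendering
#' information-preserving: the windowed sub-alignment can be reconstructed
#' exactly with [signature_reconstruct()].
#'
#' @param alignment a `csi_alignment`.
#' @param call one row of a [scan_csi()] result (or any list with
#'   `col_start`/`col_end`).
#' @param top_id sequence shown verbatim on the top line.
#' @param flank_context_aa residues of the top sequence shown on each side
#'   of the indel block (default 40, matching the scan window so the
#'   evidence for the flank filter is visible).
#' @param gap_char display character for alignment gaps in non-top rows.
#' @return a list of class `csi_signature`: `header` (1-based residue
#'   range of the top sequence), `rows` (tibble `seq_id`, `label`,
#'   `text`), `highlight` (`c(start, end)` columns within the rendered
#'   window), `window_cols` (alignment columns shown) and `top_id`.
#' @export
render_signature <- function(alignment, call, top_id,
                             flank_context_aa = 40L,
                             gap_char = "␣") {
  row <- alignment$residues[alignment$seq_id == top_id]
  if (length(row) != 1L) {
    abort(paste0("top_id not in alignment: ", top_id))
  }
  if (flank_context_aa < 0L) abort("flank_context_aa must be >= 0")
  top <- strsplit(row, "", fixed = TRUE)[[1L]]
  left <- rev(flank_columns(top, call$col_start - 1L, -1L, flank_context_aa))
  right <- flank_columns(top, call$col_end + 1L, 1L, flank_context_aa)
  window <- c(left, call$col_start:call$col_end, right)

  m <- aln_matrix(alignment)[, window, drop = FALSE]
  topw <- m[top_id, ]
  texts <- character(nrow(alignment))
  for (i in seq_len(nrow(alignment))) {
    chars <- m[i, ]
    if (alignment$seq_id[i] == top_id) {
      texts[i] <- paste(chars, collapse = "")
    } else {
      shown <- ifelse(
        chars == GAP, gap_char,
        ifelse(chars == topw, "-", chars)
      )
      texts[i] <- paste(shown, collapse = "")
    }
  }
  # put the top row first, keep the rest in alignment order
  ord <- order(alignment$seq_id != top_id)
  first_res <- ungapped_index(alignment, top_id, window[1L])
  last_res <- ungapped_index(alignment, top_id, window[length(window)])
  structure(
    list(
      header = sprintf(
        "%s residues %d-%d", top_id, max(first_res, 1L), last_res
      ),
      rows = tibble(
        seq_id = alignment$seq_id[ord],
        label = alignment$taxon_label[ord],
        text = texts[ord]
      ),
      highlight = c(
        match(call$col_start, window), match(call$col_end, window)
      ),
      window_cols = window,
      top_id = top_id,
      gap_char = gap_char
    ),
    class = "csi_signature"
  )
}

#' Reconstruct the windowed sub-alignment from a signature rendering
#'
#' Inverts the dash-for-identity convention of [render_signature()]: a
#' dash becomes the top line's residue, the gap display character becomes
#' `-`, everything else is taken verbatim.
#'
#' @param render a `csi_signature`.
#' @return tibble `seq_id`, `residues` — the original windowed rows.
#' @export
signature_reconstruct <- function(render) {
  top <- strsplit(
    render$rows$text[render$rows$seq_id == render$top_id], ""
  )[[1L]]
  out <- map_chr(seq_len(nrow(render$rows)), function(i) {
    if (render$rows$seq_id[i] == render$top_id) {
      return(render$rows$text[i])
    }
    chars <- strsplit(render$rows$text[i], "", fixed = TRUE)[[1L]]
    orig <- ifelse(
      chars == render$gap_char, GAP,
      ifelse(chars == "-", top, chars)
    )
    paste(orig, collapse = "")
  })
  tibble(seq_id = render$rows$seq_id, residues = out)
}

#' @export
print.csi_signature <- function(x, ...) {
  width_id <- max(nchar(x$rows$seq_id))
  width_lab <- max(nchar(x$rows$label))
  cat(x$header, "\n", sep = "")
  marker <- paste0(
    strrep(" ", x$highlight[1L] - 1L),
    strrep("=", x$highlight[2L] - x$highlight[1L] + 1L)
  )
  cat(strrep(" ", width_id + width_lab + 4L), marker, "\n", sep = "")
  for (i in seq_len(nrow(x$rows))) {
    cat(
      formatC(x$rows$seq_id[i], width = -width_id), "  ",
      formatC(x$rows$label[i], width = -width_lab), "  ",
      x$rows$text[i], "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
format.csi_signature <- function(x, ...) {
  utils::capture.output(print(x))
}

#' Export CSI calls
#'
#' Deterministic, byte-stable serialization of a call set. The TSV has a
#' fixed column order (one row per CSI, exceptions semicolon-joined and
#' header always present); the JSON carries full per-row detail; the text
#' format embeds a [render_signature()] block per call and needs
#' `alignment`.
#'
#' @param calls a [scan_csi()] result.
#' @param format `"tsv"`, `"json"` or `"text"`.
#' @param path optional file to write; when `NULL` the document is
#'   returned as a character scalar.
#' @param alignment alignment the calls came from (text format only).
#' @param flank_context_aa context shown in text renders.
#' @return the serialized document (invisibly when `path` is given).
#' @export
export_calls <- function(calls, format = c("tsv", "json", "text"),
                         path = NULL, alignment = NULL,
                         flank_context_aa = 40L) {
  format <- match.arg(format)
  doc <- switch(format,
    tsv = {
      df <- tidy.csi_scan(calls) |>
        dplyr::select(
          "call_id", "reference_id", "reference_position", "type",
          "col_start", "col_end", "length_min", "length_max",
          "left_flank_conserved", "right_flank_conserved", "specificity",
          "exception_ids"
        )
      lines <- c(
        paste(names(df), collapse = "\t"),
        if (nrow(df)) {
          do.call(paste, c(unname(as.list(df)), sep = "\t"))
        }
      )
      paste0(paste(lines, collapse = "\n"), "\n")
    },
    json = {
      records <- map(seq_len(nrow(calls)), function(i) {
        lens <- calls$per_row_lengths[[i]]
        list(
          call_id = calls$call_id[i],
          reference_id = calls$reference_id[i],
          reference_position = calls$reference_position[i],
          type = calls$type[i],
          col_start = calls$col_start[i],
          col_end = calls$col_end[i],
          length_min = calls$length_min[i],
          length_max = calls$length_max[i],
          left_flank_conserved = calls$left_flank_conserved[i],
          right_flank_conserved = calls$right_flank_conserved[i],
          specificity = calls$specificity[i],
          exception_ids = as.list(calls$exception_ids[[i]]),
          per_row_lengths = as.list(lens)
        )
      })
      jsonlite::toJSON(
        records,
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      ) |> as.character() |> paste0("\n")
    },
    text = {
      if (nrow(calls) && is.null(alignment)) {
        abort("text export needs `alignment` to render signatures")
      }
      blocks <- map_chr(seq_len(nrow(calls)), function(i) {
        call <- calls[i, ]
        hdr <- sprintf(
          "CSI %d: %s of %s aa at %s position %d (%s)",
          call$call_id, call$type,
          if (call$length_min == call$length_max) call$length_min else
            paste0(call$length_min, "-", call$length_max),
          call$reference_id, call$reference_position, call$specificity
        )
        render <- render_signature(
          alignment, call, call$reference_id, flank_context_aa
        )
        paste(c(hdr, format(render)), collapse = "\n")
      })
      if (length(blocks) == 0L) blocks <- "No conserved signature indels."
      paste0(paste(blocks, collapse = "\n\n"), "\n")
    }
  )
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(doc)), con)
    return(invisible(doc))
  }
  doc
}
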