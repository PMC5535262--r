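#' Per-column conservation profile
#'
#' Scores every alignment column over the rows named by the partition
#' (rows outside the partition are ignored). A column's majority residue
#' is the most frequent of the 20 amino acids in that column; its fraction
#' is taken over all partition rows, so gaps and the unknown residue `X`
#' dilute conservation but can never carry it. A column is conserved when
#' the majority fraction reaches `conservation_fraction`.
#'
#' Ties between equally frequent residues are broken alphabetically, so
#' the profile is deterministic.
#'
#' @param alignment a `csi_alignment`.
#' @param partition a `csi_partition`.
#' @param config a [scan_config()].
#' @return a tibble of class `csi_profile` with one row per column:
#'   `column`, `majority_residue` (NA when the column holds no residue),
#'   `majority_fraction`, `is_conserved`.
#' @export
conservation_profile <- function(alignment, partition,
                                 config = scan_config()) {
  ids <- c(
    group_ids(alignment, partition, "ingroup"),
    group_ids(alignment, partition, "outgroup")
  )
  m <- aln_matrix(alignment)[ids, , drop = FALSE]
  n <- nrow(m)
  nc <- ncol(m)
  maj_res <- rep(NA_character_, nc)
  maj_frac <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    col <- col[col %in% AA_RESIDUES]
    if (length(col)) {
      counts <- table(col)
      # which.max on a table breaks ties by name order (alphabetical)
      best <- names(counts)[which.max(counts)]
      maj_res[j] <- best
      maj_frac[j] <- counts[[best]] / n
    }
  }
  structure(
    tibble(
      column = seq_len(nc),
      majority_residue = maj_res,
      majority_fraction = maj_frac,
      is_conserved = maj_frac >= config$conservation_fraction
    ),
    conservation_fraction = config$conservation_fraction,
    class = c("csi_profile", class(tibble()))
  )
}

#' Plot a conservation profile
#'
#' @param object a `csi_profile`.
#' @param ... unused.
#' @return a ggplot: majority fraction per column, with the conservation
#'   threshold as a dashed line and conserved columns highlighted.
#' @method autoplot csi_profile
#' @export
autoplot.csi_profile <- function(object, ...) {
  thr <- attr(object, "conservation_fraction", exact = TRUE)
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$column, y = .data$majority_fraction,
      fill = .data$is_conserved
    )
  ) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
      name = "conserved"
    ) +
    ggplot2::labs(
      x = "alignment column", y = "majority residue fraction",
      title = "Column conservation"
    ) +
    ggplot2::theme_minimal()
}
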