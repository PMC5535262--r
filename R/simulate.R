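#' Describe one planted indel
#'
#' @param position 1-based ancestor residue index. An insert is placed
#'   immediately after this residue; a deletion removes the ancestor
#'   residues starting at it.
#' @param length residue length: a single integer, or for inserts a
#'   two-element `c(min, max)` range drawn independently per in-group row
#'   (deletions must be fixed-length).
#' @param type `"insert"` (in-group carries residues, out-group gapped) or
#'   `"deletion"` (the mirror).
#' @param n_exceptions number of out-group rows sharing the indel (they
#'   carry the full-length insert, or are also gapped for a deletion).
#' @return a list of class `csi_planted_indel`.
#' @export
planted_indel <- function(position, length, type = c("insert", "deletion"),
                          n_exceptions = 0L) {
  type <- match.arg(type)
  length <- as.integer(length)
  if (!base::length(length) %in% 1:2 || any(length < 1L)) {
    abort("`length` must be a positive integer or c(min, max) range")
  }
  if (base::length(length) == 1L) length <- c(length, length)
  if (length[1L] > length[2L]) abort("length range must have min <= max")
  if (type == "deletion" && length[1L] != length[2L]) {
    abort("deletions must have a fixed length, not a range")
  }
  structure(
    list(
      position = as.integer(position),
      length_min = length[1L],
      length_max = length[2L],
      type = type,
      n_exceptions = as.integer(n_exceptions)
    ),
    class = "csi_planted_indel"
  )
}

default_planted_indels <- function() {
  # the study's indel spectrum: 1, 2 and 4 aa inserts, 1 aa deletions,
  # and one large length-variable (43-44 aa) insert
  list(
    planted_indel(80L, 2L, "insert"),
    planted_indel(160L, 4L, "insert"),
    planted_indel(240L, 1L, "deletion"),
    planted_indel(320L, 1L, "insert"),
    planted_indel(400L, c(43L, 44L), "insert"),
    planted_indel(520L, 1L, "deletion")
  )
}

#' Specify a synthetic alignment with planted clade-specific indels
#'
#' Defines the generative model used by [simulate_msa()]: a uniform-random
#' ancestor protein, copied to every row; independent per-site
#' substitutions per row (uniform over the 19 alternative residues)
#' everywhere except within `frozen_flank_aa` residues of each planted
#' indel; and the planted indels themselves, realized as in-group-specific
#' residue blocks (inserts) or in-group-specific gap blocks (deletions),
#' with optional out-group exception rows sharing the indel. Defaults
#' emulate the scale of the ribonucleotide-reductase alignments that
#' motivated the method: ~12 in-group and ~10 out-group homologs of a
#' ~600 aa protein, with indels spanning the 1–44 aa spectrum.
#'
#' @param seed integer seed; the same spec and seed always reproduce the
#'   identical alignment, partition and truth.
#' @param n_ingroup,n_outgroup number of rows per group.
#' @param core_length_aa ancestor (gap-free) protein length.
#' @param substitution_rate per-site, per-row substitution probability in
#'   `[0, 1)` outside frozen flanks.
#' @param planted_indels list of [planted_indel()] descriptions;
#'   footprints (including frozen flanks) must not overlap.
#' @param frozen_flank_aa ancestor residues on each side of every planted
#'   indel exempt from substitution, guaranteeing conserved flanks.
#' @return a list of class `csi_synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_ingroup = 12L,
                           n_outgroup = 10L,
                           core_length_aa = 600L,
                           substitution_rate = 0.05,
                           planted_indels = default_planted_indels(),
                           frozen_flank_aa = 10L) {
  spec <- list(
    seed = as.integer(seed),
    n_ingroup = as.integer(n_ingroup),
    n_outgroup = as.integer(n_outgroup),
    core_length_aa = as.integer(core_length_aa),
    substitution_rate = as.numeric(substitution_rate),
    planted_indels = planted_indels,
    frozen_flank_aa = as.integer(frozen_flank_aa)
  )
  if (spec$n_ingroup < 1L || spec$n_outgroup < 1L) {
    abort("both groups need at least one row")
  }
  if (spec$substitution_rate < 0 || spec$substitution_rate >= 1) {
    abort("substitution_rate must be in [0, 1)")
  }
  if (spec$frozen_flank_aa < 0L) abort("frozen_flank_aa must be >= 0")
  # footprint in ancestor coordinates, frozen flanks included
  foot <- map(planted_indels, function(pi) {
    if (!inherits(pi, "csi_planted_indel")) {
      abort("planted_indels must be built with planted_indel()")
    }
    if (pi$type == "insert") {
      c(pi$position - spec$frozen_flank_aa + 1L,
        pi$position + spec$frozen_flank_aa)
    } else {
      c(pi$position - spec$frozen_flank_aa,
        pi$position + pi$length_max - 1L + spec$frozen_flank_aa)
    }
  })
  for (f in foot) {
    if (f[1L] < 1L || f[2L] > spec$core_length_aa) {
      abort("a planted indel (with its frozen flanks) falls outside the core")
    }
  }
  if (length(foot) > 1L) {
    ord <- order(map_int(foot, 1L))
    foot <- foot[ord]
    for (i in seq_along(foot)[-1L]) {
      if (foot[[i]][1L] <= foot[[i - 1L]][2L]) {
        abort("planted indels overlap (frozen flanks included)")
      }
    }
  }
  structure(spec, class = "csi_synthetic_spec")
}

#' Simulate a protein alignment with planted clade-specific indels
#'
#' Realizes a [synthetic_spec()]: draws the ancestor, applies per-row
#' substitution noise outside frozen flanks, and splices in the planted
#' indels. In-group rows are named `in_01, in_02, ...`, out-group rows
#' `out_01, ...`; exception rows are the first `n_exceptions` out-group
#' rows of each indel. Insert content is random per row; a row's insert
#' length is drawn uniformly from the spec's range and the block width is
#' the largest realized length (left-aligned, gap-padded).
#'
#' @param spec a `csi_synthetic_spec`.
#' @return list with elements `alignment` (a `csi_alignment`),
#'   `partition` (a `csi_partition`) and `truth`, a tibble of class
#'   `csi_truth` with one row per planted indel: `indel_id`, `type`,
#'   `position`, `length_min`/`length_max` (realized over carrier rows),
#'   `col_start`/`col_end` (realized alignment span), `exception_ids`
#'   and `per_row_lengths`. The truth carries the partition and the
#'   reference id (`in_01`) as attributes so downstream fixtures need no
#'   extra plumbing.
#' @export
simulate_msa <- function(spec) {
  if (!inherits(spec, "csi_synthetic_spec")) {
    abort("`spec` must be built with synthetic_spec()")
  }
  with_seed(spec$seed, simulate_msa_impl(spec))
}

simulate_msa_impl <- function(spec) {
  n_in <- spec$n_ingroup
  n_out <- spec$n_outgroup
  n <- n_in + n_out
  L <- spec$core_length_aa
  ids <- c(
    sprintf("in_%02d", seq_len(n_in)),
    sprintf("out_%02d", seq_len(n_out))
  )
  labels <- c(
    sprintf("ingroup taxon %d", seq_len(n_in)),
    sprintf("outgroup taxon %d", seq_len(n_out))
  )
  in_ids <- ids[seq_len(n_in)]
  out_ids <- ids[n_in + seq_len(n_out)]

  ancestor <- sample(AA_RESIDUES, L, replace = TRUE)
  core <- matrix(rep(ancestor, each = n), nrow = n)
  rownames(core) <- ids

  # frozen ancestor positions: flanks of every indel, plus the body of
  # deletions (the retained out-group residues stay recognizable)
  frozen <- logical(L)
  indels <- spec$planted_indels
  for (pi in indels) {
    if (pi$type == "insert") {
      span <- (pi$position - spec$frozen_flank_aa + 1L):
        (pi$position + spec$frozen_flank_aa)
    } else {
      span <- (pi$position - spec$frozen_flank_aa):
        (pi$position + pi$length_max - 1L + spec$frozen_flank_aa)
    }
    frozen[span] <- TRUE
  }

  if (spec$substitution_rate > 0) {
    open <- which(!frozen)
    for (i in seq_len(n)) {
      hit <- open[stats::runif(length(open)) < spec$substitution_rate]
      for (p in hit) {
        core[i, p] <- sample(setdiff(AA_RESIDUES, core[i, p]), 1L)
      }
    }
  }

  # assemble final columns left to right, splicing indel blocks
  indels <- indels[order(map_int(indels, "position"))]
  segments <- list()
  truth_rows <- list()
  cursor <- 1L # next ancestor position to copy
  emitted <- 0L # alignment columns emitted so far

  emit_core <- function(from, to) {
    if (from > to) {
      return(invisible())
    }
    segments[[length(segments) + 1L]] <<- core[, from:to, drop = FALSE]
    emitted <<- emitted + (to - from + 1L)
  }

  for (k in seq_along(indels)) {
    pi <- indels[[k]]
    exc <- out_ids[seq_len(pi$n_exceptions)]
    if (pi$type == "insert") {
      emit_core(cursor, pi$position)
      cursor <- pi$position + 1L
      row_len <- stats::setNames(integer(n), ids)
      row_len[in_ids] <- if (pi$length_min == pi$length_max) {
        pi$length_min
      } else {
        sample(pi$length_min:pi$length_max, n_in, replace = TRUE)
      }
      width <- max(row_len[in_ids])
      row_len[exc] <- width # exceptions share the full-length insert
      block <- matrix(GAP, nrow = n, ncol = width, dimnames = list(ids))
      for (id in ids[row_len > 0L]) {
        block[id, seq_len(row_len[id])] <-
          sample(AA_RESIDUES, row_len[id], replace = TRUE)
      }
      segments[[length(segments) + 1L]] <- block
      span <- c(emitted + 1L, emitted + width)
      emitted <- emitted + width
      realized <- range(row_len[in_ids])
    } else {
      emit_core(cursor, pi$position - 1L)
      width <- pi$length_max
      cursor <- pi$position + width
      block <- core[, pi$position:(pi$position + width - 1L), drop = FALSE]
      block[c(in_ids, exc), ] <- GAP
      segments[[length(segments) + 1L]] <- block
      span <- c(emitted + 1L, emitted + width)
      emitted <- emitted + width
      row_len <- rowSums(block != GAP)
      realized <- c(width, width)
    }
    truth_rows[[k]] <- tibble(
      indel_id = k,
      type = pi$type,
      position = pi$position,
      length_min = realized[1L],
      length_max = realized[2L],
      col_start = span[1L],
      col_end = span[2L],
      exception_ids = list(exc),
      per_row_lengths = list(row_len)
    )
  }
  emit_core(cursor, L)

  m <- do.call(cbind, segments)
  aln <- alignment(
    stats::setNames(matrix_to_residues(m), ids),
    taxon_labels = labels
  )
  part <- taxon_partition(in_ids, out_ids, aln)
  truth <- dplyr::bind_rows(truth_rows)
  if (nrow(truth) == 0L) {
    truth <- tibble(
      indel_id = integer(0), type = character(0), position = integer(0),
      length_min = integer(0), length_max = integer(0),
      col_start = integer(0), col_end = integer(0),
      exception_ids = list(), per_row_lengths = list()
    )
  }
  truth <- structure(
    truth,
    reference_id = in_ids[1L],
    ingroup = in_ids,
    outgroup = out_ids,
    class = c("csi_truth", class(tibble()))
  )
  list(alignment = aln, partition = part, truth = truth)
}

#' Degrade flank conservation around a planted indel
#'
#' Substitutes residues in randomly chosen rows of randomly chosen
#' conserved columns within one flank window of a planted indel until the
#' window holds exactly `target_conserved` conserved columns. Used to
#' build fixtures probing the flank-filter threshold: at the published
#' minimum the signature is still reported, one below it is not. Never
#' introduces gaps, so the discriminating indel pattern is untouched.
#'
#' @param alignment the simulated `csi_alignment`.
#' @param truth the `csi_truth` from the same [simulate_msa()] run (it
#'   carries the partition and reference id).
#' @param side `"left"` or `"right"` flank.
#' @param target_conserved desired conserved-column count in the window;
#'   must not exceed the current count.
#' @param config a [scan_config()] (defines window and conservation
#'   threshold).
#' @param seed integer seed for the degradation choices.
#' @param which which planted indel to degrade (row of `truth`).
#' @return the modified `csi_alignment`.
#' @export
degrade_flanks <- function(alignment, truth, side = c("left", "right"),
                           target_conserved, config = scan_config(),
                           seed = 1L, which = 1L) {
  side <- match.arg(side)
  ref_id <- attr(truth, "reference_id", exact = TRUE)
  part <- taxon_partition(
    attr(truth, "ingroup", exact = TRUE),
    attr(truth, "outgroup", exact = TRUE),
    alignment
  )
  entry <- truth[which, ]
  ref <- strsplit(
    alignment$residues[alignment$seq_id == ref_id], ""
  )[[1L]]
  cols <- if (side == "left") {
    flank_columns(ref, entry$col_start - 1L, -1L, config$flank_window_aa)
  } else {
    flank_columns(ref, entry$col_end + 1L, 1L, config$flank_window_aa)
  }
  part_ids <- c(
    group_ids(alignment, part, "ingroup"),
    group_ids(alignment, part, "outgroup")
  )
  m <- aln_matrix(alignment)

  conserved_in <- function(mm) {
    prof <- conservation_profile(
      new_alignment(
        tibble(
          seq_id = rownames(mm), taxon_label = rownames(mm),
          residues = matrix_to_residues(mm)
        ),
        ncol(mm)
      ),
      part, config
    )
    prof$is_conserved
  }

  is_cons <- conserved_in(m)
  current <- sum(is_cons[cols])
  if (target_conserved > current) {
    abort(paste0(
      "unreachable target: window holds ", current,
      " conserved column(s), cannot raise to ", target_conserved
    ))
  }
  if (target_conserved == current) {
    return(alignment)
  }
  with_seed(seed, {
    while (current > target_conserved) {
      cand <- cols[is_cons[cols]]
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      guard <- 0L
      while (is_cons[j]) {
        col <- m[part_ids, j]
        res <- col[col %in% AA_RESIDUES]
        counts <- table(res)
        maj <- names(counts)[which.max(counts)]
        holders <- part_ids[col == maj]
        victim <- if (length(holders) == 1L) holders else
          sample(holders, 1L)
        m[victim, j] <- sample(setdiff(AA_RESIDUES, maj), 1L)
        # rescore just this column
        colv <- m[part_ids, j]
        resv <- colv[colv %in% AA_RESIDUES]
        frac <- if (length(resv)) max(table(resv)) / length(part_ids) else 0
        is_cons[j] <- frac >= config$conservation_fraction
        guard <- guard + 1L
        if (guard > 10000L) abort("degradation failed to converge")
      }
      current <- sum(is_cons[cols])
    }
  })
  new_alignment(
    tibble(
      seq_id = alignment$seq_id,
      taxon_label = alignment$taxon_label,
      residues = matrix_to_residues(m)[alignment$seq_id]
    ),
    n_cols(alignment)
  )
}

#' Score recovery of planted indels
#'
#' A call matches a truth entry iff their alignment spans are identical
#' and their types agree. Precision is matched calls over all calls (1.0
#' when there are no calls), recall is matched truth entries over all
#' truth entries (1.0 when the truth is empty).
#'
#' @param truth a `csi_truth`.
#' @param calls a [scan_csi()] result from the same alignment.
#' @return one-row tibble: `precision`, `recall`, `n_truth`, `n_calls`,
#'   `n_matched`; the matched (indel_id, call_id) pairs are in
#'   `attr(, "matches")`.
#' @export
evaluate_recovery <- function(truth, calls) {
  key <- function(type, s, e) paste(type, s, e)
  truth_keys <- key(truth$type, truth$col_start, truth$col_end)
  call_keys <- key(calls$type, calls$col_start, calls$col_end)
  hit <- match(call_keys, truth_keys)
  matches <- tibble(
    call_id = calls$call_id[!is.na(hit)],
    indel_id = truth$indel_id[hit[!is.na(hit)]]
  )
  n_calls <- nrow(calls)
  n_truth <- nrow(truth)
  n_matched_calls <- sum(!is.na(hit))
  n_matched_truth <- length(unique(matches$indel_id))
  structure(
    tibble(
      precision = if (n_calls == 0L) 1 else n_matched_calls / n_calls,
      recall = if (n_truth == 0L) 1 else n_matched_truth / n_truth,
      n_truth = n_truth,
      n_calls = n_calls,
      n_matched = n_matched_calls
    ),
    matches = matches
  )
}
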