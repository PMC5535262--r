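# ---- small construction helpers -------------------------------------------

make_aln <- function(seqs, labels = NULL) {
  alignment(seqs, taxon_labels = labels)
}

write_fasta <- function(seqs, path = withr::local_tempfile(
                          fileext = ".fasta",
                          .local_envir = parent.frame()
                        )) {
  lines <- unlist(lapply(names(seqs), function(id) {
    c(paste0(">", id), seqs[[id]])
  }))
  writeLines(lines, path)
  path
}

write_partition_tsv <- function(ingroup, outgroup,
                                path = withr::local_tempfile(
                                  fileext = ".tsv",
                                  .local_envir = parent.frame()
                                )) {
  writeLines(
    c(
      paste(ingroup, "ingroup", sep = "\t"),
      paste(outgroup, "outgroup", sep = "\t")
    ),
    path
  )
  path
}

# Hand-built fixture with an indel inside fully conserved flanks and a
# controllable number of non-conserved columns. 6 in-group + 4 out-group
# rows; `left_conserved_at` gives the distances (in columns, which equal
# reference residues because the flanks are gap-free) to the left of the
# indel at which the flank columns are conserved; every other left-flank
# column is made non-conserved (in-group all 'A' = 6/10 < 0.8). The right
# flank is fully conserved over `right_len` columns.
positional_flank_fixture <- function(indel_len = 4L,
                                     left_len = 45L,
                                     left_conserved_at = c(1:4, 40),
                                     right_len = 45L) {
  n_in <- 6L
  n_out <- 4L
  n <- n_in + n_out
  set.seed(42)
  cons_left <- sample(c("D", "E", "F", "G", "H"), left_len, replace = TRUE)
  cons_right <- sample(c("K", "L", "M", "N"), right_len, replace = TRUE)
  rows <- character(n)
  for (i in seq_len(n)) {
    left <- character(left_len)
    for (d in seq_len(left_len)) {
      # column at distance d from the indel (d = 1 is adjacent)
      j <- left_len - d + 1L
      if (d %in% left_conserved_at) {
        left[j] <- cons_left[d]
      } else {
        left[j] <- if (i <= n_in) "A" else c("C", "I", "P", "R")[i - n_in]
      }
    }
    mid <- if (i <= n_in) strrep("W", indel_len) else strrep("-", indel_len)
    rows[i] <- paste0(
      paste(left, collapse = ""), mid, paste(cons_right, collapse = "")
    )
  }
  ids <- c(sprintf("in_%02d", 1:n_in), sprintf("out_%02d", 1:n_out))
  names(rows) <- ids
  list(
    alignment = make_aln(rows),
    partition = taxon_partition(ids[1:n_in], ids[-(1:n_in)]),
    span = c(left_len + 1L, left_len + indel_len)
  )
}

# ---- brute-force oracle (independent of the package internals) -------------

oracle_chars <- function(aln) {
  do.call(rbind, strsplit(aln$residues, "", fixed = TRUE))
}

# direct per-column conservation: loops and explicit counting
oracle_conserved <- function(aln, in_ids, out_ids, threshold) {
  m <- oracle_chars(aln)
  rownames(m) <- aln$seq_id
  m <- m[c(in_ids, out_ids), , drop = FALSE]
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sapply(seq_len(ncol(m)), function(j) {
    best <- 0L
    for (r in aa20) best <- max(best, sum(m[, j] == r))
    best / nrow(m) >= threshold
  })
}

# Brute-force CSI scan: enumerates every column interval and tests the
# full predicate directly. Independent formulation: an interval is a
# candidate iff its endpoints are discriminating columns, every internal
# run of non-discriminating columns is short enough to bridge, and it
# cannot be extended to a nearby discriminating column.
oracle_scan <- function(aln, part, cfg, ref_id) {
  in_ids <- intersect(aln$seq_id, part$seq_id[part$group == "ingroup"])
  out_ids <- intersect(aln$seq_id, part$seq_id[part$group == "outgroup"])
  m <- oracle_chars(aln)
  rownames(m) <- aln$seq_id
  nc <- ncol(m)
  conserved <- oracle_conserved(aln, in_ids, out_ids, cfg$conservation_fraction)
  ref <- m[ref_id, ]

  col_ok <- function(j, type) {
    if (type == "insert") {
      out_gapped <- sum(m[out_ids, j] == "-")
      in_present <- sum(m[in_ids, j] != "-")
      out_gapped / length(out_ids) >= cfg$outgroup_absence_fraction &&
        in_present > 0L
    } else {
      in_gapped <- sum(m[in_ids, j] == "-")
      out_present <- sum(m[out_ids, j] != "-")
      in_gapped / length(in_ids) >= cfg$outgroup_absence_fraction &&
        out_present > 0L
    }
  }

  walk_count <- function(from, step) {
    seen <- 0L
    count <- 0L
    j <- from
    while (j >= 1L && j <= nc && seen < cfg$flank_window_aa) {
      if (conserved[j]) count <- count + 1L
      if (ref[j] != "-") seen <- seen + 1L
      j <- j + step
    }
    count
  }

  calls <- list()
  for (type in c("insert", "deletion")) {
    ok <- sapply(seq_len(nc), col_ok, type = type)
    for (i in seq_len(nc)) {
      for (j in i:nc) {
        if (!ok[i] || !ok[j]) next
        # internal bridges short enough?
        runs_ok <- TRUE
        if (j > i) {
          gap_run <- 0L
          for (k in (i):(j)) {
            if (!ok[k]) gap_run <- gap_run + 1L else {
              if (gap_run > cfg$merge_gap_cols) runs_ok <- FALSE
              gap_run <- 0L
            }
          }
        }
        if (!runs_ok) next
        # maximal: no reachable discriminating column just outside
        ext <- FALSE
        for (k in seq_len(nc)) {
          if (ok[k] && ((k < i && i - k - 1L <= cfg$merge_gap_cols) ||
            (k > j && k - j - 1L <= cfg$merge_gap_cols))) {
            ext <- TRUE
          }
        }
        if (ext) next
        # region-level presence on the carrier group
        carriers <- if (type == "insert") in_ids else out_ids
        has_res <- sapply(carriers, function(id) {
          any(m[id, i:j] != "-")
        })
        if (mean(has_res) < cfg$ingroup_presence_fraction) {
          next
        }
        left <- walk_count(i - 1L, -1L)
        right <- walk_count(j + 1L, 1L)
        if (left < cfg$min_flank_conserved ||
          right < cfg$min_flank_conserved) {
          next
        }
        exc <- character(0)
        for (id in out_ids) {
          n_res <- sum(m[id, i:j] != "-")
          if (type == "insert" && n_res > 0L) exc <- c(exc, id)
          if (type == "deletion" && n_res == 0L) exc <- c(exc, id)
        }
        calls[[length(calls) + 1L]] <- data.frame(
          type = type, col_start = i, col_end = j,
          left_flank_conserved = left, right_flank_conserved = right,
          specificity = if (length(exc)) "shared_with_exceptions" else
            "exclusive",
          exception_ids = paste(exc, collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out)) {
    out <- data.frame(
      type = character(0), col_start = integer(0), col_end = integer(0),
      left_flank_conserved = integer(0), right_flank_conserved = integer(0),
      specificity = character(0), exception_ids = character(0)
    )
  }
  out[order(out$col_start, out$type), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small alignment + partition + config for oracle comparisons
random_small_instance <- function(seed) {
  set.seed(seed)
  n_in <- sample(1:4, 1)
  n_out <- sample(1:4, 1)
  nc <- sample(4:12, 1)
  alphabet <- c("A", "C", "D", "-", "-")
  ids <- c(sprintf("i%d", seq_len(n_in)), sprintf("o%d", seq_len(n_out)))
  seqs <- vapply(ids, function(id) {
    paste(sample(alphabet, nc, replace = TRUE), collapse = "")
  }, character(1))
  # a gap-only reference makes every flank window empty; allow it sometimes
  aln <- alignment(seqs)
  part <- taxon_partition(ids[seq_len(n_in)], ids[-seq_len(n_in)])
  window <- sample(1:4, 1)
  cfg <- scan_config(
    flank_window_aa = window,
    min_flank_conserved = sample(0:min(2, window), 1),
    conservation_fraction = sample(c(0.5, 0.6, 0.8, 1.0), 1),
    ingroup_presence_fraction = sample(c(0.5, 0.75, 1.0), 1),
    outgroup_absence_fraction = sample(c(0.5, 0.75, 1.0), 1),
    merge_gap_cols = sample(0:1, 1)
  )
  list(alignment = aln, partition = part, config = cfg, reference = ids[1])
}

scan_as_plain <- function(scan) {
  df <- as.data.frame(tidy(scan))
  df <- df[, c(
    "type", "col_start", "col_end", "left_flank_conserved",
    "right_flank_conserved", "specificity", "exception_ids"
  )]
  df <- df[order(df$col_start, df$type), , drop = FALSE]
  rownames(df) <- NULL
  df
}
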