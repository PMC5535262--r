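#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_int map_chr map_dbl map_lgl imap pmap
NULL

# the 20 standard amino acids; 'X' is unknown and never matches anything
AA_RESIDUES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

GAP <- "-"

# character matrix view of an alignment (rows = sequences, named by seq_id)
aln_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$residues, "", fixed = TRUE))
  rownames(m) <- alignment$seq_id
  m
}

matrix_to_residues <- function(m) {
  apply(m, 1L, paste, collapse = "")
}

# stable seeded RNG scope; all package randomness goes through here
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
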