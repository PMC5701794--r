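#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n count distinct across all_of
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# FNV-1a 32-bit hash of a single string, done in doubles (exact: all
# intermediates stay below 2^53). Used for label-derived seed substreams and
# for the simulator's deterministic selection; must be stable across
# platforms and R sessions, which rules out R's own RNG machinery here.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h * 16777619 mod 2^32, split as h*403 + (h mod 256)*2^24
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  h
}

# Uniform-looking value in [0, 1) derived deterministically from a string.
hash_unit <- function(s) {
  vapply(s, fnv1a32, numeric(1), USE.NAMES = FALSE) / 4294967296
}

# Named substream seed below 2^31, derived from a master seed and a label so
# that every stochastic stage draws from its own reproducible stream.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 1000003 + fnv1a32(label)) %% 2147483647)
}

# Translate in-frame DNA strings; out-of-frame or empty input yields NA.
translate_nt <- function(nt) {
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nchar(nt) > 0L & nchar(nt) %% 3L == 0L
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[ok]),
      no.init.codon = TRUE
    ))
  }
  out
}

# Single-codon lookup against the standard genetic code.
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  ba <- utf8ToInt(a)
  bb <- utf8ToInt(b)
  if (length(ba) != length(bb)) {
    abort("hamming() requires equal-length strings")
  }
  sum(ba != bb)
}

is_dna <- function(x) {
  !is.na(x) & nchar(x) > 0L & !grepl("[^ACGT]", x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

utils::globalVariables(c(
  ".", "count", "cdr3_aa", "v_group", "j_group", "key", "label",
  "percent", "sample_id", "value", "n_distinct_cdr3", "metric",
  "comparison_class", "read_id", "productive", "junction_aa",
  "v_call", "j_call", "group_id", "segment_id", "nt_sequence",
  "clonotype_id", "pre_error", "mouse_id", "mhc_allele", "tcrb",
  "n_bases", "sequence", "sample_a", "sample_b", "length_aa",
  "n_pairs", "depth", "kind", "stem", "dup_class", "anchor_offset",
  "family", "subfamily", "members", "representative_sequence",
  "pass", "group"
))
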