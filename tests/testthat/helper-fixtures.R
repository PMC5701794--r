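# Deterministic toy fixtures, built in code.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small hand-controlled germline reference: two distinct V families (plus an
# optional identical A/D/N triple), two J segments.  V anchor (Cys codon) at
# offset 30 with a 6-nt trimmable tail; J anchor (F/W) at offset 9.
make_toy_reference <- function(dup = FALSE) {
  set.seed(101)
  v1 <- paste0(rand_dna(30), "TGT", "GCTGCA")
  v2 <- paste0(rand_dna(30), "TGC", "AGGTCA")
  v3 <- paste0(rand_dna(30), "TGT", "TCAGAC")
  j1 <- paste0(rand_dna(9), "TTT", "GGA", rand_dna(12))
  j2 <- paste0(rand_dna(9), "TGG", "GGT", rand_dna(12))
  rows <- tibble::tibble(
    segment_id = c("TRAV01-1A", "TRAV02-1A", "TRAJ01", "TRAJ02"),
    kind = c("V", "V", "J", "J"),
    family = c(1L, 2L, 1L, 2L),
    subfamily = 1L,
    dup_class = c("A", "A", "none", "none"),
    nt_sequence = c(v1, v2, j1, j2),
    anchor_offset = c(30L, 30L, 9L, 9L)
  )
  if (dup) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      segment_id = c("TRAV03-1A", "TRAV03-1D", "TRAV03-1N"),
      kind = "V", family = 3L, subfamily = 1L,
      dup_class = c("A", "D", "N"),
      nt_sequence = v3, anchor_offset = 30L
    ))
  }
  germline_reference(rows)
}

# Assemble a junction-spanning read from germline pieces.
make_read <- function(v_seq, j_seq, n_seq = "", t_v = 0L, t_j = 0L) {
  paste0(substr(v_seq, 1L, nchar(v_seq) - t_v), n_seq,
         substr(j_seq, 1L + t_j, nchar(j_seq)))
}

# Annotated-sequence tibble from bare components (for repertoire tests).
make_annotated <- function(v, j, cdr3, n_bases = 0L, sample_id = "s1") {
  k <- max(length(v), length(j), length(cdr3))
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(k)),
    sample_id = sample_id,
    v_call = rep_len(v, k), j_call = rep_len(j, k),
    junction_aa = rep_len(cdr3, k),
    n_bases = rep_len(as.integer(n_bases), k),
    productive = TRUE
  )
}

# Repertoire straight from named key counts (cdr3_only scheme).
rep_from_named_counts <- function(counts, sample_id = "s",
                                  metadata = list()) {
  repertoire_from_counts(
    tibble::tibble(cdr3_aa = as.character(names(counts)),
                   count = as.integer(counts)),
    key_scheme = "cdr3_only", metadata = metadata, sample_id = sample_id
  )
}

# Independent brute-force evaluation of the Chao et al. (2005)
# abundance-based Jaccard index, written as explicit per-species loops.
chao_jaccard_oracle <- function(xa, xb) {
  shared <- intersect(names(xa), names(xb))
  if (length(shared) == 0) {
    return(0)
  }
  n <- sum(xa)
  m <- sum(xb)
  one_side <- function(x, y, n, m) {
    u <- 0
    f1 <- 0
    f2 <- 0
    rare_sum <- 0
    for (s in shared) {
      u <- u + x[[s]] / n
      if (y[[s]] == 1) {
        f1 <- f1 + 1
        rare_sum <- rare_sum + x[[s]] / n
      } else if (y[[s]] == 2) {
        f2 <- f2 + 1
      }
    }
    denom <- if (f2 == 0) 1 else f2
    u <- u + ((m - 1) / m) * (f1 / (2 * denom)) * rare_sum
    if (u > 1) u <- 1
    u
  }
  u <- one_side(xa, xb, n, m)
  v <- one_side(xb, xa, m, n)
  (u * v) / (u + v - u * v)
}

# Random abundance-table pair sharing part of the species pool.
random_table_pair <- function(max_species = 20L, max_count = 50L) {
  pool <- paste0("sp", seq_len(max_species))
  ka <- sample(pool, sample(2:max_species, 1))
  kb <- sample(pool, sample(2:max_species, 1))
  xa <- stats::setNames(sample.int(max_count, length(ka), replace = TRUE), ka)
  xb <- stats::setNames(sample.int(max_count, length(kb), replace = TRUE), kb)
  list(a = xa, b = xb)
}

# Two-sample cohort with planted per-(V, J)-pair distinct-CDR3 counts
# 4, 5 and 6 (for the minimum-distinct-sequence filter).
make_filter_cohort <- function() {
  cdr3s <- function(n) paste0("CA", strrep("G", seq_len(n)), "F")
  mk <- function(n_a, sid) {
    repertoire_from_counts(
      dplyr::bind_rows(
        tibble::tibble(v_group = "TRAV01-1A", j_group = "TRAJ01",
                       cdr3_aa = cdr3s(n_a), count = 2L),
        tibble::tibble(v_group = "TRAV02-1A", j_group = "TRAJ01",
                       cdr3_aa = cdr3s(5), count = 2L),
        tibble::tibble(v_group = "TRAV02-1A", j_group = "TRAJ02",
                       cdr3_aa = cdr3s(6), count = 2L)
      ),
      "full_tcra",
      metadata = list(mhc_allele = "b", tcrb = "DObWT"), sample_id = sid
    )
  }
  cohort_design(list(mk(4, "s1"), mk(5, "s2")))
}

# Desk-scale simulator config used across tests.
small_config <- function(...) {
  defaults <- list(
    mhc_alleles = c("b", "f"), tcrb_chains = "DObWT",
    n_mice_per_genotype = 2L, depth = 800L, richness = 80L,
    error_rate = 0, seed = 7L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}
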