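ref <- make_toy_reference(dup = TRUE)
groups <- collapse_indistinguishable(ref)
v1 <- ref$nt_sequence[ref$segment_id == "TRAV01-1A"]
v2 <- ref$nt_sequence[ref$segment_id == "TRAV02-1A"]
j1 <- ref$nt_sequence[ref$segment_id == "TRAJ01"]

test_that("segment assignment finds the exact and near-exact source", {
  read <- make_read(v1, j1, "GGG")
  va <- assign_segment(read, groups, "V")
  expect_equal(va$group_id, "TRAV01-1A")
  expect_equal(va$mismatch_count, 0L)
  expect_equal(va$span, c(0L, nchar(v1)))
  ja <- assign_segment(read, groups, "J")
  expect_equal(ja$group_id, "TRAJ01")
  expect_equal(ja$span, c(nchar(read) - nchar(j1), nchar(read)))

  # a single substitution 20 nt into the V still maps uniquely
  mut <- read
  pos <- 20L
  substr(mut, pos, pos) <-
    setdiff(c("A", "C", "G", "T"), substr(read, pos, pos))[1]
  va2 <- assign_segment(mut, groups, "V")
  expect_equal(va2$group_id, "TRAV01-1A")
  expect_equal(va2$mismatch_count, 1L)

  # reads from a duplicated subfamily map to the merged group id
  v3 <- ref$nt_sequence[ref$segment_id == "TRAV03-1A"]
  va3 <- assign_segment(make_read(v3, j1, "GG"), groups, "V")
  expect_equal(va3$group_id, "TRAV03-1ADN")
})

test_that("unrelated sequence is flagged unassignable", {
  set.seed(5)
  junk <- rand_dna(90)
  expect_null(assign_segment(junk, groups, "V"))
  expect_null(assign_segment(junk, groups, "J"))
  expect_error(assign_segment("ACGT", groups[groups$kind == "V", ], "J"),
               "no ambiguity groups")
})

test_that("correction respects the protected junction window", {
  read <- make_read(v1, j1)
  sv <- nchar(v1)
  sjs <- sv + 1L
  v_align <- list(sequence = v1, span = c(0L, sv), anchor_offset = 30L)
  j_align <- list(sequence = j1, span = c(sv, nchar(read)),
                  anchor_offset = 9L)
  flip <- function(s, p) {
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    s
  }

  # clean read: untouched
  res <- correct_errors(read, v_align, j_align)
  expect_equal(res$corrected_nt, read)
  expect_equal(res$corrections_applied, 0L)

  # 5 nt before the V end: corrected back to germline
  res <- correct_errors(flip(read, sv - 5L), v_align, j_align)
  expect_equal(res$corrected_nt, read)
  expect_equal(res$corrections_applied, 1L)

  # exactly 3 nt before the V end: protected, NOT corrected
  mut <- flip(read, sv - 3L)
  res <- correct_errors(mut, v_align, j_align)
  expect_equal(res$corrected_nt, mut)
  expect_equal(res$corrections_applied, 0L)

  # J side mirror: >3 after the J start corrected, <=3 protected
  res <- correct_errors(flip(read, sjs + 4L), v_align, j_align)
  expect_equal(res$corrected_nt, read)
  mut <- flip(read, sjs + 3L)
  res <- correct_errors(mut, v_align, j_align)
  expect_equal(res$corrected_nt, mut)
})

test_that("CDR3 extraction spans cysteine through F/W/L and checks frame", {
  # purpose-built micro segments: V anchor at its very end, J anchor at 0
  v <- paste0("GGCACCGGCACC", "TGT")
  j <- paste0("TTT", "GGA", "GGCACC")
  va <- list(sequence = v, span = c(0L, nchar(v)), anchor_offset = 12L)
  make_j_align <- function(read) {
    list(sequence = j, span = c(nchar(read) - nchar(j), nchar(read)),
         anchor_offset = 0L)
  }

  read <- paste0(v, "GCAAGG", j)
  res <- extract_cdr3(read, va, make_j_align(read))
  expect_true(res$ok)
  expect_equal(res$cdr3_nt, "TGTGCAAGGTTT")
  expect_equal(res$cdr3_aa, "CARF")
  expect_true(res$productive)

  # out-of-frame junction (13 nt) is non-productive
  read <- paste0(v, "GCAAGGA", j)
  res <- extract_cdr3(read, va, make_j_align(read))
  expect_false(res$productive)
  expect_true(is.na(res$cdr3_aa))

  # internal stop codon is non-productive
  read <- paste0(v, "GCATAA", j)
  res <- extract_cdr3(read, va, make_j_align(read))
  expect_equal(res$cdr3_aa, "CA*F")
  expect_false(res$productive)

  # anchor outside the aligned span fails extraction
  short <- list(sequence = v, span = c(0L, 10L), anchor_offset = 12L)
  read <- paste0(v, "GCAAGG", j)
  expect_false(extract_cdr3(read, short, make_j_align(read))$ok)
})

test_that("N-base estimation uses maximal-V-first germline attribution", {
  expect_equal(estimate_n_bases(make_read(v1, j1), v1, j1), 0L)

  # insert matching neither flank counts fully (no trimming, no extension)
  ins <- "GGCC"
  expect_equal(estimate_n_bases(make_read(v1, j1, ins), v1, j1), 4L)

  # first inserted base reproduces the trimmed germline base -> absorbed
  v <- paste0("GGCACCGGCACC", "TGT", "AC")
  j <- j1
  read <- make_read(v, j, "AA", t_v = 2L)
  expect_equal(estimate_n_bases(read, v, j), 1L)

  # brute-force cross-check on random junctions: leftover never negative
  # and zero for fully germline reads
  set.seed(11)
  for (i in 1:25) {
    n_seq <- if (i %% 2) rand_dna(sample(0:6, 1)) else ""
    read <- make_read(v1, j1, n_seq,
                      t_v = sample(0:4, 1), t_j = sample(0:4, 1))
    nb <- estimate_n_bases(read, v1, j1)
    expect_gte(nb, 0L)
    expect_lte(nb, nchar(n_seq))
  }
})

test_that("singleton filtering keeps exactly the repeated clonotypes", {
  ann <- make_annotated(
    v = "TRAV01-1A", j = "TRAJ01",
    cdr3 = c("CAAF", "CAAF", "CAAF", "CCCF")
  )
  kept <- filter_singletons(ann)
  expect_equal(unique(kept$junction_aa), "CAAF")
  expect_equal(nrow(kept), 3L)

  all_unique <- make_annotated("TRAV01-1A", "TRAJ01",
                               c("CAAF", "CCCF", "CGGF"))
  expect_equal(nrow(filter_singletons(all_unique)), 0L)

  mixed <- make_annotated("TRAV01-1A", "TRAJ01",
                          c("CAAF", "CAAF", "CCCF", "CCCF", "CGGF"))
  expect_equal(nrow(filter_singletons(mixed)), 4L)
  expect_setequal(unique(filter_singletons(mixed)$junction_aa),
                  c("CAAF", "CCCF"))

  expect_equal(nrow(filter_singletons(ann[0, ])), 0L)
  two_samples <- ann
  two_samples$sample_id[1] <- "s2"
  expect_error(filter_singletons(two_samples), "single sample")
})

test_that("full annotation recovers planted reads and flags junk", {
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    nt_sequence = c(make_read(v1, j1, "GGG"),
                    make_read(v2, j1, "GCAA", t_v = 1L, t_j = 2L),
                    paste(rep("ACGT", 23), collapse = "")),
    sample_id = "s1"
  )
  ann <- annotate_reads(reads, groups = groups)
  expect_equal(ann$v_call[1], "TRAV01-1A")
  expect_equal(ann$j_call[1:2], c("TRAJ01", "TRAJ01"))
  expect_match(ann$flag[3], "unassignable")
  expect_true(all(substr(ann$junction_aa[ann$productive], 1, 1) == "C"))
})
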