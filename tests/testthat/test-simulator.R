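test_that("the simulated reference validates and plants duplications", {
  cfg <- small_config()
  ref <- simulate_reference(cfg)
  expect_s3_class(ref, "germline_reference")
  groups <- collapse_indistinguishable(ref)
  sizes <- vapply(groups$members, length, integer(1))
  expect_true(any(sizes == 3))  # planted A/D/N triple
  expect_true(any(sizes == 2))  # planted A/D pair
  expect_equal(sum(sizes), nrow(ref))

  # round-trips through FASTA + TSV and is byte-stable across calls
  fa1 <- tempfile(fileext = ".fasta")
  fa2 <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_reference(ref, fa1, tsv)
  write_reference(simulate_reference(cfg), fa2, tsv)
  expect_equal(readLines(fa1), readLines(fa2))
  expect_equal(as.data.frame(load_reference(fa1, tsv)), as.data.frame(ref))
})

test_that("rearrangement draws respect the configured distributions", {
  cfg <- small_config(j_positional_bias = 0)
  ref <- simulate_reference(cfg)
  cand <- simulate_rearrangements(ref, cfg, 6000, seed = 5)

  # neutral positional bias: J usage uniform within multinomial noise
  freq <- table(factor(cand$j_id, levels = sprintf("TRAJ%02d",
                                                   1:cfg$n_j_segments)))
  p0 <- 1 / cfg$n_j_segments
  expect_lt(max(abs(freq / sum(freq) - p0)), 4 * sqrt(p0 / 6000) + 0.005)

  # strong bias makes the most-distal J the mode
  cfg2 <- small_config(j_positional_bias = 1.5)
  cand2 <- simulate_rearrangements(ref, cfg2, 2000, seed = 5)
  expect_equal(names(which.max(table(cand2$j_id))),
               sprintf("TRAJ%02d", cfg$n_j_segments))

  # ground truth reconstructs every candidate read exactly
  vt <- tcrarep:::distinct_v_table(ref)
  jt <- ref[ref$kind == "J", ]
  rebuilt <- paste0(
    substr(vt$nt_sequence[match(cand$v_stem, vt$stem)], 1, 60 - cand$t_v),
    cand$n_seq,
    substr(jt$nt_sequence[match(cand$j_id, jt$segment_id)], 1 + cand$t_j, 48)
  )
  expect_equal(rebuilt, cand$read)
})

test_that("with trimming off the canonical N count equals the drawn count", {
  cfg <- small_config(v_trim = list(max = 0L, p = 0.5),
                      j_trim = list(max = 0L, p = 0.5))
  ref <- simulate_reference(cfg)
  cand <- simulate_rearrangements(ref, cfg, 800, seed = 6)
  expect_equal(cand$n_bases, cand$n_drawn)
})

test_that("hash selection is deterministic, genotype-specific and calibrated", {
  cfg <- small_config(selection = list(mode = "hash_acceptance",
                                       acceptance_rate = 0.1))
  set.seed(13)
  aa_pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cdr3 <- unique(vapply(1:4000, function(i) {
    paste0("C", paste(sample(aa_pool, 7, replace = TRUE), collapse = ""), "F")
  }, character(1)))

  acc1 <- apply_selection(cdr3, "b:DObWT", cfg)
  acc2 <- apply_selection(cdr3, "b:DObWT", cfg)
  expect_identical(acc1, acc2)   # same genotype, same fate

  accA <- apply_selection(cdr3, "b:DObWT", cfg)
  accB <- apply_selection(cdr3, "f:DObWT", cfg)
  # acceptance rate close to nominal on both keys
  expect_equal(mean(accA), 0.1, tolerance = 0.25)
  # cross-genotype sharing of accepted sets ~ acceptance_rate
  shared_frac <- mean(accB[accA])
  p <- 0.1
  ci <- 4 * sqrt(p * (1 - p) / sum(accA))
  expect_lt(abs(shared_frac - p), ci)

  # rate 1 keeps everything
  cfg1 <- small_config(selection = list(mode = "hash_acceptance",
                                        acceptance_rate = 1))
  expect_true(all(apply_selection(cdr3, "b:DObWT", cfg1)))
  # neutral mode keeps everything too
  cfg0 <- small_config(selection = list(mode = "neutral"))
  expect_true(all(apply_selection(cdr3, "b:DObWT", cfg0)))
})

test_that("amino-acid preference selection enriches the configured motif", {
  cfg <- small_config(selection = list(
    mode = "aa_preference", acceptance_rate = 0.1,
    preferences = list(list(length = 12L, position = 4L, aa = "R",
                            boost = 8))
  ))
  set.seed(17)
  aa_pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cdr3 <- vapply(1:4000, function(i) {
    paste0("C", paste(sample(aa_pool, 10, replace = TRUE), collapse = ""),
           "F")
  }, character(1))  # all length 12
  acc <- apply_selection(cdr3, "b:DObWT", cfg)
  hit <- substr(cdr3, 4, 4) == "R"
  expect_gt(mean(acc[hit]), 3 * mean(acc[!hit]))
})

test_that("cohort simulation is deterministic and internally consistent", {
  cfg <- small_config(error_rate = 0.002, depth = 400L, richness = 60L)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$reads$nt_sequence, sim2$reads$nt_sequence)
  expect_identical(sim1$truth$clonotypes$read, sim2$truth$clonotypes$read)

  # counts sum to depth per mouse; pre-error reads match their clonotype
  clono <- sim1$truth$clonotypes
  per_mouse <- tapply(clono$count, clono$sample_id, sum)
  expect_true(all(per_mouse == 400L))
  m <- match(sim1$reads$clonotype_id, clono$clonotype_id)
  expect_identical(sim1$reads$pre_error, clono$read[m])

  # within-genotype sharing structurally exceeds between for hash selection
  key <- paste(clono$v_group, clono$j_group, clono$cdr3_aa, sep = "|")
  sets <- split(key, clono$sample_id)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  within <- jac(sets$m_b_DObWT_1, sets$m_b_DObWT_2)
  between <- mean(c(jac(sets$m_b_DObWT_1, sets$m_f_DObWT_1),
                    jac(sets$m_b_DObWT_2, sets$m_f_DObWT_2)))
  expect_gt(within, between)
})

test_that("error-free cohorts are recovered perfectly end to end", {
  cfg <- small_config(depth = 500L, richness = 60L, error_rate = 0)
  sim <- simulate_cohort(cfg)
  sid <- sim$design$sample_id[1]
  reads <- sim$reads[sim$reads$sample_id == sid, ]
  ann <- annotate_reads(
    tibble::tibble(read_id = reads$read_id,
                   nt_sequence = reads$nt_sequence, sample_id = sid),
    groups = sim$groups
  )
  truth <- sim$truth$clonotypes
  m <- match(reads$clonotype_id, truth$clonotype_id)
  expect_true(all(ann$productive))
  expect_equal(ann$v_call, truth$v_group[m])
  expect_equal(ann$j_call, truth$j_group[m])
  expect_equal(ann$junction_aa, truth$cdr3_aa[m])
  expect_equal(ann$n_bases, truth$n_bases[m])
  expect_equal(ann$corrections_applied, rep(0L, nrow(ann)))
})
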