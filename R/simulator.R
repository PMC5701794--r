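#' Configuration for the V(D)J rearrangement-and-selection simulator
#'
#' The generator emulates the observable structure of single-TCRb-chain
#' mouse cohorts: a germline segment pool with duplicated (indistinguishable)
#' V subfamily members, V accessibility weights, an exponential tilt towards
#' TRAJs distal to the TRAV locus, geometric exonucleolytic trimming and
#' geometric N-base addition at the junction, a deterministic
#' genotype-specific selection filter that induces within-genotype clonotype
#' sharing, lognormal (uneven, non-Poissonian) clonal abundances, and
#' per-base substitution sequencing errors.
#'
#' @param n_v_segments,n_j_segments Numbers of distinct V and J germline
#'   sequences.
#' @param v_duplication List of duplication-class letter sets; the first
#'   `length(v_duplication)` V sequences are emitted once per letter as
#'   byte-identical alleles (exercising ambiguity-group collapapsing).
#' @param v_accessibility_weights Probability vector over the distinct V
#'   sequences (default uniform).
#' @param j_positional_bias Strength b >= 0 of the distal-TRAJ preference:
#'   P(J_i) proportional to exp(b * i) with i increasing towards the distal
#'   end of the locus.
#' @param v_trim,j_trim Lists `list(max, p)`: junction-end trimming is
#'   geometric(p) censored at `max` bases.
#' @param n_addition List `list(max, p)`: untemplated base count is
#'   geometric(p) censored at `max`.
#' @param selection List `list(mode, acceptance_rate, preferences)`. Modes:
#'   `"neutral"` (every productive candidate kept), `"hash_acceptance"`
#'   (accept iff a deterministic hash of (CDR3a, genotype key) falls below
#'   `acceptance_rate`; identical CDR3a are accepted identically in all mice
#'   of a genotype) and `"aa_preference"` (hash acceptance with the rate
#'   multiplied by `boost` for CDR3a matching a preference
#'   `list(length, position, aa, boost)`).
#' @param abundance List `list(distribution, sigma)`; `"lognormal"` clonal
#'   weights (x generation multiplicity) or `"uniform"`.
#' @param error_rate Per-base substitution probability.
#' @param depth Reads emitted per mouse.
#' @param richness Selected clonotype draws per mouse.
#' @param n_mice_per_genotype,mhc_alleles,tcrb_chains Cohort layout.
#' @param seed Master seed (mandatory); every stage draws from a named
#'   substream derived from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_v_segments = 16L,
                              n_j_segments = 18L,
                              v_duplication = list(c("A", "D", "N"),
                                                   c("A", "D")),
                              v_accessibility_weights = NULL,
                              j_positional_bias = 0.15,
                              v_trim = list(max = 6L, p = 0.45),
                              j_trim = list(max = 6L, p = 0.45),
                              n_addition = list(max = 12L, p = 0.2),
                              selection = list(mode = "hash_acceptance",
                                               acceptance_rate = 0.1,
                                               preferences = NULL),
                              abundance = list(distribution = "lognormal",
                                               sigma = 1.5),
                              error_rate = 0.002,
                              depth = 5000L,
                              richness = 300L,
                              n_mice_per_genotype = 3L,
                              mhc_alleles = c("b", "f", "s"),
                              tcrb_chains = c("DObWT", "DOb48A"),
                              seed) {
  if (missing(seed)) {
    abort("simulation_config() requires an explicit seed")
  }
  if (is.null(v_accessibility_weights)) {
    v_accessibility_weights <- rep(1 / n_v_segments, n_v_segments)
  }
  if (length(v_accessibility_weights) != n_v_segments ||
      abs(sum(v_accessibility_weights) - 1) > 1e-8 ||
      any(v_accessibility_weights < 0)) {
    abort("v_accessibility_weights must be a probability vector over the V segments")
  }
  stopifnot(
    n_v_segments >= 2L, n_j_segments >= 2L,
    j_positional_bias >= 0,
    error_rate >= 0, error_rate <= 1,
    selection$mode %in% c("neutral", "hash_acceptance", "aa_preference"),
    abundance$distribution %in% c("lognormal", "uniform")
  )
  if (selection$mode != "neutral") {
    rate <- selection$acceptance_rate
    if (is.null(rate) || rate <= 0 || rate > 1) {
      abort("selection$acceptance_rate must be in (0, 1]")
    }
  }
  if (length(v_duplication) > n_v_segments) {
    abort("more duplication specs than V segments")
  }
  structure(
    list(n_v_segments = as.integer(n_v_segments),
         n_j_segments = as.integer(n_j_segments),
         v_duplication = v_duplication,
         v_accessibility_weights = v_accessibility_weights,
         j_positional_bias = j_positional_bias,
         v_trim = v_trim, j_trim = j_trim, n_addition = n_addition,
         selection = selection, abundance = abundance,
         error_rate = error_rate, depth = as.integer(depth),
         richness = as.integer(richness),
         n_mice_per_genotype = as.integer(n_mice_per_genotype),
         mhc_alleles = mhc_alleles, tcrb_chains = tcrb_chains,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Segment geometry shared by the generator: V = 51 nt body + Cys anchor +
# 6 trimmable nt; J = 12 trimmable nt + F/W/L anchor + G codon + 30 nt.
V_LEN <- 60L
V_ANCHOR <- 51L
J_LEN <- 48L
J_ANCHOR <- 12L

# Gene segments are protein coding: the CDR3-contributing stretches (the V
# tail after the Cys, the J run-up to the F/W/L) must not carry in-frame
# stop codons, otherwise productivity would spuriously depend on segment
# identity.
STOP_CODONS <- c("TAA", "TAG", "TGA")
random_coding <- function(n_codons) {
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- random_dna(3)
      if (!cd %in% STOP_CODONS) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

#' Simulate a germline TRAV/TRAJ reference
#'
#' Random V segments carrying a terminal-region cysteine anchor and J
#' segments carrying an F/W/L-G anchor motif; the configured duplication
#' sets are emitted as byte-identical alleles under A/D/N letters so that
#' ambiguity-group collapsing is exercised.  TRAJ numbering increases
#' towards the distal end of the locus.
#'
#' @param config A `simulation_config`.
#' @return A validated `germline_reference`.
#' @export
simulate_reference <- function(config) {
  with_seed(derive_seed(config$seed, "reference"), {
    rows <- list()
    for (i in seq_len(config$n_v_segments)) {
      seq_i <- paste0(random_dna(V_ANCHOR), "TGT", random_coding(2))
      letters_i <- if (i <= length(config$v_duplication)) {
        config$v_duplication[[i]]
      } else {
        "A"
      }
      for (lt in letters_i) {
        rows[[length(rows) + 1L]] <- tibble(
          segment_id = sprintf("TRAV%02d-1%s", i, lt),
          kind = "V", family = i, subfamily = 1L, dup_class = lt,
          nt_sequence = seq_i, anchor_offset = V_ANCHOR
        )
      }
    }
    for (j in seq_len(config$n_j_segments)) {
      anchor <- sample(c("TTT", "TTC", "TGG", "TTG", "CTG", "CTC"), 1)
      gly <- sample(c("GGA", "GGC", "GGG", "GGT"), 1)
      rows[[length(rows) + 1L]] <- tibble(
        segment_id = sprintf("TRAJ%02d", j),
        kind = "J", family = j, subfamily = 1L, dup_class = "none",
        nt_sequence = paste0(random_coding(4), anchor, gly,
                             random_dna(30)),
        anchor_offset = J_ANCHOR
      )
    }
    germline_reference(bind_rows(rows))
  })
}

# Distinct V sequences with their member allele ids.
distinct_v_table <- function(reference) {
  v <- reference[reference$kind == "V", ]
  v$stem <- segment_stem(v$segment_id, v$dup_class)
  idx <- split(seq_len(nrow(v)), match(v$stem, unique(v$stem)))
  tibble(
    stem = unique(v$stem),
    nt_sequence = vapply(idx, function(i) v$nt_sequence[i[1]], character(1)),
    members = lapply(idx, function(i) v$segment_id[i])
  )
}

# Censored-geometric draw: min(Geom(p), max).
rgeom_capped <- function(n, p, max) {
  pmin(stats::rgeom(n, p), max)
}

# Analytical mean of the censored geometric, E[min(Geom(p), max)].
mean_geom_capped <- function(p, max) {
  ((1 - p) / p) * (1 - (1 - p)^max)
}

#' Simulate V-J rearrangement candidates
#'
#' Draws V by accessibility weight, J with the distal exponential tilt,
#' censored-geometric trims and N additions, and assembles the
#' pre-selection, pre-error candidate read together with its ground truth
#' (including the canonical, maximal-V-extension-first N-base attribution
#' actually recoverable from sequence).
#'
#' @param reference A `germline_reference` (typically from
#'   [simulate_reference()]).
#' @param config A `simulation_config`.
#' @param n Number of candidates.
#' @param seed Optional seed; when NULL the current RNG state is used.
#' @return Tibble with one row per candidate: segment ids/groups, trims,
#'   `n_drawn`, `n_seq`, `read`, `cdr3_nt`, `cdr3_aa`, `productive`,
#'   `n_bases`.
#' @export
simulate_rearrangements <- function(reference, config, n, seed = NULL) {
  run <- function() add_truth_n_bases(rearrange_batch(reference, config, n),
                                      reference)
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Canonical N-base attribution of the pre-error read, computed with the
# same maximal-extension convention the annotation reports (the drawn N
# count itself is not identifiable once trimming is in play).
add_truth_n_bases <- function(cand, reference) {
  if (nrow(cand) == 0) {
    cand$n_bases <- integer(0)
    return(cand)
  }
  vt <- distinct_v_table(reference)
  jt <- reference[reference$kind == "J", ]
  v_seq <- vt$nt_sequence[match(cand$v_stem, vt$stem)]
  j_seq <- jt$nt_sequence[match(cand$j_id, jt$segment_id)]
  uniq <- !duplicated(cand$read)
  nb <- mapply(estimate_n_bases, cand$read[uniq], v_seq[uniq], j_seq[uniq],
               USE.NAMES = FALSE)
  cand$n_bases <- as.integer(nb[match(cand$read, cand$read[uniq])])
  cand
}

rearrange_batch <- function(reference, config, n) {
  vt <- distinct_v_table(reference)
  jt <- reference[reference$kind == "J", ]
  n_j <- nrow(jt)
  w_j <- exp(config$j_positional_bias * (seq_len(n_j) - 1))
  w_j <- w_j / sum(w_j)

  v_i <- sample.int(nrow(vt), n, replace = TRUE,
                    prob = config$v_accessibility_weights)
  j_i <- sample.int(n_j, n, replace = TRUE, prob = w_j)
  t_v <- rgeom_capped(n, config$v_trim$p, config$v_trim$max)
  t_j <- rgeom_capped(n, config$j_trim$p, config$j_trim$max)
  n_len <- rgeom_capped(n, config$n_addition$p, config$n_addition$max)

  n_seq <- character(n)
  total <- sum(n_len)
  if (total > 0) {
    bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    grp <- rep.int(seq_len(n), n_len)
    sp <- split(bases, grp)
    n_seq[as.integer(names(sp))] <-
      vapply(sp, paste, character(1), collapse = "")
  }
  # true source allele: uniform over indistinguishable duplicate members
  v_member <- vapply(v_i, function(i) {
    m <- vt$members[[i]]
    if (length(m) == 1L) m else sample(m, 1)
  }, character(1))

  v_seq <- vt$nt_sequence[v_i]
  j_seq <- jt$nt_sequence[j_i]
  read <- paste0(substr(v_seq, 1L, V_LEN - t_v), n_seq,
                 substr(j_seq, 1L + t_j, J_LEN))
  lr <- nchar(read)

  anchors_ok <- t_v <= (V_LEN - V_ANCHOR - 3L) & t_j <= J_ANCHOR
  p_v <- V_ANCHOR + 1L
  p_j <- lr - J_LEN + J_ANCHOR + 1L
  cdr3_nt <- ifelse(anchors_ok, substr(read, p_v, p_j + 2L), NA_character_)
  in_frame <- anchors_ok & nchar(cdr3_nt) %% 3L == 0L
  cdr3_aa <- rep(NA_character_, n)
  cdr3_aa[in_frame] <- translate_nt(cdr3_nt[in_frame])
  productive <- in_frame & !is.na(cdr3_aa) &
    !grepl("*", cdr3_aa, fixed = TRUE)

  tibble(
    v_id = v_member, j_id = jt$segment_id[j_i],
    v_stem = vt$stem[v_i],
    t_v = t_v, t_j = t_j, n_drawn = n_len, n_seq = n_seq,
    read = read, cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
    productive = productive
  )
}

#' Deterministic selection of productive candidates
#'
#' In `hash_acceptance` mode a candidate CDR3a is accepted for a genotype
#' iff a deterministic 32-bit hash of the pair (CDR3a, genotype key),
#' mapped to [0, 1), falls below the acceptance rate — so the same CDR3a
#' meets the same fate in every mouse of a genotype, while the accepted
#' sets of two genotypes overlap only by chance (about `acceptance_rate`
#' of either set).  In `aa_preference` mode the rate is additionally
#' multiplied by a boost for CDR3a matching configured positional
#' amino-acid preferences (planting detectable enrichments).
#'
#' @param cdr3_aa Character vector of productive CDR3a sequences.
#' @param genotype Genotype key (e.g. `"b:DObWT"`).
#' @param config A `simulation_config`.
#' @return Logical acceptance vector.
#' @export
apply_selection <- function(cdr3_aa, genotype, config) {
  mode <- config$selection$mode
  if (mode == "neutral") {
    return(rep(TRUE, length(cdr3_aa)))
  }
  rate <- rep(config$selection$acceptance_rate, length(cdr3_aa))
  if (mode == "aa_preference") {
    for (pref in config$selection$preferences) {
      hit <- nchar(cdr3_aa) == pref$length &
        substr(cdr3_aa, pref$position, pref$position) == pref$aa
      rate[hit] <- rate[hit] * pref$boost
    }
    rate <- pmin(1, rate)
  }
  # genotype key first: the differing bytes enter the hash early and get
  # diffused through every subsequent multiply round
  hash_unit(paste0(genotype, "::", cdr3_aa)) < rate
}

# Draw `n_needed` accepted productive candidates for one genotype,
# batching until filled.
draw_selected <- function(reference, config, genotype, n_needed) {
  got <- list()
  have <- 0L
  p_hat <- 0.25 * if (config$selection$mode == "neutral") 1 else
    config$selection$acceptance_rate
  for (iter in 1:60) {
    if (have >= n_needed) break
    b <- as.integer(min(2e5, max(2000, ceiling((n_needed - have) / p_hat))))
    cand <- rearrange_batch(reference, config, b)
    cand <- cand[cand$productive, , drop = FALSE]
    if (nrow(cand) > 0) {
      keep <- apply_selection(cand$cdr3_aa, genotype, config)
      cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand) > 0) {
      got[[length(got) + 1L]] <- cand
      have <- have + nrow(cand)
    }
  }
  if (have < n_needed) {
    abort(paste0("selection too strict: could not draw ", n_needed,
                 " accepted clonotypes for genotype ", genotype))
  }
  out <- bind_rows(got)
  add_truth_n_bases(out[seq_len(n_needed), , drop = FALSE], reference)
}

apply_sequencing_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) {
    return(seqs)
  }
  lens <- nchar(seqs)
  total <- sum(lens)
  hit <- which(stats::runif(total) < error_rate)
  if (length(hit) == 0) {
    return(seqs)
  }
  ends <- cumsum(lens)
  read_idx <- findInterval(hit - 1L, ends) + 1L
  pos <- hit - c(0L, ends)[read_idx]
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(hit)) {
    i <- read_idx[k]
    old <- substr(seqs[i], pos[k], pos[k])
    new <- sample(setdiff(bases, old), 1)
    substr(seqs[i], pos[k], pos[k]) <- new
  }
  seqs
}

#' Simulate a full per-mouse read cohort with ground truth
#'
#' For every genotype (MHC allele x TCRb chain) and mouse: selected
#' clonotypes are drawn from the rearrangement-plus-selection process,
#' clonal abundances follow the configured (by default lognormal, i.e.
#' uneven and non-Poissonian) model scaled by generation multiplicity,
#' reads are emitted to the configured depth and substitution errors
#' applied.  Everything is a pure function of the config (and its seed).
#'
#' @param config A `simulation_config`.
#' @param emit_reads When FALSE, stop after the clonotype tables (much
#'   faster; read-level truth absent).
#' @param dir Optional output directory: writes reference FASTA/TSV,
#'   per-sample read FASTA, ground-truth TSVs and a cohort design YAML.
#' @return List of class `tcra_cohort_sim` with `config`, `reference`,
#'   `groups`, `design`, `truth` (`clonotypes`, `reads`,
#'   `genotype_shared`) and `reads` (per-read tibble incl. pre-error
#'   sequence) when emitted.
#' @export
simulate_cohort <- function(config, emit_reads = TRUE, dir = NULL) {
  reference <- simulate_reference(config)
  groups <- collapse_indistinguishable(reference)
  v_groups <- groups[groups$kind == "V", ]
  stem_to_group <- stats::setNames(
    v_groups$group_id,
    vapply(v_groups$members, function(m)
      segment_stem(m[1], substr(m[1], nchar(m[1]), nchar(m[1]))),
      character(1))
  )

  genotypes <- expand.grid(mhc_allele = config$mhc_alleles,
                           tcrb = config$tcrb_chains,
                           stringsAsFactors = FALSE)
  design <- list()
  clono_all <- list()
  reads_all <- list()

  for (gi in seq_len(nrow(genotypes))) {
    mhc <- genotypes$mhc_allele[gi]
    beta <- genotypes$tcrb[gi]
    gkey <- paste(mhc, beta, sep = ":")
    n_mice <- config$n_mice_per_genotype
    drawn <- with_seed(
      derive_seed(config$seed, paste0("genotype:", gkey)),
      draw_selected(reference, config, gkey,
                    n_mice * config$richness)
    )
    for (mi in seq_len(n_mice)) {
      sample_id <- sprintf("m_%s_%s_%d", mhc, beta, mi)
      rows <- drawn[((mi - 1) * config$richness + 1):(mi * config$richness), ]
      # collapse repeat draws of the same rearrangement (convergent
      # generation); multiplicity feeds the abundance weight
      key <- rows$read
      first <- !duplicated(key)
      mult <- as.integer(table(key)[key[first]])
      cl <- rows[first, , drop = FALSE]
      k <- nrow(cl)

      counts <- with_seed(
        derive_seed(config$seed, paste0("abundance:", sample_id)), {
          w <- if (config$abundance$distribution == "lognormal") {
            mult * stats::rlnorm(k, 0, config$abundance$sigma)
          } else {
            as.numeric(mult)
          }
          as.vector(stats::rmultinom(1, config$depth, w))
        }
      )
      keep <- counts > 0
      cl <- cl[keep, , drop = FALSE]
      counts <- counts[keep]
      cl$count <- counts
      cl$sample_id <- sample_id
      cl$clonotype_id <- sprintf("%s_c%04d", sample_id, seq_len(nrow(cl)))
      cl$v_group <- unname(stem_to_group[cl$v_stem])
      cl$j_group <- cl$j_id
      clono_all[[length(clono_all) + 1L]] <- cl

      design[[length(design) + 1L]] <- tibble(
        sample_id = sample_id, mouse_id = sample_id,
        mhc_allele = mhc, tcrb = beta, compartment = "naive_CD4"
      )

      if (emit_reads) {
        pre <- base::rep.int(cl$read, cl$count)
        cids <- base::rep.int(cl$clonotype_id, cl$count)
        post <- with_seed(
          derive_seed(config$seed, paste0("errors:", sample_id)),
          apply_sequencing_errors(pre, config$error_rate)
        )
        reads_all[[length(reads_all) + 1L]] <- tibble(
          read_id = sprintf("%s_r%05d", sample_id, seq_along(pre)),
          sample_id = sample_id, clonotype_id = cids,
          nt_sequence = post, pre_error = pre
        )
      }
    }
  }

  clono <- bind_rows(clono_all)
  reads <- if (emit_reads) bind_rows(reads_all) else NULL
  design <- bind_rows(design)

  full_key <- paste(clono$v_group, clono$j_group, clono$cdr3_aa, sep = "|")
  shared <- lapply(split(seq_len(nrow(clono)),
                         paste(design$mhc_allele[match(clono$sample_id,
                                                       design$sample_id)],
                               design$tcrb[match(clono$sample_id,
                                                 design$sample_id)],
                               sep = ":")),
                   function(idx) {
                     per_mouse <- split(full_key[idx], clono$sample_id[idx])
                     Reduce(intersect, per_mouse)
                   })

  sim <- structure(
    list(config = config, reference = reference, groups = groups,
         design = design,
         truth = list(clonotypes = clono, genotype_shared = shared),
         reads = reads),
    class = "tcra_cohort_sim"
  )
  if (!is.null(dir)) {
    write_cohort(sim, dir)
  }
  sim
}

#' @export
print.tcra_cohort_sim <- function(x, ...) {
  cat("<tcra_cohort_sim>", nrow(x$design), "mice,",
      nrow(x$truth$clonotypes), "clonotype records",
      if (is.null(x$reads)) "(no reads emitted)" else
        paste0(", ", nrow(x$reads), " reads"), "\n")
  invisible(x)
}

# Write a simulated cohort to standard on-disk formats.
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reference(sim$reference, file.path(dir, "reference.fasta"),
                  file.path(dir, "reference.tsv"))
  utils::write.table(
    sim$truth$clonotypes[, c("sample_id", "clonotype_id", "v_id", "j_id",
                             "v_group", "j_group", "t_v", "t_j", "n_drawn",
                             "n_bases", "cdr3_nt", "cdr3_aa", "read",
                             "count")],
    file.path(dir, "truth_clonotypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(sim$reads)) {
    for (sid in unique(sim$reads$sample_id)) {
      sub <- sim$reads[sim$reads$sample_id == sid, ]
      ss <- Biostrings::DNAStringSet(sub$nt_sequence)
      names(ss) <- sub$read_id
      Biostrings::writeXStringSet(ss, file.path(dir, paste0(sid, ".fasta")))
    }
    utils::write.table(sim$reads[, c("read_id", "sample_id", "clonotype_id",
                                     "pre_error")],
                       file.path(dir, "truth_reads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  design_yaml <- lapply(seq_len(nrow(sim$design)), function(i) {
    as.list(sim$design[i, ])
  })
  names(design_yaml) <- sim$design$sample_id
  yaml::write_yaml(list(samples = design_yaml),
                   file.path(dir, "design.yaml"))
  invisible(sim)
}
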