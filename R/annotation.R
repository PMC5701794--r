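#' Read TCRa junction-spanning reads from FASTA or FASTQ
#'
#' Qualities in FASTQ input are ignored; reads are assumed to start at the
#' first base of the rearranged V segment and to run through the J.
#'
#' @param path FASTA/FASTQ file (format detected from the extension).
#' @param sample_id Sample identifier attached to every read.
#' @return Tibble with columns `read_id`, `nt_sequence`, `sample_id`.
#' @export
read_reads <- function(path, sample_id) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    "fastq"
  } else {
    "fasta"
  }
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(
    read_id = sub("\\s.*$", "", names(seqs)),
    nt_sequence = as.character(seqs),
    sample_id = sample_id
  )
}

# Per-group scoring of an end-anchored ungapped alignment.  For V the
# germline prefix is laid on the read 5' end; for J the germline suffix on
# the read 3' end.  Candidate spans shorten the germline by 0..max_trim
# junction-proximal bases (modelling exonucleolytic trimming); within a
# group the span with the fewest mismatches (ties: longest span) wins,
# subject to the mismatch-rate ceiling.
score_group <- function(read_bytes, germ_bytes, from_end, max_trim,
                        max_mismatch_rate) {
  lg <- length(germ_bytes)
  lr <- length(read_bytes)
  if (from_end) {
    read_bytes <- rev(read_bytes)
    germ_bytes <- rev(germ_bytes)
  }
  k <- min(lg, lr)
  mm <- cumsum(read_bytes[seq_len(k)] != germ_bytes[seq_len(k)])
  spans <- lg - (0:max_trim)
  spans <- spans[spans >= 1L & spans <= k]
  if (length(spans) == 0L) {
    return(NULL)
  }
  m <- mm[spans]
  ok <- m <= floor(max_mismatch_rate * spans)
  if (!any(ok)) {
    return(NULL)
  }
  spans <- spans[ok]
  m <- m[ok]
  best_m <- min(m)
  best_span <- max(spans[m == best_m])
  list(mismatches = best_m, span = best_span)
}

#' Assign a read to its best-matching V or J ambiguity group
#'
#' Ungapped, end-anchored alignment of each group representative against the
#' read's 5' end (V) or 3' end (J), allowing up to `max_trim` germline bases
#' to have been removed at the junction-proximal end.  The winning group has
#' the fewest mismatches; ties are broken by longer aligned span, then by
#' lexicographic group id.  Reads whose best alignment exceeds the mismatch
#' ceiling are flagged unassignable.
#'
#' @param nt_sequence Read sequence (single string).
#' @param groups An `ambiguity_groups` tibble.
#' @param kind `"V"` or `"J"`.
#' @param max_trim Maximum junction-proximal germline truncation considered.
#' @param max_mismatch_rate Ceiling on mismatches per aligned base.
#' @return `NULL` if unassignable, else a list with `group_id`, `span`
#'   (0-based half-open interval on the read) and `mismatch_count`.
#' @export
assign_segment <- function(nt_sequence, groups, kind = c("V", "J"),
                           max_trim = 15L, max_mismatch_rate = 0.1) {
  kind <- match.arg(kind)
  g <- groups[groups$kind == kind, ]
  if (nrow(g) == 0L) {
    abort(paste0("no ambiguity groups of kind ", kind))
  }
  read_bytes <- utf8ToInt(nt_sequence)
  best <- NULL
  for (i in order(g$group_id)) {
    sc <- score_group(read_bytes, utf8ToInt(g$representative_sequence[i]),
                      from_end = (kind == "J"), max_trim, max_mismatch_rate)
    if (is.null(sc)) next
    if (is.null(best) || sc$mismatches < best$mismatches ||
        (sc$mismatches == best$mismatches && sc$span > best$span)) {
      best <- c(sc, list(group_id = g$group_id[i], idx = i))
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  span <- if (kind == "V") {
    c(0L, best$span)
  } else {
    c(length(read_bytes) - best$span, length(read_bytes))
  }
  list(group_id = best$group_id, span = span,
       mismatch_count = best$mismatches)
}

#' Correct sequencing errors against germline outside the junction window
#'
#' Within the V-aligned span, read bases that disagree with germline are
#' replaced by the germline base only at positions more than three
#' nucleotides before the predicted V end; within the J span, only at
#' positions more than three nucleotides after the predicted J start.  The
#' three junction-proximal positions on each side, and everything between
#' the spans, are never touched, so untemplated (N-region) bases cannot be
#' "corrected" away.  Overlapping V/J spans (a junction-free read) disable
#' correction inside the overlap and flag the read.
#'
#' @param nt_sequence Read sequence.
#' @param v_alignment,j_alignment Lists with `sequence` (group
#'   representative) and `span` as returned by [assign_segment()].
#' @return List with `corrected_nt`, `corrections_applied` and
#'   `overlap_flagged`.
#' @export
correct_errors <- function(nt_sequence, v_alignment, j_alignment) {
  rb <- utf8ToInt(nt_sequence)
  lr <- length(rb)
  sv <- v_alignment$span[2]           # V span end (1-based length)
  sjs <- j_alignment$span[1] + 1L     # J span start, 1-based
  overlap <- sjs <= sv

  vb <- utf8ToInt(v_alignment$sequence)
  jb <- utf8ToInt(j_alignment$sequence)
  t_j <- length(jb) - (lr - sjs + 1L) # germline J bases trimmed at its 5' end

  n_corr <- 0L
  if (sv >= 1L) {
    pv <- seq_len(max(0L, sv - 4L))
    if (overlap) pv <- pv[pv < sjs]
    fix <- pv[rb[pv] != vb[pv]]
    rb[fix] <- vb[fix]
    n_corr <- n_corr + length(fix)
  }
  pj <- if (sjs + 4L <= lr) seq.int(sjs + 4L, lr) else integer(0)
  if (overlap) pj <- pj[pj > sv]
  if (length(pj) > 0) {
    gj <- jb[t_j + (pj - sjs) + 1L]
    fix <- pj[rb[pj] != gj]
    rb[fix] <- jb[t_j + (fix - sjs) + 1L]
    n_corr <- n_corr + length(fix)
  }
  list(corrected_nt = intToUtf8(rb),
       corrections_applied = n_corr,
       overlap_flagged = overlap)
}

#' Extract the CDR3a from an annotated read
#'
#' The CDR3a runs from the first base of the conserved V-end cysteine codon
#' through the last base of the conserved J F/W/L codon, inclusive.  A read
#' is productive when the junction length is a multiple of three, its
#' translation starts with C, ends with F, W or L, and contains no stop.
#'
#' @param nt_sequence Corrected read sequence.
#' @param v_alignment,j_alignment Alignments carrying `sequence`, `span` and
#'   `anchor_offset` (0-based, on the germline representative).
#' @return List with `cdr3_nt`, `cdr3_aa`, `productive` and `ok` (FALSE when
#'   an anchor falls outside its aligned span).
#' @export
extract_cdr3 <- function(nt_sequence, v_alignment, j_alignment) {
  lr <- nchar(nt_sequence)
  sv <- v_alignment$span[2]
  sjs <- j_alignment$span[1] + 1L
  lj <- nchar(j_alignment$sequence)
  t_j <- lj - (lr - sjs + 1L)

  p_v <- v_alignment$anchor_offset + 1L
  p_j <- lr - lj + j_alignment$anchor_offset + 1L
  fail <- list(cdr3_nt = NA_character_, cdr3_aa = NA_character_,
               productive = FALSE, ok = FALSE)
  if (p_v + 2L > sv) return(fail)                 # Cys codon not in V span
  if (j_alignment$anchor_offset < t_j) return(fail) # anchor trimmed away
  if (p_j < sjs || p_j + 2L > lr) return(fail)
  if (p_j < p_v) return(fail)

  cdr3_nt <- substr(nt_sequence, p_v, p_j + 2L)
  in_frame <- nchar(cdr3_nt) %% 3L == 0L
  cdr3_aa <- if (in_frame) translate_nt(cdr3_nt) else NA_character_
  productive <- in_frame && !is.na(cdr3_aa) &&
    substr(cdr3_aa, 1L, 1L) == "C" &&
    substr(cdr3_aa, nchar(cdr3_aa), nchar(cdr3_aa)) %in% c("F", "W", "L") &&
    !grepl("*", cdr3_aa, fixed = TRUE)
  list(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, productive = productive,
       ok = TRUE)
}

#' Estimate the number of untemplated (N-region) bases
#'
#' Bases are attributed to germline greedily: the maximal contiguous 5'
#' stretch of the read matching the germline V is assigned to V first, then
#' the maximal contiguous 3' stretch matching the germline J is assigned to
#' J over the remainder.  What is left over is the N-region estimate
#' (floored at zero).  P-nucleotides are not modelled, so a junction base
#' that happens to match a trimmed germline base is counted as templated.
#'
#' @param nt_sequence Corrected read sequence.
#' @param v_sequence,j_sequence Germline representatives of the assigned
#'   groups.
#' @return Integer N-base estimate.
#' @export
estimate_n_bases <- function(nt_sequence, v_sequence, j_sequence) {
  rb <- utf8ToInt(nt_sequence)
  vb <- utf8ToInt(v_sequence)
  jb <- utf8ToInt(j_sequence)
  lr <- length(rb)

  k <- min(lr, length(vb))
  mm <- rb[seq_len(k)] != vb[seq_len(k)]
  k_v <- if (any(mm)) which.max(mm) - 1L else k

  rem <- lr - k_v
  kj <- min(rem, length(jb))
  if (kj > 0L) {
    mmj <- rev(rb)[seq_len(kj)] != rev(jb)[seq_len(kj)]
    k_j <- if (any(mmj)) which.max(mmj) - 1L else kj
  } else {
    k_j <- 0L
  }
  max(0L, lr - k_v - k_j)
}

#' Clonotype keys for annotated sequences
#'
#' @param annotated Tibble with columns `v_call`, `j_call`, `junction_aa`.
#' @param key_scheme One of `"full_tcra"` (V group + J group + CDR3a amino
#'   acids), `"cdr3_only"`, `"vj_pair"`.
#' @return Character vector of keys (NA where a component is missing).
#' @export
clonotype_key <- function(annotated, key_scheme = c("full_tcra", "cdr3_only",
                                                    "vj_pair")) {
  key_scheme <- match.arg(key_scheme)
  key <- switch(key_scheme,
    full_tcra = paste(annotated$v_call, annotated$j_call,
                      annotated$junction_aa, sep = "|"),
    cdr3_only = annotated$junction_aa,
    vj_pair = paste(annotated$v_call, annotated$j_call, sep = "|")
  )
  if (key_scheme != "cdr3_only") {
    key[is.na(annotated$v_call) | is.na(annotated$j_call) |
          (key_scheme == "full_tcra" & is.na(annotated$junction_aa))] <-
      NA_character_
  }
  key
}

#' Remove clonotypes observed only once in a sample
#'
#' Sequencing errors in the untemplated junction cannot be corrected against
#' germline, so clonotype keys seen a single time in a sequencing run are
#' dropped as probable misreads.
#'
#' @param annotated Annotated sequences from one sample.
#' @param key_scheme Clonotype definition used for counting.
#' @param min_count Minimum occurrences to retain (default 2).
#' @return The retained rows of `annotated`.
#' @export
filter_singletons <- function(annotated, key_scheme = "full_tcra",
                              min_count = 2L) {
  if (nrow(annotated) == 0L) {
    return(annotated)
  }
  if (length(unique(annotated$sample_id)) > 1L) {
    abort("filter_singletons() expects sequences from a single sample")
  }
  key <- clonotype_key(annotated, key_scheme)
  tab <- table(key)
  keep <- !is.na(key) & tab[key] >= min_count
  annotated[keep, , drop = FALSE]
}

#' Annotate junction-spanning TCRa reads against a germline reference
#'
#' Runs the full per-read pipeline: V and J ambiguity-group assignment,
#' germline error correction outside the protected junction window, CDR3a
#' extraction and N-base estimation.  Identical read sequences are processed
#' once and the results joined back, so deeply sequenced clonotypes cost no
#' extra work.
#'
#' @param reads Tibble from [read_reads()] (columns `read_id`,
#'   `nt_sequence`, `sample_id`).
#' @param reference A `germline_reference` (or precomputed
#'   `ambiguity_groups` via `groups`).
#' @param groups Optional `ambiguity_groups`; computed from `reference`
#'   when missing.
#' @param correct Apply germline error correction (default TRUE).
#' @param max_trim,max_mismatch_rate Assignment parameters, see
#'   [assign_segment()].
#' @return AIRR-style rearrangement tibble with one row per read: `read_id`,
#'   `sample_id`, `sequence`, `v_call`, `j_call`, `sequence_corrected`,
#'   `corrections_applied`, `junction`, `junction_aa`, `n_bases`,
#'   `productive`, `flag` plus the aligned span columns.
#' @export
annotate_reads <- function(reads, reference = NULL, groups = NULL,
                           correct = TRUE, max_trim = 15L,
                           max_mismatch_rate = 0.1) {
  if (is.null(groups)) {
    if (is.null(reference)) {
      abort("supply either a germline_reference or precomputed groups")
    }
    groups <- collapse_indistinguishable(reference)
  }
  uniq <- unique(reads$nt_sequence)
  res <- lapply(uniq, function(s) {
    annotate_one(s, groups, correct, max_trim, max_mismatch_rate)
  })
  res <- bind_rows(res)
  res$nt_sequence <- uniq
  out <- left_join(reads, res, by = "nt_sequence")
  out$sequence <- out$nt_sequence
  out$nt_sequence <- NULL
  as_tibble(out[, c("read_id", "sample_id", "sequence", "v_call", "j_call",
                    "v_span_end", "j_span_start", "v_mismatches",
                    "j_mismatches", "sequence_corrected",
                    "corrections_applied", "junction", "junction_aa",
                    "n_bases", "productive", "flag")])
}

annotate_one <- function(s, groups, correct, max_trim, max_mismatch_rate) {
  na_row <- tibble(
    v_call = NA_character_, j_call = NA_character_,
    v_span_end = NA_integer_, j_span_start = NA_integer_,
    v_mismatches = NA_integer_, j_mismatches = NA_integer_,
    sequence_corrected = s, corrections_applied = 0L,
    junction = NA_character_, junction_aa = NA_character_,
    n_bases = NA_integer_, productive = FALSE, flag = NA_character_
  )
  va <- assign_segment(s, groups, "V", max_trim, max_mismatch_rate)
  if (is.null(va)) {
    na_row$flag <- "unassignable_v"
    return(na_row)
  }
  ja <- assign_segment(s, groups, "J", max_trim, max_mismatch_rate)
  if (is.null(ja)) {
    na_row$flag <- "unassignable_j"
    na_row$v_call <- va$group_id
    return(na_row)
  }
  gv <- groups[groups$kind == "V" & groups$group_id == va$group_id, ]
  gj <- groups[groups$kind == "J" & groups$group_id == ja$group_id, ]
  v_align <- list(sequence = gv$representative_sequence[1],
                  span = va$span, anchor_offset = gv$anchor_offset[1])
  j_align <- list(sequence = gj$representative_sequence[1],
                  span = ja$span, anchor_offset = gj$anchor_offset[1])

  if (correct) {
    corr <- correct_errors(s, v_align, j_align)
  } else {
    corr <- list(corrected_nt = s, corrections_applied = 0L,
                 overlap_flagged = j_align$span[1] + 1L <= v_align$span[2])
  }
  cdr3 <- extract_cdr3(corr$corrected_nt, v_align, j_align)
  nb <- if (cdr3$ok) {
    estimate_n_bases(corr$corrected_nt, v_align$sequence, j_align$sequence)
  } else {
    NA_integer_
  }
  flag <- if (corr$overlap_flagged) {
    "vj_overlap"
  } else if (!cdr3$ok) {
    "anchor_outside_span"
  } else {
    NA_character_
  }
  tibble(
    v_call = va$group_id, j_call = ja$group_id,
    v_span_end = va$span[2], j_span_start = ja$span[1],
    v_mismatches = va$mismatch_count, j_mismatches = ja$mismatch_count,
    sequence_corrected = corr$corrected_nt,
    corrections_applied = corr$corrections_applied,
    junction = cdr3$cdr3_nt, junction_aa = cdr3$cdr3_aa,
    n_bases = nb, productive = cdr3$productive, flag = flag
  )
}

#' Write / read an AIRR-style rearrangement table
#'
#' @param annotated Annotated tibble from [annotate_reads()].
#' @param path Output TSV path.
#' @return Invisibly, `annotated` (writer) or the tibble (reader).
#' @export
write_rearrangements <- function(annotated, path) {
  utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(annotated)
}

#' @rdname write_rearrangements
#' @export
read_rearrangements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  df$productive <- as.logical(df$productive)
  as_tibble(df)
}
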