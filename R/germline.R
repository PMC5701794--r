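#' Germline TRAV/TRAJ reference handling
#'
#' A germline reference is a tibble with one row per TRAV or TRAJ allele and
#' columns `segment_id`, `kind` ("V" or "J"), `family`, `subfamily`,
#' `dup_class` ("A", "D", "N" or "none"), `nt_sequence` and `anchor_offset`
#' (0-based offset of the first base of the conserved anchor codon: the
#' CDR3-opening cysteine for V segments, the phenylalanine/tryptophan/leucine
#' of the F/W/L-G motif for J segments).
#'
#' @name germline_reference
NULL

#' Construct and validate a germline reference
#'
#' Validates segment identifiers, sequences and anchor codons.  V anchors
#' must translate to C; J anchors to F, W or L with the following codon a G.
#'
#' @param segments Data frame with columns `segment_id`, `kind`, `family`,
#'   `subfamily`, `dup_class`, `nt_sequence`, `anchor_offset`.
#' @return A tibble of class `germline_reference`.
#' @export
germline_reference <- function(segments) {
  segments <- as_tibble(segments)
  required <- c("segment_id", "kind", "family", "subfamily", "dup_class",
                "nt_sequence", "anchor_offset")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0) {
    abort(paste0("reference metadata is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  segments$family <- as.integer(segments$family)
  segments$subfamily <- as.integer(segments$subfamily)
  segments$anchor_offset <- as.integer(segments$anchor_offset)

  dup <- segments$segment_id[duplicated(segments$segment_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate segment_id in reference: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!all(segments$kind %in% c("V", "J"))) {
    abort("segment kind must be 'V' or 'J'")
  }
  if (!all(segments$dup_class %in% c("A", "D", "N", "none"))) {
    abort("dup_class must be one of 'A', 'D', 'N', 'none'")
  }
  bad <- !is_dna(segments$nt_sequence)
  if (any(bad)) {
    abort(paste0("non-ACGT or empty sequence for segment(s): ",
                 paste(segments$segment_id[bad], collapse = ", ")))
  }
  too_short <- segments$anchor_offset < 0 |
    segments$anchor_offset + 3L > nchar(segments$nt_sequence)
  if (any(too_short)) {
    abort(paste0("anchor codon outside sequence for segment(s): ",
                 paste(segments$segment_id[too_short], collapse = ", ")))
  }
  anchor <- substr(segments$nt_sequence, segments$anchor_offset + 1L,
                   segments$anchor_offset + 3L)
  aa <- codon_aa(anchor)
  is_v <- segments$kind == "V"
  bad_v <- is_v & (is.na(aa) | aa != "C")
  if (any(bad_v)) {
    abort(paste0("V anchor codon does not translate to C for: ",
                 paste(segments$segment_id[bad_v], collapse = ", ")))
  }
  bad_j <- !is_v & (is.na(aa) | !aa %in% c("F", "W", "L"))
  if (any(bad_j)) {
    abort(paste0("J anchor codon does not translate to F/W/L for: ",
                 paste(segments$segment_id[bad_j], collapse = ", ")))
  }
  # F/W/L-G motif: codon following the J anchor must encode glycine
  j_rows <- which(!is_v)
  if (length(j_rows) > 0) {
    nxt_ok <- segments$anchor_offset[j_rows] + 6L <=
      nchar(segments$nt_sequence[j_rows])
    nxt <- substr(segments$nt_sequence[j_rows],
                  segments$anchor_offset[j_rows] + 4L,
                  segments$anchor_offset[j_rows] + 6L)
    g_ok <- nxt_ok & !is.na(codon_aa(nxt)) & codon_aa(nxt) == "G"
    if (any(!g_ok)) {
      abort(paste0("J segment lacks G codon after the F/W/L anchor: ",
                   paste(segments$segment_id[j_rows][!g_ok], collapse = ", ")))
    }
  }
  structure(segments[, required], class = c("germline_reference",
                                            class(segments)))
}

#' Load a germline reference from FASTA plus sidecar metadata
#'
#' The FASTA holds one record per segment allele; the tab-separated metadata
#' file supplies `segment_id`, `kind`, `family`, `subfamily`, `dup_class`
#' and `anchor_offset` (0-based).  FASTA ids and metadata rows must match
#' one-to-one.
#'
#' @param fasta_path Path to the reference FASTA.
#' @param metadata_path Path to the tab-separated metadata table.
#' @return A validated `germline_reference` tibble.
#' @export
load_reference <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  ids <- names(seqs)
  missing_meta <- setdiff(ids, meta$segment_id)
  if (length(missing_meta) > 0) {
    abort(paste0("no metadata row for FASTA record(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  missing_seq <- setdiff(meta$segment_id, ids)
  if (length(missing_seq) > 0) {
    abort(paste0("no FASTA record for metadata row(s): ",
                 paste(missing_seq, collapse = ", ")))
  }
  meta <- meta[match(ids, meta$segment_id), ]
  meta$nt_sequence <- as.character(seqs)
  germline_reference(meta)
}

#' Write a germline reference as FASTA plus metadata TSV
#'
#' @param reference A `germline_reference`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the reference.
#' @export
write_reference <- function(reference, fasta_path, metadata_path) {
  seqs <- Biostrings::DNAStringSet(reference$nt_sequence)
  names(seqs) <- reference$segment_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  meta <- reference[, c("segment_id", "kind", "family", "subfamily",
                        "dup_class", "anchor_offset")]
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(reference)
}

# Family-subfamily stem of a segment id: the id minus its trailing
# duplication-class letter ("TRAV06-3A" -> "TRAV06-3"); segments with
# dup_class "none" have no letter to strip.
segment_stem <- function(segment_id, dup_class) {
  ifelse(dup_class == "none", segment_id,
         substr(segment_id, 1L, nchar(segment_id) - 1L))
}

#' Collapse indistinguishable germline segments into ambiguity groups
#'
#' Subfamily members whose stored sequences are identical cannot be told
#' apart by sequence and are reported jointly under a group id made of the
#' shared family-subfamily stem plus the sorted duplication-class letters of
#' the members (e.g. `TRAV06-3ADN`).  Segments with a unique sequence keep
#' their plain id.  Identical sequences in *different* family-subfamily
#' stems are kept separate with a warning.
#'
#' @param reference A `germline_reference`.
#' @return A tibble of class `ambiguity_groups` with columns `group_id`,
#'   `kind`, `members` (list column of segment ids), `representative_sequence`
#'   and `anchor_offset`.
#' @export
collapse_indistinguishable <- function(reference) {
  stopifnot(inherits(reference, "germline_reference"))
  ref <- as_tibble(reference)
  ref$stem <- segment_stem(ref$segment_id, ref$dup_class)

  # warn on cross-stem identical sequences (not merged)
  for (k in unique(ref$kind)) {
    sub <- ref[ref$kind == k, ]
    by_seq <- split(sub$stem, sub$nt_sequence)
    cross <- vapply(by_seq, function(s) length(unique(s)) > 1, logical(1))
    if (any(cross)) {
      warn(paste0("identical ", k, " sequences found across different ",
                  "family-subfamily stems; kept as separate groups"))
    }
  }

  key <- paste(ref$kind, ref$stem, ref$nt_sequence, sep = "\r")
  groups <- lapply(split(seq_len(nrow(ref)), key), function(idx) {
    rows <- ref[idx, ]
    if (length(unique(rows$anchor_offset)) != 1L) {
      abort(paste0("indistinguishable segments disagree on anchor_offset: ",
                   paste(rows$segment_id, collapse = ", ")))
    }
    if (nrow(rows) == 1L) {
      gid <- rows$segment_id
    } else {
      letters_sorted <- sort(rows$dup_class)
      gid <- paste0(rows$stem[1], paste(letters_sorted, collapse = ""))
    }
    tibble(
      group_id = gid,
      kind = rows$kind[1],
      members = list(sort(rows$segment_id)),
      representative_sequence = rows$nt_sequence[1],
      anchor_offset = rows$anchor_offset[1]
    )
  })
  out <- bind_rows(groups)
  out <- out[order(out$kind, out$group_id), ]
  structure(out, class = c("ambiguity_groups", class(out)))
}
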