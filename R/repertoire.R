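#' Build a per-sample clonotype abundance table
#'
#' Aggregates productive, singleton-filtered annotated sequences from one
#' sample into a clonotype count table under a chosen clonotype definition.
#'
#' @param annotated Annotated sequences (one sample, productive,
#'   singleton-filtered).
#' @param key_scheme Clonotype definition: `"full_tcra"` (V group, J group,
#'   CDR3a amino acids), `"cdr3_only"` or `"vj_pair"`.
#' @param metadata Named list of sample metadata; recognised fields are
#'   `mouse_id`, `mhc_allele`, `tcrb`, `compartment`.
#' @param sample_id Sample identifier; defaults to the one in `annotated`.
#' @return Object of class `tcra_repertoire`: a list with `sample_id`,
#'   `metadata`, `key_scheme`, `total_reads` and `clonotypes`, a tibble of
#'   key columns plus `count`.
#' @export
build_repertoire <- function(annotated,
                             key_scheme = c("full_tcra", "cdr3_only",
                                            "vj_pair"),
                             metadata = list(), sample_id = NULL) {
  key_scheme <- match.arg(key_scheme)
  if (nrow(annotated) > 0) {
    sid <- unique(annotated$sample_id)
    if (length(sid) > 1L) {
      abort("build_repertoire() expects sequences from a single sample")
    }
    if (any(!annotated$productive)) {
      abort("non-productive sequences passed to build_repertoire()")
    }
    sample_id <- sample_id %||% sid
  } else {
    sample_id <- sample_id %||% NA_character_
  }

  cols <- switch(key_scheme,
    full_tcra = c("v_group", "j_group", "cdr3_aa"),
    cdr3_only = "cdr3_aa",
    vj_pair = c("v_group", "j_group")
  )
  if (nrow(annotated) == 0) {
    clono <- as_tibble(stats::setNames(
      c(rep(list(character(0)), length(cols)), list(integer(0))),
      c(cols, "count")
    ))
  } else {
    df <- tibble(
      v_group = annotated$v_call,
      j_group = annotated$j_call,
      cdr3_aa = annotated$junction_aa
    )[, cols, drop = FALSE]
    clono <- df |>
      group_by(across(all_of(cols))) |>
      summarise(count = n(), .groups = "drop") |>
      arrange(across(all_of(cols)))
  }
  structure(
    list(sample_id = sample_id, metadata = metadata,
         key_scheme = key_scheme,
         total_reads = sum(clono$count),
         clonotypes = clono),
    class = "tcra_repertoire"
  )
}

#' Construct a repertoire directly from a clonotype count table
#'
#' @param clonotypes Tibble with the key columns of `key_scheme` plus
#'   `count` (strictly positive).
#' @inheritParams build_repertoire
#' @return A `tcra_repertoire`.
#' @export
repertoire_from_counts <- function(clonotypes,
                                   key_scheme = c("full_tcra", "cdr3_only",
                                                  "vj_pair"),
                                   metadata = list(), sample_id = NA) {
  key_scheme <- match.arg(key_scheme)
  clonotypes <- as_tibble(clonotypes)
  if (nrow(clonotypes) > 0 && any(clonotypes$count <= 0)) {
    abort("clonotype counts must be strictly positive")
  }
  structure(
    list(sample_id = sample_id, metadata = metadata,
         key_scheme = key_scheme,
         total_reads = sum(clonotypes$count),
         clonotypes = clonotypes),
    class = "tcra_repertoire"
  )
}

#' @export
print.tcra_repertoire <- function(x, ...) {
  cat("<tcra_repertoire> sample", x$sample_id,
      "|", nrow(x$clonotypes), "clonotypes,",
      x$total_reads, "reads |", "key:", x$key_scheme, "\n")
  invisible(x)
}

# Single string key per clonotype row (used by the overlap statistics).
repertoire_keys <- function(rep) {
  cols <- setdiff(names(rep$clonotypes), "count")
  if (nrow(rep$clonotypes) == 0) {
    return(character(0))
  }
  do.call(paste, c(rep$clonotypes[cols], sep = "|"))
}

#' Coarsen a repertoire to a simpler clonotype definition
#'
#' Re-keys e.g. a full-TCRa repertoire to CDR3a-only keys; counts are
#' re-aggregated, total reads conserved.
#'
#' @param rep A `tcra_repertoire` keyed `full_tcra`.
#' @param key_scheme Target scheme (`"cdr3_only"` or `"vj_pair"`).
#' @return A `tcra_repertoire` under the coarser scheme.
#' @export
rekey_repertoire <- function(rep, key_scheme = c("cdr3_only", "vj_pair")) {
  key_scheme <- match.arg(key_scheme)
  if (rep$key_scheme != "full_tcra") {
    abort("rekey_repertoire() needs a full_tcra-keyed repertoire")
  }
  cols <- switch(key_scheme, cdr3_only = "cdr3_aa",
                 vj_pair = c("v_group", "j_group"))
  clono <- rep$clonotypes |>
    group_by(across(all_of(cols))) |>
    summarise(count = sum(count), .groups = "drop") |>
    arrange(across(all_of(cols)))
  repertoire_from_counts(clono, key_scheme, rep$metadata, rep$sample_id)
}

# Chromosome-order sort key for segment-group labels: TRAV groups order by
# family then subfamily; TRAJ labels by their numeric position.
segment_order <- function(labels, axis) {
  if (axis == "TRAV_group") {
    fam <- as.integer(sub("^TRAV0*([0-9]+).*$", "\\1", labels))
    subfam <- suppressWarnings(
      as.integer(sub("^TRAV[0-9]+-0*([0-9]+).*$", "\\1", labels))
    )
    subfam[is.na(subfam)] <- 0L
    order(fam, subfam, labels)
  } else {
    pos <- as.integer(sub("^TRAJ0*([0-9]+).*$", "\\1", labels))
    order(pos, labels)
  }
}

#' Segment usage of a repertoire
#'
#' Percent use of each TRAV ambiguity group or TRAJ.  Abundance weighting
#' (per read) is the default, matching per-cell usage summaries; unique
#' weighting counts each clonotype once.
#'
#' @param rep A `tcra_repertoire` whose keys carry V/J information.
#' @param axis `"TRAV_group"` or `"TRAJ"`.
#' @param weight `"reads"` (abundance-weighted, default) or `"unique"`.
#' @param labels Optional label set to report over (missing segments get
#'   0%); defaults to the labels observed in the repertoire.
#' @return Tibble of class `usage_vector` with `label`, `count`, `percent`
#'   (sums to 100), ordered by family (TRAV) or chromosomal position
#'   (TRAJ).
#' @export
usage_table <- function(rep, axis = c("TRAV_group", "TRAJ"),
                        weight = c("reads", "unique"), labels = NULL) {
  axis <- match.arg(axis)
  weight <- match.arg(weight)
  if (rep$key_scheme == "cdr3_only") {
    abort("segment usage is unavailable for cdr3_only-keyed repertoires")
  }
  if (nrow(rep$clonotypes) == 0) {
    abort("usage_table() on an empty repertoire")
  }
  col <- if (axis == "TRAV_group") "v_group" else "j_group"
  w <- if (weight == "reads") rep$clonotypes$count else
    rep(1L, nrow(rep$clonotypes))
  agg <- tapply(w, rep$clonotypes[[col]], sum)
  labels <- labels %||% names(agg)
  counts <- stats::setNames(rep(0, length(labels)), labels)
  counts[names(agg)] <- as.numeric(agg)
  out <- tibble(label = labels, count = unname(counts))
  out <- out[segment_order(out$label, axis), ]
  out$percent <- 100 * out$count / sum(out$count)
  structure(out, axis = axis, class = c("usage_vector", class(out)))
}

#' CDR3a amino-acid length distribution of a repertoire
#'
#' @param rep A `tcra_repertoire` with CDR3a keys.
#' @param weight `"unique"` (default; each clonotype once, the natural unit
#'   when comparing different sequences) or `"reads"`.
#' @return List with `histogram` (tibble `length_aa`, `n`) and `mean`.
#'   Standard errors are computed across mice at cohort level, not within a
#'   sample (see [summarize_cohort()]).
#' @export
cdr3_length_distribution <- function(rep, weight = c("unique", "reads")) {
  weight <- match.arg(weight)
  if (nrow(rep$clonotypes) == 0) {
    abort("cdr3_length_distribution() on an empty repertoire")
  }
  if (!"cdr3_aa" %in% names(rep$clonotypes)) {
    abort("repertoire keys carry no CDR3a sequence")
  }
  len <- nchar(rep$clonotypes$cdr3_aa)
  w <- if (weight == "reads") rep$clonotypes$count else
    rep(1L, nrow(rep$clonotypes))
  hist <- tibble(length_aa = sort(unique(len)))
  hist$n <- as.numeric(tapply(w, len, sum)[as.character(hist$length_aa)])
  list(histogram = hist, mean = sum(len * w) / sum(w))
}

#' Mean number of inferred N-region bases per clonotype
#'
#' Operates on annotated sequences (the clonotype table does not retain
#' per-clonotype N counts); clonotypes are weighted uniquely by default.
#'
#' @param annotated Productive annotated sequences of one sample.
#' @param key_scheme Clonotype definition for the unique weighting.
#' @param weight `"unique"` (default) or `"reads"`.
#' @return Mean N-base estimate.
#' @export
mean_n_bases <- function(annotated, key_scheme = "full_tcra",
                         weight = c("unique", "reads")) {
  weight <- match.arg(weight)
  if (nrow(annotated) == 0) {
    abort("mean_n_bases() on empty input")
  }
  if (weight == "reads") {
    return(mean(annotated$n_bases, na.rm = TRUE))
  }
  key <- clonotype_key(annotated, key_scheme)
  ok <- !is.na(key) & !is.na(annotated$n_bases)
  per <- tapply(annotated$n_bases[ok], key[ok], mean)
  mean(per)
}

#' Positional amino-acid frequencies for CDR3a of a given length
#'
#' Positions are 1-based counting the conserved cysteine as position 1.
#' Each row (position) is a probability vector over the amino acids
#' observed there.
#'
#' @param rep A `tcra_repertoire` with CDR3a keys.
#' @param cdr3_length Amino-acid length to profile.
#' @param weight `"unique"` (default) or `"reads"`.
#' @return Matrix position x amino acid; zero rows (with a warning) when no
#'   clonotype has the requested length.
#' @export
positional_aa_frequency <- function(rep, cdr3_length,
                                    weight = c("unique", "reads")) {
  weight <- match.arg(weight)
  if (!"cdr3_aa" %in% names(rep$clonotypes)) {
    abort("repertoire keys carry no CDR3a sequence")
  }
  sel <- nchar(rep$clonotypes$cdr3_aa) == cdr3_length
  if (!any(sel)) {
    warn(paste0("no clonotypes of CDR3a length ", cdr3_length))
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  seqs <- rep$clonotypes$cdr3_aa[sel]
  w <- if (weight == "reads") rep$clonotypes$count[sel] else
    rep(1, length(seqs))
  aa_levels <- sort(unique(unlist(strsplit(seqs, ""))))
  m <- matrix(0, nrow = cdr3_length, ncol = length(aa_levels),
              dimnames = list(seq_len(cdr3_length), aa_levels))
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                  byrow = TRUE)
  for (p in seq_len(cdr3_length)) {
    tab <- tapply(w, chars[, p], sum)
    m[p, names(tab)] <- tab / sum(w)
  }
  m
}

#' Write / read a repertoire as TSV
#'
#' Metadata travels in commented header lines so one file round-trips a
#' repertoire.
#'
#' @param rep A `tcra_repertoire`.
#' @param path TSV path.
#' @return Invisibly the repertoire (writer); the repertoire (reader).
#' @export
write_repertoire <- function(rep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- rep$metadata
  hdr <- c(
    paste0("# sample_id=", rep$sample_id),
    paste0("# key_scheme=", rep$key_scheme),
    vapply(names(meta), function(k) paste0("# ", k, "=", meta[[k]]),
           character(1))
  )
  writeLines(hdr, con)
  utils::write.table(rep$clonotypes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rep)
}

#' @rdname write_repertoire
#' @export
read_repertoire <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(x) paste(x[-1], collapse = "=")),
    vapply(kv, `[[`, character(1), 1)
  )
  body <- lines[!grepl("^# ", lines)]
  clono <- utils::read.delim(text = paste(body, collapse = "\n"),
                             stringsAsFactors = FALSE)
  repertoire_from_counts(
    as_tibble(clono),
    key_scheme = meta$key_scheme,
    metadata = meta[setdiff(names(meta), c("sample_id", "key_scheme"))],
    sample_id = meta$sample_id
  )
}
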