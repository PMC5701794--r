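#' Assemble a cohort design from repertoires
#'
#' Groups samples by genotype (MHC class II allele x partner TCRb chain)
#' using each repertoire's metadata, or an explicit grouping table.
#'
#' @param reps List of `tcra_repertoire` objects.
#' @param grouping Optional tibble `sample_id`, `mhc_allele`, `tcrb`;
#'   defaults to the repertoire metadata.
#' @return Object of class `cohort_design`: list with `samples` (named list
#'   of repertoires) and `grouping`.
#' @export
cohort_design <- function(reps, grouping = NULL) {
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) {
    abort("duplicate sample ids in cohort")
  }
  if (length(reps) < 2L) {
    abort("a cohort needs at least two samples")
  }
  names(reps) <- ids
  if (is.null(grouping)) {
    grouping <- tibble(
      sample_id = ids,
      mhc_allele = vapply(reps, function(r)
        as.character(r$metadata$mhc_allele %||% NA), character(1)),
      tcrb = vapply(reps, function(r)
        as.character(r$metadata$tcrb %||% NA), character(1))
    )
  }
  missing <- setdiff(ids, grouping$sample_id)
  if (length(missing) > 0 || anyNA(grouping$mhc_allele) ||
      anyNA(grouping$tcrb)) {
    abort("every sample needs an (mhc_allele, tcrb) group assignment")
  }
  structure(list(samples = reps, grouping = grouping),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>", length(x$samples), "samples,",
      nrow(unique(x$grouping[, c("mhc_allele", "tcrb")])), "genotypes\n")
  invisible(x)
}

# Comparison class of an unordered sample pair.
pair_class <- function(mhc_a, tcrb_a, mhc_b, tcrb_b) {
  paste0(
    ifelse(mhc_a == mhc_b, "same_MHC", "diff_MHC"), "_",
    ifelse(tcrb_a == tcrb_b, "same_beta", "diff_beta")
  )
}

#' Pairwise overlap/distance matrix over a cohort
#'
#' @param design A `cohort_design`.
#' @param metric `"jaccard"`, `"chao_jaccard"` or `"euclidean_log2usage"`.
#' @param axis Usage axis (only for the Euclidean metric).
#' @param pseudocount Pseudocount for the log2-usage metric.
#' @return Symmetric matrix of metric values, sample ids as dimnames;
#'   diagonal is the metric of a sample with itself.
#' @export
pairwise_matrix <- function(design,
                            metric = c("jaccard", "chao_jaccard",
                                       "euclidean_log2usage"),
                            axis = "TRAV_group", pseudocount = 1) {
  metric <- match.arg(metric)
  reps <- design$samples
  if (metric == "euclidean_log2usage") {
    if (reps[[1]]$key_scheme == "cdr3_only") {
      abort("usage distances are incompatible with cdr3_only keys")
    }
    m <- usage_distance_matrix(reps, axis = axis, pseudocount = pseudocount)
    return(m)
  }
  fn <- if (metric == "jaccard") jaccard else chao_jaccard
  ids <- names(reps)
  k <- length(reps)
  m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- fn(reps[[i]], reps[[j]])$value
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Summarise a pairwise matrix by genotype comparison class
#'
#' Unordered sample pairs (self-pairs excluded) are partitioned into the
#' four classes same/different MHC x same/different TCRb; per class the
#' mean, SEM over pairs and pair count are reported.  Classes with no pairs
#' are omitted with a notice.
#'
#' @param mat Matrix from [pairwise_matrix()].
#' @param design The `cohort_design` that produced it.
#' @return Tibble `comparison_class`, `mean`, `sem`, `n_pairs`.
#' @export
summarize_by_class <- function(mat, design) {
  g <- design$grouping
  ids <- rownames(mat)
  idx <- match(ids, g$sample_id)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      rows[[length(rows) + 1L]] <- tibble(
        sample_a = ids[i], sample_b = ids[j],
        comparison_class = pair_class(g$mhc_allele[idx[i]], g$tcrb[idx[i]],
                                      g$mhc_allele[idx[j]], g$tcrb[idx[j]]),
        value = mat[i, j]
      )
    }
  }
  pairs <- bind_rows(rows)
  all_classes <- c("same_MHC_same_beta", "same_MHC_diff_beta",
                   "diff_MHC_same_beta", "diff_MHC_diff_beta")
  absent <- setdiff(all_classes, unique(pairs$comparison_class))
  if (length(absent) > 0) {
    inform(paste0("no sample pairs in class(es): ",
                  paste(absent, collapse = ", ")))
  }
  pairs |>
    group_by(comparison_class) |>
    summarise(
      mean = mean(value),
      sem = if (n() >= 2) stats::sd(value) / sqrt(n()) else NA_real_,
      n_pairs = n(),
      .groups = "drop"
    )
}

# Restrict a full_tcra repertoire to one (TRAV group, TRAJ) pair and re-key
# by CDR3a only.
restrict_repertoire <- function(rep, trav_group, traj) {
  if (rep$key_scheme != "full_tcra") {
    abort("restriction to a V/J pair needs full_tcra keys")
  }
  sel <- rep$clonotypes$v_group == trav_group & rep$clonotypes$j_group == traj
  clono <- rep$clonotypes[sel, c("cdr3_aa", "count")]
  clono <- clono |>
    group_by(cdr3_aa) |>
    summarise(count = sum(count), .groups = "drop")
  repertoire_from_counts(clono, "cdr3_only", rep$metadata, rep$sample_id)
}

#' V/J pairs with enough distinct CDR3a sequences in every sample
#'
#' @param design A `cohort_design` of full_tcra repertoires.
#' @param min_unique Minimum distinct CDR3a sequences per sample (default
#'   5).
#' @return List with `admissible` (tibble `v_group`, `j_group`) and
#'   `exclusions` (tibble `v_group`, `j_group`, `sample_id`,
#'   `n_distinct_cdr3` for each failing sample).
#' @export
admissible_vj_pairs <- function(design, min_unique = 5L) {
  per_sample <- bind_rows(lapply(design$samples, function(r) {
    r$clonotypes |>
      group_by(v_group, j_group) |>
      summarise(n_distinct_cdr3 = dplyr::n_distinct(cdr3_aa),
                .groups = "drop") |>
      mutate(sample_id = r$sample_id)
  }))
  all_pairs <- distinct(per_sample[, c("v_group", "j_group")])
  n_samples <- length(design$samples)
  full <- tidyr::crossing(all_pairs,
                          sample_id = names(design$samples)) |>
    left_join(per_sample, by = c("v_group", "j_group", "sample_id")) |>
    mutate(n_distinct_cdr3 = dplyr::coalesce(n_distinct_cdr3, 0L))
  fails <- full |> filter(n_distinct_cdr3 < min_unique)
  ok <- full |>
    group_by(v_group, j_group) |>
    summarise(pass = all(n_distinct_cdr3 >= min_unique), .groups = "drop") |>
    filter(pass)
  list(
    admissible = ok[, c("v_group", "j_group")],
    exclusions = fails[, c("v_group", "j_group", "sample_id",
                           "n_distinct_cdr3")]
  )
}

#' N-region (CDR3a) comparison within fixed TRAV/TRAJ pairs
#'
#' Restricting both V and J removes the germline-encoded CDR3a flanks from
#' the comparison, so remaining differences reflect the somatically
#' generated centre.  A pair enters the report only when *every* sample in
#' the cohort carries at least `min_unique` distinct CDR3a sequences for
#' it.
#'
#' @param design A `cohort_design` of full_tcra repertoires.
#' @param trav_group,traj Specific pair to compare; when NULL all
#'   admissible pairs are reported.
#' @param min_unique Per-sample distinct-CDR3a filter (default 5).
#' @param metric `"jaccard"` or `"chao_jaccard"` on the restricted CDR3a
#'   sets.
#' @return Tibble of per-class summaries with `v_group`/`j_group` columns;
#'   attribute `exclusions` logs the pairs failing the filter per sample.
#'   Empty (with a notice) when no pair is admissible.
#' @export
nregion_comparison <- function(design, trav_group = NULL, traj = NULL,
                               min_unique = 5L,
                               metric = c("jaccard", "chao_jaccard")) {
  metric <- match.arg(metric)
  adm <- admissible_vj_pairs(design, min_unique)
  pairs <- adm$admissible
  if (!is.null(trav_group) || !is.null(traj)) {
    pairs <- pairs |>
      filter(v_group == trav_group, j_group == traj)
  }
  if (nrow(pairs) == 0) {
    inform("no V/J pair passes the distinct-CDR3a filter in every sample")
    out <- tibble(v_group = character(0), j_group = character(0),
                  comparison_class = character(0), mean = numeric(0),
                  sem = numeric(0), n_pairs = integer(0))
    attr(out, "exclusions") <- adm$exclusions
    return(out)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    restricted <- lapply(design$samples, restrict_repertoire,
                         trav_group = pairs$v_group[i],
                         traj = pairs$j_group[i])
    sub <- cohort_design(restricted, design$grouping)
    mat <- pairwise_matrix(sub, metric)
    summarize_by_class(mat, sub) |>
      mutate(v_group = pairs$v_group[i], j_group = pairs$j_group[i],
             .before = 1)
  })
  out <- bind_rows(res)
  attr(out, "exclusions") <- adm$exclusions
  out
}

#' Clonotypes shared across every genotype group
#'
#' Lists the clonotypes present in at least one sample of *each* group
#' (genotype by default), with per-sample counts — the "public" sequences
#' that appear regardless of selection conditions.
#'
#' @param design A `cohort_design`.
#' @param group_by Grouping columns of the design (default genotype =
#'   `c("mhc_allele", "tcrb")`).
#' @return Tibble with the clonotype key columns, one count column per
#'   sample, and `n_groups` (number of groups the clonotype appears in);
#'   empty when nothing is shared by all groups.
#' @export
shared_sequence_report <- function(design,
                                   group_by = c("mhc_allele", "tcrb")) {
  g <- design$grouping
  group_of <- do.call(paste, c(g[group_by], sep = "|"))
  names(group_of) <- g$sample_id
  n_groups_total <- length(unique(group_of))

  long <- bind_rows(lapply(design$samples, function(r) {
    cl <- r$clonotypes
    cl$key <- repertoire_keys(r)
    cl$sample_id <- r$sample_id
    cl
  }))
  long$group <- group_of[long$sample_id]
  presence <- long |>
    group_by(key) |>
    summarise(n_groups = dplyr::n_distinct(group), .groups = "drop")
  public_keys <- presence$key[presence$n_groups == n_groups_total]
  if (length(public_keys) == 0) {
    key_cols <- setdiff(names(design$samples[[1]]$clonotypes), "count")
    return(tibble(!!!stats::setNames(
      rep(list(character(0)), length(key_cols)), key_cols
    ), n_groups = integer(0)))
  }
  wide <- long |>
    filter(key %in% public_keys) |>
    select(-group) |>
    tidyr::pivot_wider(names_from = sample_id, values_from = count,
                       values_fill = 0L)
  wide <- left_join(wide, presence, by = "key")
  wide$key <- NULL
  wide
}

#' Cohort-level summaries with SEM across mice
#'
#' Per genotype, the mean and standard error over mice of a per-sample
#' statistic (CDR3a length, observed or Chao1 richness).
#'
#' @param design A `cohort_design`.
#' @param stat `"cdr3_length"`, `"richness_observed"` or `"richness_chao1"`.
#' @return Tibble `mhc_allele`, `tcrb`, `mean`, `sem`, `n_mice`.
#' @export
summarize_cohort <- function(design,
                             stat = c("cdr3_length", "richness_observed",
                                      "richness_chao1")) {
  stat <- match.arg(stat)
  fn <- switch(stat,
    cdr3_length = function(r) cdr3_length_distribution(r)$mean,
    richness_observed = function(r) nrow(r$clonotypes),
    richness_chao1 = estimate_richness
  )
  vals <- tibble(
    sample_id = names(design$samples),
    value = vapply(design$samples, fn, numeric(1))
  ) |>
    left_join(design$grouping, by = "sample_id")
  vals |>
    group_by(mhc_allele, tcrb) |>
    summarise(
      mean = mean(value),
      sem = if (n() >= 2) stats::sd(value) / sqrt(n()) else NA_real_,
      n_mice = n(),
      .groups = "drop"
    )
}
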