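#' Species accumulation curve of a repertoire
#'
#' Expected number of unique clonotypes as a function of reads subsampled
#' without replacement, estimated by Monte-Carlo permutation of the read
#' vector.
#'
#' @param rep A `tcra_repertoire`.
#' @param depths Increasing subsampling depths; default 20 evenly spaced
#'   points up to the total read count.
#' @param permutations Number of random subsamples per depth (default 100).
#' @param seed Mandatory RNG seed.
#' @return Tibble of class `accumulation_curve` with `depth`,
#'   `mean_unique`, `sd_unique`; attributes `permutations` and `seed`.  At
#'   full depth the mean equals the observed richness exactly and the sd
#'   is 0.
#' @export
accumulation_curve <- function(rep, depths = NULL, permutations = 100L,
                               seed) {
  if (missing(seed)) {
    abort("accumulation_curve() requires an explicit seed")
  }
  total <- rep$total_reads
  if (is.null(depths)) {
    depths <- unique(pmax(1L, round(seq(total / 20, total, length.out = 20))))
  }
  depths <- sort(unique(as.integer(depths)))
  if (any(depths > total)) {
    abort("subsampling depth exceeds total reads")
  }
  if (permutations < 1L) {
    abort("permutations must be >= 1")
  }
  reads <- base::rep.int(seq_len(nrow(rep$clonotypes)), rep$clonotypes$count)
  acc <- matrix(0L, nrow = permutations, ncol = length(depths))
  with_seed(seed, {
    for (p in seq_len(permutations)) {
      shuffled <- sample(reads)
      newly_seen <- cumsum(!duplicated(shuffled))
      acc[p, ] <- newly_seen[depths]
    }
  })
  out <- tibble(
    depth = depths,
    mean_unique = colMeans(acc),
    sd_unique = apply(acc, 2, stats::sd)
  )
  structure(out, permutations = permutations, seed = seed,
            class = c("accumulation_curve", class(out)))
}

#' Chao1 estimate of total clonotype richness
#'
#' `S_obs + f1^2 / (2 f2)`, with the bias-corrected form
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` when no doubletons are present;
#' f1 and f2 are the numbers of singleton and doubleton clonotypes.
#'
#' @param rep A non-empty `tcra_repertoire`.
#' @return The Chao1 richness estimate.
#' @export
estimate_richness <- function(rep) {
  counts <- rep$clonotypes$count
  if (length(counts) == 0) {
    abort("estimate_richness() on an empty repertoire")
  }
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

overlap_result <- function(rep_a, rep_b, metric, value) {
  tibble(
    sample_a = rep_a$sample_id, sample_b = rep_b$sample_id,
    metric = metric, key_scheme = rep_a$key_scheme, value = value
  )
}

check_same_scheme <- function(rep_a, rep_b) {
  if (rep_a$key_scheme != rep_b$key_scheme) {
    abort("repertoires use different clonotype key schemes")
  }
}

#' Jaccard similarity between two repertoires
#'
#' Presence/absence overlap `|A n B| / |A u B|` over unique clonotype keys.
#'
#' @param rep_a,rep_b Repertoires under the same key scheme.
#' @return One-row `OverlapResult` tibble (`sample_a`, `sample_b`,
#'   `metric`, `key_scheme`, `value`); `value` is NA with a warning when
#'   both repertoires are empty.
#' @export
jaccard <- function(rep_a, rep_b) {
  check_same_scheme(rep_a, rep_b)
  a <- repertoire_keys(rep_a)
  b <- repertoire_keys(rep_b)
  if (length(a) == 0 && length(b) == 0) {
    warn("Jaccard undefined: both repertoires empty")
    return(overlap_result(rep_a, rep_b, "jaccard", NA_real_))
  }
  value <- length(intersect(a, b)) / length(union(a, b))
  overlap_result(rep_a, rep_b, "jaccard", value)
}

#' Chao abundance-based Jaccard index between two repertoires
#'
#' The Chao et al. (2005) estimator UV / (U + V - UV), where U and V
#' estimate the total relative abundance in each sample of the clonotypes
#' shared between the two, with a correction for unseen shared clonotypes
#' driven by the shared species that are rare (count 1 or 2) in the other
#' sample.  U and V are clamped to 1; when the doubleton correction count
#' is zero it is replaced by 1 in the denominator.
#'
#' @param rep_a,rep_b Repertoires under the same key scheme.
#' @return One-row `OverlapResult` tibble; 0 when no clonotype is shared.
#' @export
chao_jaccard <- function(rep_a, rep_b) {
  check_same_scheme(rep_a, rep_b)
  ka <- repertoire_keys(rep_a)
  kb <- repertoire_keys(rep_b)
  shared <- intersect(ka, kb)
  if (length(shared) == 0) {
    return(overlap_result(rep_a, rep_b, "chao_jaccard", 0))
  }
  x <- rep_a$clonotypes$count[match(shared, ka)]
  y <- rep_b$clonotypes$count[match(shared, kb)]
  n <- rep_a$total_reads
  m <- rep_b$total_reads

  u_hat <- function(x, y, n, m) {
    f_plus1 <- sum(y == 1)
    f_plus2 <- sum(y == 2)
    denom <- if (f_plus2 == 0) 1 else f_plus2
    u <- sum(x / n) +
      ((m - 1) / m) * (f_plus1 / (2 * denom)) * sum((x / n)[y == 1])
    min(1, u)
  }
  u <- u_hat(x, y, n, m)
  v <- u_hat(y, x, m, n)
  value <- (u * v) / (u + v - u * v)
  overlap_result(rep_a, rep_b, "chao_jaccard", value)
}

#' Euclidean distance between log2-transformed segment-usage profiles
#'
#' Segment counts are scaled to counts per 10^4 sequences, incremented by a
#' pseudocount and log2-transformed; the distance is the Euclidean norm of
#' the difference.
#'
#' @param usage_a,usage_b `usage_vector` tibbles over the same axis and
#'   label set (see [usage_table()]).
#' @param pseudocount Added to the counts-per-10^4 values before the log
#'   (default 1).
#' @return Non-negative distance.
#' @export
euclidean_usage_distance <- function(usage_a, usage_b, pseudocount = 1) {
  if (!identical(attr(usage_a, "axis"), attr(usage_b, "axis"))) {
    abort("usage vectors are on different axes")
  }
  if (!identical(usage_a$label, usage_b$label)) {
    abort("usage vectors have mismatching label sets")
  }
  l2 <- function(counts) {
    log2(counts / sum(counts) * 1e4 + pseudocount)
  }
  sqrt(sum((l2(usage_a$count) - l2(usage_b$count))^2))
}

#' Pairwise log2-usage distance matrix for a set of repertoires
#'
#' Usage vectors are aligned on the union of observed labels (absent
#' segments count 0) before the transform.
#'
#' @param reps Named list of repertoires.
#' @param axis `"TRAV_group"` or `"TRAJ"`.
#' @param weight,pseudocount Passed on to [usage_table()] /
#'   [euclidean_usage_distance()].
#' @return Symmetric distance matrix with sample ids as dimnames.
#' @export
usage_distance_matrix <- function(reps, axis = c("TRAV_group", "TRAJ"),
                                  weight = "reads", pseudocount = 1) {
  axis <- match.arg(axis)
  usages <- lapply(reps, usage_table, axis = axis, weight = weight)
  labels <- sort(unique(unlist(lapply(usages, function(u) u$label))))
  usages <- lapply(reps, usage_table, axis = axis, weight = weight,
                   labels = labels)
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  k <- length(reps)
  d <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j > i) {
        d[i, j] <- euclidean_usage_distance(usages[[i]], usages[[j]],
                                            pseudocount)
        d[j, i] <- d[i, j]
      }
    }
  }
  d
}

#' Hierarchical ordering of samples from a distance matrix
#'
#' Average-linkage (UPGMA) agglomerative clustering; the leaf order is the
#' one used to arrange heatmap rows, and the tree is also returned in
#' Newick form.
#'
#' @param distance_matrix Square symmetric matrix with zero diagonal.
#' @return List with `order` (leaf indices), `labels` (leaf labels in that
#'   order), `hclust` and `newick`.
#' @export
hierarchical_order <- function(distance_matrix) {
  m <- as.matrix(distance_matrix)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m))) ||
      any(diag(m) != 0)) {
    abort("hierarchical_order() needs a square symmetric zero-diagonal matrix")
  }
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  }
  if (nrow(m) == 1L) {
    return(list(order = 1L, labels = rownames(m), hclust = NULL,
                newick = paste0("(", rownames(m), ");")))
  }
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  phy <- ape::as.phylo(hc)
  list(order = hc$order, labels = hc$labels[hc$order], hclust = hc,
       newick = ape::write.tree(phy))
}
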