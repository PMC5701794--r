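test_that("accumulation curves behave at the extremes", {
  mono <- rep_from_named_counts(c(A = 100))
  curve <- accumulation_curve(mono, depths = c(1, 10, 100),
                              permutations = 20, seed = 1)
  expect_equal(curve$mean_unique, c(1, 1, 1))

  distinct <- rep_from_named_counts(stats::setNames(rep(1, 30),
                                                    paste0("k", 1:30)))
  curve <- accumulation_curve(distinct, depths = c(1, 7, 30),
                              permutations = 20, seed = 1)
  expect_equal(curve$mean_unique, c(1, 7, 30))

  # full depth reproduces observed richness exactly, sd 0
  rep <- rep_from_named_counts(c(A = 5, B = 3, C = 1))
  curve <- accumulation_curve(rep, depths = 9, permutations = 50, seed = 2)
  expect_equal(curve$mean_unique, 3)
  expect_equal(curve$sd_unique, 0)

  expect_error(accumulation_curve(rep, depths = 10, seed = 1), "depth")
  expect_error(accumulation_curve(rep, depths = 2), "seed")
})

test_that("accumulation means match the hypergeometric expectation", {
  skip_if_not_installed("vegan")
  # closed form at depth 2 on {A:5, B:5}: E[unique] = 2 - 2*C(5,2)/C(10,2)
  rep <- rep_from_named_counts(c(A = 5, B = 5))
  perms <- 400
  curve <- accumulation_curve(rep, depths = 2, permutations = perms,
                              seed = 33)
  mc_sd <- curve$sd_unique / sqrt(perms)
  expected <- 2 - 2 * choose(5, 2) / choose(10, 2)
  expect_lt(abs(curve$mean_unique - expected), 3 * mc_sd + 1e-12)

  # independent oracle on an uneven table at several depths
  counts <- c(a = 12, b = 5, c = 2, d = 1, e = 1)
  rep2 <- rep_from_named_counts(counts)
  curve2 <- accumulation_curve(rep2, depths = c(3, 10, 18),
                               permutations = 400, seed = 34)
  expected <- as.numeric(vegan::rarefy(matrix(counts, nrow = 1),
                                       sample = c(3, 10, 18)))
  for (i in seq_along(expected)) {
    tol <- 3 * curve2$sd_unique[i] / sqrt(400)
    expect_lt(abs(curve2$mean_unique[i] - expected[i]), tol + 1e-12)
  }
})

test_that("Chao1 follows the singleton/doubleton arithmetic", {
  no_rare <- rep_from_named_counts(c(A = 5, B = 4, C = 3))
  expect_equal(estimate_richness(no_rare), 3)

  # S_obs 10, f1 4, f2 2 -> 10 + 16/4
  counts <- stats::setNames(c(1, 1, 1, 1, 2, 2, 5, 5, 5, 9),
                            paste0("k", 1:10))
  expect_equal(estimate_richness(rep_from_named_counts(counts)), 14)

  # bias-corrected branch: f2 0, f1 3, S_obs 5 -> 5 + 3*2/2
  counts2 <- stats::setNames(c(1, 1, 1, 3, 4), paste0("k", 1:5))
  expect_equal(estimate_richness(rep_from_named_counts(counts2)), 8)

  expect_error(estimate_richness(rep_from_named_counts(integer(0))), "empty")
})

test_that("Jaccard is set overlap over unique keys", {
  a <- rep_from_named_counts(c(A = 3, B = 1, C = 7))
  b <- rep_from_named_counts(c(B = 2, C = 1, D = 9))
  expect_equal(jaccard(a, b)$value, 0.5)
  expect_equal(jaccard(a, a)$value, 1)
  disjoint <- rep_from_named_counts(c(X = 2, Y = 2))
  expect_equal(jaccard(a, disjoint)$value, 0)
  expect_equal(jaccard(a, b)$value, jaccard(b, a)$value)

  empty <- rep_from_named_counts(integer(0))
  expect_warning(res <- jaccard(empty, empty), "empty")
  expect_true(is.na(res$value))
})

test_that("Chao-Jaccard matches hand arithmetic and the brute-force oracle", {
  # identical large samples without singletons: U = V = 1
  a <- rep_from_named_counts(c(A = 10, B = 20, C = 5))
  expect_equal(chao_jaccard(a, a)$value, 1)

  # disjoint supports
  b <- rep_from_named_counts(c(X = 4, Y = 4))
  expect_equal(chao_jaccard(a, b)$value, 0)

  # {X:5, Y:5} vs {X:5, Z:5}: U = V = 0.5 -> 1/3
  p <- rep_from_named_counts(c(X = 5, Y = 5))
  q <- rep_from_named_counts(c(X = 5, Z = 5))
  expect_equal(chao_jaccard(p, q)$value, 1 / 3)

  # oracle equivalence, symmetry and bounds on random tables
  set.seed(99)
  for (i in 1:40) {
    tp <- random_table_pair()
    ra <- rep_from_named_counts(tp$a, "a")
    rb <- rep_from_named_counts(tp$b, "b")
    v1 <- chao_jaccard(ra, rb)$value
    v2 <- chao_jaccard(rb, ra)$value
    expect_equal(v1, v2)
    expect_gte(v1, 0)
    expect_lte(v1, 1)
    expect_equal(v1, chao_jaccard_oracle(tp$a, tp$b), tolerance = 1e-14)
  }
})

test_that("log2 counts-per-10^4 distance matches closed form", {
  ann_counts <- function(c1, c2) {
    rep <- repertoire_from_counts(
      tibble::tibble(v_group = c("TRAV01-1A", "TRAV02-1A"),
                     j_group = "TRAJ01", cdr3_aa = c("CAAF", "CARF"),
                     count = c(c1, c2))[c(c1, c2) > 0, ],
      "full_tcra"
    )
    usage_table(rep, "TRAV_group",
                labels = c("TRAV01-1A", "TRAV02-1A"))
  }
  ua <- ann_counts(10000, 0)
  ub <- ann_counts(0, 10000)
  expect_equal(euclidean_usage_distance(ua, ub),
               sqrt(2) * log2(10001))
  expect_equal(euclidean_usage_distance(ua, ua), 0)
  expect_equal(euclidean_usage_distance(ua, ub),
               euclidean_usage_distance(ub, ua))

  uc <- ann_counts(5000, 5000)
  dab <- euclidean_usage_distance(ua, ub)
  dac <- euclidean_usage_distance(ua, uc)
  dcb <- euclidean_usage_distance(uc, ub)
  expect_lte(dab, dac + dcb + 1e-9)

  mism <- ann_counts(1, 1)
  mism$label <- c("TRAVxx", "TRAVyy")
  expect_error(euclidean_usage_distance(ua, mism), "label")
})

test_that("hierarchical ordering groups clear blocks into clades", {
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  d <- matrix(10, 6, 6, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 0.1
  d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  res <- hierarchical_order(d)
  first3 <- res$labels[1:3]
  expect_true(setequal(first3, c("a1", "a2", "a3")) ||
                setequal(first3, c("b1", "b2", "b3")))
  expect_match(res$newick, ";$")

  one <- matrix(0, 1, 1, dimnames = list("s1", "s1"))
  expect_equal(hierarchical_order(one)$labels, "s1")

  asym <- d
  asym[1, 2] <- 99
  expect_error(hierarchical_order(asym), "symmetric")
})

test_that("permuting the input yields an isomorphic tree", {
  set.seed(21)
  n <- 6
  pts <- matrix(rnorm(n * 2), ncol = 2)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  t1 <- ape::unroot(ape::read.tree(text = hierarchical_order(d)$newick))
  perm <- sample(n)
  t2 <- ape::unroot(
    ape::read.tree(text = hierarchical_order(d[perm, perm])$newick)
  )
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})
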