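# Independent oracle: exact PERMANOVA p-value for a one-factor two-group
# design by enumerating every distinct label assignment.
exact_permanova_p <- function(d, labels) {
  n <- nrow(d)
  fstat <- function(lab) {
    des <- data.frame(sample_id = rownames(d), g = lab)
    res <- permanova(structure(d, class = c("distance_matrix", "matrix")),
                     des, "g", n_perm = 0, seed = 1)
    res$pseudo_F[1]
  }
  f_obs <- fstat(labels)
  combos <- utils::combn(n, sum(labels == labels[1]))
  fs <- apply(combos, 2, function(idx) {
    lab <- rep("b", n); lab[idx] <- "a"
    fstat(lab)
  })
  mean(fs >= f_obs - 1e-12)
}

euclid_dm <- function(x) {
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", seq_len(nrow(x))),
                      paste0("s", seq_len(nrow(x))))
  structure(d, class = c("distance_matrix", "matrix"))
}

test_that("permutation p matches exact enumeration on 3-vs-3 groups", {
  set.seed(5)
  x <- c(rnorm(3, 0), rnorm(3, 1.2))
  d <- unclass(euclid_dm(cbind(x)))
  labels <- rep(c("a", "b"), each = 3)
  p_exact <- exact_permanova_p(d, labels)
  des <- data.frame(sample_id = rownames(d), g = labels)
  res <- permanova(structure(d, class = c("distance_matrix", "matrix")),
                   des, "g", n_perm = 9999, seed = 3)
  # Monte Carlo estimate of the same null: within 3 binomial s.e.
  se <- sqrt(p_exact * (1 - p_exact) / 9999)
  expect_lt(abs(res$p_value[1] - p_exact), 3 * se + 2e-3)
})

test_that("statistics agree with vegan::adonis2 on random data", {
  skip_if_not_installed("vegan")
  set.seed(8)
  x <- matrix(rnorm(20 * 3), 20, 3)
  g <- factor(rep(c("a", "b"), each = 10))
  h <- factor(rep(c("u", "v"), times = 10))
  dm <- euclid_dm(x)
  des <- data.frame(sample_id = rownames(dm), g = g, h = h)
  res <- permanova(dm, des, c("g", "h"), n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(unclass(dm)) ~ g + h,
                        data = data.frame(g = g, h = h),
                        permutations = 99, by = "terms")
  expect_equal(res$sum_of_squares[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(res$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(res$df[1:2], ref$Df[1:2])
})

test_that("sums of squares partition and R2 sums to one", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(12 * 2), 12, 2)
    dm <- euclid_dm(x)
    des <- data.frame(sample_id = rownames(dm),
                      g = sample(c("a", "b", "c"), 12, replace = TRUE))
    if (length(unique(des$g)) < 2) next
    res <- permanova(dm, des, "g", n_perm = 9, seed = s)
    ss <- res$sum_of_squares
    expect_equal(sum(ss[res$term != "Total"]), ss[res$term == "Total"],
                 tolerance = 1e-8)
    expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-8)
    expect_gte(res$p_value[1], 1 / (9 + 1))
  }
})

test_that("degenerate inputs error and equal distances give p near 1", {
  d <- matrix(0.7, 6, 6); diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  dm <- structure(d, class = c("distance_matrix", "matrix"))
  des <- data.frame(sample_id = rownames(d), g = rep(c("a", "b"), 3))
  res <- permanova(dm, des, "g", n_perm = 99, seed = 1)
  # equidistant points: between-group mean square equals residual mean
  # square exactly, so F = 1 for every labelling and p = 1
  expect_equal(res$pseudo_F[1], 1, tolerance = 1e-8)
  expect_equal(res$p_value[1], 1)
  # constant factor has zero df
  des$g <- "a"
  expect_error(permanova(dm, des, "g", n_perm = 9, seed = 1), "zero df")
})

test_that("blocked permutations never cross blocks", {
  blocks <- rep(letters[1:5], times = c(1, 2, 3, 3, 4))
  set.seed(11)
  for (i in 1:200) {
    p <- permute_labels(length(blocks), blocks)
    expect_identical(blocks[p], blocks)
  }
})

test_that("rma_permanova reduces to free permutation with one block and is
           degenerate with singleton blocks", {
  set.seed(4)
  x <- matrix(rnorm(8 * 2), 8, 2)
  dm <- euclid_dm(x)
  des <- data.frame(sample_id = rownames(dm),
                    g = rep(c("a", "b"), each = 4),
                    blk = "all", single = paste0("b", 1:8))
  free <- permanova(dm, des, "g", n_perm = 199, seed = 7)
  oneblk <- rma_permanova(dm, des, "g", blocks = "blk", n_perm = 199, seed = 7)
  expect_equal(oneblk$p_value[1], free$p_value[1])
  # singleton blocks: only the identity permutation -> p = 1
  expect_message(
    singles <- rma_permanova(dm, des, "g", blocks = "single",
                             n_perm = 99, seed = 1),
    "identity")
  expect_equal(singles$p_value[1], 1)
})

test_that("pairwise tests match subsetted runs and cover all level pairs", {
  set.seed(12)
  x <- matrix(rnorm(12 * 2), 12, 2)
  dm <- euclid_dm(x)
  des <- data.frame(sample_id = rownames(dm),
                    g = rep(c("a", "b", "c"), each = 4))
  pw <- pairwise_permanova(dm, des, "g", n_perm = 99, seed = 5)
  expect_length(pw, 3)
  expect_setequal(names(pw), c("a.vs.b", "a.vs.c", "b.vs.c"))
  keep <- des$g %in% c("a", "c")
  sub <- structure(unclass(dm)[keep, keep],
                   class = c("distance_matrix", "matrix"))
  direct <- permanova(sub, des[keep, ], "g", n_perm = 99, seed = 5)
  expect_equal(pw[["a.vs.c"]]$pseudo_F[1], direct$pseudo_F[1])
  expect_equal(pw[["a.vs.c"]]$p_value[1], direct$p_value[1])
})

test_that("larger group shifts never weaken the evidence on average", {
  pvals <- sapply(c(0, 1, 2.5), function(shift) {
    mean(sapply(1:30, function(r) {
      set.seed(1000 * shift + r)
      x <- matrix(rnorm(12 * 2), 12, 2)
      x[7:12, ] <- x[7:12, ] + shift
      des <- data.frame(sample_id = paste0("s", 1:12),
                        g = rep(c("a", "b"), each = 6))
      permanova(euclid_dm(x), des, "g", n_perm = 99, seed = r)$p_value[1]
    }))
  })
  expect_true(all(diff(pvals) < 0))
})
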