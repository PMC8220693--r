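test_that("TMM factors behave like library-size-free compositional factors", {
  m <- matrix(rpois(200, 50) + 1, 50, 4,
              dimnames = list(sprintf("a%02d", 1:50), paste0("s", 1:4)))
  tbl <- asv_table(m)
  f <- tmm_factors(tbl)
  expect_equal(exp(mean(log(f$tmm_factor))), 1, tolerance = 1e-9)
  expect_true(all(f$tmm_factor > 0 & is.finite(f$tmm_factor)))
  # identical columns -> unit factors
  m2 <- cbind(s1 = m[, 1], s2 = m[, 1])
  f2 <- tmm_factors(asv_table(m2))
  expect_equal(f2$tmm_factor, c(1, 1))
  # pure depth difference absorbed by library size: M-values all zero
  m3 <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
  f3 <- tmm_factors(asv_table(m3))
  expect_equal(f3$tmm_factor, c(1, 1), tolerance = 1e-9)
})

test_that("TMM factors track edgeR::calcNormFactors on random counts", {
  skip_if_not_installed("edgeR")
  set.seed(21)
  m <- matrix(rnbinom(300 * 6, mu = 40, size = 1.5), 300, 6,
              dimnames = list(sprintf("a%03d", 1:300), paste0("s", 1:6)))
  m[1, ] <- m[1, ] + 1
  ref_sample <- "s1"
  mine <- tmm_factors(asv_table(m), ref = ref_sample)
  ref <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1)
  expect_equal(mine$tmm_factor, unname(ref), tolerance = 0.03)
})

test_that("voom-style weights are positive and track the mean-variance trend", {
  # homoscedastic data: near-flat trend, weight CV < 0.2
  set.seed(31)
  n <- 24
  design <- cbind(int = rep(1, n))
  mu <- runif(200, 6, 10)
  logcpm_counts <- round(2^matrix(rnorm(200 * n, mu, 0.3), 200, n))
  dimnames(logcpm_counts) <- list(sprintf("a%03d", 1:200), paste0("s", 1:n))
  vm <- voom_weights(asv_table(logcpm_counts), design = design)
  expect_true(all(vm$weights > 0 & is.finite(vm$weights)))
  expect_lt(stats::sd(vm$weights) / mean(vm$weights), 0.2)

  # Poisson counts: variance of log-cpm decreases with mean, so the fitted
  # sqrt-sd trend decreases over the bulk of the mean range
  set.seed(32)
  lam <- exp(runif(300, log(2), log(500)))
  pois <- matrix(rpois(300 * n, lam), 300, n,
                 dimnames = list(sprintf("p%03d", 1:300), paste0("s", 1:n)))
  pois[1, ] <- pois[1, ] + 1
  vmp <- voom_weights(asv_table(pois), design = design)
  tr <- vmp$trend
  mid <- tr$mean_logcpm >= quantile(tr$mean_logcpm, 0.2) &
    tr$mean_logcpm <= quantile(tr$mean_logcpm, 0.9)
  fitl <- lm(sqrt_sd ~ mean_logcpm, data = tr[mid, ])
  expect_lt(coef(fitl)[2], 0)
})

test_that("consensus correlation recovers block structure", {
  n_blocks <- 40
  design <- cbind(int = rep(1, 2 * n_blocks))
  blocks <- rep(paste0("b", seq_len(n_blocks)), each = 2)
  gen <- function(icc, seed) {
    set.seed(seed)
    g <- 200
    eb <- matrix(rnorm(g * n_blocks, 0, sqrt(icc)), g, n_blocks)
    y <- eb[, rep(seq_len(n_blocks), each = 2)] +
      matrix(rnorm(g * 2 * n_blocks, 0, sqrt(1 - icc)), g, 2 * n_blocks)
    y <- y + 8
    counts <- round(2^y)
    dimnames(counts) <- list(sprintf("g%03d", 1:g),
                             sprintf("s%03d", 1:(2 * n_blocks)))
    voom_weights(asv_table(counts), design = design)
  }
  rho_null <- consensus_correlation(gen(0, 41), blocks = blocks)
  expect_lt(abs(rho_null), 0.1)
  rho_icc <- consensus_correlation(gen(0.5, 42), blocks = blocks)
  expect_gt(rho_icc, 0.3)
  expect_lt(rho_icc, 0.7)
  # no multi-sample blocks -> rho 0 with warning
  expect_warning(
    r0 <- consensus_correlation(gen(0, 43),
                                blocks = paste0("x", seq_len(2 * n_blocks))),
    "consensus")
  expect_equal(r0, 0)
})

test_that("moderated t with d0 = 0 equals an independent weighted LS t", {
  set.seed(51)
  n <- 12
  day <- factor(rep(c("d1", "d2"), each = 6))
  X <- model.matrix(~ 0 + day)
  counts <- matrix(rpois(80 * n, 60), 80, n,
                   dimnames = list(sprintf("a%02d", 1:80), paste0("s", 1:n)))
  counts[1, ] <- counts[1, ] + 1
  vm <- voom_weights(asv_table(counts), design = X)
  ct <- matrix(c(1, -1), 2, 1, dimnames = list(colnames(X), "d1.vs.d2"))
  fit0 <- fit_moderated(vm, contrasts = ct, d0 = 0)
  # oracle: per-ASV lm with the voom weights
  for (g in c(1, 7, 33)) {
    w <- vm$weights[g, ]
    lmfit <- lm(vm$logcpm[g, ] ~ 0 + day, weights = w)
    est <- coef(lmfit)[1] - coef(lmfit)[2]
    se <- sqrt(t(c(1, -1)) %*% vcov(lmfit) %*% c(1, -1))
    t_ref <- est / se
    expect_equal(unname(fit0$t_mod[g, 1]), unname(drop(t_ref)),
                 tolerance = 1e-8)
  }
  # d0 -> Inf: all posterior variances equal the prior
  fit_inf <- fit_moderated(vm, contrasts = ct, d0 = Inf)
  expect_equal(stats::var(fit_inf$s2_post), 0)
  # estimated prior: posterior variance between s2 and s02
  fit_eb <- fit_moderated(vm, contrasts = ct)
  lo <- pmin(fit_eb$s2, fit_eb$s02); hi <- pmax(fit_eb$s2, fit_eb$s02)
  ok <- fit_eb$s2 > 0
  expect_true(all(fit_eb$s2_post[ok] >= lo[ok] - 1e-10 &
                    fit_eb$s2_post[ok] <= hi[ok] + 1e-10))
})

test_that("moderated pipeline tracks limma voom + eBayes on well-behaved data", {
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  set.seed(52)
  n <- 16
  day <- factor(rep(c("d1", "d2"), each = 8))
  X <- model.matrix(~ 0 + day)
  counts <- matrix(rnbinom(150 * n, mu = 80, size = 3), 150, n,
                   dimnames = list(sprintf("a%03d", 1:150), paste0("s", 1:n)))
  counts <- counts[rowSums(counts > 0) >= 8, ]
  tbl <- asv_table(counts)
  vm <- voom_weights(tbl, design = X)
  ct <- matrix(c(1, -1), 2, 1, dimnames = list(colnames(X), "c1"))
  mine <- fit_moderated(vm, contrasts = ct)
  dge <- edgeR::DGEList(counts)
  dge <- edgeR::calcNormFactors(dge)
  v <- limma::voom(dge, X)
  lf <- limma::lmFit(v, X)
  lf <- limma::contrasts.fit(lf, ct)
  eb <- limma::eBayes(lf)
  # same method family: log-fold-changes nearly identical, t well correlated
  expect_lt(max(abs(mine$log_fc[, 1] - eb$coefficients[, 1])), 0.2)
  expect_gt(cor(mine$t_mod[, 1], eb$t[, 1]), 0.97)
})

test_that("BH step-up matches hand-computed adjustments", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               c(0.04, 0.04, 0.04, 0.04))
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_equal(p.adjust(p, method = "BH"), c(0.004, 0.02, 4 * 0.04 / 3, 0.2))
})

test_that("batch-effect flags follow the any-contrast FDR rule", {
  flag_fixture <- function(p_day) {
    f <- list(p = matrix(p_day, 1, dimnames = list("asv1", "c1")),
              log_fc = matrix(1, 1, dimnames = list("asv1", "c1")),
              t_mod = matrix(1, 1, dimnames = list("asv1", "c1")))
    batch_effect_flags(list(day = f))
  }
  expect_true(flag_fixture(0.04)$flagged[["asv1"]])
  expect_false(flag_fixture(0.051)$flagged[["asv1"]])
  expect_warning(res <- batch_effect_flags(list()), "no contrasts")
  expect_length(res$flagged, 0)
})

test_that("technical contrasts respect the nesting structure", {
  des <- study_design(data.frame(
    sample_id = paste0("s", 1:12), sample_type = "plasma",
    sequencing_run = rep(c("r1", "r2"), c(8, 4)),
    extraction_batch = rep(c("A", "B", "C"), c(4, 4, 4)),
    extraction_day = rep(c("Ad1", "Ad2", "Bd1", "Bd2", "Cd1", "Cd2"),
                         each = 2)))
  tc <- technical_contrasts(des)
  expect_equal(ncol(tc$batch), 3)   # A-B, A-C, B-C
  expect_equal(ncol(tc$run), 1)
  expect_equal(ncol(tc$day), 3)     # only days sharing a batch
  # day contrasts never compare days of different batches
  for (j in seq_len(ncol(tc$day))) {
    active <- rownames(tc$day)[tc$day[, j] != 0]
    bt <- unique(substr(active, 1, 1))
    expect_length(bt, 1)
  }
})

test_that("criterion (i) screen controls null errors and finds planted effects", {
  nb <- simulate_nb_counts(n_asvs = 300, n_batches = 3, samples_per_batch = 10,
                           seed = 61)
  da <- run_batch_da(nb$table, nb$design)
  expect_lte(mean(!da$pass), 0.07)
  sens <- sapply(62:63, function(s) {
    nb2 <- simulate_nb_counts(n_asvs = 300, n_batches = 3,
                              samples_per_batch = 12,
                              effect_asvs = 1:40, effect_fold = 4, seed = s)
    da2 <- run_batch_da(nb2$table, nb2$design)
    mean(!da2$pass[nb2$effect_asvs])
  })
  expect_gte(mean(sens), 0.8)
  # degenerate: single batch, single day -> everything passes with a warning
  tbl <- random_table(n_asv = 10, n_samp = 6, seed = 63)
  des <- tiny_design(sample_ids(tbl))
  expect_warning(da3 <- run_batch_da(tbl, des), "no technical contrasts")
  expect_true(all(da3$pass))
})
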