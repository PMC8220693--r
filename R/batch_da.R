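#' TMM library-size normalisation factors
#'
#' Trimmed mean of M-values: per sample, the weighted mean of log2 abundance
#' ratios (M-values) against a reference sample, after trimming the most
#' extreme `trim_m` fraction by M and `trim_a` fraction by average abundance
#' (A); precision weights are the asymptotic binomial variances. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param table an [asv_table()] with >= 2 samples.
#' @param ref reference sample id, or `"auto"` to pick the sample whose
#'   upper-quartile relative abundance is closest to the mean.
#' @param trim_m two-sided trim fraction on M-values (default 0.30).
#' @param trim_a two-sided trim fraction on A-values (default 0.05).
#' @return data.frame with `sample_id`, `library_size`, `tmm_factor`.
#' @export
tmm_factors <- function(table, ref = "auto", trim_m = 0.30, trim_a = 0.05) {
  m <- unclass(table)
  if (ncol(m) < 2L) stop("need >= 2 samples")
  libs <- colSums(m)
  if (any(libs == 0)) stop("sample with zero library size")
  if (identical(ref, "auto")) {
    uq <- apply(sweep(m, 2L, libs, "/"), 2L, stats::quantile, probs = 0.75)
    ref <- colnames(m)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref %in% colnames(m)) stop("unknown reference sample: ", ref)
  xr <- m[, ref]
  Nr <- libs[ref]
  f <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]; N <- libs[j]
    ok <- x > 0 & xr > 0
    if (!any(ok))
      stop("sample ", colnames(m)[j], " shares no detected ASV with reference")
    M <- log2((x[ok] / N) / (xr[ok] / Nr))
    A <- 0.5 * log2((x[ok] / N) * (xr[ok] / Nr))
    w <- (N - x[ok]) / (N * x[ok]) + (Nr - xr[ok]) / (Nr * xr[ok])
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M, ties.method = "first") >= loM &
      rank(M, ties.method = "first") <= hiM &
      rank(A, ties.method = "first") >= loA &
      rank(A, ties.method = "first") <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  data.frame(sample_id = colnames(m), library_size = unname(libs),
             tmm_factor = unname(f), stringsAsFactors = FALSE)
}

#' Log-CPM with mean-variance precision weights
#'
#' Transforms counts to `log2` counts per million using TMM-adjusted
#' effective library sizes and a prior count of 0.5, fits the per-ASV linear
#' model, regresses the residual sqrt-standard-deviation on mean log-CPM by
#' a locally weighted smoother, and converts the fitted trend into inverse
#' predicted-variance observation weights. ASVs detected in fewer than
#' `min_detected` samples are excluded from trend fitting (high sparsity
#' otherwise drags the trend down and understates the ASV-wise variances)
#' but still receive weights from the fitted trend.
#'
#' @param table an [asv_table()].
#' @param factors [tmm_factors()] output (or `NULL` to compute internally).
#' @param design numeric model matrix (samples x coefficients).
#' @param span lowess span (default 0.5).
#' @param min_detected minimum nonzero samples for an ASV to inform the
#'   trend (default 3).
#' @return List of class `voom_matrices` with `logcpm`, `weights` (both
#'   ASV x sample), `trend` (tabulated mean -> sqrt-sd), plus the `counts`
#'   and `design` used.
#' @export
voom_weights <- function(table, factors = NULL, design, span = 0.5,
                         min_detected = 3L) {
  m <- unclass(table)
  if (is.null(factors)) factors <- tmm_factors(table)
  if (nrow(design) != ncol(m)) stop("design rows must match samples")
  if (ncol(m) < ncol(design) + 1L) stop("fewer samples than design columns + 1")
  eff <- factors$library_size[match(colnames(m), factors$sample_id)] *
    factors$tmm_factor[match(colnames(m), factors$sample_id)]
  logcpm <- log2(sweep(m + 0.5, 2L, eff + 1, "/") * 1e6)
  qx <- qr(design)
  fit <- fit_rows(logcpm, design)
  sx <- rowMeans(logcpm)
  sy <- sqrt(fit$sigma)  # sqrt of residual sd (quarter-root variance)
  use <- rowSums(m > 0) >= min_detected & fit$sigma > 0
  if (sum(use) < 10L) use <- fit$sigma > 0
  lo <- stats::lowess(sx[use], sy[use], f = span)
  pred <- stats::approxfun(lo$x, lo$y, rule = 2)
  fitted_sqrt_sd <- pred(fit$fitted)
  fitted_sqrt_sd[fitted_sqrt_sd < 1e-4] <- 1e-4
  w <- matrix(fitted_sqrt_sd^-4, nrow(m), ncol(m),
              dimnames = dimnames(m))
  out <- list(logcpm = logcpm, weights = w,
              trend = data.frame(mean_logcpm = lo$x, sqrt_sd = lo$y),
              counts = m, design = design, factors = factors)
  class(out) <- "voom_matrices"
  out
}

# Row-wise least squares of Y (genes x samples) on design X (samples x p):
# fitted values, residual variance sigma2, residual df.
fit_rows <- function(Y, X, weights = NULL) {
  n <- ncol(Y); p <- qr(X)$rank
  if (is.null(weights)) {
    q <- qr(X)
    coefs <- t(qr.coef(q, t(Y)))
    fitted <- coefs %*% t(X)
    res <- Y - fitted
    sigma2 <- rowSums(res^2) / (n - p)
    list(coef = coefs, fitted = fitted, residuals = res,
         sigma = sqrt(sigma2), df = n - p)
  } else {
    stop("use fit_moderated for weighted fits")
  }
}

#' Consensus within-block correlation
#'
#' Estimates, per ASV, the within-block (e.g. within-patient) correlation of
#' model residuals, pools the per-ASV estimates on Fisher's z scale by a
#' trimmed mean, and returns a single consensus rho for use in
#' generalised-least-squares model fitting.
#'
#' @param vm a `voom_matrices` object.
#' @param design numeric model matrix (defaults to the one inside `vm`).
#' @param blocks character/factor vector (length = samples), e.g. patient id.
#' @param trim trim fraction for the pooled mean (default 0.15).
#' @return Consensus correlation in (-1, 1); 0 with a warning when no block
#'   has more than one sample.
#' @export
consensus_correlation <- function(vm, design = vm$design, blocks,
                                  trim = 0.15) {
  blocks <- as.character(blocks)
  sizes <- table(blocks)
  if (all(sizes < 2L)) {
    warning("no multi-sample blocks; consensus correlation set to 0")
    return(0)
  }
  res <- vm$logcpm - fit_rows(vm$logcpm, design)$fitted
  pair_i <- integer(0); pair_j <- integer(0)
  for (b in names(sizes)[sizes >= 2L]) {
    idx <- which(blocks == b)
    cmb <- utils::combn(idx, 2L)
    pair_i <- c(pair_i, cmb[1L, ]); pair_j <- c(pair_j, cmb[2L, ])
  }
  s2 <- rowMeans(res^2)
  ok <- s2 > 0
  rho_g <- rowMeans(res[ok, pair_i, drop = FALSE] *
                      res[ok, pair_j, drop = FALSE]) / s2[ok]
  rho_g <- pmin(pmax(rho_g, -0.99), 0.99)
  z <- atanh(rho_g)
  tanh(mean(z, trim = trim))
}

# Inverse of the trigamma function by Newton iteration.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Empirical-Bayes squeezing of residual variances: moment matching of
# log s^2 against a scaled-F prior, giving prior df d0 and prior variance s02.
estimate_prior <- function(s2, df) {
  ok <- s2 > 0 & df > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s02 = mean(s2[s2 > 0], na.rm = TRUE)))
  z <- log(s2[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated linear-model fit with contrasts
#'
#' Per-ASV weighted least squares (optionally whitened by a block
#' equicorrelation with consensus correlation `rho`), with residual
#' variances shrunk toward an empirical-Bayes prior:
#' `s2_post = (d0*s02 + d*s2) / (d0 + d)` where `(d0, s02)` are estimated by
#' moment matching of the scaled-F distribution of the `s2`. Moderated t is
#' the contrast estimate over its posterior standard error, with `d0 + d`
#' degrees of freedom. The residual df of an ASV is reduced by the number of
#' design groups in which it has only zero counts (sparse ASVs otherwise
#' understate their variance).
#'
#' @param vm a `voom_matrices` object.
#' @param design numeric model matrix (defaults to the one inside `vm`).
#' @param contrasts numeric matrix (coefficients x contrasts), columns named.
#' @param rho consensus correlation (default 0 = ordinary weighted LS).
#' @param blocks block vector (required when `rho != 0`).
#' @param d0 optional prior df override (`0` disables moderation, `Inf`
#'   forces full shrinkage); default `NULL` estimates it from the data.
#' @return A `moderated_fit` list: `coefficients`, `log_fc`, `t_mod`, `p`
#'   (ASV x contrast matrices), `s2`, `s2_post`, `df_residual`, `d0`, `s02`,
#'   `rho`.
#' @export
fit_moderated <- function(vm, design = vm$design, contrasts, rho = 0,
                          blocks = NULL, d0 = NULL) {
  Y <- vm$logcpm
  W <- vm$weights
  G <- nrow(Y); n <- ncol(Y)
  p <- qr(design)$rank
  if (!is.matrix(contrasts)) contrasts <- matrix(contrasts, ncol = 1L)
  if (nrow(contrasts) != ncol(design))
    stop("contrast rows must match design coefficients")
  nc <- ncol(contrasts)
  Linv <- NULL
  if (rho != 0) {
    if (is.null(blocks)) stop("blocks required when rho != 0")
    R <- diag(n)
    blocks <- as.character(blocks)
    for (b in unique(blocks)) {
      idx <- which(blocks == b)
      R[idx, idx] <- rho
      diag(R)[idx] <- 1
    }
    Linv <- backsolve(chol(R), diag(n), transpose = TRUE)  # whitening: Linv %*% x
  }
  # sparsity correction: count all-zero design groups per ASV
  grp <- apply(design != 0, 1L, function(r) paste(which(r), collapse = ","))
  glev <- unique(grp)
  zero_groups <- sapply(glev, function(g) {
    cols <- grp == g
    rowSums(vm$counts[, cols, drop = FALSE] > 0) == 0
  })
  if (is.null(dim(zero_groups))) zero_groups <- matrix(zero_groups, nrow = G)
  n_zero <- rowSums(zero_groups)
  df_res <- pmax(n - p - n_zero, 1)

  coefs <- matrix(NA_real_, G, p)
  est <- tval <- matrix(NA_real_, G, nc,
                        dimnames = list(rownames(Y), colnames(contrasts)))
  se_unscaled <- matrix(NA_real_, G, nc)
  s2 <- numeric(G)
  for (g in seq_len(G)) {
    u <- sqrt(W[g, ])
    Xg <- design * u
    yg <- Y[g, ] * u
    if (!is.null(Linv)) {
      Xg <- Linv %*% Xg
      yg <- drop(Linv %*% yg)
    }
    q <- qr(Xg)
    if (q$rank < ncol(design)) stop("non-estimable contrast: singular design")
    beta <- qr.coef(q, yg)
    resid <- yg - drop(Xg %*% beta)
    s2[g] <- sum(resid^2) / (n - p)
    xtxinv <- chol2inv(qr.R(q))
    coefs[g, ] <- beta
    est[g, ] <- drop(t(contrasts) %*% beta)
    se_unscaled[g, ] <- sqrt(diag(t(contrasts) %*% xtxinv %*% contrasts))
  }
  prior <- if (is.null(d0)) estimate_prior(s2, df_res) else
    list(d0 = d0, s02 = if (is.finite(d0) && d0 > 0)
      stats::median(s2[s2 > 0]) else mean(s2[s2 > 0]))
  d0v <- prior$d0
  s2_post <- if (is.infinite(d0v)) rep(prior$s02, G) else
    (d0v * prior$s02 + df_res * s2) / (d0v + df_res)
  tval <- est / (se_unscaled * sqrt(s2_post))
  df_total <- d0v + df_res
  pval <- 2 * stats::pt(-abs(tval), df = df_total)
  out <- list(coefficients = coefs, log_fc = est, t_mod = tval, p = pval,
              s2 = s2, s2_post = s2_post, df_residual = df_res,
              d0 = d0v, s02 = prior$s02, rho = rho)
  class(out) <- "moderated_fit"
  out
}

#' Build the technical-variable contrasts for the batch-effect screen
#'
#' The model has DNA-extraction day as its only factor (one coefficient per
#' day, no intercept) since day is nested in batch and batch in run. DEB
#' contrasts average the days of each batch and compare all batch pairs;
#' day contrasts compare only days sharing a batch; run contrasts average
#' days per run and compare run pairs.
#'
#' @param design a `study_design` restricted to the modelled samples.
#' @return List with `model` (model matrix), `day_levels`, and per-variable
#'   contrast matrices `run`, `batch`, `day` (possibly zero columns).
#' @export
technical_contrasts <- function(design) {
  day <- factor(design$extraction_day)
  X <- if (nlevels(day) == 1L)
    matrix(1, length(day), 1L, dimnames = list(NULL, levels(day)))
  else stats::model.matrix(~ 0 + day)
  colnames(X) <- levels(day)
  lev <- levels(day)
  day_batch <- vapply(lev, function(d)
    design$extraction_batch[design$extraction_day == d][1L], character(1L))
  day_run <- vapply(lev, function(d)
    design$sequencing_run[design$extraction_day == d][1L], character(1L))
  pair_contrast <- function(groups) {
    gl <- sort(unique(groups))
    cols <- list()
    if (length(gl) >= 2L)
      for (i in seq_len(length(gl) - 1L)) for (j in (i + 1L):length(gl)) {
        v <- numeric(length(lev))
        v[groups == gl[i]] <- 1 / sum(groups == gl[i])
        v[groups == gl[j]] <- -1 / sum(groups == gl[j])
        cols[[paste0(gl[i], ".vs.", gl[j])]] <- v
      }
    if (!length(cols))
      return(matrix(numeric(0), nrow = length(lev), ncol = 0,
                    dimnames = list(lev, NULL)))
    out <- do.call(cbind, cols)
    rownames(out) <- lev
    out
  }
  day_cols <- list()
  for (b in sort(unique(day_batch))) {
    din <- lev[day_batch == b]
    if (length(din) >= 2L)
      for (i in seq_len(length(din) - 1L)) for (j in (i + 1L):length(din)) {
        v <- numeric(length(lev)); names(v) <- lev
        v[din[i]] <- 1; v[din[j]] <- -1
        day_cols[[paste0(din[i], ".vs.", din[j])]] <- v
      }
  }
  day_m <- if (length(day_cols)) do.call(cbind, day_cols) else
    matrix(numeric(0), nrow = length(lev), ncol = 0, dimnames = list(lev, NULL))
  list(model = X, day_levels = lev,
       run = pair_contrast(day_run),
       batch = pair_contrast(day_batch),
       day = day_m)
}

#' Flag batch-affected ASVs (decontamination criterion i)
#'
#' An ASV is flagged as batch-affected when its BH-adjusted p-value is
#' `<= fdr_cut` in any contrast of any technical variable (sequencing run,
#' extraction batch, extraction day). BH adjustment pools, per variable, all
#' of that variable's contrasts across all ASVs into one family. Unflagged
#' ASVs pass criterion (i).
#'
#' @param fits named list of `moderated_fit` objects, one per technical
#'   variable (e.g. `run`, `batch`, `day`).
#' @param fdr_cut FDR threshold (default 0.05).
#' @return List with `flagged` (named logical per ASV), `fdr` (named list of
#'   ASV x contrast FDR matrices), `table` (long-format results).
#' @export
batch_effect_flags <- function(fits, fdr_cut = 0.05) {
  fits <- fits[!vapply(fits, is.null, logical(1L))]
  fits <- fits[vapply(fits, function(f) ncol(f$p) > 0, logical(1L))]
  if (!length(fits)) {
    warning("no contrasts supplied; all ASVs pass criterion (i)")
    return(list(flagged = logical(0), fdr = list(),
                table = data.frame()))
  }
  ids <- rownames(fits[[1L]]$p)
  flagged <- stats::setNames(rep(FALSE, length(ids)), ids)
  fdr_list <- list()
  rows <- list()
  for (v in names(fits)) {
    p <- fits[[v]]$p
    fdr <- matrix(stats::p.adjust(as.vector(p), method = "BH"),
                  nrow(p), ncol(p), dimnames = dimnames(p))
    fdr_list[[v]] <- fdr
    hit <- apply(fdr <= fdr_cut, 1L, any)
    hit[is.na(hit)] <- FALSE
    flagged[rownames(p)] <- flagged[rownames(p)] | hit
    for (ct in colnames(p))
      rows[[paste(v, ct)]] <- data.frame(
        asv_id = rownames(p), variable = v, contrast = ct,
        logFC = fits[[v]]$log_fc[, ct], t = fits[[v]]$t_mod[, ct],
        p = p[, ct], fdr = fdr[, ct], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$flagged <- flagged[tab$asv_id]
  list(flagged = flagged, fdr = fdr_list, table = tab)
}

#' Run the full criterion (i) batch-effect screen
#'
#' Fits the day-factor model on the target samples (DENCs excluded by
#' default: the criterion concerns abundance differences among plasma
#' samples across technical variables), with TMM normalisation, log-CPM
#' precision weights, an optional patient-block consensus correlation, and
#' moderated t tests on run / batch / day contrasts.
#'
#' @param table an [asv_table()].
#' @param design a `study_design` covering its samples.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param sample_types sample types entering the model (default `"plasma"`).
#' @param use_blocks use patient ids as correlation blocks when available
#'   (default TRUE).
#' @return List with `flags` (see [batch_effect_flags()]), `fits`, `rho`,
#'   and `pass` (named logical: criterion (i) passers).
#' @export
run_batch_da <- function(table, design, fdr_cut = 0.05,
                         sample_types = "plasma", use_blocks = TRUE) {
  design <- align_design(table, design)
  keep <- design$sample_type %in% sample_types
  sub <- subset_asv_table(table, keep_samples = keep)
  sub <- subset_asv_table(sub, keep_asvs = rowSums(unclass(sub)) > 0)
  dsub <- design[keep, , drop = FALSE]
  if (anyNA(dsub$extraction_day))
    stop("criterion (i) requires extraction_day for modelled samples")
  tc <- technical_contrasts(dsub)
  if (ncol(tc$run) + ncol(tc$batch) + ncol(tc$day) == 0L) {
    warning("single batch/run/day: no technical contrasts; all ASVs pass")
    ids <- asv_ids(sub)
    return(list(flags = list(flagged = stats::setNames(rep(FALSE, length(ids)), ids)),
                fits = list(), rho = 0,
                pass = stats::setNames(rep(TRUE, length(ids)), ids)))
  }
  vm <- voom_weights(sub, design = tc$model)
  rho <- 0
  blocks <- NULL
  if (use_blocks && any(!is.na(dsub$patient_id))) {
    blocks <- dsub$patient_id
    blocks[is.na(blocks)] <- paste0(".na", seq_len(sum(is.na(blocks))))
    if (any(table(blocks) >= 2L))
      rho <- consensus_correlation(vm, blocks = blocks)
    else blocks <- NULL
  }
  fits <- list()
  for (v in c("run", "batch", "day"))
    if (ncol(tc[[v]]) > 0L)
      fits[[v]] <- fit_moderated(vm, contrasts = tc[[v]], rho = rho,
                                 blocks = blocks)
  flags <- batch_effect_flags(fits, fdr_cut = fdr_cut)
  ids <- asv_ids(sub)
  pass <- stats::setNames(!flags$flagged[ids], ids)
  list(flags = flags, fits = fits, rho = rho, pass = pass)
}
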