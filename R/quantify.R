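#' Poisson-corrected ddPCR concentration
#'
#' Droplet digital PCR partitions a reaction into ~20,000 droplets; the
#' fraction of positive droplets `k/n` is Poisson-corrected to the mean
#' number of template molecules per droplet, `lambda = -ln(1 - k/n)`, and
#' divided by the droplet volume to give copies per microlitre of reaction.
#' A saturated reaction (`k == n`) has no finite estimate; the value at
#' `k = n - 1` is returned as a lower bound with a warning.
#'
#' @param droplets_positive number of positive droplets (k).
#' @param droplets_total number of accepted droplets (n); a warning is
#'   issued below 10000.
#' @param droplet_volume droplet partition volume in microlitres
#'   (default 8.5e-4, the platform's nominal value).
#' @return Concentration in copies per microlitre of reaction.
#' @export
poisson_concentration <- function(droplets_positive, droplets_total,
                                  droplet_volume = 8.5e-4) {
  k <- droplets_positive; n <- droplets_total
  if (k < 0 || n <= 0 || k > n) stop("need 0 <= k <= n, n > 0")
  if (n < 10000) warning("fewer than 10000 droplets (", n, ")")
  if (k == n) {
    warning("saturated reaction (all droplets positive); lower bound returned")
    k <- n - 1
  }
  lambda <- -log(1 - k / n)
  lambda / droplet_volume
}

#' Convert eluate concentration to copies per ml of source fluid
#'
#' @param conc_dna copies per microlitre of DNA eluate.
#' @param elution_volume eluate volume in microlitres (e.g. 50).
#' @param source_volume source fluid volume in millilitres (e.g. 2 ml
#'   plasma).
#' @return Copies per millilitre of source fluid.
#' @export
copies_per_ml_source <- function(conc_dna, elution_volume, source_volume) {
  if (elution_volume <= 0 || source_volume <= 0) stop("volumes must be positive")
  conc_dna * elution_volume / source_volume
}

#' ddPCR detection call from technical replicates
#'
#' An ASV is called detected when at least 2 template copies are seen summed
#' across the duplicate reactions.
#'
#' @param replicate_copies numeric vector of detected copies per technical
#'   replicate (>= 2 replicates required).
#' @param min_copies detection threshold (default 2).
#' @return Logical.
#' @export
detect_call <- function(replicate_copies, min_copies = 2) {
  if (length(replicate_copies) < 2L)
    stop("detection calls require at least duplicate reactions")
  sum(replicate_copies) >= min_copies
}

#' Read a ddPCR well table
#'
#' CSV with columns `sample_id`, `replicate`, `droplets_total`,
#' `droplets_positive` and optional `target`.
#'
#' @param path CSV file path.
#' @return data.frame of reactions.
#' @export
read_ddpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "droplets_total", "droplets_positive")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing ddPCR columns: ", paste(miss, collapse = ", "))
  if (any(df$droplets_positive > df$droplets_total))
    stop("droplets_positive exceeds droplets_total")
  df
}

#' Agreement between ddPCR and sequencing detection
#'
#' Cohen's kappa on the paired detection calls plus Spearman rank
#' correlation on the paired quantitative measurements.
#'
#' @param ddpcr_calls,seq_presence logical vectors over the same samples.
#' @param ddpcr_conc,seq_abund paired quantitative vectors (>= 3 samples).
#' @return List with `kappa`, `p` (kappa test) and `spearman_rho`.
#' @export
agreement_with_sequencing <- function(ddpcr_calls, seq_presence,
                                      ddpcr_conc, seq_abund) {
  if (length(ddpcr_calls) != length(seq_presence))
    stop("call vectors must align")
  a <- sum(ddpcr_calls & seq_presence)
  b <- sum(ddpcr_calls & !seq_presence)
  c_ <- sum(!ddpcr_calls & seq_presence)
  d <- sum(!ddpcr_calls & !seq_presence)
  k <- cohen_kappa(a, b, c_, d)
  if (length(ddpcr_conc) < 3L) stop("need >= 3 paired samples for Spearman")
  rho <- stats::cor(ddpcr_conc, seq_abund, method = "spearman")
  list(kappa = k$kappa, p = k$p, spearman_rho = rho)
}

#' Gaussian generalised estimating equations
#'
#' Solves the GEE for a Gaussian response with an exchangeable or
#' independence working correlation over clusters (e.g. patients with
#' replicate measurements), iterating to a coefficient change below `tol`,
#' and reports robust (sandwich) standard errors with Wald z tests. With
#' clusters of size 1 (or independence working correlation) the estimates
#' equal ordinary least squares.
#'
#' @param y numeric response (e.g. log concentration or a diversity value).
#' @param x numeric model matrix (rows = observations), or a formula-ready
#'   data.frame passed through `model.matrix`.
#' @param clusters factor partitioning observations into clusters.
#' @param corr working correlation: `"exchangeable"` or `"independence"`.
#' @param tol convergence tolerance on coefficients (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @return A `gee_fit` list: `coefficients`, `robust_se`, `wald_z`, `p`,
#'   `rho` (working correlation), `converged`, `vcov`.
#' @export
gee_fit <- function(y, x, clusters,
                    corr = c("exchangeable", "independence"),
                    tol = 1e-8, max_iter = 100L) {
  corr <- match.arg(corr)
  X <- if (is.matrix(x)) x else stats::model.matrix(~ ., data = x)
  n <- length(y)
  if (nrow(X) != n || length(clusters) != n) stop("dimension mismatch")
  if (qr(X)$rank < ncol(X)) stop("singular design")
  p <- ncol(X)
  cl <- split(seq_len(n), as.character(clusters))
  beta <- stats::coef(stats::lm.fit(X, y))
  rho <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    res <- y - drop(X %*% beta)
    phi <- sum(res^2) / (n - p)
    if (corr == "exchangeable") {
      num <- 0; npairs <- 0
      for (idx in cl) {
        m <- length(idx)
        if (m > 1L) {
          e <- res[idx]
          num <- num + (sum(e)^2 - sum(e^2)) / 2
          npairs <- npairs + m * (m - 1) / 2
        }
      }
      rho <- if (npairs > 0) num / (npairs * phi) else 0
      rho <- min(max(rho, -0.99), 0.99)
    }
    A <- matrix(0, p, p)
    bvec <- numeric(p)
    for (idx in cl) {
      m <- length(idx)
      Ri <- matrix(rho, m, m); diag(Ri) <- 1
      Rinv <- solve(Ri)
      Xi <- X[idx, , drop = FALSE]
      A <- A + t(Xi) %*% Rinv %*% Xi
      bvec <- bvec + t(Xi) %*% Rinv %*% y[idx]
    }
    beta_new <- drop(solve(A, bvec))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged) stop("GEE did not converge in ", max_iter, " iterations")
  res <- y - drop(X %*% beta)
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (idx in cl) {
    m <- length(idx)
    Ri <- matrix(rho, m, m); diag(Ri) <- 1
    Rinv <- solve(Ri)
    Xi <- X[idx, , drop = FALSE]
    u <- t(Xi) %*% Rinv %*% res[idx]
    A <- A + t(Xi) %*% Rinv %*% Xi
    B <- B + u %*% t(u)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  se <- sqrt(diag(V))
  z <- beta / se
  out <- list(coefficients = stats::setNames(beta, colnames(X)),
              robust_se = stats::setNames(se, colnames(X)),
              wald_z = stats::setNames(z, colnames(X)),
              p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
              rho = rho, converged = converged, vcov = V,
              clusters = as.character(clusters))
  class(out) <- "gee_fit"
  out
}

#' Wald test of a linear hypothesis on a GEE fit
#' @param fit a `gee_fit`.
#' @param L numeric vector (or matrix row) of coefficient weights.
#' @return List with `estimate`, `se`, `z`, `p`.
#' @export
gee_linear_hypothesis <- function(fit, L) {
  L <- as.numeric(L)
  est <- sum(L * fit$coefficients)
  se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Per-sample ddPCR summary: concentrations, copies/ml and detection calls
#'
#' @param reactions data.frame as from [read_ddpcr()].
#' @param droplet_volume droplet volume in microlitres (default 8.5e-4).
#' @param elution_volume eluate volume in microlitres (default 50).
#' @param source_volume source fluid volume in ml (default 2).
#' @return data.frame per sample: mean `conc_per_ul`, `copies_per_ml`,
#'   `detected`.
#' @export
summarise_ddpcr <- function(reactions, droplet_volume = 8.5e-4,
                            elution_volume = 50, source_volume = 2) {
  out <- lapply(split(reactions, reactions$sample_id), function(df) {
    conc <- mapply(function(k, n)
      suppressWarnings(poisson_concentration(k, n, droplet_volume)),
      df$droplets_positive, df$droplets_total)
    # template molecules per reaction replicate (reaction volume spans all droplets)
    copies <- conc * df$droplets_total * droplet_volume
    data.frame(sample_id = df$sample_id[1L],
               conc_per_ul = mean(conc),
               copies_per_ml = copies_per_ml_source(mean(conc),
                                                    elution_volume,
                                                    source_volume),
               detected = detect_call(copies),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
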