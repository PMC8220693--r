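#' Cohen's kappa for a 2x2 agreement table
#'
#' Inter-rater agreement between two detection vectors summarised as a 2x2
#' table: `a` detected by both, `b` by the first only, `c` by the second
#' only, `d` by neither. `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po = (a + d)/n` and chance agreement
#' `pe = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. The significance test uses the
#' large-sample null standard error of Fleiss:
#' `SE0 = sqrt(pe + pe^2 - sum_i p_i. p_.i (p_i. + p_.i)) / ((1 - pe) sqrt(n))`,
#' `z = kappa / SE0`, p two-sided normal.
#'
#' @param a,b,c,d non-negative integer cell counts (n = a+b+c+d >= 1).
#' @return List with `kappa`, `z`, `p`, `applicable` (FALSE when chance
#'   agreement is 1 and kappa is undefined).
#' @export
cohen_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n < 1) stop("empty table")
  p1r <- (a + b) / n; p2r <- (c + d) / n  # rater-1 margins
  p1c <- (a + c) / n; p2c <- (b + d) / n  # rater-2 margins
  po <- (a + d) / n
  pe <- p1r * p1c + p2r * p2c
  if (abs(1 - pe) < 1e-12)
    return(list(kappa = NA_real_, z = NA_real_, p = NA_real_,
                applicable = FALSE))
  kappa <- (po - pe) / (1 - pe)
  se0sq <- pe + pe^2 -
    (p1r * p1c * (p1r + p1c) + p2r * p2c * (p2r + p2c))
  se0 <- sqrt(max(se0sq, 0)) / ((1 - pe) * sqrt(n))
  z <- if (is.finite(se0) && se0 > 0) kappa / se0 else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  list(kappa = kappa, z = z, p = p, applicable = TRUE)
}

#' Replicate-extraction detection agreement (criterion iii)
#'
#' For each ASV, detection (count >= 1) is compared between the two
#' replicate extractions of each patient across a pair of batches, and
#' agreement is scored by Cohen's kappa. The criterion passes for ASVs with
#' `kappa > kappa_min` and `p < alpha`. ASVs not detected in any sample of
#' the paired batches are marked not applicable.
#'
#' @param table an [asv_table()].
#' @param design a `study_design` whose `replicate_group` links each
#'   patient's sample in one batch to its re-extraction in the other.
#' @param pair character vector of the two batch ids, e.g. `c("A", "B")`.
#' @param kappa_min kappa threshold (default 0.4, strict >).
#' @param alpha significance threshold (default 0.05, strict <).
#' @return A `kappa_result` data.frame: per ASV `a`, `b`, `c`, `d`,
#'   `kappa`, `z`, `p`, `applicable`, `pass`.
#' @export
replicate_agreement_filter <- function(table, design, pair,
                                       kappa_min = 0.4, alpha = 0.05) {
  design <- align_design(table, design)
  if (length(pair) != 2L) stop("pair must name exactly two batches")
  rg <- design$replicate_group
  in_pair <- design$extraction_batch %in% pair & !is.na(rg)
  groups <- unique(rg[in_pair])
  s1 <- s2 <- character(0)
  for (g in groups) {
    m1 <- design$sample_id[in_pair & rg == g & design$extraction_batch == pair[1L]]
    m2 <- design$sample_id[in_pair & rg == g & design$extraction_batch == pair[2L]]
    if (length(m1) == 1L && length(m2) == 1L) {
      s1 <- c(s1, m1); s2 <- c(s2, m2)
    }
  }
  if (!length(s1)) stop("no matched replicate pairs across batches ",
                        pair[1L], "/", pair[2L])
  pres <- presence_matrix(table)
  det1 <- pres[, s1, drop = FALSE]
  det2 <- pres[, s2, drop = FALSE]
  a <- rowSums(det1 & det2)
  b <- rowSums(det1 & !det2)
  c_ <- rowSums(!det1 & det2)
  d <- rowSums(!det1 & !det2)
  res <- mapply(function(a, b, c, d) {
    if (a + b + c == 0)  # never seen in the paired batches
      return(c(NA, NA, NA, FALSE))
    k <- cohen_kappa(a, b, c, d)
    c(k$kappa, k$z, k$p, k$applicable)
  }, a, b, c_, d)
  out <- data.frame(asv_id = rownames(pres),
                    a = a, b = b, c = c_, d = d,
                    kappa = res[1L, ], z = res[2L, ], p = res[3L, ],
                    applicable = as.logical(res[4L, ]),
                    stringsAsFactors = FALSE)
  out$pass <- out$applicable & !is.na(out$kappa) & !is.na(out$p) &
    out$kappa > kappa_min & out$p < alpha
  rownames(out) <- NULL
  attr(out, "pair") <- pair
  attr(out, "n_pairs") <- length(s1)
  class(out) <- c("kappa_result", "data.frame")
  out
}
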