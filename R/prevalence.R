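#' Presence/absence matrix
#' @param table an [asv_table()].
#' @param min_count minimum count to call an ASV present (default 1).
#' @return Logical matrix, same dimensions as `table`.
#' @export
presence_matrix <- function(table, min_count = 1L) {
  unclass(table) >= min_count
}

#' Prevalence contaminant score for one 2x2 presence table
#'
#' One-sided score in \[0, 1\] comparing detection prevalence in true samples
#' versus negative controls: small values indicate the contaminant direction
#' (higher prevalence fraction in controls). The two-sided chi-square (1 df,
#' no continuity correction) tail probability `t` is folded to one side:
#' `t/2` when the control prevalence fraction exceeds the sample fraction,
#' `1 - t/2` otherwise. When any expected cell is below 5 or the total below
#' 20, the one-sided hypergeometric (Fisher) tail probability of seeing at
#' least the observed control presences is used instead.
#'
#' @param present_samples,absent_samples presence counts in true samples.
#' @param present_controls,absent_controls presence counts in controls.
#' @return Score in \[0, 1\].
#' @export
prevalence_score_single <- function(present_samples, absent_samples,
                                    present_controls, absent_controls) {
  a <- present_samples; b <- absent_samples
  c_ <- present_controls; d <- absent_controls
  if (any(c(a, b, c_, d) < 0)) stop("negative cell")
  n <- a + b + c_ + d
  if (n == 0) stop("all four cells zero")
  ns <- a + b; nc <- c_ + d
  pres <- a + c_
  frac_s <- if (ns > 0) a / ns else 0
  frac_c <- if (nc > 0) c_ / nc else 0
  expected <- outer(c(pres, n - pres), c(ns, nc)) / n
  if (any(expected < 5) || n < 20) {
    # Fisher branch: upper tail of control presences under fixed margins
    return(stats::phyper(c_ - 1, pres, n - pres, nc, lower.tail = FALSE))
  }
  obs <- matrix(c(a, b, c_, d), 2L, byrow = FALSE)
  exp_m <- outer(c(pres, n - pres), c(ns, nc)) / n
  chi2 <- sum((obs - exp_m)^2 / exp_m)
  t2 <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  if (frac_c > frac_s) t2 / 2 else 1 - t2 / 2
}

#' Batched prevalence-based contaminant classification (criterion ii)
#'
#' Computes the prevalence score separately within each extraction batch
#' (plasma samples vs plasma negative controls of that batch; batches where
#' the ASV occurs in neither are skipped, as are batches without controls),
#' combines the per-batch scores by their minimum, and classifies the ASV
#' as contaminant when the combined score falls strictly below `threshold`.
#' ASVs classified `"real"` pass criterion (ii).
#'
#' @param table an [asv_table()].
#' @param design a `study_design`; `sample_type` separates true samples
#'   from controls.
#' @param batch_var design column defining the batches (default
#'   `"extraction_batch"`).
#' @param threshold classification threshold (default 0.55).
#' @param sample_type,control_type sample-type tokens for true samples and
#'   negative controls (defaults `"plasma"` / `"plasma_denc"`).
#' @param min_count presence threshold (default 1 read).
#' @return A `prevalence_score` data.frame: one row per ASV with per-batch
#'   score columns (`score.<batch>`), `combined`, `classification`.
#' @export
prevalence_score_batched <- function(table, design,
                                     batch_var = "extraction_batch",
                                     threshold = 0.55,
                                     sample_type = "plasma",
                                     control_type = "plasma_denc",
                                     min_count = 1L) {
  design <- align_design(table, design)
  pres <- presence_matrix(table, min_count)
  is_sample <- design$sample_type %in% sample_type
  is_control <- design$sample_type %in% control_type
  batches <- sort(unique(design[[batch_var]][is_sample | is_control]))
  batches <- batches[!is.na(batches)]
  if (!length(batches)) stop("no batches with plasma samples or controls")
  scores <- matrix(NA_real_, nrow(pres), length(batches),
                   dimnames = list(rownames(pres), batches))
  for (b in batches) {
    s_cols <- is_sample & design[[batch_var]] == b
    c_cols <- is_control & design[[batch_var]] == b
    if (!any(c_cols)) {
      warning("batch ", b, " has no negative controls; skipped")
      next
    }
    ps <- rowSums(pres[, s_cols, drop = FALSE])
    pc <- rowSums(pres[, c_cols, drop = FALSE])
    in_batch <- (ps + pc) > 0
    for (g in which(in_batch))
      scores[g, b] <- prevalence_score_single(ps[g], sum(s_cols) - ps[g],
                                              pc[g], sum(c_cols) - pc[g])
  }
  combined <- apply(scores, 1L, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  if (anyNA(combined))
    warning(sum(is.na(combined)), " ASV(s) absent from every scored batch")
  classification <- ifelse(is.na(combined), NA_character_,
                           ifelse(combined < threshold, "contaminant", "real"))
  out <- data.frame(asv_id = rownames(pres), scores, combined = combined,
                    classification = classification,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[seq_along(batches) + 1L] <- paste0("score.", batches)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("prevalence_score", "data.frame")
  out
}
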