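#' PERMANOVA with sequential sums of squares
#'
#' Permutational multivariate analysis of variance on a distance matrix.
#' The Gower-centred inner-product matrix `G = -1/2 C A C` (with `A` the
#' squared distances and `C` the centring matrix) is partitioned by
#' sequential (Type I) projections onto the model terms in the order given;
#' pseudo-F per term is `(SS_term/df_term) / (SS_resid/df_resid)` and the
#' p-value is `(1 + #{permuted F >= observed F}) / (1 + n_perm)`, with sample
#' labels permuted freely (or within `blocks`, see [rma_permanova()]).
#'
#' @param dist a `distance_matrix` (or symmetric matrix with dimnames).
#' @param design a `study_design` or data.frame of per-sample factors, with
#'   a `sample_id` column or rownames matching the distance labels.
#' @param terms character vector of model terms in the order they should
#'   enter the model; interactions as `"a:b"` (entered after main effects).
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param blocks optional factor name: permutations are then restricted to
#'   shuffle samples only within each block.
#' @return A `permanova_result` data.frame: one row per term plus Residual
#'   and Total, columns `df`, `sum_of_squares`, `pseudo_F`, `R2`, `p_value`.
#' @export
permanova <- function(dist, design, terms, n_perm = 999, seed = 1L,
                      blocks = NULL) {
  d <- as.matrix(unclass(dist))
  n <- nrow(d)
  fac <- permanova_factors(d, design)
  for (tm in terms) for (comp in strsplit(tm, ":", fixed = TRUE)[[1L]])
    if (length(unique(fac[[comp]])) < 2L)
      stop("term ", comp, " has zero df (single level)")
  G <- gower_center(d)
  hats <- sequential_hats(fac, terms, n)
  K <- length(terms)
  dfs <- hats$df
  if (any(dfs == 0))
    stop("term(s) with zero df (constant factor?): ",
         paste(terms[dfs == 0], collapse = ", "))
  df_res <- n - 1L - sum(dfs)
  if (df_res <= 0) stop("fewer samples than model df + 1")

  block_f <- if (is.null(blocks)) NULL else {
    if (!blocks %in% names(fac)) stop("unknown blocks factor: ", blocks)
    as.character(fac[[blocks]])
  }

  stat <- function(Gp) {
    tr_prev <- 0
    ss <- numeric(K)
    for (k in seq_len(K)) {
      tr_k <- sum(hats$H[[k]] * Gp)
      ss[k] <- tr_k - tr_prev
      tr_prev <- tr_k
    }
    ss_tot <- sum(diag(Gp))
    ss_res <- ss_tot - tr_prev
    Fv <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, ss_tot = ss_tot, F = Fv)
  }
  obs <- stat(G)

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  exceed <- rep(0L, K)
  for (b in seq_len(n_perm)) {
    p <- permute_labels(n, block_f)
    Fp <- stat(G[p, p])$F
    exceed <- exceed + (Fp >= obs$F - 1e-12)
  }
  pval <- (1 + exceed) / (1 + n_perm)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    sum_of_squares = c(obs$ss, obs$ss_res, obs$ss_tot),
    pseudo_F = c(obs$F, NA, NA),
    R2 = c(obs$ss, obs$ss_res, obs$ss_tot) / obs$ss_tot,
    p_value = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "blocks") <- blocks
  class(out) <- c("permanova_result", "data.frame")
  out
}

permanova_factors <- function(d, design) {
  ids <- rownames(d)
  fac <- as.data.frame(design, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(fac)) {
    miss <- setdiff(ids, fac$sample_id)
    if (length(miss))
      stop("samples missing from design: ", paste(miss, collapse = ", "))
    fac <- fac[match(ids, fac$sample_id), , drop = FALSE]
  } else if (!is.null(rownames(fac))) {
    fac <- fac[ids, , drop = FALSE]
  }
  rownames(fac) <- ids
  fac
}

gower_center <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(A)
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
}

# Cumulative projection (hat) matrices and df increments per term.
sequential_hats <- function(fac, terms, n) {
  H <- vector("list", length(terms))
  df <- integer(length(terms))
  rank_prev <- 1L  # intercept
  for (k in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = "+")))
    X <- stats::model.matrix(fml, data = as.data.frame(lapply(fac, factor)))
    q <- qr(X)
    if (q$rank > n) stop("singular model")
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    H[[k]] <- tcrossprod(Q)
    df[k] <- q$rank - rank_prev
    rank_prev <- q$rank
  }
  list(H = H, df = df)
}

#' Draw one (optionally block-restricted) permutation of sample labels
#'
#' With `blocks = NULL` a free permutation of `1:n`; otherwise indices are
#' shuffled only within each block, so every sample maps to a sample of the
#' same block.
#'
#' @param n number of samples.
#' @param blocks optional character/factor vector of length `n`.
#' @return An integer permutation of `1:n`.
#' @export
permute_labels <- function(n, blocks = NULL) {
  if (is.null(blocks)) return(sample.int(n))
  p <- seq_len(n)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    if (length(idx) > 1L) p[idx] <- idx[sample.int(length(idx))]
  }
  p
}

#' Repeated-measures-aware PERMANOVA
#'
#' Identical statistic to [permanova()], but the null distribution is built
#' from permutations that shuffle sample labels only within each block
#' (typically the subject/patient), so repeated measurements of the same
#' subject are never exchanged across subjects.
#'
#' @inheritParams permanova
#' @param blocks factor name identifying the subject blocks.
#' @return A `permanova_result` (see [permanova()]).
#' @export
rma_permanova <- function(dist, design, terms, blocks, n_perm = 999,
                          seed = 1L) {
  fac <- permanova_factors(as.matrix(unclass(dist)), design)
  if (!blocks %in% names(fac)) stop("unknown blocks factor: ", blocks)
  sizes <- table(fac[[blocks]])
  if (all(sizes == 1L))
    message("all blocks have a single sample: only the identity permutation exists")
  permanova(dist, design, terms, n_perm = n_perm, seed = seed, blocks = blocks)
}

#' Pairwise PERMANOVA between factor levels
#'
#' One two-level test per unordered pair of levels, each on the sub-matrix
#' of samples belonging to those two levels.
#'
#' @inheritParams permanova
#' @param factor_name design factor with >= 2 levels.
#' @return Named list of `permanova_result`, one per level pair
#'   (`"a.vs.b"`).
#' @export
pairwise_permanova <- function(dist, design, factor_name, n_perm = 999,
                               seed = 1L) {
  d <- as.matrix(unclass(dist))
  fac <- permanova_factors(d, design)
  lev <- sort(unique(as.character(fac[[factor_name]])))
  if (length(lev) < 2L) stop("factor has fewer than 2 levels")
  for (l in lev) if (sum(fac[[factor_name]] == l) < 2L)
    stop("level ", l, " has fewer than 2 samples")
  out <- list()
  for (i in seq_len(length(lev) - 1L)) for (j in (i + 1L):length(lev)) {
    keep <- fac[[factor_name]] %in% c(lev[i], lev[j])
    sub <- new_distance_matrix(d[keep, keep, drop = FALSE],
                               rownames(d)[keep])
    out[[paste0(lev[i], ".vs.", lev[j])]] <-
      permanova(sub, fac[keep, , drop = FALSE], factor_name,
                n_perm = n_perm, seed = seed)
  }
  out
}

#' Write a PERMANOVA result as TSV or JSON
#' @param result a `permanova_result`.
#' @param path output path (`.json` writes JSON, anything else TSV).
#' @return `path`, invisibly.
#' @export
write_permanova <- function(result, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      table = as.data.frame(result),
      n_permutations = attr(result, "n_permutations"),
      seed = attr(result, "seed")), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
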