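#' Remove non-target lineages (eukaryota, mitochondria, chloroplast)
#'
#' 16S amplicon tables routinely pick up host mitochondrial and plastid
#' sequences; ASVs whose lineage names any of these at any rank are dropped
#' before analysis.
#'
#' @param table an [asv_table()].
#' @param tax a `taxonomy_table` covering every ASV of `table`.
#' @param patterns character vector of lineage names to remove
#'   (case-insensitive, matched as whole rank names).
#' @return The filtered `asv_table` (possibly with zero rows, with a warning).
#' @export
filter_nontarget_taxa <- function(table, tax,
                                  patterns = c("eukaryota", "mitochondria",
                                               "chloroplast")) {
  miss <- setdiff(asv_ids(table), tax$asv_id)
  if (length(miss))
    stop("missing taxonomy for: ", paste(utils::head(miss, 5L), collapse = ", "))
  tax <- tax[match(asv_ids(table), tax$asv_id), , drop = FALSE]
  ranks <- tolower(as.matrix(as.data.frame(tax)[, TAX_RANKS]))
  hit <- apply(ranks, 1L, function(v) any(v %in% tolower(patterns)))
  if (all(hit)) {
    warning("all ASVs matched non-target lineages; empty table returned")
    out <- unclass(table)[!hit, , drop = FALSE]
    class(out) <- c("asv_table", class(out))
    return(out)
  }
  subset_asv_table(table, keep_asvs = !hit)
}

subset_asv_table <- function(table, keep_asvs = NULL, keep_samples = NULL) {
  m <- unclass(table)
  if (!is.null(keep_asvs)) m <- m[keep_asvs, , drop = FALSE]
  if (!is.null(keep_samples)) m <- m[, keep_samples, drop = FALSE]
  class(m) <- c("asv_table", class(m))
  m
}

#' Merge technical replicates by summing counts
#'
#' PCR or sequencing replicates of the same biological sample are merged by
#' summing all counts; total reads are conserved. The merged sample inherits
#' the metadata of the group's first member and is named after the group key.
#'
#' @param table an [asv_table()].
#' @param design a `study_design` covering all samples.
#' @param key design column whose values group samples to be merged.
#' @return A list with elements `table` (merged `asv_table`) and `design`
#'   (one row per merged sample).
#' @export
merge_technical_replicates <- function(table, design, key) {
  design <- align_design(table, design)
  if (!key %in% names(design)) stop("unknown design column: ", key)
  grp <- as.character(design[[key]])
  if (anyNA(grp)) stop("missing values in grouping column ", key)
  for (g in unique(grp)) {
    st <- unique(design$sample_type[grp == g])
    if (length(st) > 1L)
      stop("group ", g, " mixes sample types: ", paste(st, collapse = ", "))
  }
  groups <- unique(grp)
  m <- unclass(table)
  merged <- vapply(groups, function(g) rowSums(m[, grp == g, drop = FALSE]),
                   numeric(nrow(m)))
  merged <- matrix(merged, nrow = nrow(m),
                   dimnames = list(rownames(m), groups))
  d2 <- design[match(groups, grp), , drop = FALSE]
  d2$sample_id <- groups
  rownames(d2) <- NULL
  class(d2) <- c("study_design", "data.frame")
  list(table = asv_table(merged), design = d2)
}

#' Remove low-abundance ASVs per sample-type stratum
#'
#' Within each sample-type stratum, an ASV is zeroed out of that stratum when
#' its share of the stratum's total reads falls strictly below `floor_pct`
#' percent. ASVs left with zero counts everywhere are dropped. An ASV removed
#' from one stratum is kept in another where it clears the floor.
#'
#' @param table an [asv_table()].
#' @param design a `study_design` covering all samples.
#' @param floor_pct abundance floor in percent units (default 0.01, i.e.
#'   0.01\% of the stratum's reads).
#' @return The filtered `asv_table`.
#' @export
filter_low_abundance <- function(table, design, floor_pct = 0.01) {
  design <- align_design(table, design)
  m <- unclass(table)
  for (st in unique(design$sample_type)) {
    cols <- design$sample_type == st
    tot <- sum(m[, cols, drop = FALSE])
    if (tot == 0) stop("sample type ", st, " has zero total reads")
    pct <- 100 * rowSums(m[, cols, drop = FALSE]) / tot
    m[pct < floor_pct, cols] <- 0
  }
  keep <- rowSums(m) > 0
  if (!any(keep)) {
    warning("all ASVs removed by abundance floor")
    out <- m[keep, , drop = FALSE]
    class(out) <- c("asv_table", class(out))
    return(out)
  }
  asv_table(m[keep, , drop = FALSE])
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (a multivariate
#' hypergeometric draw) down to `depth`. Samples with fewer than `depth`
#' reads are dropped with a warning. The draw for each sample is seeded from
#' `(seed, sample id)` so per-sample results do not depend on column order.
#'
#' @param table an [asv_table()].
#' @param depth target reads per sample (> 0).
#' @param seed integer seed.
#' @return The rarefied `asv_table`; every column sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  m <- unclass(table)
  libs <- colSums(m)
  drop <- libs < depth
  if (any(drop)) {
    warning(sum(drop), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(m)[drop], collapse = ", "))
    m <- m[, !drop, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("no samples at or above depth ", depth)
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- rhyper_multi(m[, j], depth,
                             seed_from(seed, colnames(m)[j]))
  }
  asv_table(out)
}

# Without-replacement subsample of a count vector to size n, by sequential
# hypergeometric draws (equivalent to sampling n reads without replacement).
rhyper_multi <- function(counts, n, seed) {
  total <- sum(counts)
  if (n == total) return(counts)
  out <- numeric(length(counts))
  remaining <- total
  left <- n
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (i in seq_along(counts)) {
    if (left == 0L) break
    ki <- counts[i]
    if (ki == 0) next
    # draws from this ASV ~ Hypergeometric(ki, remaining - ki, left)
    x <- stats::rhyper(1L, ki, remaining - ki, left)
    out[i] <- x
    left <- left - x
    remaining <- remaining - ki
  }
  out
}

# Derive a reproducible sub-seed below 2^31 from a seed and a string tag.
seed_from <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Transform a count table for downstream analysis
#'
#' Supported transforms:
#' \describe{
#'   \item{relative}{column-normalised fractions.}
#'   \item{sqrt}{element-wise square root of relative abundances.}
#'   \item{clr}{centred log-ratio of `counts + offset`:
#'     `ln((x_i + offset) / g(x + offset))` with `g` the per-sample geometric
#'     mean. Each sample's CLR components sum to zero.}
#'   \item{log_cpm}{`log2(1e6 * (x_i + prior) / (libsize + 2 * prior))`.}
#' }
#'
#' @param table an [asv_table()] (or non-negative matrix).
#' @param kind one of `"relative"`, `"sqrt"`, `"clr"`, `"log_cpm"`.
#' @param offset positive pseudo-count added before the CLR (default 1).
#' @param prior_cpm prior count for `log_cpm` (default 0.5).
#' @return A real-valued matrix with the dimensions and dimnames of `table`.
#' @export
transform_counts <- function(table, kind = c("relative", "sqrt", "clr", "log_cpm"),
                             offset = 1, prior_cpm = 0.5) {
  kind <- match.arg(kind)
  m <- unclass(table)
  libs <- colSums(m)
  if (kind %in% c("relative", "sqrt") && any(libs == 0))
    stop("zero library size")
  switch(kind,
    relative = sweep(m, 2L, libs, "/"),
    sqrt = sqrt(sweep(m, 2L, libs, "/")),
    clr = {
      if (offset <= 0) stop("clr offset must be positive")
      lx <- log(m + offset)
      sweep(lx, 2L, colMeans(lx), "-")
    },
    log_cpm = {
      if (any(libs == 0)) stop("zero library size")
      log2(sweep(m + prior_cpm, 2L, libs + 2 * prior_cpm, "/") * 1e6)
    })
}
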