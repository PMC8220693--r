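#' Observed ASV richness
#' @param sample_counts non-negative count vector.
#' @return Number of strictly positive entries.
#' @export
richness <- function(sample_counts) sum(sample_counts > 0)

#' Inverse Simpson diversity index
#'
#' `1 / sum(p_i^2)` with `p_i` the relative abundances. Equals the number of
#' taxa for a perfectly even community and 1 for a single taxon.
#'
#' @param sample_counts count vector with at least one positive entry.
#' @return The inverse Simpson index.
#' @export
inverse_simpson <- function(sample_counts) {
  tot <- sum(sample_counts)
  if (tot <= 0) stop("all-zero sample")
  p <- sample_counts / tot
  1 / sum(p^2)
}

#' Alpha diversity per sample
#' @param table an [asv_table()] (counts or transformed non-negative matrix).
#' @return data.frame with `sample_id`, `richness`, `inverse_simpson`.
#' @export
alpha_diversity <- function(table) {
  m <- unclass(table)
  data.frame(sample_id = colnames(m),
             richness = apply(m, 2L, richness),
             inverse_simpson = apply(m, 2L, inverse_simpson),
             row.names = NULL, stringsAsFactors = FALSE)
}

new_distance_matrix <- function(d, ids) {
  dimnames(d) <- list(ids, ids)
  class(d) <- c("distance_matrix", class(d))
  d
}

#' Bray-Curtis dissimilarity between all pairs of samples
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`. In the standard workflow for
#' community-structure comparisons the input is rarefied and square-root
#' transformed first (see [transform_counts()]); that is the caller's choice,
#' not hard-wired here.
#'
#' @param table an [asv_table()] or non-negative numeric matrix
#'   (features x samples).
#' @return A symmetric `distance_matrix` with entries in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  if (any(m < 0)) stop("negative input")
  n <- ncol(m)
  if (any(colSums(m) == 0)) stop("all-zero sample")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    num <- sum(abs(m[, i] - m[, j]))
    den <- sum(m[, i] + m[, j])
    d[i, j] <- d[j, i] <- num / den
  }
  new_distance_matrix(d, colnames(m))
}

#' Aitchison distance between all pairs of samples
#'
#' Euclidean distance between per-sample CLR vectors of `counts + offset`.
#' By convention the input is the non-rarefied, non-transformed count table.
#'
#' @param table an [asv_table()].
#' @param offset positive pseudo-count (default 1).
#' @return A symmetric `distance_matrix`.
#' @export
aitchison <- function(table, offset = 1) {
  z <- transform_counts(table, "clr", offset = offset)
  d <- as.matrix(stats::dist(t(z)))
  new_distance_matrix(unname(d), colnames(z))
}

#' Write / read a distance matrix as square TSV
#' @param dist a `distance_matrix`.
#' @param path file path.
#' @return `path` (write) or a `distance_matrix` (read).
#' @export
write_distance <- function(dist, path) {
  df <- data.frame(sample_id = rownames(dist), unclass(dist),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance
#' @export
read_distance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix not symmetric")
  new_distance_matrix(unname(m), df[[1L]])
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Agglomerates samples by unweighted average linkage and returns a rooted
#' ultrametric tree (root-to-leaf distances all equal; merge heights are
#' halved into branch lengths). Ties in the minimal inter-cluster distance
#' are broken by the lexicographic order of the smaller cluster's first leaf
#' id so results are deterministic.
#'
#' @param dist a `distance_matrix` with >= 2 samples.
#' @return An [ape::as.phylo()] tree (class `phylo`) with branch lengths.
#' @export
upgma <- function(dist) {
  d <- unclass(dist)
  if (anyNA(d)) stop("NaN in distances")
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 samples")
  ids <- rownames(d)
  # active clusters: list of leaf index vectors; heights of current nodes
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  cl_members <- as.list(seq_len(n))      # leaf indices per active cluster
  cl_node <- -seq_len(n)                 # hclust convention: negative = leaf
  cl_first <- ids                        # first (lexicographically) leaf id
  D <- d
  active <- rep(TRUE, n + 0L)
  Dm <- D
  diag(Dm) <- Inf
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- Dm[idx, idx, drop = FALSE]
    mn <- min(sub)
    cand <- which(sub == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break: smaller cluster's first leaf id, then the other's
    keyA <- pmin(cl_first[idx[cand[, 1L]]], cl_first[idx[cand[, 2L]]])
    keyB <- pmax(cl_first[idx[cand[, 1L]]], cl_first[idx[cand[, 2L]]])
    ord <- order(keyA, keyB)[1L]
    a <- idx[cand[ord, 1L]]; b <- idx[cand[ord, 2L]]
    if (cl_first[b] < cl_first[a]) { tmp <- a; a <- b; b <- tmp }
    merges[step, ] <- c(cl_node[a], cl_node[b])
    heights[step] <- mn
    na <- length(cl_members[[a]]); nb <- length(cl_members[[b]])
    # unweighted average linkage update
    newd <- (na * Dm[a, idx] + nb * Dm[b, idx]) / (na + nb)
    Dm[a, idx] <- newd; Dm[idx, a] <- newd
    Dm[a, a] <- Inf
    active[b] <- FALSE
    cl_members[[a]] <- c(cl_members[[a]], cl_members[[b]])
    cl_node[a] <- step
    cl_first[a] <- min(cl_first[a], cl_first[b])
  }
  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(merges[node, 1L]), leaf_order(merges[node, 2L]))
  }
  hc <- list(merge = merges, height = heights,
             order = leaf_order(n - 1L), labels = ids, method = "average")
  class(hc) <- "hclust"
  ape::as.phylo(hc)
}

#' Root-to-leaf path lengths of a tree
#' @param tree a `phylo` tree with branch lengths.
#' @return Named numeric vector of root-to-tip distances.
#' @export
root_to_tip <- function(tree) {
  nt <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  stats::setNames(depths[seq_len(nt)], tree$tip.label)
}
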