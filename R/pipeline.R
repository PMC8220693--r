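#' Default pipeline configuration
#'
#' @param floor_pct low-abundance floor in percent (default 0.01).
#' @param fdr_cut criterion (i) FDR threshold (default 0.05).
#' @param prevalence_threshold criterion (ii) score threshold (default 0.55).
#' @param kappa_min,kappa_alpha criterion (iii) thresholds (0.4 / 0.05).
#' @param include_dencs_in_da include negative controls in the criterion (i)
#'   model (default FALSE: the criterion concerns abundance differences
#'   among plasma samples).
#' @param criteria which criteria to apply (subset of `c("i","ii","iii","iv")`;
#'   mainly for ablation studies).
#' @return A named list of settings.
#' @export
pipeline_config <- function(floor_pct = 0.01, fdr_cut = 0.05,
                            prevalence_threshold = 0.55,
                            kappa_min = 0.4, kappa_alpha = 0.05,
                            include_dencs_in_da = FALSE,
                            criteria = c("i", "ii", "iii", "iv")) {
  list(floor_pct = floor_pct, fdr_cut = fdr_cut,
       prevalence_threshold = prevalence_threshold,
       kappa_min = kappa_min, kappa_alpha = kappa_alpha,
       include_dencs_in_da = include_dencs_in_da, criteria = criteria)
}

#' Identify high-confidence plasma ASVs (full decontamination pipeline)
#'
#' Runs preprocessing (non-target lineage removal, per-sample-type abundance
#' floor), then evaluates each candidate plasma ASV against four independent
#' criteria: (i) no batch effect across technical variables, (ii) higher
#' prevalence in plasma than in negative controls (combined across batches
#' by minimum score), (iii) agreement of detection between replicate
#' extractions of the same patients where such a batch pair exists, and
#' (iv) the blocklist / commensal-evidence taxonomy filter. Criteria are
#' evaluated independently and intersected, so the tally can report each
#' one separately and in combination.
#'
#' @param table an [asv_table()].
#' @param design a `study_design` with plasma samples and DENCs.
#' @param taxonomy a `taxonomy_table` covering all ASVs.
#' @param lists an `evidence_lists` object (criterion iv); `NULL` skips iv.
#' @param config see [pipeline_config()].
#' @param out_dir optional directory: every intermediate is written there.
#' @return A `decontam_report` list: `report` (per-ASV data.frame),
#'   `final_list`, `tally`, plus the per-criterion result objects.
#' @export
identify_high_confidence_asvs <- function(table, design, taxonomy,
                                          lists = NULL,
                                          config = pipeline_config(),
                                          out_dir = NULL) {
  design <- align_design(table, design)
  if (!any(design$sample_type == "plasma")) stop("no plasma samples in design")
  if (!any(design$sample_type == "plasma_denc"))
    stop("criterion (ii) requires plasma DENC samples; none in design")
  table <- filter_nontarget_taxa(table, taxonomy)
  table <- filter_low_abundance(table, design, floor_pct = config$floor_pct)
  design <- align_design(table, design)

  keep <- design$sample_type %in% c("plasma", "plasma_denc")
  tbl <- subset_asv_table(table, keep_samples = keep)
  dsn <- design[keep, , drop = FALSE]
  plasma <- dsn$sample_type == "plasma"
  rel <- transform_counts(tbl, "relative")
  mean_relabund <- rowMeans(rel[, plasma, drop = FALSE])
  candidates <- asv_ids(tbl)[rowSums(unclass(tbl)[, plasma, drop = FALSE]) > 0]
  abundance_class <- cut(100 * mean_relabund, c(-Inf, 0.1, 1, Inf),
                         labels = c("low", "medium", "high"))
  names(abundance_class) <- asv_ids(tbl)

  # criterion (i): batch differential abundance
  da_types <- if (isTRUE(config$include_dencs_in_da))
    c("plasma", "plasma_denc") else "plasma"
  da <- NULL
  pass_i <- stats::setNames(rep(TRUE, length(candidates)), candidates)
  if ("i" %in% config$criteria) {
    da <- run_batch_da(tbl, dsn, fdr_cut = config$fdr_cut,
                       sample_types = da_types)
    seen <- intersect(candidates, names(da$pass))
    pass_i[seen] <- da$pass[seen]
  }

  # criterion (ii): prevalence vs negative controls
  prev <- NULL
  pass_ii <- stats::setNames(rep(TRUE, length(candidates)), candidates)
  if ("ii" %in% config$criteria) {
    prev <- prevalence_score_batched(tbl, dsn,
                                     threshold = config$prevalence_threshold)
    cls <- stats::setNames(prev$classification, prev$asv_id)[candidates]
    pass_ii <- !is.na(cls) & cls == "real"
  }

  # criterion (iii): replicate-extraction agreement, where a pair exists
  kap <- NULL
  pair <- replicate_batch_pair(dsn)
  applicable_iii <- stats::setNames(rep(FALSE, length(candidates)), candidates)
  pass_iii <- stats::setNames(rep(TRUE, length(candidates)), candidates)
  if ("iii" %in% config$criteria && !is.null(pair)) {
    kap <- replicate_agreement_filter(tbl, dsn, pair,
                                      kappa_min = config$kappa_min,
                                      alpha = config$kappa_alpha)
    app <- stats::setNames(kap$applicable, kap$asv_id)[candidates]
    app[is.na(app)] <- FALSE
    applicable_iii <- app
    kp <- stats::setNames(kap$pass, kap$asv_id)[candidates]
    pass_iii <- ifelse(applicable_iii, kp, TRUE)
  } else if ("iii" %in% config$criteria) {
    message("no replicate batch pair in design; criterion (iii) skipped")
  }

  # criterion (iv): taxonomy evidence filter
  cats <- NULL
  pass_iv <- stats::setNames(rep(TRUE, length(candidates)), candidates)
  category <- stats::setNames(rep(NA_character_, length(candidates)), candidates)
  if ("iv" %in% config$criteria && !is.null(lists)) {
    cats <- assign_categories(taxonomy[taxonomy$asv_id %in% candidates, ],
                              lists)
    category <- stats::setNames(cats$category, cats$asv_id)[candidates]
    pass_iv <- candidates %in% criterion_iv_filter(candidates, cats)
    names(pass_iv) <- candidates
  }

  final <- pass_i & pass_ii & pass_iii & pass_iv
  report <- data.frame(
    asv_id = candidates,
    mean_relabund = mean_relabund[candidates],
    abundance_class = as.character(abundance_class[candidates]),
    criterion_i_pass = unname(pass_i),
    criterion_ii_pass = unname(pass_ii),
    criterion_iii_applicable = unname(applicable_iii),
    criterion_iii_pass = unname(pass_iii),
    criterion_iv_category = unname(category),
    criterion_iv_pass = unname(pass_iv),
    final_high_confidence = unname(final),
    stringsAsFactors = FALSE)
  if (!is.null(prev)) {
    report <- merge(report, as.data.frame(prev), by = "asv_id", sort = FALSE)
  }
  if (!is.null(kap)) {
    kk <- as.data.frame(kap)[, c("asv_id", "kappa", "p")]
    names(kk) <- c("asv_id", "kappa", "kappa_p")
    report <- merge(report, kk, by = "asv_id", sort = FALSE)
  }
  rownames(report) <- NULL
  out <- list(report = report, final_list = candidates[final],
              batch_da = da, prevalence = prev, kappa = kap,
              categories = cats, config = config,
              tally = NULL)
  out$tally <- tally_report(out)
  class(out) <- "decontam_report"
  if (!is.null(out_dir)) write_decontam_report(out, out_dir)
  out
}

# Find the batch pair linked by replicate groups, if any.
replicate_batch_pair <- function(design) {
  rg <- design$replicate_group
  if (all(is.na(rg))) return(NULL)
  b <- sort(unique(design$extraction_batch[!is.na(rg)]))
  if (length(b) != 2L) return(NULL)
  b
}

#' Tally of ASVs meeting each criterion, by abundance class
#'
#' Reproduces the structure of a criterion-by-abundance-class summary table:
#' one row per criterion (and per technical variable / batch where
#' applicable), columns for all / low / medium / high abundance ASVs, each
#' count with its percentage of the column total.
#'
#' @param result a `decontam_report` from [identify_high_confidence_asvs()].
#' @return data.frame of counts with attribute `"percent"` (same shape).
#' @export
tally_report <- function(result) {
  rep_ <- result$report
  if (!nrow(rep_)) {
    z <- data.frame(row = "Total", all = 0, low = 0, medium = 0, high = 0)
    attr(z, "percent") <- z
    return(z)
  }
  cls <- factor(rep_$abundance_class, levels = c("low", "medium", "high"))
  count_row <- function(mask) {
    c(all = sum(mask),
      low = sum(mask & cls == "low"),
      medium = sum(mask & cls == "medium"),
      high = sum(mask & cls == "high"))
  }
  rows <- list(Total = count_row(rep(TRUE, nrow(rep_))))
  da <- result$batch_da
  if (!is.null(da) && length(da$flags$fdr)) {
    for (v in names(da$flags$fdr)) {
      fdr <- da$flags$fdr[[v]]
      ok <- !apply(fdr <= result$config$fdr_cut, 1L, any)
      pass_v <- rep_$asv_id %in% rownames(fdr)[ok] |
        !rep_$asv_id %in% rownames(fdr)
      rows[[paste0("No batch effect by ", v)]] <- count_row(pass_v)
    }
  }
  rows[["No batch effect by any technical variable"]] <-
    count_row(rep_$criterion_i_pass)
  prev <- result$prevalence
  if (!is.null(prev)) {
    scol <- grep("^score\\.", names(prev), value = TRUE)
    for (s in scol) {
      v <- stats::setNames(prev[[s]], prev$asv_id)[rep_$asv_id]
      thr <- attr(prev, "threshold")
      rows[[paste0("Non-contaminant in batch ", sub("^score\\.", "", s))]] <-
        count_row(!is.na(v) & v >= thr)
    }
  }
  rows[["Non-contaminant across batches"]] <- count_row(rep_$criterion_ii_pass)
  rows[["Replicate detection agreement"]] <-
    count_row(rep_$criterion_iii_applicable & rep_$criterion_iii_pass)
  rows[["Combined bioinformatics criteria"]] <-
    count_row(rep_$criterion_i_pass & rep_$criterion_ii_pass &
                rep_$criterion_iii_pass)
  rows[["Final list after evidence filter"]] <-
    count_row(rep_$final_high_confidence)
  counts <- as.data.frame(do.call(rbind, rows))
  counts <- cbind(row = names(rows), counts)
  rownames(counts) <- NULL
  tot <- unlist(rows[["Total"]])
  pct <- counts
  for (j in 2:5) pct[[j]] <- if (tot[j - 1L] > 0)
    round(100 * counts[[j]] / tot[j - 1L], 2) else rep(0, nrow(counts))
  attr(counts, "percent") <- pct
  counts
}

#' Write a decontamination report and its intermediates to a directory
#'
#' @param result a `decontam_report`.
#' @param out_dir output directory (created if absent).
#' @param seed optional seed recorded in the run metadata.
#' @return `out_dir`, invisibly.
#' @export
write_decontam_report <- function(result, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(result$report, "report.tsv")
  writeLines(result$final_list, file.path(out_dir, "final_list.txt"))
  wt(result$tally, "tally.tsv")
  wt(attr(result$tally, "percent"), "tally_percent.tsv")
  if (!is.null(result$batch_da) && !is.null(result$batch_da$flags$table) &&
      nrow(result$batch_da$flags$table))
    wt(result$batch_da$flags$table, "criterion_i_fits.tsv")
  if (!is.null(result$prevalence))
    wt(as.data.frame(result$prevalence), "criterion_ii_prevalence.tsv")
  if (!is.null(result$kappa))
    wt(as.data.frame(result$kappa), "criterion_iii_kappa.tsv")
  if (!is.null(result$categories))
    wt(result$categories, "criterion_iv_categories.tsv")
  meta <- list(package = "cfmflow",
               version = as.character(utils::packageVersion("cfmflow")),
               r_version = R.version.string,
               seed = seed,
               config = result$config,
               n_candidates = nrow(result$report),
               n_final = length(result$final_list),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
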