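SAMPLE_TYPES <- c("plasma", "stool", "saliva",
                  "plasma_denc", "stool_denc", "saliva_denc",
                  "ntc", "mock")

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct an ASV count table
#'
#' An `asv_table` is a non-negative integer matrix of sequencing read counts
#' with ASVs as rows and samples as columns. Row and column names carry the
#' ASV and sample identifiers and must be unique.
#'
#' @param counts numeric matrix of non-negative integers with unique,
#'   non-empty rownames (ASV ids) and colnames (sample ids).
#' @return An object of class `asv_table` (an integer matrix).
#' @export
asv_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no ASVs")
  if (ncol(counts) == 0L) stop("no samples")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate ASV ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (!is.numeric(counts)) stop("non-numeric counts")
  if (anyNA(counts)) stop("missing counts")
  if (any(counts < 0)) stop("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("non-integer counts")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  class(counts) <- c("asv_table", class(counts))
  counts
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d ASVs x %d samples, %s total reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' ASV identifiers of a count table
#' @param table an `asv_table`.
#' @return Character vector of ASV ids.
#' @export
asv_ids <- function(table) rownames(table)

#' Sample identifiers of a count table
#' @param table an `asv_table`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(table) colnames(table)

#' Read an ASV count table from TSV or BIOM
#'
#' TSV dialect: first column holds ASV ids, header row holds sample ids.
#' BIOM support targets the v1 (JSON) dialect via the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`; `"auto"` guesses from the extension.
#' @return An [asv_table()].
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(asv_table(m))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no ASVs")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- ids
  asv_table(m)
}

#' Write an ASV count table to TSV or BIOM
#'
#' @param table an `asv_table`.
#' @param path output file path.
#' @param format `"tsv"` or `"biom"`; `"auto"` guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    m <- unclass(table)
    biomformat::write_biom(biomformat::make_biom(m), path)
  } else {
    df <- data.frame(asv_id = rownames(table), unclass(table),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a study design table
#'
#' Per-sample metadata: sample type, patient, sequencing run, DNA-extraction
#' batch (DEB), extraction day and replicate group. Validates that extraction
#' days are nested within batches, batches within runs, and that a replicate
#' group spans one patient and one sample type across two or more batches.
#'
#' @param df data.frame with columns `sample_id`, `sample_type` and optional
#'   `patient_id`, `sequencing_run`, `extraction_batch`, `extraction_day`,
#'   `replicate_group`.
#' @return A validated `study_design` data.frame.
#' @export
study_design <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "sample_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing design columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
  bad <- setdiff(unique(df$sample_type), SAMPLE_TYPES)
  if (length(bad))
    stop("unknown sample_type: ", paste(bad, collapse = ", "))
  for (col in c("patient_id", "sequencing_run", "extraction_batch",
                "extraction_day", "replicate_group"))
    if (!col %in% names(df)) df[[col]] <- NA_character_ else
      df[[col]] <- as.character(df[[col]])
  check_nesting <- function(inner, outer, what) {
    ok <- !is.na(df[[inner]]) & !is.na(df[[outer]])
    if (!any(ok)) return(invisible())
    tab <- unique(df[ok, c(inner, outer)])
    dup <- tab[[inner]][duplicated(tab[[inner]])]
    if (length(dup))
      stop("nesting violation: ", inner, " ", dup[1L],
           " appears in more than one ", what)
  }
  check_nesting("extraction_day", "extraction_batch", "extraction_batch")
  check_nesting("extraction_batch", "sequencing_run", "sequencing_run")
  rg <- df$replicate_group
  for (g in unique(rg[!is.na(rg)])) {
    sub <- df[!is.na(rg) & rg == g, ]
    if (length(unique(sub$patient_id)) > 1L)
      stop("replicate_group ", g, " spans more than one patient")
    if (length(unique(sub$sample_type)) > 1L)
      stop("replicate_group ", g, " spans more than one sample_type")
    if (length(unique(sub$extraction_batch)) < 2L)
      stop("replicate_group ", g, " does not span >=2 extraction batches")
  }
  class(df) <- c("study_design", "data.frame")
  df
}

#' Read a study design from TSV
#'
#' @param path TSV file with columns `sample_id`, `sample_type` and optional
#'   factor columns (`patient_id`, `sequencing_run`, `extraction_batch`,
#'   `extraction_day`, `replicate_group`).
#' @return A validated `study_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  study_design(df)
}

#' Write a study design to TSV
#' @param design a `study_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align a design to a count table
#'
#' Checks that every sample of `table` has exactly one design row and returns
#' the design reordered to the table's sample order.
#'
#' @param table an `asv_table`.
#' @param design a `study_design`.
#' @return The reordered `study_design`.
#' @export
align_design <- function(table, design) {
  miss <- setdiff(sample_ids(table), design$sample_id)
  if (length(miss))
    stop("samples missing from design: ", paste(miss, collapse = ", "))
  out <- design[match(sample_ids(table), design$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("study_design", "data.frame")
  out
}

#' Construct a taxonomy table
#'
#' One row per ASV with ordered lineage ranks (domain through genus). Empty
#' ranks may only trail non-empty ranks.
#'
#' @param df data.frame with column `asv_id`, rank columns from
#'   `c("domain","phylum","class","order","family","genus")` (missing ranks
#'   are added empty) and optional `confidence` in \[0, 1\].
#' @return A `taxonomy_table` data.frame.
#' @export
taxonomy_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"asv_id" %in% names(df)) stop("taxonomy requires an asv_id column")
  df$asv_id <- as.character(df$asv_id)
  if (anyDuplicated(df$asv_id)) stop("duplicate asv_id in taxonomy")
  for (r in TAX_RANKS) {
    if (!r %in% names(df)) df[[r]] <- ""
    df[[r]] <- as.character(df[[r]])
    df[[r]][is.na(df[[r]])] <- ""
  }
  ranks <- as.matrix(df[, TAX_RANKS])
  filled <- ranks != ""
  for (i in seq_len(nrow(filled))) {
    w <- which(filled[i, ])
    if (length(w) && any(!filled[i, seq_len(max(w))]))
      stop("taxonomy for ", df$asv_id[i], " has an empty rank before a named one")
  }
  if (!"confidence" %in% names(df)) df$confidence <- NA_real_
  df <- df[, c("asv_id", TAX_RANKS, "confidence")]
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Read a taxonomy table from TSV
#'
#' Accepts the QIIME-style layout (`Feature ID`, `Taxon` with
#' semicolon-delimited ranks and optional rank prefixes such as `g__`, and
#' `Confidence`) or an already-split layout with one column per rank.
#'
#' @param path TSV file path.
#' @return A `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  if (any(nm %in% c("taxon", "taxonomy"))) {
    idcol <- which(nm %in% c("feature id", "feature_id", "asv_id", "otu id"))[1L]
    taxcol <- which(nm %in% c("taxon", "taxonomy"))[1L]
    if (is.na(idcol)) idcol <- 1L
    lineages <- strsplit(as.character(df[[taxcol]]), ";")
    ranks <- t(vapply(lineages, function(v) {
      v <- trimws(v)
      v <- sub("^[a-z]__", "", v)  # strip QIIME rank prefixes
      length(v) <- length(TAX_RANKS)
      v[is.na(v)] <- ""
      v
    }, character(length(TAX_RANKS))))
    colnames(ranks) <- TAX_RANKS
    out <- data.frame(asv_id = as.character(df[[idcol]]), ranks,
                      stringsAsFactors = FALSE)
    conf <- which(nm == "confidence")[1L]
    if (!is.na(conf)) out$confidence <- as.numeric(df[[conf]])
    return(taxonomy_table(out))
  }
  names(df) <- nm
  taxonomy_table(df)
}

#' Write a taxonomy table to TSV (QIIME-style)
#' @param tax a `taxonomy_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  ranks <- as.matrix(as.data.frame(tax)[, TAX_RANKS])
  lineage <- apply(ranks, 1L, function(v) paste(v[v != ""], collapse = ";"))
  out <- data.frame(`Feature ID` = tax$asv_id, Taxon = lineage,
                    Confidence = tax$confidence, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
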