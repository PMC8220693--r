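#' Read contaminant-blocklist and commensal-evidence lists
#'
#' Both lists are TSV with columns `name`, `rank` (genus or family) and an
#' optional free-text `source` citation. The blocklist names taxa commonly
#' found in laboratory reagents; the evidence list names taxa with published
#' support as human commensals or pathogens in high-biomass microbiomes.
#'
#' @param blocklist_path,evidence_path TSV file paths.
#' @return An `evidence_lists` list with `blocklist` and
#'   `commensal_evidence` data.frames.
#' @export
read_evidence_lists <- function(blocklist_path, evidence_path) {
  read_one <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("name", "rank") %in% names(df)))
      stop("evidence list ", path, " needs columns name, rank")
    if (any(!nzchar(df$name))) stop("empty taxon name in ", path)
    bad <- setdiff(unique(tolower(df$rank)), TAX_RANKS)
    if (length(bad)) stop("unknown rank in ", path, ": ",
                          paste(bad, collapse = ", "))
    if (!"source" %in% names(df)) df$source <- ""
    df$rank <- tolower(df$rank)
    df[, c("name", "rank", "source")]
  }
  out <- list(blocklist = read_one(blocklist_path),
              commensal_evidence = read_one(evidence_path))
  class(out) <- "evidence_lists"
  out
}

#' Build evidence lists from data frames
#' @param blocklist,commensal_evidence data.frames with `name`, `rank`
#'   (and optional `source`) columns.
#' @return An `evidence_lists` object.
#' @export
evidence_lists <- function(blocklist, commensal_evidence) {
  fix <- function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (!"source" %in% names(df)) df$source <- ""
    df$rank <- tolower(df$rank)
    df
  }
  out <- list(blocklist = fix(blocklist),
              commensal_evidence = fix(commensal_evidence))
  class(out) <- "evidence_lists"
  out
}

normalise_taxon <- function(x) {
  x <- tolower(trimws(x))
  gsub("^\\[|\\]$", "", x)  # bracketed synonym convention
}

#' Consensus of two taxonomic classifications
#'
#' Per ASV, the consensus lineage is the deepest prefix of ranks on which
#' both classifiers agree (case-insensitive, bracketed synonyms normalised);
#' the first disagreement truncates the lineage there.
#'
#' @param lineage_a,lineage_b `taxonomy_table`s over the same ASV set.
#' @return A `taxonomy_table` of consensus lineages.
#' @export
consensus_taxonomy <- function(lineage_a, lineage_b) {
  if (!setequal(lineage_a$asv_id, lineage_b$asv_id))
    stop("classifications cover different ASV sets")
  lineage_b <- lineage_b[match(lineage_a$asv_id, lineage_b$asv_id), ]
  ra <- as.matrix(as.data.frame(lineage_a)[, TAX_RANKS])
  rb <- as.matrix(as.data.frame(lineage_b)[, TAX_RANKS])
  agree <- matrix(normalise_taxon(ra) == normalise_taxon(rb) & ra != "",
                  nrow(ra))
  out <- ra
  for (i in seq_len(nrow(ra))) {
    depth <- match(FALSE, agree[i, ], nomatch = length(TAX_RANKS) + 1L) - 1L
    if (depth < length(TAX_RANKS)) out[i, (depth + 1L):length(TAX_RANKS)] <- ""
  }
  df <- data.frame(asv_id = lineage_a$asv_id, out, stringsAsFactors = FALSE)
  colnames(df) <- c("asv_id", TAX_RANKS)
  taxonomy_table(df)
}

#' Evidence category of one lineage (criterion iv)
#'
#' Crosses contaminant-blocklist membership with commensal/pathogen evidence
#' status into six mutually exclusive categories. Matching is exact on
#' normalised names, at genus first then family. Lineages resolvable only
#' above family rank are "uncharacterised" (potentially novel members, kept).
#' The discard rule removes `"likely contaminant"` (blocklisted, no
#' evidence) and `"no evidence"` (classifiable, matching neither list).
#'
#' @param lineage named character vector or one-row lineage with ranks
#'   domain..genus.
#' @param lists an `evidence_lists` object.
#' @return List with `blocklist_hit`, `evidence_hit`, `category`,
#'   `retained`.
#' @export
assign_category <- function(lineage, lists) {
  lin <- lineage[TAX_RANKS]
  lin[is.na(lin)] <- ""
  usable <- any(nzchar(lin[c("family", "genus")]))
  match_list <- function(df) {
    hit <- FALSE
    for (r in c("genus", "family")) {
      nm <- normalise_taxon(lin[[r]])
      if (nzchar(nm) && any(df$rank == r & normalise_taxon(df$name) == nm))
        hit <- TRUE
    }
    hit
  }
  block <- match_list(lists$blocklist)
  evid <- match_list(lists$commensal_evidence)
  category <- if (block && evid) "blocklisted with commensal evidence"
    else if (block && !usable) "blocklisted, uncharacterised"
    else if (block) "likely contaminant"
    else if (evid) "commensal or pathogen evidence"
    else if (!usable) "uncharacterised"
    else "no evidence"
  retained <- !category %in% c("likely contaminant", "no evidence")
  list(blocklist_hit = block, evidence_hit = evid, category = category,
       retained = retained)
}

#' Categorise a set of ASVs against the evidence lists
#'
#' @param tax a `taxonomy_table` (typically a [consensus_taxonomy()]).
#' @param lists an `evidence_lists` object.
#' @return data.frame: `asv_id`, `lineage`, `blocklist_hit`, `evidence_hit`,
#'   `category`, `retained`.
#' @export
assign_categories <- function(tax, lists) {
  ranks <- as.data.frame(tax)[, TAX_RANKS]
  res <- lapply(seq_len(nrow(tax)), function(i)
    assign_category(unlist(ranks[i, ]), lists))
  lineage <- apply(as.matrix(ranks), 1L,
                   function(v) paste(v[nzchar(v)], collapse = ";"))
  data.frame(asv_id = tax$asv_id,
             lineage = unname(lineage),
             blocklist_hit = vapply(res, `[[`, logical(1L), "blocklist_hit"),
             evidence_hit = vapply(res, `[[`, logical(1L), "evidence_hit"),
             category = vapply(res, `[[`, character(1L), "category"),
             retained = vapply(res, `[[`, logical(1L), "retained"),
             stringsAsFactors = FALSE)
}

#' Apply the criterion (iv) discard rule
#'
#' Drops ASVs in the discard categories, preserving input order.
#'
#' @param asvs character vector of candidate ASV ids.
#' @param categories output of [assign_categories()].
#' @return The retained ASV ids, in input order.
#' @export
criterion_iv_filter <- function(asvs, categories) {
  miss <- setdiff(asvs, categories$asv_id)
  if (length(miss)) stop("uncategorised ASVs: ", paste(miss, collapse = ", "))
  keep <- categories$retained[match(asvs, categories$asv_id)]
  asvs[keep]
}
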