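#' Default configuration for the synthetic cfmDNA cohort
#'
#' The default cohort mirrors the study structure the framework assumes:
#' five DNA-extraction batches of 12 plasma samples and 8 DENCs each, the
#' second batch a replicate extraction of the first batch's patients, two
#' sequencing runs (batches A/B and C/D/E) and two extraction days per
#' batch; 200 reagent contaminants (120 shared across batches with
#' per-batch log-normal abundance multipliers, 80 batch-specific) and 20
#' planted true plasma ASVs at 0.1--1\% relative abundance present in half
#' the patients and never in DENCs; log-normal sequencing depth.
#'
#' @param n_true_asvs number of planted true-signal ASVs.
#' @param n_contaminant_asvs_shared contaminants present in every batch.
#' @param n_contaminant_asvs_batch_specific contaminants confined to one
#'   batch (split evenly across batches).
#' @param n_batches number of extraction batches (>= 1; batch 2 replicates
#'   batch 1 when `replicate_pair` is TRUE).
#' @param n_samples_per_batch plasma samples per batch.
#' @param n_dencs_per_batch negative controls per batch.
#' @param replicate_pair should batch 2 re-extract batch 1's patients?
#' @param true_prevalence fraction of patients carrying each true ASV.
#' @param true_relabund_range relative-abundance range for true ASVs.
#' @param detection_dropout probability a carrier's replicate re-extraction
#'   misses a true ASV.
#' @param contaminant_plasma_dropout probability that a given contaminant is
#'   suppressed below detectability in a given plasma extraction. True
#'   samples carry genuine DNA that competes with trace reagent DNA during
#'   amplification, so reagent contaminants are detected less consistently
#'   in samples than in pure-water DENCs; this asymmetry is what
#'   prevalence-based contaminant scoring exploits.
#' @param batch_effect_sigma log-sd of the per-batch abundance multipliers
#'   on shared contaminants.
#' @param depth_lognormal `c(meanlog, sdlog)` of reads per sample.
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_true_asvs = 20,
                       n_contaminant_asvs_shared = 120,
                       n_contaminant_asvs_batch_specific = 80,
                       n_batches = 5,
                       n_samples_per_batch = 12,
                       n_dencs_per_batch = 8,
                       replicate_pair = TRUE,
                       true_prevalence = 0.5,
                       true_relabund_range = c(0.001, 0.01),
                       detection_dropout = 0.1,
                       contaminant_plasma_dropout = 0.3,
                       batch_effect_sigma = 1,
                       depth_lognormal = c(log(4e4), 0.35),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$true_prevalence >= 0, cfg$true_prevalence <= 1,
            cfg$detection_dropout >= 0, cfg$detection_dropout <= 1,
            cfg$n_batches >= 1)
  if (cfg$replicate_pair && cfg$n_batches < 2)
    stop("replicate pair requires >= 2 batches")
  class(cfg) <- "sim_config"
  cfg
}

# Taxon name pools used to label simulated ASVs so that the blocklist and
# evidence matching of criterion (iv) is exercisable.
POOL_BLOCKLIST <- c("Ralstonia", "Cupriavidus", "Methylobacterium",
                    "Sphingomonas", "Bradyrhizobium", "Burkholderia",
                    "Herbaspirillum", "Acinetobacter", "Stenotrophomonas",
                    "Delftia", "Comamonas", "Variovorax", "Phyllobacterium",
                    "Mesorhizobium", "Aquabacterium", "Novosphingobium",
                    "Brevundimonas", "Caulobacter", "Pelomonas",
                    "Undibacterium")
POOL_EVIDENCE <- c("Faecalibacterium", "Bacteroides", "Ruminococcus",
                   "Blautia", "Veillonella", "Streptococcus", "Prevotella",
                   "Bifidobacterium", "Akkermansia", "Dorea", "Roseburia",
                   "Coprococcus", "Lactobacillus", "Deinococcus",
                   "Parabacteroides")
POOL_NOEVIDENCE <- c("Tellurimicrobium", "Abditibacterium", "Limisphaera",
                     "Thermoflexus", "Calorithrix", "Desulfatiglans",
                     "Hydrogenedens", "Caldipriscus")

#' Built-in synthetic evidence lists matching the simulator's name pools
#'
#' A stand-in blocklist of reagent-contaminant genera and a commensal/
#' pathogen evidence list of gut-associated genera, constructed to pair with
#' [simulate_cohort()]'s taxonomy labels. They are synthetic conveniences
#' for testing, not curated literature resources.
#'
#' @return An `evidence_lists` object.
#' @export
default_evidence_lists <- function() {
  evidence_lists(
    blocklist = data.frame(name = POOL_BLOCKLIST, rank = "genus",
                           source = "synthetic reagent-contaminant pool",
                           stringsAsFactors = FALSE),
    commensal_evidence = data.frame(name = POOL_EVIDENCE, rank = "genus",
                                    source = "synthetic commensal pool",
                                    stringsAsFactors = FALSE))
}

#' Simulate a plasma cfmDNA cohort with planted contaminants and signal
#'
#' Generates an ASV count table, study design, taxonomy and ground truth.
#' Contaminant ASVs receive log-normal base abundances; shared contaminants
#' appear in every batch's plasma samples and DENCs with per-batch
#' log-normal multipliers (the batch effect criterion (i) must detect);
#' batch-specific contaminants appear only in their batch. True ASVs appear
#' only in plasma of their carrier patients at low relative abundance,
#' replicated (minus dropout) in the replicate batch, and never in DENCs.
#' Reads are multinomial at log-normal depth. Fully deterministic per seed.
#'
#' @param cfg a [sim_config()].
#' @return List with `table` ([asv_table()]), `design` (`study_design`),
#'   `taxonomy` (`taxonomy_table`), `truth` (data.frame: `asv_id`, `label`,
#'   `source_batches`), and `lists` ([default_evidence_lists()]).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))
  nb <- cfg$n_batches
  batches <- LETTERS[seq_len(nb)]
  nspb <- cfg$n_samples_per_batch
  ndpb <- cfg$n_dencs_per_batch

  # --- design -------------------------------------------------------------
  rows <- list()
  patient_counter <- 0L
  batch_patients <- list()
  for (bi in seq_len(nb)) {
    b <- batches[bi]
    if (cfg$replicate_pair && bi == 2L) {
      pats <- batch_patients[[1L]]
    } else {
      pats <- sprintf("P%02d", patient_counter + seq_len(nspb))
      patient_counter <- patient_counter + nspb
    }
    batch_patients[[bi]] <- pats
    run <- if (cfg$replicate_pair && nb > 2L && bi <= 2L) "run1" else
      if (cfg$replicate_pair && nb > 2L) "run2" else "run1"
    days <- paste0(b, c("d1", "d2"))
    repgrp <- if (cfg$replicate_pair && bi <= 2L) paste0("rg.", pats) else NA
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(b, ".", pats),
      sample_type = "plasma", patient_id = pats,
      sequencing_run = run, extraction_batch = b,
      extraction_day = days[1L + (seq_len(nspb) %% 2L)],
      replicate_group = repgrp, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s.DENC%02d", b, seq_len(ndpb)),
      sample_type = "plasma_denc", patient_id = NA,
      sequencing_run = run, extraction_batch = b,
      extraction_day = days[1L + (seq_len(ndpb) %% 2L)],
      replicate_group = NA, stringsAsFactors = FALSE)
  }
  design <- study_design(do.call(rbind, rows))
  n_samples <- nrow(design)

  # --- ASV pools ----------------------------------------------------------
  n_sh <- cfg$n_contaminant_asvs_shared
  n_bs <- cfg$n_contaminant_asvs_batch_specific
  n_tr <- cfg$n_true_asvs
  ids <- c(if (n_sh) sprintf("contam.shared.%03d", seq_len(n_sh)),
           if (n_bs) sprintf("contam.batch.%03d", seq_len(n_bs)),
           if (n_tr) sprintf("true.%03d", seq_len(n_tr)))
  label <- c(rep("contaminant_shared", n_sh), rep("contaminant_batch", n_bs),
             rep("true_signal", n_tr))
  # heavy-tailed kitome: most contaminant ASVs are rare, a few dominate,
  # so the bulk of ASVs sit in the low (< 0.1%) abundance class
  base <- stats::rlnorm(n_sh + n_bs, meanlog = 0, sdlog = 3)
  bs_batch <- if (n_bs) rep(batches, length.out = n_bs) else character(0)
  # per-batch multiplier on shared contaminants
  mult <- matrix(stats::rlnorm(n_sh * nb, 0, cfg$batch_effect_sigma), n_sh, nb)

  true_ab <- if (n_tr) exp(stats::runif(n_tr,
                                        log(cfg$true_relabund_range[1L]),
                                        log(cfg$true_relabund_range[2L])))
             else numeric(0)
  all_patients <- unique(design$patient_id[!is.na(design$patient_id)])
  carriers <- lapply(seq_len(n_tr), function(i)
    all_patients[stats::runif(length(all_patients)) < cfg$true_prevalence])

  # --- expected relative abundances per sample ---------------------------
  expected <- matrix(0, length(ids), n_samples,
                     dimnames = list(ids, design$sample_id))
  for (j in seq_len(n_samples)) {
    b <- design$extraction_batch[j]
    bi <- match(b, batches)
    contam <- numeric(n_sh + n_bs)
    if (n_sh) contam[seq_len(n_sh)] <- base[seq_len(n_sh)] * mult[, bi]
    if (n_bs) {
      sel <- which(bs_batch == b)
      contam[n_sh + sel] <- base[n_sh + sel]
    }
    if (design$sample_type[j] == "plasma" && cfg$contaminant_plasma_dropout > 0) {
      # genuine DNA competes with trace reagent DNA: contaminants are
      # detected less consistently in true samples than in water controls
      sup <- stats::runif(n_sh + n_bs) < cfg$contaminant_plasma_dropout
      contam[sup] <- 0
    }
    contam <- contam / sum(contam)
    truevec <- numeric(n_tr)
    if (n_tr && design$sample_type[j] == "plasma") {
      pat <- design$patient_id[j]
      for (i in seq_len(n_tr)) {
        if (pat %in% carriers[[i]]) {
          present <- TRUE
          if (cfg$replicate_pair && bi == 2L &&
              stats::runif(1L) < cfg$detection_dropout) present <- FALSE
          if (present) truevec[i] <- true_ab[i]
        }
      }
    }
    tm <- sum(truevec)
    if (tm >= 1) stop("infeasible config: true abundance mass >= 1")
    expected[, j] <- c(contam * (1 - tm), truevec)
  }

  # --- counts -------------------------------------------------------------
  depths <- pmax(1000, round(stats::rlnorm(n_samples,
                                           cfg$depth_lognormal[1L],
                                           cfg$depth_lognormal[2L])))
  counts <- matrix(0, length(ids), n_samples, dimnames = dimnames(expected))
  for (j in seq_len(n_samples))
    counts[, j] <- stats::rmultinom(1L, depths[j], expected[, j])
  table <- asv_table(counts)

  # --- taxonomy -----------------------------------------------------------
  mk_lineage <- function(genus, uncharacterised = FALSE) {
    if (uncharacterised)
      c("Bacteria", "Planctomycetota", "Phycisphaerae", "Tepidisphaerales",
        "", "")
    else c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
           "Burkholderiales", paste0(genus, "aceae"), genus)
  }
  tax_rows <- vector("list", length(ids))
  u <- stats::runif(length(ids))
  for (i in seq_along(ids)) {
    if (label[i] == "true_signal") {
      tax_rows[[i]] <- if (u[i] < 0.8)
        mk_lineage(POOL_EVIDENCE[1L + (i %% length(POOL_EVIDENCE))])
      else mk_lineage("", uncharacterised = TRUE)
    } else {
      tax_rows[[i]] <- if (u[i] < 0.7)
        mk_lineage(POOL_BLOCKLIST[1L + (i %% length(POOL_BLOCKLIST))])
      else if (u[i] < 0.9)
        mk_lineage(POOL_NOEVIDENCE[1L + (i %% length(POOL_NOEVIDENCE))])
      else mk_lineage("", uncharacterised = TRUE)
    }
  }
  taxmat <- do.call(rbind, tax_rows)
  colnames(taxmat) <- TAX_RANKS
  taxonomy <- taxonomy_table(data.frame(asv_id = ids, taxmat,
                                        stringsAsFactors = FALSE))

  source_batches <- vapply(seq_along(ids), function(i) {
    if (label[i] == "contaminant_batch") bs_batch[i - n_sh]
    else paste(batches, collapse = ",")
  }, character(1L))
  truth <- data.frame(asv_id = ids, label = label,
                      source_batches = source_batches,
                      stringsAsFactors = FALSE)
  attr(truth, "expected_relabund") <- expected

  # truth consistency: planted signal never appears in a negative control
  denc <- design$sample_type == "plasma_denc"
  if (n_tr && any(counts[label == "true_signal", denc, drop = FALSE] > 0))
    stop("internal error: true-signal reads in a DENC")

  list(table = table, design = design, taxonomy = taxonomy, truth = truth,
       lists = default_evidence_lists())
}

#' Simulate a 20-strain even mock community across sequencing runs
#'
#' Equal true proportions multiplied by a fixed per-strain log-normal
#' amplification bias (shared across runs, emulating reproducible PCR bias),
#' then multinomial reads per run.
#'
#' @param n_strains number of strains (default 20).
#' @param bias_sigma log-sd of the shared per-strain bias (0 = unbiased).
#' @param n_runs number of sequencing runs / columns (default 2).
#' @param depth reads per run (default 50000).
#' @param seed integer seed.
#' @param drop_strains optional strain indices whose bias is set to zero
#'   (emulates a strain the assay cannot recover).
#' @return An [asv_table()], one column per run.
#' @export
simulate_mock_community <- function(n_strains = 20, bias_sigma = 1,
                                    n_runs = 2, depth = 50000, seed = 1L,
                                    drop_strains = integer(0)) {
  if (n_strains < 2) stop("need >= 2 strains")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  bias <- stats::rlnorm(n_strains, 0, bias_sigma)
  bias[drop_strains] <- 0
  p <- bias / sum(bias)
  counts <- vapply(seq_len(n_runs), function(r) stats::rmultinom(1L, depth, p)[, 1L],
                   numeric(n_strains))
  dimnames(counts) <- list(sprintf("strain%02d", seq_len(n_strains)),
                           sprintf("mockrun%d", seq_len(n_runs)))
  asv_table(counts)
}

#' Simulate a target-DNA dilution series with constant contaminant input
#'
#' Target reads are proportional to input concentration below a saturation
#' plateau while contaminant reads stay constant in expectation, so the
#' contaminant proportion rises as the target is diluted out.
#'
#' @param concentrations positive, descending target concentrations
#'   (copies/microlitre).
#' @param n_contaminants size of the contaminant pool (default 30).
#' @param reads_at_max expected target reads at/above the plateau
#'   (default 50000).
#' @param contaminant_reads expected total contaminant reads per library
#'   (default 300).
#' @param plateau_conc concentration at which target reads saturate
#'   (default 100 copies/ul).
#' @param seed integer seed.
#' @return An [asv_table()]: rows = target plus contaminant ASVs, one column
#'   per dilution.
#' @export
simulate_dilution_series <- function(concentrations, n_contaminants = 30,
                                     reads_at_max = 50000,
                                     contaminant_reads = 300,
                                     plateau_conc = 100, seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(rev(concentrations), strictly = FALSE))
    stop("concentrations must be descending")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  contam_p <- if (n_contaminants > 0)
    stats::rlnorm(n_contaminants, 0, 1) else numeric(0)
  contam_p <- if (n_contaminants > 0) contam_p / sum(contam_p) else contam_p
  counts <- vapply(concentrations, function(conc) {
    target <- stats::rpois(1L, reads_at_max * min(1, conc / plateau_conc))
    contam <- if (n_contaminants > 0)
      stats::rpois(n_contaminants, contaminant_reads * contam_p) else numeric(0)
    c(target, contam)
  }, numeric(1L + n_contaminants))
  counts <- matrix(counts, nrow = 1L + n_contaminants)
  rownames(counts) <- c("target.ecoli",
                        if (n_contaminants > 0)
                          sprintf("contam.%02d", seq_len(n_contaminants)))
  colnames(counts) <- sprintf("dilution%02d", seq_along(concentrations))
  # guard against an all-zero row in deep dilutions breaking validation
  asv_table(counts[rowSums(counts) > 0 | seq_len(nrow(counts)) == 1L, ,
                   drop = FALSE])
}

#' Negative-binomial count simulator for batch-effect power studies
#'
#' Equal-mean negative-binomial counts across batches, optionally with a
#' fold-change enrichment of selected ASVs in one batch, for error-control
#' and sensitivity studies of the criterion (i) screen.
#'
#' @param n_asvs number of ASVs.
#' @param n_batches number of extraction batches (one run, two days each).
#' @param samples_per_batch plasma samples per batch.
#' @param mu_log mean/sd of log base means (default log-normal around 50
#'   reads).
#' @param size NB dispersion parameter (default 2).
#' @param effect_asvs indices of enriched ASVs (default none).
#' @param effect_fold fold enrichment in the first batch (default 4).
#' @param seed integer seed.
#' @return List with `table` and `design` ready for [run_batch_da()].
#' @export
simulate_nb_counts <- function(n_asvs = 500, n_batches = 3,
                               samples_per_batch = 12,
                               mu_log = c(log(50), 1), size = 2,
                               effect_asvs = integer(0), effect_fold = 4,
                               seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  batches <- LETTERS[seq_len(n_batches)]
  design <- do.call(rbind, lapply(batches, function(b) data.frame(
    sample_id = sprintf("%s.S%02d", b, seq_len(samples_per_batch)),
    sample_type = "plasma", patient_id = NA,
    sequencing_run = "run1", extraction_batch = b,
    extraction_day = paste0(b, "d", 1L + (seq_len(samples_per_batch) %% 2L)),
    replicate_group = NA, stringsAsFactors = FALSE)))
  design <- study_design(design)
  mu <- stats::rlnorm(n_asvs, mu_log[1L], mu_log[2L])
  n <- nrow(design)
  counts <- matrix(stats::rnbinom(n_asvs * n, mu = mu, size = size),
                   n_asvs, n)
  if (length(effect_asvs)) {
    first <- design$extraction_batch == batches[1L]
    counts[effect_asvs, first] <-
      stats::rnbinom(length(effect_asvs) * sum(first),
                     mu = mu[effect_asvs] * effect_fold, size = size)
  }
  dimnames(counts) <- list(sprintf("asv%04d", seq_len(n_asvs)),
                           design$sample_id)
  keep <- rowSums(counts) > 0
  list(table = asv_table(counts[keep, , drop = FALSE]),
       design = design, effect_asvs = rownames(counts)[
         seq_len(n_asvs) %in% effect_asvs & keep])
}

#' Score a final ASV list against the simulation ground truth
#'
#' @param truth the `truth` data.frame from [simulate_cohort()].
#' @param final_list character vector of ASV ids retained by the pipeline.
#' @return List with `sensitivity` (recovered fraction of true-signal ASVs),
#'   `false_pass_rate` (contaminant fraction within `final_list`; 0 when the
#'   list is empty) and `confusion` (per-label retained/total counts).
#' @export
evaluate_recovery <- function(truth, final_list) {
  stray <- setdiff(final_list, truth$asv_id)
  if (length(stray)) stop("final list contains unknown ASVs: ",
                          paste(stray, collapse = ", "))
  is_true <- truth$label == "true_signal"
  n_true <- sum(is_true)
  rec <- truth$asv_id %in% final_list
  sens <- if (n_true) sum(rec & is_true) / n_true else NA_real_
  fpr <- if (length(final_list)) sum(rec & !is_true) / length(final_list) else 0
  confusion <- stats::aggregate(list(retained = rec),
                                by = list(label = truth$label), FUN = sum)
  confusion$total <- as.vector(table(truth$label)[confusion$label])
  list(sensitivity = sens, false_pass_rate = fpr, confusion = confusion)
}
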