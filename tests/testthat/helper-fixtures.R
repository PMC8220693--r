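# Small in-code fixtures shared across test files.

tiny_table <- function(m = NULL) {
  if (is.null(m))
    m <- matrix(c(5, 0, 1, 2, 0, 7), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("asv", 1:3), paste0("s", 1:2)))
  asv_table(m)
}

random_table <- function(n_asv = 20, n_samp = 6, lambda = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_asv * n_samp, lambda), n_asv, n_samp,
              dimnames = list(sprintf("asv%02d", seq_len(n_asv)),
                              sprintf("s%02d", seq_len(n_samp))))
  m[1, ] <- m[1, ] + 1  # guarantee no all-zero sample
  asv_table(m)
}

tiny_design <- function(sample_ids, sample_type = "plasma", batch = "A",
                        day = NULL, patient = NA, run = "run1",
                        replicate_group = NA) {
  n <- length(sample_ids)
  study_design(data.frame(
    sample_id = sample_ids,
    sample_type = rep_len(sample_type, n),
    patient_id = rep_len(patient, n),
    sequencing_run = rep_len(run, n),
    extraction_batch = rep_len(batch, n),
    extraction_day = if (is.null(day)) paste0(rep_len(batch, n), "d1") else
      rep_len(day, n),
    replicate_group = rep_len(replicate_group, n),
    stringsAsFactors = FALSE))
}

tiny_taxonomy <- function(asv_ids, genus = "Faecalibacterium",
                          family = "Ruminococcaceae") {
  taxonomy_table(data.frame(
    asv_id = asv_ids,
    domain = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
    order = "Oscillospirales",
    family = rep_len(family, length(asv_ids)),
    genus = rep_len(genus, length(asv_ids)),
    stringsAsFactors = FALSE))
}

small_cohort <- function(seed = 1) {
  simulate_cohort(sim_config(
    n_true_asvs = 8, n_contaminant_asvs_shared = 40,
    n_contaminant_asvs_batch_specific = 15, n_batches = 3,
    n_samples_per_batch = 8, n_dencs_per_batch = 6,
    depth_lognormal = c(log(2e4), 0.3), seed = seed))
}
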