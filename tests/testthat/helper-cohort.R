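# small cohort configurations reused across test files
small_config <- function(seed = 11, ...) {
  cohort_config(n_patients = 24, n_paired = 12, n_genes = 300, n_mirnas = 60,
                n_meth_sites = 600, frac_de_genes = 0.25,
                planted_mirna_pairs = 5, planted_meth_genes = 5,
                planted_cna_genes = 5, n_key_genes = 3, seed = seed, ...)
}

null_config <- function(seed = 11, n_genes = 300, n_paired = 12,
                        n_patients = 24) {
  cohort_config(n_patients = n_patients, n_paired = n_paired,
                n_genes = n_genes, n_mirnas = 60, n_meth_sites = 600,
                frac_de_genes = 0, planted_mirna_pairs = 0,
                planted_meth_genes = 0, planted_cna_genes = 0,
                n_key_genes = 0, seed = seed)
}

# simple sample metadata for hand-built matrices: p paired patients
toy_meta <- function(p) {
  tibble::tibble(
    sample_id = c(sprintf("P%02d-T", 1:p), sprintf("P%02d-N", 1:p)),
    patient_id = rep(sprintf("P%02d", 1:p), 2),
    tissue = rep(c("tumor", "normal"), each = p))
}

# wide omics tibble from a features x samples matrix
toy_matrix <- function(m) {
  tibble::tibble(feature_id = rownames(m)) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}
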