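#!/usr/bin/env Rscript
# Step 5: binding characterization. Simulates titrations at the dissociation
# constants reported for the candidate aptamers (both assay formats: APCE at
# 10 nM probe over 0-240 nM protein; anisotropy at 100 nM probe over
# 0-750 nM) with 2% amplitude-referenced noise, fits the quadratic isotherm
# by nonlinear least squares, and tabulates recovered vs true Kd.

suppressPackageStartupMessages(library(selexenrich))

kd <- selex_reported_kd()
rows <- list()
for (i in seq_len(nrow(kd))) {
  id <- kd$id[i]
  # APCE format
  if (!is.na(kd$apce_kd_nM[i]) && kd$apce_kd_nM[i] <= 2000) {
    d <- simulate_binding_assay(kd$apce_kd_nM[i], A = 10, constant = 1,
                                T_grid = apce_titration(), noise_sd = 0.02,
                                replicates = 2, seed = 500 + i)
    f <- fit_isotherm(d, A = 10)
    rows[[paste0(id, "_apce")]] <- data.frame(
      id = id, assay = "apce", true_kd_nM = kd$apce_kd_nM[i],
      fitted_kd_nM = round(f$Kd_hat, 1), se_kd_nM = round(f$se_Kd, 1),
      converged = f$converged)
  }
  # anisotropy format (skip censored lower-bound entries)
  if (!kd$anisotropy_censored[i] && kd$anisotropy_kd_nM[i] <= 30000) {
    d <- simulate_binding_assay(kd$anisotropy_kd_nM[i], A = 100,
                                constant = 0.05,
                                T_grid = anisotropy_titration(),
                                noise_sd = 0.02, replicates = 2,
                                seed = 600 + i)
    f <- fit_isotherm(d, A = 100)
    rows[[paste0(id, "_aniso")]] <- data.frame(
      id = id, assay = "anisotropy", true_kd_nM = kd$anisotropy_kd_nM[i],
      fitted_kd_nM = round(f$Kd_hat, 1), se_kd_nM = round(f$se_Kd, 1),
      converged = f$converged)
  }
}
fits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
dir.create("results", showWarnings = FALSE)
write.table(fits, "results/kd_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("simulated-titration Kd recovery at the reported affinities:")
print(fits, row.names = FALSE)
message("note: affinities far above the titrated concentration range ",
        "(e.g. 26000 nM anisotropy over 0-750 nM) are weakly identified; ",
        "standard errors reflect that.")
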