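#!/usr/bin/env Rscript
# Step 4 — calibration of the comparison machinery on synthetic data
# with known ground truth. With no injected bias the natural-vs-control
# AUC should sit at chance for all three statistics (the generator then
# IS the control law); injecting a minimal-pair preference (beta_loc)
# should surface specifically in the Loc AUC. Also verifies that the
# three rank-normalized statistics are mutually uncorrelated over the
# distinct rank-table entries.

suppressMessages(library(phonogeom))

rows <- list()
for (b in c(0, 1, 2)) {
  r <- run_recovery_experiment(beta_loc = b, n_languages = 300, seed = 1)
  rows[[length(rows) + 1]] <- data.frame(
    beta_loc = b, auc_econ = r$auc[["econ"]], auc_loc = r$auc[["loc"]],
    auc_glob = r$auc[["glob"]]
  )
  message(sprintf("beta_loc = %g: AUC econ %.3f, loc %.3f, glob %.3f",
                  b, r$auc[["econ"]], r$auc[["loc"]], r$auc[["glob"]]))
  if (b == 0) {
    dc <- decorrelation_check(r$table)
    message(sprintf("decorrelation over rank-table entries: |r| econ-loc %.1e, econ-glob %.1e, loc-glob %.1e",
                    abs(dc[1]), abs(dc[2]), abs(dc[3])))
  }
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/recovery.csv", row.names = FALSE)
message("recovery curve written to results/recovery.csv")
stopifnot(all(diff(out$auc_loc) > -0.05))  # Loc AUC non-decreasing in the bias
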