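#!/usr/bin/env Rscript
# Fit the three suitability algorithms (climate envelope, quadratic
# logistic regression, random forest) for every retained species, evaluate
# them by 4-fold cross-validated AUC, project onto every climate scenario,
# and combine into AUC-weighted ensembles.
source(file.path("analysis", "_common.R"))

art <- stage_sdms(stage_occurrences(stage_simulate(config, master_seed)))

dir.create(res_path("rasters"), showWarnings = FALSE)
for (id in names(art$sdm)) {
  s <- art$sdm[[id]]
  write_cv_table(s$cv, res_path(sprintf("cv_%s.csv", id)))
  for (sc in names(s$ensembles)) {
    write_ascii_grid(s$ensembles[[sc]],
                     res_path("rasters", sprintf("ensemble_%s_%s.asc", id, sc)))
  }
  cat(sprintf("%-12s 4-fold AUC: %s (ensemble weights)\n", id,
              paste(sprintf("%s %.3f", names(s$weights), s$weights),
                    collapse = ", ")))
}
focal <- config$network$focal
cat(sprintf("focal species '%s' mean CV AUC (no network): %.3f\n",
            focal, mean(art$sdm[[focal]]$weights)))
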