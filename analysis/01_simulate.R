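#!/usr/bin/env Rscript
# Build the virtual ecosystem: six autocorrelated bioclimatic surfaces for
# the present and two warming scenarios, five Gaussian-niche species, a
# land mask and gazetteer for record cleaning, and contaminated occurrence
# samples.
source(file.path("analysis", "_common.R"))

art <- stage_simulate(config, master_seed)

dir.create(res_path("climate"), showWarnings = FALSE)
for (sc in names(art$grids)) {
  for (v in names(art$grids[[sc]]$layers)) {
    write_ascii_grid(art$grids[[sc]]$layers[[v]],
                     res_path("climate", sprintf("%s_%s.asc", sc, v)),
                     g = art$grids[[sc]])
  }
}
write_occurrences(art$occurrences_raw, res_path("occurrences_raw.csv"))
write_ascii_grid(art$fixtures$land_mask, res_path("land_mask.asc"))
write.csv(art$fixtures$gazetteer, res_path("gazetteer.csv"),
          row.names = FALSE)
write_ascii_grid(art$regions, res_path("regions.asc"), g = art$grids$present)
write_config(config, res_path("config.yaml"))

cat(sprintf("simulated %d x %d grid (%.2f deg cells), %d scenarios\n",
            art$grids$present$n_rows, art$grids$present$n_cols,
            art$grids$present$cell_size, length(art$grids)))
cat(sprintf("sampled %d occurrence records across %d species\n",
            nrow(art$occurrences_raw), length(art$species)))
cat(sprintf("land fraction %.2f, gazetteer entries %d\n",
            mean(art$fixtures$land_mask$presence),
            nrow(art$fixtures$gazetteer)))
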