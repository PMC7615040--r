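#!/usr/bin/env Rscript
# Clean the raw records: basis-of-record whitelist, the coordinate-error
# tests (capitals/centroids, equal lon/lat, institution buffer, sea, plain
# zeros, out-of-range), rarefaction to one record per cell, and the
# 20-record minimum for modelling.
source(file.path("analysis", "_common.R"))

art <- stage_occurrences(stage_simulate(config, master_seed))

write_occurrences(art$records, res_path("occurrences_clean.csv"))
write_cleaning_report(art$cleaning_report, res_path("cleaning_report.txt"))
write.csv(art$species_status, res_path("species_status.csv"),
          row.names = FALSE)

rp <- art$cleaning_report
cat(sprintf("cleaning: %d of %d records failed the tests and were removed\n",
            rp$total_removed, rp$input_rows))
print(rp)
cat(sprintf("after rarefaction: %d records across %d species (all >= %d: %s)\n",
            nrow(art$records), nrow(art$species_status),
            config$sdm$min_records,
            all(art$species_status$retained)))
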