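#!/usr/bin/env Rscript
# Stage 2 — seasonal prey abundance layers.
#
# Summarizes trapping captures to mean individuals per grid and spotlight
# sightings to availability-standardized indices, quartile-ranks both
# against their pooled study-period values (low/medium/high/very high),
# reclassifies the vegetation raster per season-year, and combines the two
# rank rasters 2/3 (small mammal) : 1/3 (leporid).

suppressPackageStartupMessages(library(igprsf))
simdir <- "results/sim"
out <- "results/prey"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

land <- read_landscape(file.path(simdir, "landscape"))
trapping <- read.csv(file.path(simdir, "trapping.csv"))
spotlight <- read.csv(file.path(simdir, "spotlight.csv"))
transects <- read.csv(file.path(simdir, "transects.csv"))

sm <- summarize_captures(trapping)
lep <- summarize_sightings(spotlight, transects)
rank_sm <- rank_abundance(sm, "small_mammal")
rank_lep <- rank_abundance(lep, "leporid")

cat("small-mammal quartile cuts:",
    paste(round(rank_sm$thresholds, 2), collapse = " / "), "\n")
cat("leporid quartile cuts:     ",
    paste(round(rank_lep$thresholds, 3), collapse = " / "), "\n")
cat(sprintf("captures averaged %.1f individuals/grid/session (range %d-%d)\n",
            mean(trapping$count), min(trapping$count), max(trapping$count)))

write.csv(rbind(ranking_table(rank_sm), ranking_table(rank_lep)),
          file.path(out, "abundance_ranking.csv"), row.names = FALSE)

prey <- build_prey_rasters(trapping, spotlight, transects, land$vegetation)
for (sy in names(prey$prey)) {
  write_esri_ascii(prey$prey[[sy]], file.path(out, paste0("prey_", sy, ".asc")))
}
cat("wrote", length(prey$prey), "seasonal prey rasters and the ranking table to",
    out, "\n")
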