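#!/usr/bin/env Rscript
# Stage 5 — run manifest.
#
# Enumerates every artifact the preceding stages wrote under results/ with
# its MD5 hash, so a rerun with the same seeds can be verified
# byte-for-byte.

suppressPackageStartupMessages(library(igprsf))
files <- list.files("results", recursive = TRUE, full.names = TRUE)
files <- files[!grepl("manifest\\.json$", files)]
manifest <- data.frame(file = sub("^results/", "", files),
                       md5 = unname(tools::md5sum(files)))
jsonlite::write_json(manifest, "results/manifest.json", pretty = TRUE)
cat("manifest:", nrow(manifest), "artifacts hashed ->",
    "results/manifest.json\n")
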