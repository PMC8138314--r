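#!/usr/bin/env Rscript

# Optional helper (requires network): download the ligand-GPCR crystal
# structures used by the published case-study score tables into
# inst/extdata/real/, so that tests/testthat/test-acceptance.R and
# calibrate_config() can reproduce those scores. The core package never
# requires network access.
#
# Usage: Rscript scripts/fetch_structures.R [dest_dir]

ids <- c("6DRX", "3NYA", "5TVN", "3D4S", "3UON", "3NY8")
dest <- commandArgs(trailingOnly = TRUE)
dest <- if (length(dest)) dest[1] else "inst/extdata/real"
dir.create(dest, showWarnings = FALSE, recursive = TRUE)
bio3d::get.pdb(ids, path = dest)
cat("downloaded:", paste(ids, collapse = ", "), "into", dest, "\n")
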