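#!/usr/bin/env Rscript
# Stage 2: colourimetric descriptors per painting.
#
# For every painting in the corpus: the number of discernible colours (unit
# cubes in CIELAB), the convex-hull colour volume, the least-squares gamut
# ellipse in (a*, b*), and the channel means. The output table uses the usual
# reporting abbreviations (NDC, L*, a*, b*, Angle, Ratio, Area, Volume).

suppressMessages(library(relcolors))

paths <- Sys.glob("results/paintings/painting_*.png")
if (!length(paths)) stop("run analysis/01_synthesize_paintings.R first")

rows <- list()
for (p in paths) {
  lab <- image_to_lab(read_image_rgb(p))
  df <- as.data.frame(summarize_gamut(lab))
  df <- cbind(data.frame(image = basename(p)), df)
  rows[[length(rows) + 1]] <- df
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/gamut_descriptors.csv", row.names = FALSE)

cat("per-image gamut descriptors:\n")
print(tab, digits = 4)
cat(sprintf("\nmeans: NDC %.0f, volume %.0f, ellipse area %.0f, axis ratio %.2f\n",
            mean(tab$NDC), mean(tab$Volume), mean(tab$Area), mean(tab$Ratio)))
write_run_manifest("results/gamut_manifest.json",
                   params = list(stage = "gamut", inputs = basename(paths)),
                   outputs = "results/gamut_descriptors.csv")
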