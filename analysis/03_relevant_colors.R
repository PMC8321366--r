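#!/usr/bin/env Rscript
# Stage 3: the two palette routes and their agreement.
#
# Computational route: density-ranked extraction with lightness/chroma gates.
# Subjective route: simulated observers click inside relevant chromatic areas;
# each selection averages its 5x5 pixel window and counts as one relevant
# colour. Agreement is the fraction of subjective colours within 10 Delta E of
# a computational colour, plus the hull-area overlap of the two gamuts in
# (a*, b*), echoing the comparison of computational and experimental palettes.

suppressMessages(library(relcolors))

base_seed <- 20260926L
n_observers <- 3
paths <- Sys.glob("results/paintings/painting_*.png")
if (!length(paths)) stop("run analysis/01_synthesize_paintings.R first")
dir.create("results/palettes", recursive = TRUE, showWarnings = FALSE)

rows <- list(); all_subj <- list(); outputs <- character(0)
for (i in seq_along(paths)) {
  lab <- image_to_lab(read_image_rgb(paths[i]))
  comp <- extract_relevant_colors(lab)
  cp <- sprintf("results/palettes/painting_%02d_computational.json", i)
  write_palette_json(comp, cp)
  outputs <- c(outputs, cp)

  # observers need the painting object for region-aware clicking; regenerate
  # it deterministically from the corpus seed
  pt <- generate_painting(K = 21, noise_sigma = 3, shading_amplitude = 5,
                          seed = base_seed + i)
  for (ob in seq_len(n_observers)) {
    obs <- simulate_observer(pt, click_prob = 0.9, chroma_bias = 1,
                             seed = base_seed + 100 * ob + i)
    if (!nrow(obs)) next
    subj <- subjective_palette(obs)
    all_subj[[length(all_subj) + 1]] <- subj$colors
    ov <- palette_overlap(comp, subj, tol = 10)
    rows[[length(rows) + 1]] <- data.frame(
      image = basename(paths[i]), observer = ob,
      NRC_computational = comp$size, NRC_subjective = subj$size,
      subjective_covered = ov$subjective_covered,
      computational_covered = ov$computational_covered,
      hull_area_iou = ov$hull_area_iou)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/palette_overlap.csv", row.names = FALSE)

cat("palette agreement per painting and observer:\n")
print(tab, digits = 3)
cat(sprintf("\nmean subjective colours %.1f (sd %.1f); mean computational %.1f (sd %.1f)\n",
            mean(tab$NRC_subjective), sd(tab$NRC_subjective),
            mean(tab$NRC_computational), sd(tab$NRC_computational)))
cat(sprintf("mean overlap: %.2f of subjective colours covered; hull IoU %.2f\n",
            mean(tab$subjective_covered), mean(tab$hull_area_iou, na.rm = TRUE)))

# pooled hue/chroma structure of the subjective colours (all observers)
pooled <- new_palette(do.call(rbind, all_subj), "subjective")
hc <- hue_chroma_table(pooled)
write.csv(hc$hue_hist, "results/subjective_hue_histogram.csv", row.names = FALSE)
write.csv(hc$chroma_hist, "results/subjective_chroma_histogram.csv", row.names = FALSE)
cat(sprintf("pooled subjective colours: %d; fraction with chroma < 35: %.2f\n",
            pooled$size, mean(hc$table$chroma < 35)))

write_run_manifest("results/palettes_manifest.json",
                   params = list(stage = "relevant_colors", base_seed = base_seed,
                                 n_observers = n_observers, click_prob = 0.9,
                                 chroma_bias = 1, overlap_tol = 10),
                   outputs = c(outputs, "results/palette_overlap.csv",
                               "results/subjective_hue_histogram.csv",
                               "results/subjective_chroma_histogram.csv"))
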