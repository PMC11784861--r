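#!/usr/bin/env Rscript
# Ensemble detection on the planted calcium raster and the
# strong-late/weak-late split of the connectivity metrics.

suppressPackageStartupMessages(library(cortexwaves))
seed <- 1
out <- "results/ensembles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

raster <- read_calcium_raster("results/inputs/calcium")
gt <- attr(raster, "ground_truth")
es <- detect_ensembles(raster, n_shuffles = 1000, seed = seed)
jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
j <- vapply(gt$members, function(g)
  max(c(0, vapply(es$membership, function(m) jacc(unlist(g), m),
                  numeric(1)))), numeric(1))
cat(sprintf("planted %d ensembles; recovered %d (%d significant components); mean Jaccard %.2f\n",
            length(gt$members), length(es$membership), es$n_components,
            mean(j)))
jsonlite::write_json(
  list(membership = es$membership,
       sizes = vapply(es$ensembles, `[[`, numeric(1), "size"),
       n_connections = vapply(es$ensembles, `[[`, numeric(1),
                              "n_connections"),
       reactivation = vapply(es$ensembles, `[[`, numeric(1),
                             "reactivation")),
  file.path(out, "ensembles.json"), auto_unbox = TRUE, digits = NA)

# split by a synthetic strong/weak alternation of trial windows
n_frames <- ncol(raster$dff)
trial_frames <- split(seq_len(n_frames),
                      rep(1:8, each = ceiling(n_frames / 8))[seq_len(n_frames)])
labels <- rep(c("strong", "weak"), 4)
grp <- split_by_late_wave(raster, trial_frames, labels, n_shuffles = 300,
                          seed = seed)
for (g in names(grp)) {
  cat(sprintf("%s-late group: %d trials, %d ensembles, median size %s\n",
              g, grp[[g]]$n_trials, length(grp[[g]]$size),
              ifelse(length(grp[[g]]$size), median(grp[[g]]$size), NA)))
}
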