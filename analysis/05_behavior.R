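#!/usr/bin/env Rscript
# Whisker kinematics and task metrics on the synthetic pose table: whisker
# phase, Menger curvature during touch, ROI touch detection with the
# 100-ms interval filter, and d-prime from a synthetic outcome mix.

suppressPackageStartupMessages(library(cortexwaves))
out <- "results/behavior"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- behavior_spec(seed = 1)
pose <- generate_whisker_traces(spec)
gt <- attr(pose, "ground_truth")

wp <- whisker_phase(pose, spec$frame_rate, pad = spec$pad)
bend <- whisker_bend(pose)
cat(sprintf("median curvature during touch %.4f 1/px (planted %.4f); off-touch %.2e\n",
            median(bend[gt$touch_frames]), spec$bend_curvature,
            median(abs(bend[-gt$touch_frames]))))

touches <- detect_touches(pose, gt$roi_polygon)
kept <- filter_touch_intervals(touches$touch_frame, spec$frame_rate)
cat(sprintf("detected %d touch episodes (planted %d); %d survive the 100-ms filter\n",
            nrow(touches), nrow(spec$touch_episodes), length(kept)))
write.table(touches, file.path(out, "touches.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

# synthetic go/no-go session: 40 hits, 10 misses, 35 CR, 15 FA
stimuli <- c(rep("go", 50), rep("nogo", 50))
starts <- seq_len(100) * 3
licked <- c(rep(TRUE, 40), rep(FALSE, 10), rep(FALSE, 35), rep(TRUE, 15))
outcomes <- classify_outcomes(stimuli, starts, starts[licked] + 0.5)
cat(sprintf("hit rate %.2f, FA rate %.2f, D' = %.3f (expert threshold 1.5)\n",
            attr(outcomes, "hit_rate"), attr(outcomes, "fa_rate"),
            attr(outcomes, "dprime")))
write.table(outcomes, file.path(out, "outcomes.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
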