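#!/usr/bin/env Rscript
# Step 1: simulate raw two-wavelength fNIRS recordings for a cohort of
# synthetic subjects -- one calibration and one online session each, with
# the default block design (10 two-back blocks interleaved with 11 relax
# blocks) and physiological noise. Raw series are large and go under
# scratch/; results/ receives the cohort manifest.

suppressMessages(library(nirstate))

base_seed <- 42L
n_subjects <- 12L # the study cohort size
raw_dir <- "scratch/analysis/raw"
dir.create(raw_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

manifest <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
  subject <- sprintf("SIM%02d", i)
  out <- lapply(c(calibration = 0L, online = 1L), function(offset) {
    seed <- base_seed + 2L * i + offset
    s <- simulate_session(sim_config(seed = seed))
    path <- file.path(raw_dir, sprintf(
      "%s_%s.tsv", subject,
      if (offset == 0L) "calibration" else "online"
    ))
    write_recording(s$recording, path)
    data.frame(
      subject = subject,
      session = if (offset == 0L) "calibration" else "online",
      seed = seed,
      n_samples = nrow(s$recording$intensity),
      n_events = nrow(s$recording$events),
      duration_s = s$design$total_duration,
      path = path
    )
  })
  rbind(out$calibration, out$online)
}))

write.table(manifest, "results/01_cohort_manifest.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat(sprintf(
  "simulated %d subjects x 2 sessions (%.0f s each at 10 Hz, 12 channels x 2 wavelengths)\n",
  n_subjects, manifest$duration_s[1]
))
cat("raw recordings under", raw_dir, "- manifest in results/01_cohort_manifest.tsv\n")
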