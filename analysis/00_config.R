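# Shared configuration for the analysis drivers. Each numbered script can
# be run from the repository root with Rscript; intermediate (binary)
# artifacts live under scratch/, tables under results/.

library(trwmap)

cfg <- list(
  seed = 1L,
  stimulus_s = 255,       # 4'15" excerpt
  silence_s = 3,          # silent lead-in per run
  tr = 1.5,               # seconds
  sample_rate = 12000,    # Hz, synthetic audio
  crossfade_s = 0.010,
  level_params = list(    # measure / phrase / section durations (s)
    measure = list(mean = 1.29, sd = 0.12),
    phrase = list(mean = 6.32, sd = 1.91),
    section = list(mean = 38.28, sd = 12.46)),
  grid = c(12, 12, 12),
  n_subjects = 15,
  alpha = 1, sigma = 1,   # stimulus-locked amplitude / noise sd
  n_perm = 500,           # phase-randomization replicates
  q_star = 0.05,
  crop_trs = 15,
  cutoff_hz = 0.01,

  stim_dir = "scratch/stimuli",
  cohort_dir = "scratch/cohort",
  preproc_dir = "scratch/preproc",
  isc_dir = "scratch/isc",
  results_dir = "results"
)

dir.create(cfg$results_dir, showWarnings = FALSE, recursive = TRUE)
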