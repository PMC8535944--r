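# Shared fixtures, built in code at test time.

# A clean normal recording with known beat times.
clean_recording <- function(bpm = 60, duration = 8, snr_db = 30, seed = 7,
                            class_label = "normal") {
  cfg <- synth_config(duration = duration, bpm = bpm, snr_db = snr_db,
                      seed = seed)
  synth_recording(cfg, class_label)
}

# Short seeded segments for feature tests.
seeded_segment <- function(n = 1600, seed = 1, sample_rate = 2000) {
  set.seed(seed)
  pcg_recording(stats::rnorm(n), sample_rate, id = paste0("seg", seed))
}

# The challenge corpus split counts, used as manifest input.
pascal_count_manifest <- function() {
  data.frame(
    split = c("A", "B", "A", "B", "noisy_murmur", "A", "B", "noisy_normal"),
    label = c("normal", "normal", "murmur", "murmur", "murmur",
              "extrasystole", "extrasystole", "normal"),
    count = c(31, 200, 34, 66, 29, 19, 46, 120),
    stringsAsFactors = FALSE
  )
}
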