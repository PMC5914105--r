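# Simulate the 30-sample study: ten chromatograms for each of the three
# fermented Cordyceps product classes (Jinshuibao-capsule-like,
# Jinshuibao-tablet-like, Bailing-capsule-like), with known true contents.
source("analysis/00_config.R")

st <- generate_study(study_config())

for (sid in names(st$samples))
  write_chromatogram(st$samples[[sid]],
                     file.path(study_dir, paste0(sid, ".txt")))
save_tsv(st$metadata, file.path(study_dir, "sample_metadata.tsv"))
save_tsv(st$truth, file.path(study_dir, "ground_truth.tsv"))

message(sprintf("simulated %d chromatograms (%d per class), %d common peaks",
                length(st$samples), study_config()$samples_per_class,
                nrow(default_peak_specs())))
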