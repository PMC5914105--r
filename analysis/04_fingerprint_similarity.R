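# Standardize every chromatogram (retention-time warp onto the template),
# build the pooled mean fingerprint and score each sample's cosine and
# Pearson similarity against it, plus class-level means.
source("analysis/00_config.R")

meta <- read_tsv(file.path(study_dir, "sample_metadata.tsv"))
matched <- read_tsv(file.path(tables_dir, "peak_table.tsv"))

traces <- lapply(meta$sample_id, function(sid) {
  ch <- read_chromatogram(file.path(study_dir, paste0(sid, ".txt")))
  m <- matched[matched$sample_id == sid, ]
  fingerprint_vector(normalize_retention(ch, m), mode = "trace")
})
names(traces) <- meta$sample_id

reference <- build_reference(traces)
classes <- setNames(meta$class, meta$sample_id)
rep <- similarity_report(traces, reference, classes = classes)
save_tsv(rep, file.path(tables_dir, "similarity.tsv"))
cm <- attr(rep, "class_means")
save_tsv(data.frame(class = names(cm), mean_cosine = as.numeric(cm)),
         file.path(tables_dir, "similarity_class_means.tsv"))
message(sprintf("per-sample cosine range %.4f-%.4f; class means: %s",
                min(rep$cosine), max(rep$cosine),
                paste(sprintf("%s %.3f", names(cm), cm), collapse = ", ")))
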