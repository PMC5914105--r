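# Hierarchical cluster analysis of the common-peak-area fingerprints:
# cosine distance, between-groups (average) linkage, and the two-group cut
# expected to isolate the Bailing-like samples.
source("analysis/00_config.R")

meta <- read_tsv(file.path(study_dir, "sample_metadata.tsv"))
matched <- read_tsv(file.path(tables_dir, "peak_table.tsv"))

pv <- lapply(meta$sample_id, function(sid)
  fingerprint_vector(matched[matched$sample_id == sid, ], mode = "peaks"))
names(pv) <- meta$sample_id

d <- cosine_distance_matrix(pv)
tree <- hca_between_groups(d)
tree_newick(tree, file.path(tables_dir, "dendrogram.nwk"))
writeLines(tree_text(tree), file.path(tables_dir, "dendrogram.txt"))

groups <- data.frame(sample_id = meta$sample_id, class = meta$class,
                     group_k2 = unname(cut_groups(tree, 2L)[meta$sample_id]),
                     group_k3 = unname(cut_groups(tree, 3L)[meta$sample_id]))
save_tsv(groups, file.path(tables_dir, "groups.tsv"))
message("k = 2 split by class:")
print(table(groups$class, groups$group_k2))
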