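#!/usr/bin/env Rscript
# Stage 3: mixed-type association structure, skewness, and a Mapper
# topological summary of the experiment space.

suppressMessages(library(hazardbn))

final <- read.csv("results/02_final_features.csv", stringsAsFactors = FALSE)

assoc <- association_matrix(final)
write_association_matrix(assoc, csv_path = "results/03_associations.csv",
                         json_path = "results/03_associations.json")

num_cols <- names(final)[vapply(final, is.numeric, NA)]
skew <- vapply(final[num_cols], skewness, 0)
write.csv(data.frame(feature = names(skew), skewness = round(skew, 2)),
          "results/03_skewness.csv", row.names = FALSE)

cat("association matrix over", ncol(assoc$matrix), "columns written\n")
off <- abs(assoc$matrix)
off[lower.tri(off, diag = TRUE)] <- NA
strongest <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
cat(sprintf("strongest off-diagonal association: %s ~ %s (%.2f)\n",
            rownames(assoc$matrix)[strongest[[1]]],
            colnames(assoc$matrix)[strongest[[2]]],
            assoc$matrix[strongest[[1]], strongest[[2]]]))
cat("features outside the +/-2 skewness band:",
    paste(names(skew)[abs(skew) > 2], collapse = ", "), "\n")

X <- final[, setdiff(num_cols, "viability")]
mg <- mapper_graph(X, lens = final$viability, n_intervals = 10,
                   overlap = 0.3, linkage_threshold = 0.6)
write_mapper_graph(mg, "results/03_mapper.graphml")
cat(sprintf("Mapper summary: %d nodes, %d edges covering %d rows\n",
            length(mg$nodes), nrow(mg$edges),
            length(unique(unlist(lapply(mg$nodes, `[[`, "members"))))))
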