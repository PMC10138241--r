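#!/usr/bin/env Rscript
# Translate the trained weights into strengths of association (SA),
# filter to the maximum-SA spanning tree -- the semantic connectivity map
# -- and identify its hubs. Exports edge CSV, GraphML and DOT.

suppressPackageStartupMessages(library(autocmap))

fit <- read_autocm("results/model")
map <- connectivity_map(fit)

export_map(map, "results/map_edges.csv", format = "edge_csv")
export_map(map, "results/map_all_pairs.csv", format = "edge_csv",
           edges = "all")
export_map(map, "results/map.graphml", format = "graphml")
export_map(map, "results/map.dot", format = "dot")

cat(sprintf("map: %d nodes, %d tree edges, SA %.2f-%.2f\n",
            length(map$nodes), nrow(map$edges), min(map$edges$sa),
            max(map$edges$sa)))
deg <- table(c(map$edges$node_a, map$edges$node_b))
cat(sprintf("hub(s) (tree degree %d): %s\n", max(deg),
            paste(map$hubs, collapse = ", ")))
cat("strongest connections:\n")
top <- utils::head(map$edges[order(-map$edges$sa), ], 5)
for (k in seq_len(nrow(top))) {
  cat(sprintf("  %s -- %s  SA = %.2f\n", top$node_a[k], top$node_b[k],
              top$sa[k]))
}
cat("wrote results/map_edges.csv, map_all_pairs.csv, map.graphml, map.dot\n")
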