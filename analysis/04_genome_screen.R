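#!/usr/bin/env Rscript
# Genome screen on 50 seeded synthetic genomes with planted routes, degraded
# and split operons, decoys and sub-threshold spurious hits. Writes
# results/screen_results.csv and results/screen_truth_comparison.csv.

suppressMessages(library(rglypath))

dir.create("results", showWarnings = FALSE)
ruleset <- load_ruleset()

plan <- genome_plan(n_genomes = 50, seed = 91, emit_sequences = FALSE)
g <- make_genomes(plan, ruleset)

res <- screen(g$hits, ruleset, genome_map = g$genome_map)
write.csv(res, "results/screen_results.csv", row.names = FALSE)

merged <- merge(g$truth, res, by = "genome", suffixes = c(".truth", ""))
comparison <- data.frame(
  genome = merged$genome,
  route_planted = merged$route_planted,
  intactness = merged$intactness,
  route_A_truth = merged$route_A.truth, route_A_called = merged$route_A,
  route_B_truth = merged$route_B.truth, route_B_called = merged$route_B,
  agree = merged$route_A == merged$route_A.truth &
          merged$route_B == merged$route_B.truth &
          merged$both_routes == merged$both_routes.truth,
  stringsAsFactors = FALSE)
write.csv(comparison, "results/screen_truth_comparison.csv", row.names = FALSE)

cat("Screen vs planted truth on", nrow(comparison), "genomes:",
    sum(comparison$agree), "agree,", sum(!comparison$agree), "disagree\n\n")
print(table(route = comparison$route_planted,
            intactness = comparison$intactness))
cat("\nDegraded operons (below the per-complex minimum) and operons split by\n",
    "more than the 20-kb window are called absent; sub-threshold spurious\n",
    "hits never flip a call.\n", sep = "")
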