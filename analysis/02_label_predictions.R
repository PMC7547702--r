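#!/usr/bin/env Rscript
# Predicted 13C mass-isotopomer signatures of the two glycine-assimilation
# routes under a labelled-formate tracer (99 atom-% 13C formate, CO2 pool at
# natural abundance), plus the idealized tracer for reference. Writes
# results/predicted_mids.csv.

suppressMessages(library(rglypath))

model <- load_pathway_model()
dir.create("results", showWarnings = FALSE)

tracers <- list(ideal = tracer_config(list(formate = 1, CO2 = 0)),
                experiment = tracer_config())  # 0.99 / 0.0107

rows <- list()
for (tn in names(tracers)) {
  for (route in c("GR", "serine")) {
    mids <- predict_amino_acid_mids(route, tracers[[tn]], model)
    for (m in names(mids)) {
      v <- as.numeric(mids[[m]])
      rows[[length(rows) + 1]] <- data.frame(
        tracer = tn, route = route, metabolite = m,
        m_shift = seq_along(v) - 1, fraction = v, stringsAsFactors = FALSE)
    }
  }
}
preds <- do.call(rbind, rows)
write.csv(preds, "results/predicted_mids.csv", row.names = FALSE)

dominant <- subset(preds, tracer == "ideal" & fraction > 0.5)
cat("Dominant isotopomer per metabolite (ideal tracer):\n")
print(reshape(dominant[, c("route", "metabolite", "m_shift")],
              idvar = "metabolite", timevar = "route", direction = "wide"),
      row.names = FALSE)
cat("\nBoth routes single-label glycine and double-label serine; they part\n",
    "company at pyruvate (M+1 via glycine reductase vs M+2 via serine\n",
    "deaminase), and the shift propagates into alanine, valine, leucine,\n",
    "threonine, proline, PEP, 3-PG and aspartate.\n", sep = "")
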