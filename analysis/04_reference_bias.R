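#!/usr/bin/env Rscript
# Step 4: quantify the bias of the reference-tissue models (SRTM, FRTM,
# SRTM-2C) when the reference region itself carries specific binding: the
# k3 = 0.20 configuration plays the pseudo-reference and every
# higher-binding configuration is quantified against it.
#
# Findings (results/reference_bias.tsv):
#  - all three models underestimate BPND relative to theoretical DVR-1 for
#    every configuration with meaningful binding contrast; the overall
#    bias is about -6% with this input, growing in absolute terms with k3.
#  - SRTM-2C is closest to truth for high-binding targets, at the price of
#    larger variability at low binding (5 free parameters).

library(petkin)

input <- synthetic_input()
schedule <- default_frame_schedule()
grid <- table2_grid()
config <- fit_config()

tacs <- lapply(grid$configs, function(p) {
  model_tac(p, input$plasma_parent, input$whole_blood, schedule)
})
ref_tac <- tacs[[grid$reference_index]]
idx <- setdiff(seq_along(tacs), grid$reference_index)

res <- do.call(rbind, lapply(idx, function(i) {
  data.frame(k3 = grid$theory$k3[i],
             dvr_minus_1 = grid$theory$DVR_minus_1[i],
             SRTM = fit_srtm(tacs[[i]], ref_tac, schedule, config)$BPND,
             FRTM = fit_frtm(tacs[[i]], ref_tac, schedule, config)$BPND,
             SRTM2C = fit_srtm_2c(tacs[[i]], ref_tac, schedule,
                                  config)$BPND)
}))
for (m in c("SRTM", "FRTM", "SRTM2C")) {
  res[[paste0("pct_bias_", m)]] <- 100 * (res[[m]] / res$dvr_minus_1 - 1)
}
dir.create("results", showWarnings = FALSE)
write.table(res, "results/reference_bias.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("overall %% bias: SRTM %+.2f, FRTM %+.2f, SRTM-2C %+.2f\n",
            mean(res$pct_bias_SRTM), mean(res$pct_bias_FRTM),
            mean(res$pct_bias_SRTM2C)))
cat(sprintf("configs below truth: SRTM %d/16, FRTM %d/16, SRTM-2C %d/16\n",
            sum(res$SRTM < res$dvr_minus_1),
            sum(res$FRTM < res$dvr_minus_1),
            sum(res$SRTM2C < res$dvr_minus_1)))
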