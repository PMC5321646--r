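#!/usr/bin/env Rscript
# Step 2: fit 1TCM, 2TCM and spectral analysis to the noiseless TAC of
# every grid configuration and compare AIC and VT recovery.
#
# Findings (written to results/noiseless_preference.tsv):
#  - AIC always prefers the 2TCM on these three-tissue TACs, and the AIC
#    gap shrinks monotonically as specific binding (k3) grows: at high
#    binding the non-specific compartment is proportionally invisible.
#  - The 1TCM underestimates VT badly at low binding (-47% at k3 = 0.20)
#    but approaches the 2TCM at high binding (-1.8% at k3 = 2.60).
#  - Spectral analysis tracks the theoretical VT within ~0.1% everywhere.

library(petkin)

input <- synthetic_input()
schedule <- default_frame_schedule()
grid <- table2_grid()
config <- fit_config()

rows <- lapply(seq_along(grid$configs), function(i) {
  tac <- model_tac(grid$configs[[i]], input$plasma_parent,
                   input$whole_blood, schedule)
  f1 <- fit_compartment_model(tac, input$plasma_parent, input$whole_blood,
                              schedule, "1T", config)
  f2 <- fit_compartment_model(tac, input$plasma_parent, input$whole_blood,
                              schedule, "2T", config)
  sa <- spectral_fit(tac, input$plasma_parent, schedule,
                     vB = config$vB_fixed, whole_blood = input$whole_blood)
  data.frame(k3 = grid$theory$k3[i], VT_true = grid$theory$VT[i],
             aic_1T = f1$aic, aic_2T = f2$aic, aic_gap = f1$aic - f2$aic,
             VT_1T = f1$macro$VT, VT_2T = f2$macro$VT, VT_SA = sa$VT)
})
res <- do.call(rbind, rows)
res$pct_err_1T <- 100 * (res$VT_1T / res$VT_true - 1)
res$pct_err_2T <- 100 * (res$VT_2T / res$VT_true - 1)
res$pct_err_SA <- 100 * (res$VT_SA / res$VT_true - 1)

dir.create("results", showWarnings = FALSE)
write.table(res, "results/noiseless_preference.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("2TCM preferred on %d/17 configs; AIC gap %0.1f -> %0.1f\n",
            sum(res$aic_gap > 0), res$aic_gap[1], res$aic_gap[17]))
cat(sprintf("VT %%err at k3=0.20: 1T %+.1f, 2T %+.1f, SA %+.2f\n",
            res$pct_err_1T[1], res$pct_err_2T[1], res$pct_err_SA[1]))
cat(sprintf("VT %%err at k3=2.60: 1T %+.1f, 2T %+.1f, SA %+.2f\n",
            res$pct_err_1T[17], res$pct_err_2T[17], res$pct_err_SA[17]))
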