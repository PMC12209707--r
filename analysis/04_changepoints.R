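#!/usr/bin/env Rscript
# Bayesian piecewise-linear decomposition of each predicted trajectory:
# breakpoint ages with 95% credible intervals, mean slopes (mL/year)
# between breakpoints, plateau scan and peak age.

library(lifespiro)

dir.create("results", showWarnings = FALSE)
for (sex in c("F", "M")) {
  for (param in c("FEV1", "FVC")) {
    stem <- sprintf("results/trajectory_%s_%s", sex, param)
    pred <- read.csv(paste0(stem, ".csv"))
    s <- trend_series(pred$age, pred$mean)
    post <- decompose_trend(s, seed = 20260922L)
    bp <- call_breakpoints(post)
    sl <- segment_slopes(s, post, bp)
    pk <- peak_estimate(s, post, bp)
    pl <- plateau_scan(post)
    jsonlite::write_json(
      list(sex = sex, parameter = param, breakpoints = bp, slopes = sl,
           peak = pk, plateaus = pl),
      sprintf("results/changepoints_%s_%s.json", sex, param),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(sign_probabilities(post),
              sprintf("results/sign_probs_%s_%s.csv", sex, param),
              row.names = FALSE)
    cat(sprintf("%s %s: breakpoints at %s; slopes %s mL/y; peak %.0f (%.0f-%.0f); %d plateau(s)\n",
                sex, param,
                paste(sprintf("%.0f (%.0f-%.0f)", bp$age, bp$lo95, bp$hi95),
                      collapse = ", "),
                paste(round(sl$slope_mL_yr), collapse = "/"),
                pk$age, pk$lo95, pk$hi95, nrow(pl)))
  }
}
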