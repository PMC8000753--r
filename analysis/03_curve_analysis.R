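#!/usr/bin/env Rscript
# Stage 3: three-region analysis of the embedding force-distance curves.
#
# Averages the replicates into a mean line with an SD band, detects the
# linear region II, and fits the region-II regression (slope a, intercept b,
# R^2). Writes the mean line, the fit report, and a figure.

suppressPackageStartupMessages(library(scaffembed))
dir.create("results", showWarnings = FALSE)

curves <- read_force_curves("results/force_curves.csv")
ml <- mean_curve(curves)
seg <- detect_regions(ml)
fit <- fit_region2(ml, seg)
print(fit)

write.csv(ml, "results/mean_curve.csv", row.names = FALSE)
write_region_fit(fit, "results/region2_fit.json")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(ml, aes(displacement_mm, mean_N)) +
    geom_ribbon(aes(ymin = mean_N - sd_N, ymax = mean_N + sd_N),
                fill = "steelblue", alpha = 0.3) +
    geom_line(colour = "steelblue") +
    geom_vline(xintercept = c(fit$b1, fit$b2), linetype = 2) +
    geom_abline(slope = fit$a, intercept = fit$b, colour = "black",
                linetype = 3) +
    labs(x = "embedding displacement (mm)", y = "embedding force (N)",
         title = sprintf("region II: a = %.2f N/mm, b = %.2f N, R² = %.4f",
                         fit$a, fit$b, fit$r_squared))
  ggsave("results/mean_curve.png", p, width = 7, height = 4.5, dpi = 150)
  message("wrote results/mean_curve.png")
}
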