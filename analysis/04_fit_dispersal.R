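#!/usr/bin/env Rscript
# Stage 4 -- dispersal probability and dispersal distance models.
#
# Binomial mixed model for the per-recapture dispersal indicator over
# all events, Gaussian mixed model for the distance (km) over dispersed
# events; credible intervals from 2000 simulated posterior draws of the
# fixed effects. Writes table2.csv, table3_distance.csv and the
# dispersal-vs-elevation figure.

suppressPackageStartupMessages(library(elevcmr))

seed <- 2012L
out <- file.path("results", "tables")
farms <- read_farms(file.path("results", "sim", "farms.csv"))
events <- utils::read.csv(file.path(out, "events_with_shift.csv"),
                          stringsAsFactors = FALSE)
events$dispersed <- events$dispersed == 1
std <- standardize(farms$elevation)$standardizer

prob_fit <- fit_glmm_binomial(build_design(events, "probability", farms, std))
prob_sim <- simulate_posterior(prob_fit, n_draws = 2000, seed = seed)
print(prob_fit)
write.csv(cbind(prob_sim$table[, c("label", "estimate", "lo95", "hi95")],
                row.names = NULL),
          file.path(out, "table2.csv"), row.names = FALSE)

disp <- events[events$dispersed, ]
message(nrow(disp), " dispersal events; mean distance ",
        round(mean(disp$distance[disp$age_class == "adult"]), 2),
        " km (breeding) / ",
        round(mean(disp$distance[disp$age_class == "juvenile"]), 2),
        " km (natal)")
dist_fit <- fit_lmm_gaussian(build_design(disp, "distance", farms, std))
dist_sim <- simulate_posterior(dist_fit, n_draws = 2000, seed = seed)
write.csv(dist_sim$table[, c("label", "estimate", "lo95", "hi95")],
          file.path(out, "table3_distance.csv"), row.names = FALSE)

grid <- seq(min(farms$elevation), max(farms$elevation), length.out = 50)
pdf(file.path(out, "dispersal_vs_elevation.pdf"), 7, 5)
cols <- c(adult_male = "steelblue", adult_female = "firebrick",
          juvenile_male = "lightblue3", juvenile_female = "salmon")
plot(NULL, xlim = range(grid), ylim = c(0, 1),
     xlab = "Elevation (m a.s.l.)", ylab = "Dispersal probability")
for (cls in names(cols)) {
  cv <- predict_dispersal_curve(prob_fit, grid, cls, seed = seed)
  lines(cv$elevation, cv$median, col = cols[[cls]], lwd = 2,
        lty = if (grepl("juvenile", cls)) 2 else 1)
}
legend("bottomleft", legend = names(cols), col = cols, lwd = 2, bty = "n")
dev.off()
message("dispersal tables and figure written to ", out)
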