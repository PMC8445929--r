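#!/usr/bin/env Rscript
# Stage 3 -- fit the hierarchical survival model.
#
# Cormack-Jolly-Seber likelihood with age/sex/elevation/edge effects,
# farm and year random intercepts, and the categorical sex mixture for
# unsexed nestlings, sampled with the adaptive Metropolis sampler
# (3 chains here; expect a few minutes on one CPU). Writes the
# parameter table, the posterior draws and the survival-vs-elevation
# figure under results/.

suppressPackageStartupMessages(library(elevcmr))

seed <- 2012L
inp <- file.path("results", "sim")
out <- file.path("results", "tables")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

farms <- read_farms(file.path(inp, "farms.csv"))
captures <- read_captures(file.path(inp, "captures.csv"), farms)
std <- standardize(farms$elevation)$standardizer
histories <- build_histories(captures, farms, range(captures$year), std)
dat <- prepare_cjs_data(histories, farms)
message(dat$n_total, " histories (", dat$n_recaptured, " recaptured), ",
        length(dat$first), " unique weighted rows")

post <- fit_cjs(dat, cjs_mcmc_config(n_chains = 3, n_iter = 30000,
                                     n_burn = 15000, thin = 10), seed = seed)
print(post)

tab1 <- post$summary[, c("label", "mean", "lo95", "hi95", "ess", "rhat")]
names(tab1)[1] <- "parameter"
write.csv(tab1, file.path(out, "table1.csv"), row.names = FALSE)
write.csv(as.data.frame(post$draws), file.path(out, "survival_draws.csv"),
          row.names = FALSE)

grid <- seq(min(farms$elevation), max(farms$elevation), length.out = 50)
pdf(file.path(out, "survival_vs_elevation.pdf"), 7, 5)
cols <- c(adult_male = "steelblue", adult_female = "firebrick",
          juvenile = "black")
plot(NULL, xlim = range(grid), ylim = c(0, 1),
     xlab = "Elevation (m a.s.l.)", ylab = "Apparent survival")
for (cls in names(cols)) {
  cv <- predict_survival_curve(post, grid, std, cls)
  polygon(c(cv$elevation, rev(cv$elevation)), c(cv$lo95, rev(cv$hi95)),
          col = grDevices::adjustcolor(cols[[cls]], 0.25), border = NA)
  lines(cv$elevation, cv$median, col = cols[[cls]], lwd = 2)
}
legend("topright", legend = names(cols), col = cols, lwd = 2, bty = "n")
dev.off()
message("survival table and figure written to ", out)
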