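#!/usr/bin/env Rscript
# Coupled wave-seagrass pattern formation.
#
# Runs the coupled linearized simulator under the default study conditions
# (forcing at 0.96 a*, seeded noise) for 25 forcing periods, then measures
# the emerged pattern: wavenumber spectrum, dominant-mode ratio, growth rate
# and crest spacing. Writes the final fields and the spectrum.

suppressMessages(library(braggrass))
dir.create("results", showWarnings = FALSE)

seed <- 1
cfg <- default_pattern_config(seed = seed)
cat(sprintf("== Pattern formation ==\nforcing a = %.3f m (0.96 a*), T = %g s\n",
            cfg$wp$a, cfg$wp$T))

res <- run_simulation(cfg)
bs <- res$basic_state
cat(sprintf("basic state: n0 = %.3f, H0 = %.2f m, forcing wavelength %.1f m\n",
            bs$n0, bs$H0, res$lam))

ps <- pattern_spectrum(res$n1, res$grid, res$kappa)
r <- growth_rate(res)
cs <- crest_spacing(res$n1, res$grid, min_sep = res$lam / 4)
cat(sprintf("after %d periods: dominant wavenumber ratio k_n1*/k = %.3f\n",
            res$n_periods_run, ps$ratio))
cat(sprintf("growth rate of the Bragg mode: %+0.3f per forcing period\n", r))
cat(sprintf("crest spacing: %.1f m = %.3f of the forcing wavelength\n",
            cs, cs / res$lam))

fields <- data.frame(x = res$grid$x, eta1 = res$eta1, n1 = res$n1,
                     tau_b1 = res$tau_b1, interior = res$grid$interior)
write.csv(fields, "results/pattern_fields.csv", row.names = FALSE)
write.csv(data.frame(k = ps$k, power = ps$power),
          "results/pattern_spectrum.csv", row.names = FALSE)
write_manifest(cfg, "results/03_manifest.json",
               extra = list(stage = "pattern_formation",
                            dominant_ratio = ps$ratio, growth_rate = r))
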