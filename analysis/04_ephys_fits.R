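#!/usr/bin/env Rscript
# Voltage-clamp and current-clamp analysis chain on synthetic recordings:
# leak subtraction, tail-current activation Boltzmann, double-Boltzmann
# steady-state inactivation, toxin-subtraction current isolation, recovery
# kinetics, and action-potential thresholds from ramp and step protocols.

suppressPackageStartupMessages(library(kv64pain))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

fits <- list()

# activation: leaky, noisy sweeps -> leak subtraction -> tail curve -> fit
sp <- ephys_spec(noise_sd = 10, leak_g_ns = 1.5)
act <- gen_sweeps(sp, "activation", seed = seed)
clean <- leak_subtract(act$series, c(-110, -80))
f_act <- fit_boltzmann(tail_activation_curve(clean))
cat(sprintf("Activation (truth V50 = %g, k = %g): fitted V50 = %.2f mV, k = %.2f mV\n",
            sp$activation$v_half, sp$activation$slope,
            f_act$v_half, f_act$slope))
fits$activation <- data.frame(curve = "activation", top = f_act$top,
                              v_half = f_act$v_half, slope = f_act$slope,
                              rms = f_act$rms)

# steady-state inactivation: double Boltzmann availability
spi <- ephys_spec(noise_sd = 5)
ina <- gen_sweeps(spi, "inactivation", seed = seed + 1L)
f_ina <- fit_double_boltzmann(availability_curve(ina$series),
                              seed = seed, decreasing = TRUE)
cat(sprintf(paste0(
  "Inactivation (truth V1 = %g, V2 = %g, F = %g): fitted V1 = %.1f mV, ",
  "V2 = %.1f mV, F = %.2f%s\n"),
  spi$inactivation$v_half_1, spi$inactivation$v_half_2,
  spi$inactivation$fraction, f_ina$v_half_1, f_ina$v_half_2,
  f_ina$fraction, if (f_ina$degenerate) " [degenerate]" else ""))
fits$inactivation <- data.frame(curve = "inactivation", top = f_ina$top,
                                v_half = f_ina$v_half_1,
                                slope = f_ina$slope_1, rms = f_ina$rms)

# toxin-sensitive current isolation
pair <- gen_sweeps(ephys_spec(noise_sd = 0), "sctx_pair", seed = seed)
sens <- sctx_subtract(pair$pre, pair$post)
mr <- max_fractional_reduction(pair$pre, pair$post)
cat(sprintf("Toxin-sensitive current: maximal reduction %.1f%% at the %+d mV step\n",
            100 * mr$reduction, as.integer(mr$voltage)))

# recovery from inactivation
rec <- gen_sweeps(ephys_spec(noise_sd = 0.03), "recovery", seed = seed + 2L)
f_rec <- fit_recovery(rec$intervals, rec$ratios)
cat(sprintf("Recovery (truth tau = 500 ms): fitted tau = %.0f ms, A = %.2f\n",
            f_rec$tau, f_rec$amplitude))

# action-potential thresholds
ramp <- gen_sweeps(ephys_spec(), "ramp", seed = seed)
steps <- gen_sweeps(ephys_spec(), "step", seed = seed)
thr_ramp <- ap_threshold_ramp(ramp$trace)
thr_step <- ap_threshold_step(steps$steps)
cat(sprintf(
  "AP threshold: ramp %.0f pA, step %.0f pA (analytic rheobase %.0f pA)\n",
  thr_ramp, thr_step, ramp$truth$rheobase))

out <- do.call(rbind, fits)
out <- rbind(out, data.frame(curve = "recovery", top = NA,
                             v_half = NA, slope = NA, rms = f_rec$rms))
write_tsv_dot(out, "results/ephys_fits.tsv")
write_tsv_dot(data.frame(measure = c("sctx_max_reduction_pct",
                                     "ramp_threshold_pa",
                                     "step_threshold_pa",
                                     "analytic_rheobase_pa",
                                     "recovery_tau_ms"),
                         value = c(100 * mr$reduction, thr_ramp, thr_step,
                                   ramp$truth$rheobase, f_rec$tau)),
             "results/ephys_measures.tsv")
cat("Wrote results/ephys_fits.tsv and results/ephys_measures.tsv\n")
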