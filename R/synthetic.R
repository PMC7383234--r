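#' Evaluate code under a local, explicit RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so generators are pure functions of (spec, seed) and
#' leave no global side effects.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Cohort specification for the genotype generator
#'
#' The null model is binomial sampling of each SNP's rare-allele (or
#' carrier) counts at its reference frequency; enrichment is simulated by
#' multiplying selected SNPs' frequencies (`spike`), emulating the study
#' design of a discovery cohort of 100 exomes scanned against population
#' reference frequencies such as the 0.0072 carrier frequency of the
#' KCNG4 rare allele in 18,878 European reference individuals.
#'
#' @param n_individuals Cohort size.
#' @param n_snps Number of SNPs.
#' @param freq_range Reference-frequency range; frequencies are drawn
#'   log-uniformly over it unless `freq_uniform = TRUE` (plain uniform).
#' @param spike Optional data frame with columns `index` and `multiplier`,
#'   plus an optional `ref_freq` column pinning the spiked SNPs' reference
#'   frequencies instead of drawing them.
#' @param dropout Per-individual, per-SNP probability of a missing call
#'   (reduces `n_assessed`), in `[0, 1)`.
#' @param ref_freq_kind `"carrier"` or `"allele"`.
#' @param ref_cohort_size Reference cohort size attached to every SNP, or
#'   `NA` to force the goodness-of-fit layout downstream.
#' @param freq_uniform Draw frequencies uniformly instead of log-uniformly.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_individuals = 100, n_snps = 2000,
                        freq_range = c(1e-4, 0.5), spike = NULL,
                        dropout = 0, ref_freq_kind = c("carrier", "allele"),
                        ref_cohort_size = NA, freq_uniform = FALSE) {
  ref_freq_kind <- match.arg(ref_freq_kind)
  stopifnot(n_individuals >= 1, n_snps >= 1, dropout >= 0, dropout < 1,
            length(freq_range) == 2, all(freq_range > 0),
            all(freq_range <= 1))
  if (!is.null(spike)) {
    stopifnot(all(c("index", "multiplier") %in% names(spike)),
              all(spike$multiplier >= 0),
              all(spike$index >= 1 & spike$index <= n_snps))
  }
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 freq_range = freq_range, spike = spike, dropout = dropout,
                 ref_freq_kind = ref_freq_kind,
                 ref_cohort_size = ref_cohort_size,
                 freq_uniform = freq_uniform),
            class = "cohort_spec")
}

#' Generate a synthetic SNP cohort table with ground truth
#'
#' Draws per-SNP reference frequencies from the spec's range, applies spike
#' multipliers (capped at frequency 1), thins coverage by the dropout
#' probability, and samples counts binomially: in carrier mode,
#' `carrier_count ~ Binom(n_assessed, f)` with all carriers heterozygous;
#' in allele mode, genotype counts are multinomial under Hardy-Weinberg at
#' allele frequency `f`, giving consistent `rare_allele_count` and
#' `carrier_count`. Annotation columns default to an all-pass state
#' (deleterious missense, in the gene set, no ortholog/artifact flags) so
#' the filter cascade is exercised via explicit overrides in fixtures.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with `records` (a SNP table accepted by [snp_scan()]) and
#'   `truth` (`snp_id`, `ref_freq`, `multiplier`, `spiked`).
#' @export
gen_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(seed, {
    n <- spec$n_snps
    f <- if (spec$freq_uniform) {
      stats::runif(n, spec$freq_range[1], spec$freq_range[2])
    } else {
      exp(stats::runif(n, log(spec$freq_range[1]), log(spec$freq_range[2])))
    }
    mult <- rep(1, n)
    if (!is.null(spec$spike)) {
      mult[spec$spike$index] <- spec$spike$multiplier
      if ("ref_freq" %in% names(spec$spike)) {
        f[spec$spike$index] <- spec$spike$ref_freq
      }
    }
    f_true <- pmin(f * mult, 1)
    n_assessed <- stats::rbinom(n, spec$n_individuals, 1 - spec$dropout)
    if (spec$ref_freq_kind == "carrier") {
      carrier <- stats::rbinom(n, n_assessed, f_true)
      rare <- carrier  # heterozygous carriers
    } else {
      hom <- stats::rbinom(n, n_assessed, f_true^2)
      het <- stats::rbinom(n, n_assessed - hom,
                           ifelse(f_true < 1,
                                  2 * f_true * (1 - f_true) / (1 - f_true^2),
                                  0))
      het[f_true == 1] <- 0
      carrier <- hom + het
      rare <- 2 * hom + het
    }
    ids <- sprintf("rs%06d", seq_len(n))
    records <- data.frame(
      snp_id = ids,
      gene = sprintf("GENE%04d", seq_len(n)),
      consequence = "missense_deleterious",
      in_gene_set = TRUE,
      ortholog_common_flag = FALSE,
      artifact_flag = "none",
      n_assessed = n_assessed,
      rare_allele_count = rare,
      carrier_count = carrier,
      ref_freq = f,
      ref_freq_kind = spec$ref_freq_kind,
      ref_cohort_size = spec$ref_cohort_size,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(snp_id = ids, ref_freq = f, multiplier = mult,
                        spiked = mult != 1, stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Generate two Gaussian groups at stated summary parameters
#'
#' Emulates a two-group sensory-testing outcome: independent normal samples
#' at the given means and SDs, returned with their exact sample summaries
#' so summary-statistic and raw-data tests can be cross-checked.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group parameters; SDs must be > 0.
#' @param seed Integer seed.
#' @return List with `x`, `y` and their [summarize_group()] summaries.
#' @export
gen_qst_groups <- function(n1, mean1, sd1, n2, mean2, sd2, seed) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  with_local_seed(seed, {
    x <- stats::rnorm(n1, mean1, sd1)
    y <- stats::rnorm(n2, mean2, sd2)
    list(x = x, y = y, summary1 = summarize_group(x),
         summary2 = summarize_group(y))
  })
}

#' Electrophysiology generator specification
#'
#' Ground-truth parameters for the sweep generators: a Boltzmann activation
#' curve, a (double) Boltzmann availability curve, exponential recovery, a
#' linear leak, Gaussian noise, and a leaky-integrate-and-fire (LIF) cell
#' for current-clamp traces. The LIF is a minimal spiking stand-in, not a
#' biophysical Kv2.1 model.
#'
#' @param activation List `(top, v_half, slope)`.
#' @param inactivation List `(top, fraction, v_half_1, slope_1, v_half_2,
#'   slope_2)`; set `fraction = 1` for a single component.
#' @param recovery List `(amplitude, tau)` in ms.
#' @param lif List `(v_rest, v_th, r_mohm, tau_ms)`; resistance in MOhm.
#' @param leak_g_ns Leak conductance, nS.
#' @param noise_sd Additive Gaussian noise SD (pA for current traces,
#'   normalized units for curve points).
#' @param i_max Maximal channel current, pA.
#' @param voltages Command-voltage grid, mV.
#' @param dt Sample interval, ms.
#' @return An `ephys_spec` list.
#' @export
ephys_spec <- function(activation = list(top = 1, v_half = -20, slope = 9.5),
                       inactivation = list(top = 1, fraction = 0.4,
                                           v_half_1 = -30, slope_1 = 10,
                                           v_half_2 = -60, slope_2 = 12),
                       recovery = list(amplitude = 0.8, tau = 500),
                       lif = list(v_rest = -60, v_th = -40,
                                  r_mohm = 100, tau_ms = 10),
                       leak_g_ns = 0, noise_sd = 0, i_max = 2000,
                       voltages = seq(-110, 40, by = 10), dt = 0.5) {
  stopifnot(noise_sd >= 0, i_max > 0, dt > 0,
            activation$slope > 0, recovery$tau > 0,
            lif$r_mohm > 0, lif$tau_ms > 0)
  structure(list(activation = activation, inactivation = inactivation,
                 recovery = recovery, lif = lif, leak_g_ns = leak_g_ns,
                 noise_sd = noise_sd, i_max = i_max, voltages = voltages,
                 dt = dt),
            class = "ephys_spec")
}

gen_activation_series <- function(spec, step_ms = 200, tail_ms = 200,
                                  tail_mv = -60, tau_tail = 20) {
  act <- spec$activation
  tg <- seq(0, step_ms + tail_ms - spec$dt, by = spec$dt)
  sweeps <- lapply(spec$voltages, function(v) {
    open <- boltzmann(v, act$top, act$v_half, act$slope)
    vcmd <- ifelse(tg < step_ms, v, tail_mv)
    i_chan <- ifelse(tg < step_ms,
                     spec$i_max * open,
                     spec$i_max * open * exp(-(tg - step_ms) / tau_tail))
    i <- i_chan + spec$leak_g_ns * vcmd +
      stats::rnorm(length(tg), 0, spec$noise_sd)
    list(command = v, time = tg, value = i, vcmd = vcmd)
  })
  sweep_series("activation", sweeps, holding = -90,
               metadata = list(tail_start_ms = step_ms, tail_mv = tail_mv))
}

gen_inactivation_series <- function(spec, test_mv = 50, test_ms = 200,
                                    prepulse_ms = 0, tau_slow = 500,
                                    availability = NULL) {
  ina <- spec$inactivation
  avail_fun <- availability %||% function(v) {
    double_boltzmann(v, ina$top, ina$fraction, ina$v_half_1, ina$slope_1,
                     ina$v_half_2, ina$slope_2, decreasing = TRUE)
  }
  tg <- seq(0, test_ms - spec$dt, by = spec$dt)
  sweeps <- lapply(spec$voltages, function(v) {
    a <- avail_fun(v)
    i <- spec$i_max * a * exp(-tg / tau_slow) +
      spec$leak_g_ns * test_mv +
      stats::rnorm(length(tg), 0, spec$noise_sd)
    list(command = v, time = tg, value = i,
         vcmd = rep(test_mv, length(tg)))
  })
  sweep_series("inactivation", sweeps, holding = -90,
               metadata = list(test_start_ms = 0, test_mv = test_mv,
                               conditioning_ms = 5000))
}

#' Generate synthetic sweep series or traces for a protocol
#'
#' Produces inputs with the structure each analysis step assumes, plus the
#' generating ground truth:
#' * `"activation"`: step + tail sweeps whose tail amplitudes follow the
#'   spec's Boltzmann activation curve (tail decay tau 20 ms), with
#'   optional linear leak and Gaussian noise.
#' * `"inactivation"`: double-pulse test currents scaled by the (double)
#'   Boltzmann availability of the conditioning voltage.
#' * `"recovery"`: interval/ratio points from `1 - A exp(-dt/tau)`.
#' * `"ramp"`: LIF membrane-voltage trace under a 0-1 nA, 1 s ramp.
#' * `"step"`: LIF trace family under +10 pA, 50 ms increments.
#' * `"sctx_pair"`: paired pre/post series where the pre current is the sum
#'   of two Boltzmann-activated components and the post series retains only
#'   the toxin-insensitive component, so subtraction recovers the first.
#'
#' @param spec An [ephys_spec()].
#' @param protocol One of the protocols above.
#' @param seed Integer seed (noise and any jitter).
#' @param ... Protocol options passed to the internal builders.
#' @return For sweep protocols, a list with `series` (or `pre`/`post`) and
#'   `truth`; for `"recovery"`, `intervals`, `ratios` and `truth`; for
#'   `"ramp"`/`"step"`, the trace(s) and the analytic `truth`.
#' @export
gen_sweeps <- function(spec, protocol = c("activation", "inactivation",
                                          "recovery", "ramp", "step",
                                          "sctx_pair"),
                       seed = 1, ...) {
  stopifnot(inherits(spec, "ephys_spec"))
  protocol <- match.arg(protocol)
  with_local_seed(seed, switch(protocol,
    activation = list(series = gen_activation_series(spec, ...),
                      truth = spec$activation),
    inactivation = list(series = gen_inactivation_series(spec, ...),
                        truth = spec$inactivation),
    recovery = {
      intervals <- c(10, 20, 50, 100, 200, 500, 1000, 2000, 5000)
      rec <- spec$recovery
      ratios <- 1 - rec$amplitude * exp(-intervals / rec$tau) +
        stats::rnorm(length(intervals), 0, spec$noise_sd)
      list(intervals = intervals, ratios = pmin(pmax(ratios, 0), 1.2),
           truth = rec)
    },
    ramp = {
      trace <- lif_ramp_trace(spec$lif, dt = spec$dt, ...)
      list(trace = trace,
           truth = c(spec$lif,
                     rheobase = lif_rheobase(spec$lif)))
    },
    step = {
      steps <- lif_step_family(spec$lif, dt = spec$dt, ...)
      list(steps = steps,
           truth = c(spec$lif, rheobase = lif_rheobase(spec$lif)))
    },
    sctx_pair = gen_sctx_pair(spec, ...)
  ))
}

# Paired pre/post-toxin step series. Defaults are calibrated so the
# toxin-sensitive fraction of steady-state current rises with voltage and
# reaches ~52.7% at the +20 mV step (the study's maximum-reduction point).
gen_sctx_pair <- function(spec, step_ms = 200,
                          voltages = seq(-80, 20, by = 10),
                          sensitive = list(v_half = 0, slope = 8,
                                           i_max = 1128),
                          resistant = list(v_half = -20, slope = 15,
                                           i_max = 1000)) {
  tg <- seq(0, step_ms - spec$dt, by = spec$dt)
  comp <- function(v, prm) prm$i_max * boltzmann(v, 1, prm$v_half, prm$slope)
  mk <- function(include_sensitive) {
    sweeps <- lapply(voltages, function(v) {
      i <- comp(v, resistant) +
        (if (include_sensitive) comp(v, sensitive) else 0) +
        spec$leak_g_ns * v +
        stats::rnorm(length(tg), 0, spec$noise_sd)
      list(command = v, time = tg, value = i,
           vcmd = rep(v, length(tg)))
    })
    sweep_series("activation", sweeps, holding = -90,
                 metadata = list(tail_start_ms = step_ms))
  }
  s20 <- comp(max(voltages), sensitive)
  list(pre = mk(TRUE), post = mk(FALSE),
       truth = list(sensitive = sensitive, resistant = resistant,
                    reduction_at_max = s20 /
                      (s20 + comp(max(voltages), resistant))))
}

#' Analytic rheobase of the LIF cell
#'
#' Minimal sustained current that reaches threshold at steady state:
#' `(v_th - v_rest) / R`.
#'
#' @param lif List with `v_rest`, `v_th` (mV) and `r_mohm` (MOhm).
#' @return Rheobase, pA.
#' @export
lif_rheobase <- function(lif) {
  (lif$v_th - lif$v_rest) / lif$r_mohm * 1000
}

# Integrate the LIF membrane equation under injected current i_pa(t):
# tau dV/dt = -(V - v_rest) + R * I. A crossing of v_th produces a
# stereotyped spike sample at +30 mV followed by reset to v_rest.
simulate_lif <- function(lif, i_pa, dt) {
  n <- length(i_pa)
  v <- numeric(n)
  v[1] <- lif$v_rest
  r_mv_per_pa <- lif$r_mohm / 1000
  refractory <- 0
  for (k in 2:n) {
    if (refractory > 0) {
      v[k] <- lif$v_rest
      refractory <- refractory - 1
      next
    }
    dv <- (-(v[k - 1] - lif$v_rest) + r_mv_per_pa * i_pa[k - 1]) / lif$tau_ms
    v[k] <- v[k - 1] + dt * dv
    if (v[k] >= lif$v_th) {
      v[k] <- 30  # stereotyped spike peak
      refractory <- max(1L, round(2 / dt))
    }
  }
  v
}

lif_ramp_trace <- function(lif, dt = 0.5, i_end_pa = 1000,
                           duration_ms = 1000) {
  tg <- seq(0, duration_ms, by = dt)
  i <- i_end_pa * tg / duration_ms
  list(time = tg, voltage = simulate_lif(lif, i, dt), current = i)
}

lif_step_family <- function(lif, dt = 0.5, step_pa = 10, max_pa = 1000,
                            step_ms = 50) {
  tg <- seq(0, step_ms, by = dt)
  levels <- seq(step_pa, max_pa, by = step_pa)
  lapply(levels, function(lv) {
    list(current = lv, time = tg,
         voltage = simulate_lif(lif, rep(lv, length(tg)), dt))
  })
}

#' Generate a synthetic single-cell Cq matrix
#'
#' Bernoulli positivity per gene and population with Gaussian Cq values for
#' positive wells (truncated below the calling threshold), `NA` sentinel for
#' no amplification, a housekeeping gene positive in every cell except
#' requested QC-failure cells, and optional bath-control columns.
#'
#' @param pops Named integer vector of population sizes,
#'   e.g. `c(TL = 44, LS = 45)`.
#' @param p_pos Named list per gene of either a single probability or a
#'   named vector of per-population probabilities.
#' @param cq_mean Named numeric vector of mean Cq for positive cells.
#' @param cq_sd Common Cq SD.
#' @param housekeeping Housekeeping gene name (always positive).
#' @param hk_cq_mean Housekeeping mean Cq.
#' @param n_qc_fail Number of cells (per run) with a failed housekeeping
#'   reaction.
#' @param n_bath Number of bath-control columns (expected all-negative).
#' @param contaminate_bath Force one bath column positive for one gene
#'   (to exercise the contamination flag).
#' @param threshold Calling threshold used for truncation, cycles.
#' @param seed Integer seed.
#' @return A `cq_matrix`: list with `cq` (genes x cells matrix),
#'   `population` (per cell), `is_bath` (per cell), `housekeeping`.
#' @export
gen_cq_matrix <- function(pops = c(TL = 44, LS = 45),
                          p_pos = list(Kcng4 = c(TL = 19 / 44, LS = 11 / 45),
                                       Kcnb1 = c(TL = 36 / 44, LS = 30 / 45),
                                       Trpv1 = 0.95, Scn10a = 0.93),
                          cq_mean = c(Kcng4 = 27.2, Kcnb1 = 16.3,
                                      Trpv1 = 24, Scn10a = 25),
                          cq_sd = 1.5, housekeeping = "Gapdh",
                          hk_cq_mean = 16, n_qc_fail = 0, n_bath = 0,
                          contaminate_bath = FALSE, threshold = 35,
                          seed = 1) {
  stopifnot(length(pops) >= 1, !is.null(names(pops)))
  genes <- c(names(p_pos), housekeeping)
  with_local_seed(seed, {
    n_cells <- sum(pops) + n_bath
    population <- c(rep(names(pops), pops), rep("bath", n_bath))
    is_bath <- population == "bath"
    cq <- matrix(NA_real_, nrow = length(genes), ncol = n_cells,
                 dimnames = list(genes, NULL))
    rtrunc_cq <- function(n, m) {
      # normal truncated above at the calling threshold
      u <- stats::runif(n, 0, stats::pnorm(threshold, m, cq_sd))
      stats::qnorm(u, m, cq_sd)
    }
    for (g in names(p_pos)) {
      pr <- p_pos[[g]]
      p_cell <- if (length(pr) == 1) rep(pr, n_cells)
                else unname(pr[population])
      p_cell[is_bath] <- 0
      pos <- stats::runif(n_cells) < p_cell
      cq[g, pos] <- rtrunc_cq(sum(pos), cq_mean[[g]])
    }
    hk_pos <- !is_bath
    if (n_qc_fail > 0) {
      fail <- sample(which(!is_bath), n_qc_fail)
      hk_pos[fail] <- FALSE
    }
    cq[housekeeping, hk_pos] <- rtrunc_cq(sum(hk_pos), hk_cq_mean)
    if (contaminate_bath && n_bath > 0) {
      cq[names(p_pos)[1], which(is_bath)[1]] <- 30
    }
    structure(list(cq = cq, population = population, is_bath = is_bath,
                   housekeeping = housekeeping, threshold = threshold),
              class = "cq_matrix")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
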