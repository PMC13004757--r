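# shorter f-I protocol for test speed; rates stabilize immediately in a
# deterministic LIF so only rate quantization is affected
fast_fi <- function(neuron, ...) {
  fi_curve(neuron, duration = 4000, settle = 500, ...)
}

test_that("simulated f-I curves match the analytic LIF rate", {
  np <- neuron_params(Cm = 580, g_leak = 4)
  fi <- fast_fi(np)
  expect_equal(fi$rates[1], 0)  # 0 nA is subthreshold
  ana <- lif_rate_analytic(np, fi$currents)
  sup <- fi$currents > 0.1
  expect_true(all(abs(fi$rates[sup] - ana[sup]) / ana[sup] < 0.02))
  expect_true(all(diff(fi$rates) >= 0))
  # all-subthreshold protocol: zero AUC
  fi0 <- fast_fi(np, currents = c(0, 0.02, 0.04))
  expect_equal(fi0$auc, 0)
})

test_that("AUC decreases monotonically with capacitance", {
  aucs <- vapply(c(400, 580, 800, 1200), function(cm)
    fast_fi(neuron_params(Cm = cm, g_leak = 4))$auc, 0)
  expect_true(all(diff(aucs) < 0))
})

test_that("capacitance mapping: ratio method reproduces the printed pairs", {
  expect_equal(capacitance_from_auc(1, 1, method = "ratio"), 1)
  # 6.7% and 16.1% AUC reductions -> +7.2% and +19.2% capacitance
  expect_equal(capacitance_from_auc(1 - 0.067, 1), 1.072, tolerance = 1e-3)
  expect_equal(capacitance_from_auc(1 - 0.161, 1), 1.192, tolerance = 1e-3)
  # exposed exponent
  expect_equal(capacitance_from_auc(0.9, 1, exponent = 2), (1 / 0.9)^2)
})

test_that("capacitance fit round-trips and agrees with the ratio method", {
  np <- neuron_params(Cm = 580, g_leak = 4)
  ref_auc <- fast_fi(np)$auc
  # round trip: set Cm*, compute its AUC, recover Cm* within 1%
  target <- fast_fi(neuron_params(Cm = 700, g_leak = 4))$auc
  cm <- capacitance_from_auc(target, method = "fit", neuron = np,
                             duration = 4000, settle = 500)
  expect_equal(cm, 700, tolerance = 0.01)
  # near-linearity: fit and ratio agree within 5% for a 6.7% change
  cm2 <- capacitance_from_auc((1 - 0.067) * ref_auc, method = "fit",
                              neuron = np, duration = 4000, settle = 500)
  ratio2 <- 580 * capacitance_from_auc((1 - 0.067) * ref_auc, ref_auc)
  expect_lt(abs(cm2 - ratio2) / ratio2, 0.05)
})

test_that("perturbations transform the network as specified", {
  net <- build_mmn_network(mmn_params(), seed = 1)
  # magnitude 1 leaves the network unchanged
  same <- apply_perturbation(net, "capacitance_scale", 1)
  expect_equal(same$populations, net$populations)
  # capacitance scaling hits exactly the excitatory populations
  up <- apply_perturbation(net, "capacitance_scale", 1.192)
  for (nm in c("EO", "ES", "ED", "EP", "EP2", "ESD", "EDD"))
    expect_equal(up$populations[[nm]]$neuron$Cm,
                 net$populations[[nm]]$neuron$Cm * 1.192)
  for (nm in c("IS", "ID"))
    expect_equal(up$populations[[nm]]$neuron$Cm,
                 net$populations[[nm]]$neuron$Cm)
  # conductance scaling multiplies AMPA/NMDA onto targeted populations
  dn <- apply_perturbation(net, "excitatory_conductance_scale", 0.81)
  pr0 <- Filter(function(p) p$target == "EO", net$projections)[[1]]
  pr1 <- Filter(function(p) p$target == "EO", dn$projections)[[1]]
  expect_equal(pr1$kinetics[[1]]$g_max, pr0$kinetics[[1]]$g_max * 0.81)
  expect_error(apply_perturbation(net, "capacitance_scale", 2,
                                  targets = "QQ"), "unknown")
})

test_that("cortical output population behaves at the limits", {
  net <- build_mmn_network(co_fit_mmn_params(), n = 20, seed = 1)
  # zero noise, zero conductance: CO silent
  off <- attach_cortical_output(net, cortical_output_params(
    g_ampa = 0, noise_sd = 0))
  prot <- quick_protocol("frequency_deviant")
  rec <- run_protocol(off, prot, seed = 1)
  expect_identical(sum(rec$population == "CO"), 0L)
  # spontaneous rate increases with the noise SD (no EO input)
  rates <- vapply(c(1.25, 1.75, 2.5), function(ns) {
    co <- attach_cortical_output(net, cortical_output_params(
      g_ampa = 0, noise_sd = ns))
    r <- run_protocol(co, prot, seed = 1)
    sum(r$population == "CO")
  }, 0)
  expect_true(all(diff(rates) > 0))
  expect_error(attach_cortical_output(
    attach_cortical_output(net), cortical_output_params()), "already")
})

test_that("fitting the cortical output recovers a planted optimum", {
  net <- build_mmn_network(co_fit_mmn_params(), n = 20, seed = 1)
  prot <- quick_protocol("frequency_deviant")
  # degenerate single-cell grid returns that cell
  f1 <- fit_cortical_output(net, g_grid = 2000, noise_grid = 1.5,
                            protocol = prot, seeds = 1)
  expect_equal(f1$best$g_ampa, 2000)
  expect_equal(f1$best$noise_sd, 1.5)
  # plant targets generated at a known cell; the fit must select it
  planted <- cortical_output_params(g_ampa = 3000, noise_sd = 1.75)
  rr <- co_response_rates(attach_cortical_output(net, planted), prot,
                          seeds = 1:2)
  f2 <- fit_cortical_output(net, target_rates = c(rr$standard, rr$deviant),
                            g_grid = c(500, 3000), noise_grid = c(0.5, 1.75),
                            protocol = prot, seeds = 1:2)
  expect_equal(f2$best$g_ampa, 3000)
  expect_equal(f2$best$noise_sd, 1.75)
})

test_that("synthetic cohorts have the stated group structure", {
  tab <- synthesize_subject_aucs(215, 211, mean_reduction = 0.161,
                                 region = "PFC", seed = 3)
  expect_identical(nrow(tab), 426L)
  # control mean normalized to exactly 1
  expect_equal(mean(tab$auc_norm[tab$group == "CTRL"]), 1)
  expect_true(all(tab$auc_norm > 0))
  # SCZ mean within the CLT band around 1 - 0.161
  scz <- tab$auc_norm[tab$group == "SCZ"]
  expect_gt(mean(scz), 0.80)
  expect_lt(mean(scz), 0.88)
  expect_identical(tab,
                   synthesize_subject_aucs(215, 211, 0.161, region = "PFC",
                                           seed = 3))
  # no reduction: group means agree
  t0 <- synthesize_subject_aucs(300, 300, mean_reduction = 0, seed = 5)
  expect_lt(abs(mean(t0$auc_norm[t0$group == "SCZ"]) - 1), 0.03)
})
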