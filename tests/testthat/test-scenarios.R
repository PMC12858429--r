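healthy_cfg <- healthy_network()

v1_pconnect <- function(cfg) {
  vapply(Filter(function(p) p$pre %in% c("V1RG", "Ia_F", "Ia_E",
                                         "RC_F", "RC_E"),
                cfg$projections), `[[`, 0, "p_connect")
}

test_that("the early stage halves V1 connection probabilities exactly", {
  p45 <- apply_stage(healthy_cfg, "P45")
  expect_equal(v1_pconnect(p45), v1_pconnect(healthy_cfg) * 0.5)
  # the printed worked example: 28% -> 14%
  expect_equal(0.28 * stage_table("P45")$v1_projection_scale, 0.14)
  # non-V1 projections untouched
  other <- function(cfg) vapply(Filter(function(p)
    !p$pre %in% c("V1RG", "Ia_F", "Ia_E", "RC_F", "RC_E"),
    cfg$projections), `[[`, 0, "p_connect")
  expect_identical(other(p45), other(healthy_cfg))
})

test_that("the healthy stage is the identity transform", {
  expect_identical(apply_stage(healthy_cfg, "healthy"), healthy_cfg)
  iv <- intervention_config()   # all defaults off
  expect_identical(apply_intervention(healthy_cfg, iv,
                                      healthy = healthy_cfg), healthy_cfg)
  # stabilization factor exactly 1 is also the identity
  iv1 <- intervention_config(stabilize_v1 = 1)
  expect_identical(apply_intervention(healthy_cfg, iv1,
                                      healthy = healthy_cfg), healthy_cfg)
})

test_that("cell survival rounds to the nearest whole neuron", {
  for (case in list(c(0.5, 25), c(0.7, 36), c(0.33, 10), c(0.99, 7),
                    c(0.1, 14), c(0.45, 61), c(1, 50), c(0.66, 33),
                    c(0.8, 41), c(0.05, 9))) {
    s <- case[1]; n <- case[2]
    cfg <- network_config(list(population_spec("V2a_F", n)), list())
    st <- stage_config("P63", survival = list(V2a_F = s))
    got <- apply_stage(cfg, st)$populations$V2a_F$n
    expect_identical(got, max(1L, as.integer(round(s * n))))
  }
  expect_error(stage_config("P63", survival = list(V1RG = 1.2)), "\\[0, 1\\]")
})

test_that("the late stage scales V0c-to-motoneuron weights only", {
  p112 <- apply_stage(healthy_cfg, "P112")
  scale <- stage_table("P112")$v0c_weight_scale
  expect_gt(scale, 1)
  for (j in seq_along(healthy_cfg$projections)) {
    pr0 <- healthy_cfg$projections[[j]]
    pr1 <- p112$projections[[j]]
    if (grepl("^V0c", pr0$pre) && grepl("^MNP", pr0$post)) {
      expect_equal(pr1$weight_mean, pr0$weight_mean * scale)
    } else {
      expect_equal(pr1$weight_mean, pr0$weight_mean)
    }
  }
  # drives never change across stages
  for (p in names(healthy_cfg$populations))
    expect_equal(p112$populations[[p]]$drive_mean,
                 healthy_cfg$populations[[p]]$drive_mean)
})

test_that("sparing restores exactly the spared population block", {
  p112 <- apply_stage(healthy_cfg, "P112")
  spared <- apply_intervention(p112, intervention_config(spare_v2a = TRUE),
                               healthy = healthy_cfg)
  expect_identical(spared$populations$V2a_F$n,
                   healthy_cfg$populations$V2a_F$n)
  expect_identical(spared$populations$V2a_E$n,
                   healthy_cfg$populations$V2a_E$n)
  # V1 populations remain degenerated
  expect_lt(spared$populations$V1RG$n, healthy_cfg$populations$V1RG$n)
  # frame property: nothing else changed relative to the stage transform
  rest <- setdiff(names(p112$populations), c("V2a_F", "V2a_E"))
  for (p in rest)
    expect_identical(spared$populations[[p]], p112$populations[[p]])
  expect_identical(spared$projections, p112$projections)
})

test_that("V1 rescue restores cells and probabilities; boost is separate", {
  p112 <- apply_stage(healthy_cfg, "P112")
  resc <- apply_intervention(p112, intervention_config(rescue_v1 = TRUE),
                             healthy = healthy_cfg)
  expect_identical(resc$populations$V1RG$n, healthy_cfg$populations$V1RG$n)
  expect_equal(v1_pconnect(resc), v1_pconnect(healthy_cfg))
  expect_error(intervention_config(rescue_v1 = TRUE, stabilize_v1 = 2),
               "mutually exclusive")
})

test_that("stabilization multiplies only surviving V1 weights", {
  p45 <- apply_stage(healthy_cfg, "P45")
  st <- apply_intervention(p45, intervention_config(stabilize_v1 = 2),
                           healthy = healthy_cfg)
  for (j in seq_along(p45$projections)) {
    pr0 <- p45$projections[[j]]; pr1 <- st$projections[[j]]
    f <- if (pr0$pre %in% c("V1RG", "Ia_F", "Ia_E", "RC_F", "RC_E")) 2 else 1
    expect_equal(pr1$weight_mean, pr0$weight_mean * f)
    expect_equal(pr1$p_connect, pr0$p_connect)  # probabilities untouched
  }
})

test_that("slow dynamics scale only the selected side's RC/Ia/MNP kinetics", {
  p45 <- apply_stage(healthy_cfg, "P45")
  slow <- apply_intervention(
    p45, intervention_config(slow_dynamics = "flexor", slow_factor = 2),
    healthy = healthy_cfg)
  targets <- c("RC_F->MNP_F", "Ia_F->MNP_F", "MNP_F->RC_F")
  for (j in seq_along(p45$projections)) {
    pr0 <- p45$projections[[j]]; pr1 <- slow$projections[[j]]
    key <- paste0(pr0$pre, "->", pr0$post)
    f <- if (key %in% targets) 2 else 1
    expect_equal(pr1$kinetics$tau_rise, pr0$kinetics$tau_rise * f)
    expect_equal(pr1$kinetics$tau_decay, pr0$kinetics$tau_decay * f)
  }
  # extensor-side projections bitwise unchanged under flexor-side slowing
  ext_idx <- which(vapply(p45$projections, function(p)
    p$pre %in% c("RC_E", "Ia_E", "MNP_E"), NA))
  expect_identical(slow$projections[ext_idx], p45$projections[ext_idx])

  sym <- apply_intervention(
    p45, intervention_config(slow_dynamics = "symmetric"),
    healthy = healthy_cfg)
  both <- c(targets, c("RC_E->MNP_E", "Ia_E->MNP_E", "MNP_E->RC_E"))
  n_scaled <- sum(vapply(seq_along(p45$projections), function(j)
    sym$projections[[j]]$kinetics$tau_decay >
      p45$projections[[j]]$kinetics$tau_decay, NA))
  expect_identical(n_scaled, length(both))
})

test_that("the condition matrix is canonical, named and closed under validation", {
  cm <- condition_matrix()
  expect_true(all(c("healthy", "P112_no_intervention",
                    "P45_slow_dynamics_stabilized") %in% names(cm)))
  expect_length(cm, 19)  # healthy baseline + 18 disease/intervention panels
  for (cond in cm) {
    cfg <- build_condition(cond, healthy = healthy_cfg)
    expect_length(validate_network(cfg), 0)
  }
})

test_that("degeneration shrinks the expected synapse count monotonically", {
  expected_synapses <- function(cfg) {
    sum(vapply(cfg$projections, function(pr) {
      np <- cfg$populations[[pr$pre]]$n
      if (pr$pre_subset != "all") {
        frac <- cfg$populations[[pr$pre]]$excitatory_fraction
        np <- round(np * if (pr$pre_subset == "excitatory") frac
                    else 1 - frac)
      }
      pr$p_connect * np * cfg$populations[[pr$post]]$n
    }, 0))
  }
  e <- vapply(c("healthy", "P45", "P63", "P112"), function(st)
    expected_synapses(apply_stage(healthy_cfg, st)), 0)
  expect_true(all(diff(e) < 0))
})
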