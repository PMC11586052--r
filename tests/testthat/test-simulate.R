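test_that("default design reproduces the study's isolate counts", {
  sim <- simulate_study(sim_config(seed = 2))
  expect_identical(nrow(sim$meta), 235L)
  expect_identical(sum(sim$meta$kingdom == "Bacteria"), 115L)
  expect_identical(sum(sim$meta$kingdom == "Fungi"), 120L)
  expect_identical(length(unique(sim$meta$leaf_id)), 12L)
  # one deficient control leaf with 5 bacteria
  tab <- table(sim$meta$leaf_id[sim$meta$kingdom == "Bacteria"])
  expect_identical(sort(unique(as.vector(tab))), c(5L, 10L))
})

test_that("simulation is deterministic under a seed, including written files", {
  s1 <- simulate_study(sim_config(seed = 5))
  s2 <- simulate_study(sim_config(seed = 5))
  expect_identical(s1$plates$absorbance, s2$plates$absorbance)
  s3 <- simulate_study(sim_config(seed = 6))
  expect_false(identical(s1$plates$absorbance, s3$plates$absorbance))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulated_study(s1, d1)
  write_simulated_study(s2, d2)
  for (f in c("plates.tsv", "metadata.tsv", "layout.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("written study files feed straight back through the plate reader", {
  sim <- simulate_study(sim_config(seed = 8, plots_per_treatment = 1L,
                                   plants_per_plot = 1L, bacteria_per_leaf = 2L,
                                   fungi_per_leaf = 2L, deficient_leaf = NULL))
  d <- withr::local_tempdir()
  write_simulated_study(sim, d)
  lay <- read_layout(file.path(d, "layout.tsv"))
  plates <- read_plates(file.path(d, "plates.tsv"), lay,
                        file.path(d, "metadata.tsv"))
  expect_equal(plates$absorbance, sim$plates$absorbance)
  expect_equal(plates$meta, sim$meta)
})

test_that("noiseless degenerate case returns the latent means exactly", {
  cfg <- sim_config(seed = 3, noise_sd = 0,
                    usage_prob = matrix(1, 2, 2,
                                        dimnames = list(c("Bacteria", "Fungi"),
                                                        c("control", "NPKu"))),
                    shape = matrix(Inf, 2, 2,
                                   dimnames = list(c("Bacteria", "Fungi"),
                                                   c("control", "NPKu"))),
                    isolate_sdlog = 0, leaf_sdlog = 0,
                    substrate_baseline = rep(1, 95))
  sim <- simulate_study(cfg)
  prof <- correct_and_threshold(sim$plates)
  expect_equal(unname(niche_width(prof)), rep(95L, 235))
  expect_equal(unname(evenness(prof)), rep(1, 235))
  # corrected OD equals the configured cell mean exactly
  f_ctl <- prof$meta$kingdom == "Fungi" & prof$meta$treatment == "control"
  expected <- 0.245 * cfg$treat_mult["Fungi", "control"]
  expect_true(all(abs(prof$od[f_ctl, ] - expected) < 1e-12))
})

test_that("simulated grand mean OD tracks the configured kingdom means", {
  # Monte-Carlo expectation check on ~200 isolates per kingdom
  sim <- simulate_study(sim_config(seed = 12))
  prof <- correct_and_threshold(sim$plates)
  for (k in c("Bacteria", "Fungi")) {
    sel <- prof$meta$kingdom == k
    grand <- mean(prof$od_clipped[sel, ])
    cfg <- sim_config()
    expected <- cfg$kingdom_mean[k] * mean(cfg$treat_mult[k, ]) *
      mean(cfg$usage_prob[k, ])
    # within 3 standard errors (SE dominated by isolate-level lognormal)
    se <- expected * 0.3 / sqrt(sum(sel))
    expect_lt(abs(grand - expected), 3 * se + 0.01)
  }
})

test_that("presets resolve with documented structure; unknown preset errors", {
  ps <- planted_effect_presets(seed = 4)
  expect_named(ps, c("null", "paper-like", "strong"))
  expect_true(all(ps$null$treat_mult[, "control"] == ps$null$treat_mult[, "NPKu"]))
  expect_true(all(ps$null$usage_prob[, "control"] == ps$null$usage_prob[, "NPKu"]))
  # paper-like: fungal NPKu has lower mean multiplier, usage, and shape
  pl <- ps[["paper-like"]]
  expect_lt(pl$treat_mult["Fungi", "NPKu"], pl$treat_mult["Fungi", "control"])
  expect_lt(pl$usage_prob["Fungi", "NPKu"], pl$usage_prob["Fungi", "control"])
  expect_lt(pl$shape["Fungi", "NPKu"], pl$shape["Fungi", "control"])
  # strong doubles the fungal gaps
  st <- ps$strong
  expect_equal(pl$treat_mult["Fungi", "control"] - st$treat_mult["Fungi", "NPKu"],
               2 * (pl$treat_mult["Fungi", "control"] - pl$treat_mult["Fungi", "NPKu"]))
  expect_error(sim_config("medium"), "unknown preset")
  expect_error(sim_config(bacteria_per_leaf = 0L, fungi_per_leaf = 0L,
                          deficient_leaf = NULL) |> simulate_study(),
               "zero isolates")
})

test_that("expected fungal niche width falls under NPKu in the paper-like preset", {
  # direct expectation under the config: usage probability drops 0.889 -> 0.823
  cfg <- sim_config()
  expect_lt(cfg$usage_prob["Fungi", "NPKu"] * 95,
            cfg$usage_prob["Fungi", "control"] * 95 - 5)
  # and realized NW follows at study size
  sim <- simulate_study(sim_config(seed = 15))
  prof <- correct_and_threshold(sim$plates)
  nw <- niche_width(prof); m <- prof$meta
  expect_lt(mean(nw[m$kingdom == "Fungi" & m$treatment == "NPKu"]),
            mean(nw[m$kingdom == "Fungi" & m$treatment == "control"]))
})

test_that("correlated distance generator hits its target correlation", {
  set.seed(75)
  d <- dist(matrix(rnorm(30 * 4), 30, 4))
  for (r in c(0.2, 0.55, 0.9)) {
    d2 <- simulate_correlated_distance(d, r, seed = 7)
    expect_equal(cor(as.vector(d), as.vector(d2)), r, tolerance = 1e-6)
    expect_true(all(as.vector(d2) >= 0))
  }
})
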