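# The directional overlap statistic: per substrate used by both isolates,
# min(OD_i/OD_j, 1); averaged over the full plate (denominator 95).

test_that("hand example shows the statistic's asymmetry", {
  od_i <- od_vec(0.4, 0.2, fill = 0)
  od_j <- od_vec(0.2, 0.004, fill = 0)   # j uses only substrate 1
  pi_ <- profiles_from_od(rbind(od_i, od_j), fix_meta(2))
  ui <- pi_$usage[1, ]; uj <- pi_$usage[2, ]
  expect_equal(pairwise_overlap(od_i, od_j, ui, uj), 1 / 95)
  expect_equal(pairwise_overlap(od_j, od_i, uj, ui), 0.5 / 95)
})

test_that("identical full profiles give 1; disjoint niches give 0 both ways", {
  full <- od_vec(fill = 0.3)
  u <- rep(TRUE, 95)
  expect_equal(pairwise_overlap(full, full, u, u), 1.0)
  a <- od_vec(rep(0.2, 40), fill = 0)
  b <- c(rep(0, 40), rep(0.2, 55))
  ua <- a >= 0.005; ub <- b >= 0.005
  expect_equal(pairwise_overlap(a, b, ua, ub), 0)
  expect_equal(pairwise_overlap(b, a, ub, ua), 0)
})

test_that("overlap invariants hold on random profiles", {
  set.seed(51)
  for (rep in 1:20) {
    od <- matrix(rgamma(2 * 95, 1, 10) * rbinom(2 * 95, 1, 0.7), 2, 95)
    prof <- profiles_from_od(od, fix_meta(2))
    u <- prof$usage; oc <- prof$od_clipped
    nw <- unname(niche_width(prof))
    # self-overlap = NW/95
    expect_equal(pairwise_overlap(oc[1, ], oc[1, ], u[1, ], u[1, ]), nw[1] / 95)
    # bounds
    o12 <- pairwise_overlap(oc[1, ], oc[2, ], u[1, ], u[2, ])
    expect_gte(o12, 0)
    expect_lte(o12, min(nw) / 95)
    # scale invariance
    expect_equal(pairwise_overlap(oc[1, ] * 3.7, oc[2, ] * 3.7, u[1, ], u[2, ]),
                 o12)
    # full coverage: i >= j everywhere j uses -> overlap = NW_j/95
    hi <- pmax(oc[1, ], oc[2, ]) + 0.01
    expect_equal(pairwise_overlap(hi, oc[2, ], rep(TRUE, 95), u[2, ]),
                 nw[2] / 95)
  }
})

test_that("vectorized implementation matches the naive loop oracle", {
  set.seed(52)
  for (rep in 1:200) {
    od <- matrix(rgamma(2 * 95, 1.5, 8) * rbinom(2 * 95, 1, 0.8), 2, 95)
    prof <- profiles_from_od(od, fix_meta(2, leaf = "L"))
    oc <- prof$od_clipped; u <- prof$usage
    expect_equal(pairwise_overlap(oc[1, ], oc[2, ], u[1, ], u[2, ]),
                 bf_overlap(oc[1, ], oc[2, ], u[1, ], u[2, ]),
                 tolerance = 1e-14)
  }
})

test_that("sympatric pair enumeration satisfies the m(m-1) identity", {
  meta <- fix_meta(5, kingdom = c("Bacteria", "Bacteria", "Fungi", "Fungi", "Fungi"))
  pu <- sympatric_pairs(meta)
  expect_identical(nrow(pu$pairs), 20L)  # 5*4
  cc <- as.vector(pu$counts[, "control"])
  names(cc) <- rownames(pu$counts)
  expect_identical(cc[c("B:B", "F:F", "B:F", "F:B")], c("B:B" = 2L, "F:F" = 6L,
                                                        "B:F" = 6L, "F:B" = 6L))
  # lone isolate on a leaf contributes no pairs
  meta2 <- rbind(meta, fix_meta(1, leaf = "lonely"))
  meta2$isolate_id[6] <- "solo"
  expect_identical(nrow(sympatric_pairs(meta2)$pairs), 20L)
})

test_that("study design yields 550 control and 600 NPKu B:F ordered pairs", {
  sim <- simulate_study(sim_config(seed = 1))
  expect_identical(sum(sim$meta$kingdom == "Bacteria"), 115L)
  expect_identical(sum(sim$meta$kingdom == "Fungi"), 120L)
  expect_identical(nrow(sim$meta), 235L)
  pu <- sympatric_pairs(sim$meta)
  expect_identical(unname(pu$counts["B:F", "control"]), 550L)
  expect_identical(unname(pu$counts["B:F", "NPKu"]), 600L)
})

test_that("overlap table is deterministic and summaries match cell counts", {
  sim <- simulate_study(sim_config(seed = 9, plots_per_treatment = 1L,
                                   plants_per_plot = 1L, bacteria_per_leaf = 3L,
                                   fungi_per_leaf = 3L, deficient_leaf = NULL))
  prof <- correct_and_threshold(sim$plates)
  ov1 <- overlap_table(prof)
  ov2 <- overlap_table(prof)
  expect_identical(ov1, ov2)
  expect_true(all(ov1$omega_bar >= 0 & ov1$omega_bar <= 1))
  smry <- group_overlap_summary(ov1)
  pu <- sympatric_pairs(prof$meta)
  for (k in seq_len(nrow(smry))) {
    expect_identical(smry$n[k],
                     unname(pu$counts[smry$pair_class[k], smry$treatment[k]]))
  }
  # empty cells undefined, constant cells sd 0
  empty <- smry[smry$n == 0, ]
  expect_true(all(is.na(empty$mean)))
})

test_that("fungi-dominant simulation gives mean F:B overlap above B:F", {
  sim <- simulate_study(sim_config(seed = 14))
  prof <- correct_and_threshold(sim$plates)
  smry <- group_overlap_summary(overlap_table(prof))
  fb <- smry$mean[smry$pair_class == "F:B"]
  bf <- smry$mean[smry$pair_class == "B:F"]
  expect_true(all(fb > bf))
})
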