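test_that("neighbor census matches hand counts on planted fibrils", {
  g <- generate_box(box_spec(box_edge = 50, fibrils = list(rep("XAN", 5L)),
                             seed = 1))
  # 3.4 A spacing: a 5 A centre cutoff sees only adjacent stack neighbors
  cen5 <- neighbor_census(g$frame, census_params(molecule_com_cutoff = 5))
  expect_identical(sort(cen5$per_obs$n_xanthine), c(1L, 1L, 2L, 2L, 2L))
  expect_equal(unname(cen5$means["n_xanthine"]), 8 / 5)
  # a 7 A cutoff also sees second neighbors at 6.8 A
  cen7 <- neighbor_census(g$frame, census_params(molecule_com_cutoff = 7))
  expect_identical(sort(cen7$per_obs$n_xanthine), c(2L, 2L, 3L, 3L, 4L))
  expect_equal(unname(cen7$means["n_xanthine"]), 14 / 5)
  # both agree with the O(N^2) brute-force oracle
  expect_identical(cen7$per_obs[, -1L],
                   oracle_census(g$frame, census_params(7, 5)))
  # single xanthine alone: zero neighbors
  g1 <- generate_box(box_spec(box_edge = 30, n_free_xanthine = 1, seed = 2))
  expect_equal(unname(neighbor_census(g1$frame)$means["n_xanthine"]), 0)
  gw <- generate_box(box_spec(box_edge = 30, n_water = 10, seed = 2))
  expect_error(neighbor_census(gw$frame), "no xanthine")
})

test_that("cell-list census equals the brute-force path on random boxes", {
  for (seed in 1:6) {
    g <- generate_box(box_spec(
      box_edge = runif(1, 18, 40),
      fibrils = if (seed %% 2) list(c("XAN", "AGT", "XAN")) else list(),
      n_free_xanthine = sample(2:6, 1), n_free_agent = sample(0:3, 1),
      n_water = sample(10:40, 1), seed = seed))
    cl <- neighbor_census(g$frame, method = "cell")
    br <- neighbor_census(g$frame, method = "brute")
    expect_identical(cl$per_obs, br$per_obs)
  }
})

test_that("census counts are monotone in the cutoff", {
  g <- generate_box(recovery_spec(17))
  prev <- NULL
  for (rc in c(4, 5.5, 7, 9, 12)) {
    cen <- neighbor_census(g$frame, census_params(rc, rc * 0.7))
    if (!is.null(prev)) {
      expect_true(all(cen$per_obs$n_xanthine >= prev$per_obs$n_xanthine))
      expect_true(all(cen$per_obs$n_agent >= prev$per_obs$n_agent))
      expect_true(all(cen$per_obs$n_water >= prev$per_obs$n_water))
    }
    prev <- cen
  }
})

test_that("axial classification recovers planted structure and rejects side-by-side pairs", {
  # coplanar side-by-side pair: zero axial displacement, no contact
  hex <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  fr <- make_frame(list(hex, sweep(hex, 2L, c(4, 0, 0), "+")),
                   c("xanthine", "xanthine"), 50, plane = list(1:6, 1:6))
  ax <- classify_axial(fr)
  expect_true(all(is.na(ax$up_mol)) && all(is.na(ax$down_mol)))
  # stacked pair at 3.4 A is a mutual axial contact
  fs <- make_frame(list(hex, sweep(hex, 2L, c(0, 0, 3.4), "+")),
                   c("xanthine", "xanthine"), 50, plane = list(1:6, 1:6))
  axs <- classify_axial(fs)
  expect_identical(sum(!is.na(c(axs$up_mol, axs$down_mol))), 2L)
  # planted boxes at zero noise: slot classification equals ground truth,
  # including the identity of each occupant
  for (seed in 1:5) {
    g <- generate_box(recovery_spec(seed))
    ax <- classify_axial(g$frame)
    tr <- g$truth
    xan <- tr$molecules$molecule_id[tr$molecules$role == "xanthine"]
    expect_identical(ax$k_slots, tr$molecules$planted_k[xan])
    up_true <- tr$axial$up_mol[xan]
    dn_true <- tr$axial$down_mol[xan]
    same <- (ax$up_mol %in% c(up_true, dn_true)) | is.na(ax$up_mol)
    expect_true(all(same))
    # occupant sets match as unordered pairs (the generator's "up" is the
    # fibril direction, the classifier's is the normal's arbitrary sign)
    for (q in seq_along(xan)) {
      expect_setequal(
        sort(c(ax$up_mol[q], ax$down_mol[q]), na.last = NA),
        sort(c(up_true[q], dn_true[q]), na.last = NA))
    }
  }
})

test_that("config distribution pools observations correctly", {
  g0 <- generate_box(box_spec(box_edge = 60, n_free_xanthine = 12, seed = 4))
  p0 <- config_distribution(classify_axial(g0$frame))
  expect_equal(unname(p0["P0"]), 1)
  expect_equal(sum(p0), 1)
  # mixed planted boxes: P matches the planted histogram at zero noise
  g <- generate_box(recovery_spec(9))
  ax <- classify_axial(g$frame)
  p <- config_distribution(ax)
  k_true <- g$truth$molecules$planted_k[g$truth$molecules$role == "xanthine"]
  expect_equal(as.numeric(unclass(p)),
               as.numeric(table(factor(k_true, 0:3)) / length(k_true)))
  # doubling every observation leaves P unchanged
  p2 <- config_distribution(rbind(ax, ax))
  expect_equal(unclass(p2), unclass(p), ignore_attr = TRUE)
})

test_that("agent efficiency implements the bias-corrected formula", {
  expect_equal(agent_efficiency(c(1, 0, 0, 0), 10, 5)$efficiency, 0)
  expect_equal(agent_efficiency(c(0, 1, 0, 0), 7, 7)$efficiency, 1)
  expect_equal(agent_efficiency(c(0.5, 0.5, 0, 0), 10, 5)$efficiency, 1.0)
  set.seed(8)
  for (rep in 1:20) {
    p <- diff(c(0, sort(runif(3)), 1))
    nx <- sample(5:40, 1); na <- sample(1:20, 1)
    e <- agent_efficiency(p, nx, na)
    expect_equal(e$efficiency, sum((0:3) * p) * nx / na)
    expect_gte(e$efficiency, 0)
  }
  expect_error(agent_efficiency(c(1, 0, 0, 0), 10, 0), "positive")
  # doubling the box (same P, doubled counts) leaves E unchanged
  e1 <- agent_efficiency(c(0.2, 0.5, 0.3, 0), 10, 4)
  e2 <- agent_efficiency(c(0.2, 0.5, 0.3, 0), 20, 8)
  expect_equal(e1$efficiency, e2$efficiency)
})

test_that("efficiency equals direct enumeration over planted boxes", {
  for (seed in c(21, 22, 23)) {
    g <- generate_box(recovery_spec(seed))
    roles <- molecule_roles(g$frame)
    ax <- classify_axial(g$frame)
    p <- config_distribution(ax)
    e <- agent_efficiency(p, sum(roles == "xanthine"), sum(roles == "agent"))
    direct <- sum(ax$k_slots) / sum(roles == "agent")
    expect_equal(e$efficiency, direct, tolerance = 1e-12)
  }
})

test_that("aggregate detection flags fibrils and distinguishes agent placement", {
  g <- generate_box(box_spec(box_edge = 50, fibrils = list(rep("XAN", 6L)),
                             seed = 1))
  agg <- detect_aggregates(g$frame)
  expect_identical(nrow(agg$components), 1L)
  expect_identical(agg$components$size, 6L)
  expect_true(agg$components$is_fibril)
  # two disjoint stacked pairs: two size-2 components, neither a fibril
  g2 <- generate_box(box_spec(box_edge = 50,
                              fibrils = list(rep("XAN", 2L), rep("XAN", 2L)),
                              seed = 2))
  agg2 <- detect_aggregates(g2$frame)
  expect_identical(agg2$components$size, c(2L, 2L))
  expect_false(any(agg2$components$is_fibril))
  # intercalated vs end-capped agents via interior-agent fraction
  gi <- generate_box(box_spec(box_edge = 50,
                              fibrils = list(c("XAN", "AGT", "XAN", "AGT",
                                               "XAN")), seed = 3))
  ge <- generate_box(box_spec(box_edge = 50,
                              fibrils = list(c("AGT", "XAN", "XAN", "XAN",
                                               "AGT")), seed = 3))
  ci <- detect_aggregates(gi$frame)$components
  ce <- detect_aggregates(ge$frame)$components
  expect_equal(ci$interior_agent_fraction, 1)
  expect_equal(ce$interior_agent_fraction, 0)
  expect_true(ci$is_fibril && ce$is_fibril)
})

test_that("intercalated agents lower the xanthine-xanthine neighbor count", {
  pure <- generate_box(box_spec(box_edge = 50,
                                fibrils = list(rep("XAN", 6L),
                                               rep("XAN", 6L)), seed = 5))
  mixed <- generate_box(box_spec(box_edge = 50,
                                 fibrils = list(
                                   c("XAN", "AGT", "XAN", "AGT", "XAN", "AGT"),
                                   c("XAN", "AGT", "XAN", "AGT", "XAN", "AGT")),
                                 seed = 5))
  prm <- census_params(molecule_com_cutoff = 5)
  expect_lt(neighbor_census(mixed$frame, prm)$means["n_xanthine"],
            neighbor_census(pure$frame, prm)$means["n_xanthine"])
})
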