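test_that("the regime grid is the Cartesian product with a separate baseline", {
  grid <- regime_grid(c(0.1, 0.15, 0.2, 0.25, 0.3), c(20, 40, 60))
  expect_equal(nrow(grid), 15)
  expect_equal(anyDuplicated(grid$id), 0)
  expect_equal(nrow(regime_grid(numeric(0), 20)), 0)
  expect_equal(nrow(regime_grid(0.1, c(20, 40, 60))), 3)
  # stable ordering: rebuilding gives identical tibbles
  expect_identical(grid, regime_grid(c(0.1, 0.15, 0.2, 0.25, 0.3),
                                     c(20, 40, 60)))
  full <- regime_set()
  expect_equal(nrow(full), 16)
  expect_equal(full$kind[1], "clearcut")
})

test_that("invalid regime parameters are rejected", {
  expect_error(regime_grid(c(0.1, 0.1), c(20)), "Duplicate")
  expect_error(gapcut_regime(0, 40))
  expect_error(gapcut_regime(1.2, 40))
  expect_error(gapcut_regime(0.3, 90), "rotation")
  expect_error(gapcut_regime(0.3, 42), "multiple")
})

test_that("stand states enforce the two-cohort invariants", {
  s <- stand_state(c(30, 70), c(0.3, 0.7))
  expect_equal(s$ages, c(70, 30)) # reordered oldest first
  expect_error(stand_state(c(10, 20, 30), c(0.2, 0.3, 0.5)), "1 or 2")
  expect_error(stand_state(c(10, 20), c(0.5, 0.4)), "sum to 1")
  expect_error(stand_state(12, 1), "multiples")
  # equal ages merge
  m <- stand_state(c(0, 0), c(0.3, 0.7))
  expect_length(m$ages, 1)
  expect_equal(m$shares, 1)
})

test_that("the scheduler emits harvest, gap cut and thinning at the right ages", {
  cc <- clearcut_regime()
  gc <- gapcut_regime(0.3, 40)
  a1 <- scheduled_actions(stand_state(85, 1, regime_id = "clearcut"), cc)
  expect_equal(a1$kind, c("final_harvest", "replant"))
  a2 <- scheduled_actions(stand_state(40, 1, regime_id = gc$id), gc)
  expect_equal(a2$kind, "gap_cut")
  expect_equal(a2$s_gap, 0.3)
  a3 <- scheduled_actions(
    stand_state(c(70, 30), c(0.7, 0.3), regime_id = gc$id), gc
  )
  expect_equal(a3$kind, c("thinning", "thinning"))
  # two-cohort stand at age_gap receives no second gap cut
  a4 <- scheduled_actions(
    stand_state(c(40, 20), c(0.7, 0.3), regime_id = gc$id), gc
  )
  expect_false("gap_cut" %in% a4$kind)
})

test_that("actions conserve shares and merge replants", {
  gc <- gapcut_regime(0.3, 40)
  s <- stand_state(40, 1, regime_id = gc$id)
  cut <- apply_action(s, scheduled_actions(s, gc)[1, ])
  expect_equal(cut$ages, c(40, 0))
  expect_equal(cut$shares, c(0.7, 0.3))
  expect_equal(cut$origins[2], "gap_regeneration")
  expect_equal(sum(cut$shares), 1)

  # both cohorts replanted at once merge into a single full-share cohort
  bare <- stand_state(c(40, 0), c(0.7, 0.3))
  bare$ages <- c(NA_real_, NA_real_)
  r1 <- apply_action(bare, tibble::tibble(kind = "replant", cohort = 1,
                                          s_gap = NA_real_))
  r2 <- apply_action(r1, tibble::tibble(kind = "replant", cohort = 2,
                                        s_gap = NA_real_))
  expect_length(r2$ages, 1)
  expect_equal(r2$shares, 1)
})

test_that("one hand-traced management cycle of a gap-cut regime", {
  # regime s = 0.3, age_gap = 40: follow the scheduler from the gap cut to
  # the leading cohort's final harvest
  gc <- gapcut_regime(0.3, 40)
  s <- stand_state(40, 1, regime_id = gc$id)
  s <- apply_action(s, scheduled_actions(s, gc)[1, ]) # (40, 0.7) + (0, 0.3)
  for (i in 1:9) { # nine 5-yr steps: ages 40/0 -> 85/45
    s <- stand_state(s$ages + 5, s$shares, s$origins, regime_id = gc$id)
  }
  expect_equal(s$ages, c(85, 45))
  acts <- scheduled_actions(s, gc)
  expect_equal(acts$kind, c("final_harvest", "replant", "thinning"))
  for (i in seq_len(nrow(acts))) s <- apply_action(s, acts[i, ])
  # former gap cohort leads, harvested share replanted at age 0
  expect_equal(s$ages, c(45, 0))
  expect_equal(s$shares, c(0.3, 0.7))
  expect_equal(s$origins[1], "gap_regeneration")
})

test_that("illegal actions name the violated invariant", {
  s <- stand_state(c(40, 20), c(0.7, 0.3))
  expect_error(
    apply_action(s, tibble::tibble(kind = "gap_cut", cohort = 1, s_gap = 0.3)),
    "single established cohort"
  )
  expect_error(
    apply_action(s, tibble::tibble(kind = "replant", cohort = 1,
                                   s_gap = NA_real_)),
    "bare"
  )
})

test_that("zero-hazard clear-cut is periodic with the rotation period", {
  tr <- deterministic_trajectory(clearcut_regime(), series_years = 600)
  # after the first cycle, states and cash flows repeat every 85 years
  i0 <- which(tr$t >= 85 & tr$t <= 600 - 85)
  i1 <- match(tr$t[i0] + 85, tr$t)
  expect_equal(tr$lead_age[i0], tr$lead_age[i1])
  expect_equal(tr$cf[i0], tr$cf[i1])
  expect_equal(tr$carbon[i0], tr$carbon[i1])
})

test_that("the engine visits exactly the breadth-first reachable state space", {
  for (regime in list(clearcut_regime(), gapcut_regime(0.3, 40))) {
    # long undisturbed run; regime id fixed so keys line up with the closure
    tr <- deterministic_trajectory(regime, series_years = 2000)
    visited <- unique(state_key(
      regime$id, tr$lead_age, tr$gap_age, tr$lead_share
    ))
    closure <- reachable_states(regime)
    expect_setequal(visited, closure$key)
  }
})
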