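# minimal window with two consecutive valid assemblages
toy_turnover <- function(s_prev, s_now, sti_vals) {
  sti <- data.frame(species = names(sti_vals), sti = unname(sti_vals),
                    n_records = 1L)
  asm <- rbind(
    data.frame(window_id = 1L, period = 0L, species = s_prev, n = 1L),
    data.frame(window_id = 1L, period = 1L, species = s_now, n = 1L))
  cti <- compute_cti(asm, sti)
  list(events = turnover_events(cti, asm, sti), cti = cti, sti = sti,
       asm = asm)
}

test_that("gained and lost species are the set differences", {
  tt <- toy_turnover(c("A", "B"), c("B", "C"),
                     c(A = 10, B = 12, C = 15))
  ev <- tt$events
  expect_equal(ev$species[ev$status == "gained"], "C")
  expect_equal(ev$species[ev$status == "lost"], "A")

  same <- toy_turnover(c("A", "B"), c("A", "B"), c(A = 10, B = 12))
  expect_equal(nrow(same$events), 0)

  # a window lacking a valid assemblage at t-1 contributes no events
  gap <- toy_turnover("A", c("B", "C"), c(A = 10, B = 12, C = 15))
  expect_equal(nrow(gap$events), 0)
})

test_that("rSTI is STI minus the previous-period CTI, with interpretable sign", {
  tt <- toy_turnover(c("A", "B"), c("A", "B", "C"),
                     c(A = 10, B = 14, C = 15))
  ev <- tt$events
  expect_equal(ev$rsti, 15 - 12)   # CTI(t-1) = mean(10, 14)

  # boundary: STI equal to CTI(t-1)
  tt0 <- toy_turnover(c("A", "B"), c("A", "B", "C"),
                      c(A = 10, B = 14, C = 12))
  expect_equal(tt0$events$rsti, 0)

  # all-warm colonisation: every gained rSTI > 0 and CTI increases,
  # verified by direct mean recomputation
  tt2 <- toy_turnover(c("A", "B"), c("A", "B", "C", "D"),
                      c(A = 10, B = 12, C = 20, D = 18))
  expect_true(all(tt2$events$rsti > 0))
  cti_t0 <- mean(c(10, 12)); cti_t1 <- mean(c(10, 12, 20, 18))
  expect_equal(tt2$cti$cti, c(cti_t0, cti_t1))
  expect_gt(cti_t1, cti_t0)
})

test_that("species without an STI produce no orphan events", {
  sti <- data.frame(species = c("A", "B", "C"), sti = c(10, 12, 15),
                    n_records = 1L)
  asm <- rbind(
    data.frame(window_id = 1L, period = 0L, species = c("A", "B"), n = 1L),
    data.frame(window_id = 1L, period = 1L,
               species = c("B", "C", "ghost"), n = 1L))
  ev <- turnover_events(compute_cti(asm, sti), asm, sti)
  expect_false("ghost" %in% ev$species)
  expect_true(all(ev$species %in% sti$species))
})

test_that("relabelling the interval swaps gained and lost", {
  sti <- data.frame(species = c("A", "B", "C", "D"),
                    sti = c(10, 12, 15, 8), n_records = 1L)
  fwd <- rbind(
    data.frame(window_id = 1L, period = 0L, species = c("A", "B"), n = 1L),
    data.frame(window_id = 1L, period = 1L, species = c("B", "C", "D"),
               n = 1L))
  rev <- fwd; rev$period <- 1L - rev$period
  ev_f <- turnover_events(compute_cti(fwd, sti), fwd, sti)
  ev_r <- turnover_events(compute_cti(rev, sti), rev, sti)
  expect_setequal(ev_f$species[ev_f$status == "gained"],
                  ev_r$species[ev_r$status == "lost"])
  expect_setequal(ev_f$species[ev_f$status == "lost"],
                  ev_r$species[ev_r$status == "gained"])
})

test_that("CTI change decomposes exactly into gains and losses everywhere", {
  a <- cached_compact(1)
  p <- a$pipeline
  ev <- turnover_events(p$cti, p$assemblages, p$sti)
  sti_of <- function(sp) p$sti$sti[match(sp, p$sti$species)]
  asm <- p$assemblages[p$assemblages$species %in% p$sti$species, ]
  checked <- 0L
  for (w in unique(ev$window_id)) {
    for (tp in unique(ev$to_period[ev$window_id == w])) {
      s_prev <- asm$species[asm$window_id == w & asm$period == tp - 1]
      g <- ev$species[ev$window_id == w & ev$to_period == tp &
                        ev$status == "gained"]
      l <- ev$species[ev$window_id == w & ev$to_period == tp &
                        ev$status == "lost"]
      cti_prev <- p$cti$cti[p$cti$window_id == w & p$cti$period == tp - 1]
      cti_now <- p$cti$cti[p$cti$window_id == w & p$cti$period == tp]
      n_now <- length(s_prev) - length(l) + length(g)
      recon <- (sum(sti_of(s_prev)) - sum(sti_of(l)) + sum(sti_of(g))) /
        n_now
      expect_equal(cti_now, recon, tolerance = 1e-10)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 100)
})

test_that("turnover summaries report means, bootstrap CIs and sign proportions", {
  ev <- data.frame(window_id = 1L, from_period = 0L, to_period = 1L,
                   species = letters[1:4],
                   status = c("gained", "gained", "lost", "lost"),
                   rsti = c(1, 3, -1, 1))
  s <- summarize_turnover(ev, n_boot = 500, seed = 2)
  g <- s[s$status == "gained", ]; l <- s[s$status == "lost", ]
  expect_equal(g$mean_rsti, 2)
  expect_equal(g$prop_positive, 1)
  expect_equal(l$mean_rsti, 0)
  expect_equal(l$prop_positive, 0.5)
  expect_true(g$lower <= g$mean_rsti & g$upper >= g$mean_rsti)

  only_g <- ev[ev$status == "gained", ]
  s2 <- summarize_turnover(only_g, n_boot = 100)
  expect_true(is.na(s2$mean_rsti[s2$status == "lost"]))
  expect_equal(s2$n_events[s2$status == "lost"], 0L)
})

test_that("under tracked warming, gained species are locally warm-adapted", {
  a <- cached_compact(1)
  p <- a$pipeline
  ev <- turnover_events(p$cti, p$assemblages, p$sti)
  s <- summarize_turnover(ev, n_boot = 200, seed = 3)
  g <- s[s$status == "gained", ]; l <- s[s$status == "lost", ]
  # warming shifts assemblages towards warm-adapted membership: colonisers
  # sit above the previous community mean on average, and above leavers
  expect_gt(g$mean_rsti, 0)
  expect_gt(g$prop_positive, 0.5)
  expect_gt(g$mean_rsti, l$mean_rsti)
})
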