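make_cells <- function(mask, pixel_size_um = 1.3)
  foreground_background_rings(label_tumor_cells(mask, min_area_px = 1,
                                                pixel_size_um = pixel_size_um))

test_that("traces from a zero green channel are identically zero", {
  mk <- matrix(FALSE, 30, 30); mk[5:9, 5:9] <- TRUE; mk[20:24, 18:22] <- TRUE
  cells <- make_cells(mk)
  green <- array(0, c(30, 30, 8))
  tr <- extract_green_traces(green, cells)
  expect_equal(nrow(tr), 2 * 8)
  expect_true(all(tr$corrected == 0))
  expect_true(all(tr$fg == 0 & tr$bg == 0))
})

test_that("a rendered plateau is recovered within the noise budget", {
  cfg <- small_cfg(seed = 44, lambda0_per_h = 0.4, duration_h = 10)
  v <- generate_toc_video(cfg, channels = c("red", "green"))
  cells <- detect_tumor_cells(v$stack)
  tr <- extract_green_traces(v$stack, cells)
  truth <- v$truth$cells
  # match detected cells to truth and check the post-rise corrected level
  for (i in seq_len(nrow(cells))) {
    d <- sqrt((truth$row - cells$row[i])^2 + (truth$col - cells$col[i])^2)
    j <- which.min(d)
    t_ev <- truth$apoptosis_time_h[j]
    if (!is.finite(t_ev) || t_ev > 10 - 3) next
    late <- tr$label == cells$label[i] &
      tr$t_h > t_ev + cfg$green_rise_frames * cfg$dt_fluor_min / 60
    lvl <- mean(tr$corrected[late])
    # foreground mean dilutes the plateau at the smoothed disc edge
    expect_gt(lvl, 0.55 * cfg$green_plateau)
    expect_lt(lvl, 1.1 * cfg$green_plateau)
  }
})

test_that("traces depend only on pixels inside the fixed masks", {
  mk <- matrix(FALSE, 40, 40); mk[10:14, 10:14] <- TRUE
  cells <- make_cells(mk)
  withr::with_seed(3, {
    green <- array(runif(40 * 40 * 5, 0, 100), c(40, 40, 5))
    tr1 <- extract_green_traces(green, cells)
    used <- union(cells$fg_px[[1]], cells$ring_px[[1]])
    outside <- setdiff(seq_len(40 * 40), used)
    g2 <- green
    for (f in 1:5) {
      frame <- g2[, , f]
      frame[outside] <- sample(frame[outside])  # permute content outside masks
      g2[, , f] <- frame
    }
    tr2 <- extract_green_traces(g2, cells)
    expect_equal(tr1, tr2)
  })
})

test_that("cells with a fully collided ring fall back to global background", {
  mk <- matrix(FALSE, 20, 20)
  mk[5:8, 5:8] <- TRUE
  cells <- make_cells(mk)
  cells$ring_px[[1]] <- integer()   # simulate a ring swallowed by neighbours
  green <- array(7, c(20, 20, 3))
  tr <- extract_green_traces(green, cells)
  expect_true(all(tr$bg_fallback))
  expect_true(all(tr$bg == 7))
})

test_that("event calling: none on flat noise, exact frame on a step", {
  withr::with_seed(21, {
    flat <- tibble::tibble(label = 1L, frame = 1:60, t_h = (0:59) * 0.5,
                           corrected = rnorm(60))
    expect_equal(nrow(call_apoptosis_events(flat)), 0)
  })
  withr::with_seed(22, {
    x <- rnorm(60)
    x[20:60] <- x[20:60] + 10 * sd(x[1:19])
    step <- tibble::tibble(label = 1L, frame = 1:60, t_h = (0:59) * 0.5,
                           corrected = x)
    ev <- call_apoptosis_events(step)
    expect_equal(ev$event_frame, 20L)
    expect_equal(ev$event_time_h, 19 * 0.5)
  })
  short <- tibble::tibble(label = 1L, frame = 1:2, t_h = 0:1, corrected = c(0, 0))
  expect_error(call_apoptosis_events(short, m_consec = 3), "shorter")
})

test_that("event calling is translation-equivariant in time", {
  withr::with_seed(9, {
    base <- rnorm(40)
    sig <- c(base, rep(25, 20))
    for (shift in c(0, 5, 12)) {
      x <- c(rnorm(shift), sig)
      tr <- tibble::tibble(label = 1L, frame = seq_along(x),
                           t_h = (seq_along(x) - 1) * 0.5, corrected = x)
      ev <- call_apoptosis_events(tr)
      expect_equal(ev$event_frame, 41L + shift)
    }
  })
})

test_that("events are recovered from a rendered default-scale video", {
  cfg <- sim_config(seed = 50, duration_h = 24, n_cancer = 60L, n_caf = 0L,
                    field_size_px = c(420L, 420L), lambda0_per_h = 0.05)
  v <- generate_toc_video(cfg, channels = c("red", "green"))
  cells <- detect_tumor_cells(v$stack)
  ev <- call_apoptosis_events(extract_green_traces(v$stack, cells))
  truth <- v$truth$cells
  n_true <- sum(is.finite(truth$apoptosis_time_h) &
                  truth$apoptosis_time_h <= 24)
  expect_lte(abs(nrow(ev) - n_true), 3)
  # per-cell timing for matched cells
  errs <- c()
  for (i in seq_len(nrow(ev))) {
    ci <- cells[cells$label == ev$label[i], ]
    d <- sqrt((truth$row - ci$row)^2 + (truth$col - ci$col)^2)
    t_true <- truth$apoptosis_time_h[which.min(d)]
    if (is.finite(t_true)) errs <- c(errs, abs(ev$event_time_h[i] - t_true))
  }
  expect_lte(median(errs), 0.5)
})

test_that("survival formula instances and brute-force oracle agree", {
  expect_equal(survival_curve(numeric(), 10, 30)$survival_pct, rep(100, 4))
  s <- survival_curve(c(3, 12, 19), 10, 30)
  expect_equal(s$survival_pct[s$t_n == 20], 70)   # 10 alive, 3 events
  expect_equal(s$survival_pct[s$t_n == 0], 100)
  expect_error(survival_curve(c(1), 0, 30), "n_alive_t0")

  withr::with_seed(77, {
    for (rep in 1:20) {
      n0 <- sample(20:200, 1)
      times <- runif(min(sample(0:50, 1), n0), 0, 72)
      tab <- survival_curve(times, n0, 72)
      sorted <- sort(times)
      for (k in seq_len(nrow(tab))) {
        cnt <- sum(sorted <= tab$t_n[k])   # brute-force cumulative count
        expect_equal(tab$survival_pct[k], (n0 - cnt) / n0 * 100)
      }
      expect_true(all(diff(tab$survival_pct) <= 0))
    }
  })
})

test_that("apoptosis rate: formula instance, undefined windows, conservation", {
  r <- apoptosis_rate_curve(c(rep(2, 2), rep(15, 1)), 8, 30)
  expect_equal(r$rate_pct[r$t_n == 0], 2 / 8 * 100)  # 8 alive, 2 events -> 25%
  expect_equal(sum(r$events_in_window), 3)

  # all dead in the first window -> later windows undefined, not zero
  expect_warning(r2 <- apoptosis_rate_curve(rep(5, 4), 4, 30), "undefined")
  expect_true(all(is.na(r2$rate_pct[r2$t_n >= 10])))
  expect_equal(r2$rate_pct[1], 100)
})

test_that("survival and rate satisfy the multiplicative window identity", {
  withr::with_seed(31, {
    for (rep in 1:100) {
      n0 <- sample(5:100, 1)
      times <- runif(min(rpois(1, 20), n0), 0, 70)
      s <- survival_curve(times, n0, 70)
      r <- apoptosis_rate_curve(times, n0, 70)
      for (k in seq_len(nrow(r))) {
        if (r$alive[k] == 0) next
        s_now <- s$survival_pct[s$t_n == r$t_n[k]]
        s_next <- s$survival_pct[s$t_n == r$t_n[k] + 10]
        expect_equal(s_next, s_now * (1 - r$rate_pct[k] / 100))
      }
    }
  }) |> suppressWarnings()
})

test_that("paired Wilcoxon: identical tables give p = 1, ordered pairs 1/64", {
  kin <- function(vals, cond) dplyr::bind_rows(lapply(seq_along(vals), function(i)
    tibble::tibble(condition = cond, video = paste0("v", i), t_n = 0,
                   survival_pct = vals[[i]])))
  a <- kin(as.list(c(80, 70, 90, 85, 75, 95)), "co")
  res_id <- compare_conditions(a, a)
  expect_equal(res_id$statistic, 0)
  expect_equal(res_id$p_value, 1)

  b <- kin(as.list(c(70, 60, 80, 75, 65, 85)), "mono")
  res <- compare_conditions(a, b, alternative = "greater")
  expect_equal(res$p_value, 1 / 64)  # exact sign-flip null, 6 pairs one-way
  expect_equal(res$n_pairs, 6L)
  expect_gt(res$direction, 0)

  expect_error(compare_conditions(a, b[1:3, ]), "matched")
})

test_that("exact sign-flip p matches wilcox.test on tie-free data", {
  withr::with_seed(13, {
    for (rep in 1:25) {
      n <- sample(4:12, 1)
      x <- rnorm(n); y <- rnorm(n)
      ours <- tocstamp:::signflip_wilcoxon(x, y, "two.sided")
      ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(ours$p_value, ref$p.value)
      expect_equal(ours$statistic, unname(ref$statistic))
    }
  })
})

test_that("sign-flip p-values are calibrated under a permuted-pairing null", {
  withr::with_seed(41, {
    ps <- replicate(200, {
      # independent arms: paired differences are iid symmetric under the null
      tocstamp:::signflip_wilcoxon(rnorm(8), rnorm(8), "two.sided")$p_value
    })
    grid <- seq(0.05, 0.95, by = 0.05)
    d <- max(abs(sapply(grid, function(g) mean(ps <= g)) - grid))
    expect_lt(d, 0.15)
  })
})
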