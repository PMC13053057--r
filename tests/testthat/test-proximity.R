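test_that("minimum CAF distance: geometry instances and exhaustive oracle", {
  mk <- matrix(FALSE, 30, 30)
  mk[11, 11] <- TRUE   # 0-based (10, 10)
  # centroid one pixel-diagonal away
  expect_equal(min_caf_distance(c(9, 9), mk, pixel_size_um = 1.3),
               sqrt(2) * 1.3)
  expect_true(is.na(min_caf_distance(c(5, 5), matrix(FALSE, 10, 10))))

  withr::with_seed(91, {
    for (rep in 1:50) {
      mk <- random_mask(40, 40)
      cent <- runif(2, 0, 39)
      got <- min_caf_distance(cent, mk, pixel_size_um = 1)
      expect_equal(got, brute_min_boundary_dist(cent, mk), tolerance = 1e-12)
    }
  })
})

test_that("boundary distance equals nearest-mask-pixel distance outside the mask", {
  withr::with_seed(92, {
    for (rep in 1:50) {
      mk <- random_mask(36, 36)
      repeat {
        cent <- runif(2, 0, 35)
        if (!mk[round(cent[1]) + 1, round(cent[2]) + 1]) break
      }
      expect_equal(brute_min_boundary_dist(cent, mk),
                   brute_min_mask_dist(cent, mk), tolerance = 1e-12)
    }
  })
})

test_that("contact counting uses a strict 18-um threshold", {
  px <- 1.0
  mk_at <- function(dist_px) {
    mk <- matrix(FALSE, 60, 70); mk[31, 31 + dist_px] <- TRUE
    mk
  }
  dists <- c(17, 19, 10, 30, 16)
  masks <- array(FALSE, c(60, 70, 5))
  for (f in seq_along(dists)) masks[, , f] <- mk_at(dists[f])
  # distances 17, 19, 10, 30, 16 px at 1 um/px -> 3 contacts (strict <)
  got <- count_contacts(c(30, 30), masks, threshold_um = 18,
                        pixel_size_um = px)
  expect_equal(got, 3L)
  # a pixel at exactly 18.0 um is not a contact
  expect_equal(count_contacts(c(30, 30), mk_at(18) |> array(c(60, 70, 1)),
                              threshold_um = 18, pixel_size_um = px), 0L)
  expect_equal(count_contacts(c(30, 30), array(FALSE, c(60, 70, 3)),
                              threshold_um = 18, pixel_size_um = px), 0L)
  expect_error(count_contacts(c(30, 30), masks, window_h = c(10, 20),
                              frame_times_h = 0:4), "empty")
})

test_that("IOU at radius: identity, emptiness, half-plane oracle", {
  dims <- c(120, 120)
  cent <- c(60, 60)
  disc_idx <- tocstamp:::disc_indices(cent, 30, dims)
  disc_mask <- matrix(FALSE, dims[1], dims[2]); disc_mask[disc_idx] <- TRUE
  expect_equal(iou_at_radius(cent, disc_mask, radius_um = 30, pixel_size_um = 1), 1)
  expect_equal(iou_at_radius(cent, matrix(FALSE, 120, 120), 30, 1), 0)

  half <- matrix(FALSE, 120, 120); half[, 61:120] <- TRUE  # half-plane
  got <- iou_at_radius(cent, half, radius_um = 30, pixel_size_um = 1)
  expect_equal(got, brute_iou(cent, half, 30), tolerance = 1e-12)

  withr::with_seed(93, {
    for (rep in 1:30) {
      mk <- random_mask(50, 50)
      cent <- runif(2, 5, 44)
      r <- runif(1, 4, 20)
      expect_equal(iou_at_radius(cent, mk, r, 1), brute_iou(cent, mk, r),
                   tolerance = 1e-12)
    }
  })
})

test_that("IOU grows as CAF pixels are added inside the disc", {
  cent <- c(40, 40)
  mk <- matrix(FALSE, 80, 80)
  mk[10:12, 10:12] <- TRUE   # fixed pixels outside the disc
  prev <- iou_at_radius(cent, mk, radius_um = 15, pixel_size_um = 1)
  inside <- tocstamp:::disc_indices(cent, 15, c(80, 80))
  withr::with_seed(5, inside <- sample(inside))
  for (k in c(20, 80, 200)) {
    mk2 <- mk; mk2[inside[1:k]] <- TRUE
    cur <- iou_at_radius(cent, mk2, radius_um = 15, pixel_size_um = 1)
    expect_gt(cur, prev)
    prev <- cur
  }
  expect_lte(prev, 1)
})

test_that("proximity records agree with the per-frame oracles", {
  cfg <- small_cfg(seed = 71, duration_h = 1, n_caf = 3L)
  v <- generate_toc_video(cfg, render = FALSE)
  cells_tbl <- tibble::tibble(label = v$truth$cells$id,
                              row = v$truth$cells$row,
                              col = v$truth$cells$col,
                              touches_border = FALSE)
  masks <- v$truth$caf_masks
  rec <- proximity_records(cells_tbl, masks, frame_times_h = v$truth$t_trans_h,
                           pixel_size_um = cfg$pixel_size_um)
  expect_equal(nrow(rec), nrow(cells_tbl) * dim(masks)[3])
  for (k in sample(nrow(rec), 25)) {
    row <- rec[k, ]
    cent <- c(cells_tbl$row[cells_tbl$label == row$label],
              cells_tbl$col[cells_tbl$label == row$label])
    mk <- masks[, , row$frame]
    d_mask <- brute_min_mask_dist(cent, mk) * cfg$pixel_size_um
    expect_equal(row$in_contact, d_mask < 18)
    if (!row$in_contact && any(mk))
      expect_equal(row$min_dist_um,
                   brute_min_boundary_dist(cent, mk) * cfg$pixel_size_um,
                   tolerance = 1e-9)
    if (row$in_contact) expect_true(is.na(row$min_dist_um))
    expect_equal(row$iou, brute_iou(cent, mk, 82 / cfg$pixel_size_um),
                 tolerance = 1e-12)
  }
  # recorded min distances are never below the contact threshold
  expect_true(all(rec$min_dist_um >= 18, na.rm = TRUE))
})

test_that("fate table assigns dead iff an event occurs by the horizon", {
  cells <- tibble::tibble(label = 1:4, touches_border = c(FALSE, FALSE, TRUE, FALSE))
  events <- tibble::tibble(label = c(1L, 2L), event_time_h = c(30, 80))
  ft <- fate_table(cells, events, horizon_h = 72)
  expect_equal(as.character(ft$fate), c("dead", "alive", "alive", "alive"))
  expect_equal(ft$event_time_h, c(30, NA, NA, NA))
})

test_that("stratification recovers a strong planted effect with the right direction", {
  withr::with_seed(314, {
    n <- 60; nf <- 30
    # synthetic records: alive cells close to CAFs, dead cells far
    fate <- rep(c("alive", "dead"), each = n / 2)
    base <- ifelse(fate == "alive", 30, 90)
    rec <- dplyr::bind_rows(lapply(seq_len(n), function(i)
      tibble::tibble(label = i, frame = seq_len(nf), t_h = seq(0, 8, length.out = nf),
                     in_contact = FALSE,
                     min_dist_um = base[i] + runif(nf, 0, 10),
                     iou = pmax(0, 0.3 - base[i] / 400 + runif(nf, 0, 0.02)))))
    fates <- tibble::tibble(label = seq_len(n), touches_border = FALSE,
                            event_time_h = ifelse(fate == "dead", 60, NA_real_),
                            fate = factor(fate, levels = c("dead", "alive")))
    res <- stratify_by_fate(rec, fates, n_perm = 199)
    td <- tidy(res)
    md <- td[td$parameter == "min_dist_um", ]
    expect_lt(md$direction, 0)        # alive closer
    expect_lt(md$p_value, 0.01)
    io <- td[td$parameter == "iou", ]
    expect_gt(io$direction, 0)        # alive more covered
    expect_lt(io$p_value, 0.01)
    expect_equal(glance(res)$n_cells, n)
  })
})

test_that("identical strata give D = 0 and p = 1; empty strata error", {
  nf <- 10
  rec <- dplyr::bind_rows(lapply(1:10, function(i)
    tibble::tibble(label = i, frame = 1:nf, t_h = seq(0, 8, length.out = nf),
                   in_contact = FALSE, min_dist_um = 20 + (1:nf),
                   iou = 0.1)))
  fates <- tibble::tibble(label = 1:10, touches_border = FALSE,
                          event_time_h = c(rep(60, 5), rep(NA_real_, 5)),
                          fate = factor(rep(c("dead", "alive"), each = 5),
                                        levels = c("dead", "alive")))
  res <- stratify_by_fate(rec, fates, n_perm = 99)
  td <- tidy(res)
  expect_true(all(td$ks_D == 0))
  expect_true(all(td$p_value == 1))

  all_dead <- dplyr::mutate(fates, event_time_h = 60,
                            fate = factor("dead", levels = c("dead", "alive")))
  expect_error(stratify_by_fate(rec, all_dead, n_perm = 9), "alive")
})

test_that("cells dying inside the early window keep only pre-event records", {
  rec <- tibble::tibble(label = 1L, frame = 1:9, t_h = seq(0, 8, by = 1),
                        in_contact = FALSE, min_dist_um = 20 + (1:9), iou = 0)
  rec2 <- dplyr::bind_rows(rec, dplyr::mutate(rec, label = 2L))
  fates <- tibble::tibble(label = c(1L, 2L), touches_border = FALSE,
                          event_time_h = c(4, NA_real_),
                          fate = factor(c("dead", "alive"),
                                        levels = c("dead", "alive")))
  res <- stratify_by_fate(rec2, fates, n_perm = 9)
  s <- res$samples
  expect_equal(sum(s$parameter == "min_dist_um" & s$fate == "dead"), 5)  # t <= 4
  expect_equal(sum(s$parameter == "min_dist_um" & s$fate == "alive"), 9)
})
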