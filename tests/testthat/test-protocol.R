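test_that("grid construction yields the full stimulus Cartesian product", {
  both <- build_grid(c("left", "right"))
  expect_equal(nrow(both$remaining), 192)
  expect_equal(both$current_ear, "left")
  left <- build_grid("left")
  expect_equal(nrow(left$remaining), 96)
  reduced <- build_grid("right", frequencies_hz = 1000,
                        intensities_db = c(10, 20, 30, 40))
  expect_equal(nrow(reduced$remaining), 4)
  expect_error(build_grid(character(0)), "nonempty")
  expect_error(build_grid("middle"), "nonempty subset")
})

test_that("next_stimulus draws from the current ear and switches only when empty", {
  st <- build_grid("left", frequencies_hz = 500, intensities_db = 40)
  expect_equal(next_stimulus(st)$intensity_db, 40)

  st <- build_grid(c("left", "right"), frequencies_hz = 500,
                   intensities_db = c(10, 20))
  # exhaust the left ear
  for (db in c(10, 20)) {
    stim <- data.frame(ear = "left", frequency_hz = 500, intensity_db = db)
    st <- apply_response(st, stim, heard = FALSE, onset_s = db)
  }
  expect_equal(st$current_ear, "right")
  expect_equal(next_stimulus(st)$ear, "right")

  full <- build_grid()
  set.seed(99); a <- next_stimulus(full)
  set.seed(99); b <- next_stimulus(full)
  expect_identical(a, b)
})

test_that("responses prune higher intensities when heard, lower when unheard", {
  st <- build_grid("left")
  stim <- data.frame(ear = "left", frequency_hz = 1000, intensity_db = 50)
  heard <- apply_response(st, stim, TRUE, onset_s = 0, response_s = 0.4)
  expect_equal(nrow(heard$remaining), 96 - 1 - 7)
  left1k <- heard$remaining[heard$remaining$frequency_hz == 1000, ]
  expect_true(all(left1k$intensity_db < 50))

  unheard <- apply_response(st, stim, FALSE, onset_s = 0)
  expect_equal(nrow(unheard$remaining), 96 - 1 - 4)
  left1k <- unheard$remaining[unheard$remaining$frequency_hz == 1000, ]
  expect_true(all(left1k$intensity_db > 50))

  top <- data.frame(ear = "left", frequency_hz = 125, intensity_db = 120)
  at_top <- apply_response(st, top, TRUE, onset_s = 0, response_s = 0.3)
  expect_equal(nrow(at_top$remaining), 95)

  expect_error(apply_response(heard, stim, TRUE, 2, 2.4),
               "protocol violation")
})

test_that("deterministic listener hears at or above threshold, inclusive", {
  lst <- flat_listener(40)
  at <- data.frame(ear = "left", frequency_hz = 1000, intensity_db = 40)
  below <- transform(at, intensity_db = 30)
  expect_true(simulate_listener(lst, at))
  expect_false(simulate_listener(lst, below))
  expect_error(
    simulate_listener(listener_model(data.frame(
      ear = "left", frequency_hz = 500, threshold_db = 40)), at),
    "no threshold")
})

test_that("psychometric listener at threshold is a fair coin (logistic midpoint)", {
  lst <- flat_listener(40, slope_db = 5)
  at <- data.frame(ear = "left", frequency_hz = 1000, intensity_db = 40)
  set.seed(42)
  hits <- mean(replicate(2000, simulate_listener(lst, at)))
  # 99.9% binomial band around the closed-form plogis(0) = 0.5
  expect_lt(abs(hits - 0.5), 3.29 * sqrt(0.25 / 2000))
  above <- transform(at, intensity_db = 60)
  set.seed(43)
  p60 <- mean(replicate(2000, simulate_listener(lst, above)))
  expect_lt(abs(p60 - plogis(20 / 5)), 0.03)
})

test_that("sessions stay within the 96-trial bound and are seed-reproducible", {
  never <- flat_listener(NO_RESPONSE_DB, ears = "left")
  tr <- run_session(never, ears = "left", seed = 3)
  expect_lte(nrow(tr), 96)
  expect_false(any(tr$heard))

  always <- flat_listener(10, ears = "left")
  tr2 <- run_session(always, ears = "left", seed = 3)
  expect_lte(nrow(tr2), 96)
  expect_true(all(tr2$heard))
  # hears everything: one presentation settles each frequency
  expect_equal(sum(tr2$heard), nrow(tr2))

  expect_identical(run_session(flat_listener(60), seed = 11),
                   run_session(flat_listener(60), seed = 11))

  # every presented stimulus appears exactly once
  tr3 <- run_session(flat_listener(60), seed = 5)
  expect_false(any(duplicated(tr3[c("ear", "frequency_hz", "intensity_db")])))
  expect_true(all(tr3$response_s[tr3$heard] > tr3$onset_s[tr3$heard]))
  expect_true(all(is.na(tr3$response_s[!tr3$heard])))
})

test_that("audiogram recovery is exact for every presentation order on a reduced grid", {
  dbs <- c(10, 20, 30, 40)
  orders <- expand.grid(rep(list(seq_len(4)), 4))
  orders <- orders[apply(orders, 1, function(r) length(unique(r)) == 4), ]
  for (true_thr in c(10, 30, 40)) {
    for (i in seq_len(nrow(orders))) {
      st <- build_grid("left", frequencies_hz = 1000, intensities_db = dbs)
      onset <- 0
      for (j in as.numeric(orders[i, ])) {
        stim <- data.frame(ear = "left", frequency_hz = 1000,
                           intensity_db = dbs[j])
        at <- st$remaining
        present <- any(at$intensity_db == dbs[j])
        if (!present) next
        heard <- dbs[j] >= true_thr
        st <- apply_response(st, stim, heard, onset,
                             if (heard) onset + 0.4 else NA_real_)
        onset <- onset + 2
      }
      ag <- compute_audiogram(st$trials, frequencies_hz = 1000)
      expect_equal(ag$threshold_db, true_thr)
    }
  }
})

test_that("audiogram reports minima per frequency and NR when nothing was heard", {
  trials <- data.frame(
    ear = "left", frequency_hz = c(1000, 1000, 8000),
    intensity_db = c(50, 40, 90),
    heard = c(TRUE, TRUE, FALSE),
    onset_s = c(0, 2, 4), response_s = c(0.4, 2.4, NA))
  ag <- compute_audiogram(trials, frequencies_hz = c(1000, 8000))
  expect_equal(ag$threshold_db[ag$frequency_hz == 1000], 40)
  expect_true(is.na(ag$threshold_db[ag$frequency_hz == 8000]))
})

test_that("session CSV and JSON round trips preserve the trial log", {
  tr <- run_session(flat_listener(60), seed = 2)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_session_csv(tr, csv)
  write_session_json(tr, js)
  expect_equal(read_session_csv(csv), tr, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(read_session_json(js), tr, tolerance = 1e-12,
               ignore_attr = TRUE)
  ag <- compute_audiogram(tr)
  agf <- tempfile(fileext = ".csv")
  write_audiogram_csv(ag, agf)
  back <- read.csv(agf, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 16)  # 8 frequencies x 2 ears
})
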