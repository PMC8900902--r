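test_that("anchor intervals span t-15 to t+15 and merge on overlap", {
  one <- make_prompts(1, 0, t0 = ts_at("2024-03-04 12:00:00"))
  iv <- ema_anchor_intervals(one)
  expect_identical(iv$start_ts, ts_at("2024-03-04 11:45:00"))
  expect_identical(iv$end_ts, ts_at("2024-03-04 12:15:00"))

  two <- make_prompts(2, 0, t0 = ts_at("2024-03-04 12:00:00"), spacing = 1200)
  merged <- ema_anchor_intervals(two)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$start_ts, ts_at("2024-03-04 11:45:00"))
  expect_identical(merged$end_ts, ts_at("2024-03-04 12:35:00"))

  none <- make_prompts(0, 3)
  expect_identical(nrow(ema_anchor_intervals(none)), 0L)
})

test_that("minute classification requires all three sensor conditions", {
  m <- tibble::tibble(
    participant_id = "p1",
    minute_start = ts_at("2024-03-04 10:00:00") + 60 * 0:3,
    accel_available = c(TRUE, TRUE, FALSE, TRUE),
    movement = c(TRUE, FALSE, TRUE, TRUE),
    beacon_available = c(TRUE, TRUE, TRUE, FALSE)
  )
  expect_identical(classify_minute(m), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("sensor intervals merge contiguous participating minutes", {
  mk <- function(mins, part = TRUE) {
    tibble::tibble(
      participant_id = "p1",
      minute_start = ts_at("2024-03-04 10:00:00") + 60 * mins,
      accel_available = part, movement = part, beacon_available = TRUE
    )
  }
  run <- sensor_intervals(mk(0:2))
  expect_identical(run$start_ts, ts_at("2024-03-04 10:00:00"))
  expect_identical(run$end_ts, ts_at("2024-03-04 10:03:00"))

  gap <- sensor_intervals(mk(c(0, 2)))
  expect_identical(nrow(gap), 2L)

  expect_error(sensor_intervals(dplyr::bind_rows(mk(0), mk(0))), "duplicate")
})

test_that("sensor intervals equal a brute-force run-length scan", {
  for (rep in 1:4) {
    set.seed(200 + rep)
    flags <- runif(120) < 0.5
    m <- tibble::tibble(
      participant_id = "p1",
      minute_start = ts_at("2024-03-04 08:00:00") + 60 * (0:119),
      accel_available = flags, movement = flags, beacon_available = TRUE
    )
    iv <- sensor_intervals(m)
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    expect_identical(nrow(iv), sum(keep))
    expect_identical(
      as.numeric(iv$start_ts),
      as.numeric(m$minute_start[starts[keep]])
    )
    expect_identical(
      as.numeric(iv$end_ts),
      as.numeric(m$minute_start[ends[keep]]) + 60
    )
  }
})

test_that("interval union is correct, idempotent, commutative, monotone", {
  a <- participation_intervals(
    "p1", ts_at("2024-03-04 10:00:00"), ts_at("2024-03-04 10:30:00")
  )
  b <- participation_intervals(
    "p1", ts_at("2024-03-04 10:15:00"), ts_at("2024-03-04 10:45:00")
  )
  u <- union_participation(a, b)
  expect_identical(nrow(u), 1L)
  expect_identical(u$start_ts, ts_at("2024-03-04 10:00:00"))
  expect_identical(u$end_ts, ts_at("2024-03-04 10:45:00"))

  disj <- participation_intervals(
    "p1", ts_at("2024-03-04 12:00:00"), ts_at("2024-03-04 12:10:00")
  )
  u2 <- union_participation(a, disj)
  expect_identical(nrow(u2), 2L)
  expect_true(all(u2$start_ts == sort(u2$start_ts)))

  expect_identical(union_participation(a, b), union_participation(b, a))
  expect_identical(union_participation(u, u), u)
  expect_gte(
    participation_seconds(union_participation(a, b, disj)),
    participation_seconds(union_participation(a, b))
  )
})

test_that("union membership matches per-minute brute-force indicators", {
  day0 <- as.numeric(ts_at("2024-03-04 00:00:00"))
  grid <- day0 + 60 * (0:1439)
  for (rep in 1:4) {
    set.seed(300 + rep)
    rand_iv <- function(n) {
      s <- day0 + sort(sample(0:1400, n)) * 60
      participation_intervals(
        "p1",
        as.POSIXct(s, tz = tz_utc, origin = "1970-01-01"),
        as.POSIXct(s + sample(1:90, n, replace = TRUE) * 60,
          tz = tz_utc, origin = "1970-01-01"
        )
      )
    }
    a <- rand_iv(8)
    b <- rand_iv(8)
    u <- union_participation(a, b)
    ind_union <- oracle_minute_indicator(grid, u$start_ts, u$end_ts)
    ind_parts <- oracle_minute_indicator(grid, a$start_ts, a$end_ts) |
      oracle_minute_indicator(grid, b$start_ts, b$end_ts)
    expect_identical(ind_union, ind_parts)
    # total time invariant under input ordering
    expect_identical(
      participation_seconds(dplyr::bind_rows(a, b)),
      participation_seconds(dplyr::bind_rows(b, a)[sample.int(16), ])
    )
  }
})

test_that("prompt filtering keeps received prompts inside intervals only", {
  iv <- participation_intervals(
    "p1", ts_at("2024-03-04 11:45:00"), ts_at("2024-03-04 12:15:00")
  )
  inside <- make_prompts(1, 0, t0 = ts_at("2024-03-04 12:00:00"))
  expect_identical(nrow(filter_prompts(inside, iv)), 1L)

  # half-open: a prompt exactly at the end bound is excluded
  boundary <- make_prompts(1, 0, t0 = ts_at("2024-03-04 12:15:00"))
  expect_identical(nrow(filter_prompts(boundary, iv)), 0L)

  lost <- make_prompts(0, 0, n_lost = 1, t0 = ts_at("2024-03-04 12:00:00"))
  expect_identical(nrow(filter_prompts(lost, iv)), 0L)

  other <- make_prompts(1, 0,
    participant_id = "p2",
    t0 = ts_at("2024-03-04 12:00:00")
  )
  expect_identical(nrow(filter_prompts(other, iv)), 0L)
})

test_that("filtering equals a brute-force membership test on random data", {
  set.seed(17)
  day0 <- ts_at("2024-03-04 00:00:00")
  prompts <- make_prompts(40, 0, t0 = day0, spacing = 1950)
  s <- day0 + sort(sample(0:1300, 10)) * 60
  iv <- participation_intervals("p1", s, s + sample(5:60, 10, TRUE) * 60)
  kept <- filter_prompts(prompts, iv)
  norm <- normalize_intervals(iv)
  manual <- vapply(seq_len(nrow(prompts)), function(i) {
    t <- as.numeric(prompts$received_ts[i])
    any(t >= as.numeric(norm$start_ts) & t < as.numeric(norm$end_ts))
  }, logical(1))
  expect_identical(kept$prompt_id, prompts$prompt_id[manual])
})

test_that("every answered prompt survives the full participation algorithm", {
  dep <- simulate_deployment(tiny_config())
  part <- participation_algorithm(dep$prompts, dep$sensor_minutes)
  answered_ids <- dep$prompts$prompt_id[
    dep$prompts$answer_state %in% c("partial", "complete")
  ]
  expect_true(all(answered_ids %in% part$retained_prompts$prompt_id))
})

test_that("perfect sensors and delivery retain every received prompt", {
  cfg <- tiny_config(
    accel_available_prob = 1, movement_prob = 1, beacon_available_prob = 1,
    prompt_delivery_failure_prob = 0
  )
  dep <- simulate_deployment(cfg)
  part <- participation_algorithm(dep$prompts, dep$sensor_minutes)
  expect_true(all(dep$prompts$received))
  expect_identical(nrow(part$retained_prompts), nrow(dep$prompts))
})
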