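# File formats: DAM monitor text, voltage/ROI/choice tables, YAML config.
# All round-trips must be identities; malformed files fail with context.

test_that("a hand-built DAM file parses to exact per-channel series", {
  path <- withr::local_tempfile(fileext = ".txt")
  ts <- list(date = rep("01 Jan 24", 3), time = c("08:00:00", "08:01:00", "08:02:00"))
  rows <- vapply(1:3, function(i) {
    paste(c(i, ts$date[i], ts$time[i], 1, rep(0, 6), rep(i - 1, 32)),
          collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  cmap <- data.frame(channel = 1:32, fly_id = sprintf("f%02d", 1:32),
                     genotype = "g")
  series <- read_dam(path, cmap)
  expect_length(series, 32)
  for (s in series) expect_equal(s$counts, 0:2)
})

test_that("write_dam / read_dam round-trips counts", {
  p <- genotype_preset("g", locomotor = list(amplitude = 0))
  coh <- simulate_locomotor(p, n_flies = 3, days_ld = 1, days_dd = 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam(coh, path)
  cmap <- data.frame(channel = 1:3,
                     fly_id = vapply(coh, `[[`, character(1), "fly_id"),
                     genotype = "g")
  back <- read_dam(path, cmap)
  for (i in 1:3) expect_identical(back[[i]]$counts, coh[[i]]$counts)
})

test_that("malformed DAM rows fail with line context", {
  path <- withr::local_tempfile(fileext = ".txt")
  good <- paste(c(1, "01 Jan 24", "08:00:00", 1, rep(0, 6), rep(1, 32)),
                collapse = "\t")
  bad <- paste(c(2, "01 Jan 24", "08:01:00", 1, rep(0, 6), rep(1, 31)),
               collapse = "\t")   # 41 columns
  writeLines(c(good, bad), path)
  cmap <- data.frame(channel = 1, fly_id = "f", genotype = "g")
  expect_error(read_dam(path, cmap), "line 2")

  # negative count
  neg <- sub("\t1$", "\t-1", good)
  writeLines(c(good, sub("08:00:00", "08:01:00", neg)), path)
  expect_error(read_dam(path, cmap), "negative")

  # gap in timestamps: error unless zero-filled
  gap <- sub("08:00:00", "08:05:00", sub("^1\t", "2\t", good))
  writeLines(c(good, gap), path)
  expect_error(read_dam(path, cmap), "missing minutes")
  filled <- read_dam(path, cmap, zero_fill = TRUE)
  expect_length(filled[[1]]$counts, 6)
  expect_equal(sum(filled[[1]]$counts), 2)

  # non-monotone timestamps
  backstep <- sub("08:00:00", "07:59:00", sub("^1\t", "2\t", good))
  writeLines(c(good, backstep), path)
  expect_error(read_dam(path, cmap), "non-monotone")

  # non-valid status rows are skipped with a warning
  dead <- sub("\t1\t0", "\t51\t0", sub("08:00:00", "08:01:00", sub("^1\t", "2\t", good)))
  writeLines(c(good, dead), path)
  expect_warning(r <- read_dam(path, cmap), "status")
  expect_length(r[[1]]$counts, 1)
})

test_that("voltage tables round-trip exactly and validate their length", {
  p <- genotype_preset("g", ephys = list(noise_sd_mv = 1))
  proto <- sweep_protocol(pre_dark_s = 1, stim_s = 0.5, post_s = 1, n_sweeps = 2)
  rec <- simulate_voltage(p, proto, seed = 3, zt_of_recording = 6.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_voltage_table(rec, path)
  back <- read_voltage_table(path)
  expect_equal(back$voltage_mv, rec$voltage_mv)
  expect_equal(back$cell_id, rec$cell_id)
  expect_equal(back$zt_of_recording, 6.5)
  expect_equal(back$protocol$n_sweeps, 2)

  # drop the units row
  lines <- readLines(path)
  writeLines(lines[lines != "s\tmV"], path)
  expect_error(read_voltage_table(path), "units row")

  # truncate beyond one sample of the protocol length
  writeLines(head(lines, -10), path)
  expect_error(read_voltage_table(path), "does not match protocol")
})

test_that("ROI and choice tables round-trip and enforce invariants", {
  p <- genotype_preset("g")
  tab <- simulate_roi(p, 2, 3, zt = 11, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roi_table(tab, path)
  back <- read_roi_table(path)
  expect_equal(back$mean_intensity, tab$mean_intensity)
  expect_equal(back$zt, tab$zt)

  bad <- tab; bad$background_intensity <- 0
  expect_error(write_roi_table(bad, path), "background")
  lines <- readLines(path)
  lines[4] <- sub("\t11\t", "\t12\t", lines[4])
  writeLines(lines, path)
  expect_error(read_roi_table(path), "zt")

  coh <- simulate_choice(p, 3, 10, seed = 5)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_choice_table(coh, cpath)
  back2 <- read_choice_table(cpath)
  for (cs in coh) {
    expect_identical(back2[[cs$fly_id]]$lit_counts, cs$lit_counts)
    expect_identical(back2[[cs$fly_id]]$dark_counts, cs$dark_counts)
  }
})

test_that("YAML config reading validates fields by name", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 3", "locomotor:", "  min_power: two"), path)
  expect_error(read_config(path), "locomotor\\$min_power")
  writeLines(c("seed: 3", "stats:", "  q: 1.5"), path)
  expect_error(read_config(path), "stats\\$q")
  writeLines("seed: 3", path)
  cfg <- read_config(path)
  expect_equal(cfg$locomotor$min_power, 20)   # defaults fill in
  expect_equal(cfg$stats$q, 0.1)
})

test_that("ground-truth sidecars serialize generator parameters", {
  p <- genotype_preset("g")
  coh <- simulate_locomotor(p, 2, 1, 1, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(attr(coh, "ground_truth"), path)
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(gt$tau_h, rep(24, 2))
  expect_equal(gt$rhythmic, c(TRUE, TRUE))
})
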