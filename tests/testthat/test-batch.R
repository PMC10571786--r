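# writes a small fixture set to dir and returns the wli paths + reference
write_fixture_set <- function(dir, n, seed0 = 80, width = 64, height = 64) {
  paths <- character(n)
  ref <- NULL
  for (i in seq_len(n)) {
    sp <- synthetic_spec(width = width, height = height, vessel_count = 4,
                         seed = seed0 + i)
    pair <- generate_pair(sp)
    paths[i] <- file.path(dir, sprintf("frame_%02d.png", i))
    write_image(pair$wli, paths[i])
    if (i == 1) {
      ref <- file.path(dir, "reference.png")
      write_image(pair$nbi_ref, ref)
    }
  }
  list(sources = paths, reference = ref)
}

test_that("run_batch writes frames and a CSV with per-image rows plus MEAN", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(dir, 5)
  cfg <- run_config(source_paths = fx$sources, reference_path = fx$reference,
                    output_dir = file.path(dir, "out"))
  summary <- suppressMessages(run_batch(cfg))
  expect_equal(summary$status, 0L)
  expect_equal(summary$n_ok, 5L)
  expect_true(all(file.exists(
    file.path(dir, "out", sprintf("frame_%02d_nbi.png", 1:5)))))
  rep <- read.csv(cfg$report_path, stringsAsFactors = FALSE)
  expect_equal(nrow(rep), 6L)
  expect_identical(rep$image_id[6], "MEAN")
  expect_false(anyDuplicated(rep$image_id[1:5]) > 0)
  expect_equal(rep$ssim_pct[6], mean(rep$ssim_pct[1:5]), tolerance = 1e-6)
  expect_true(all(rep$ssim_pct[1:5] > 0 & rep$ssim_pct[1:5] <= 100))
})

test_that("batch runs are deterministic given identical inputs", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(dir, 3)
  run_once <- function(tag) {
    cfg <- run_config(source_paths = fx$sources,
                      reference_path = fx$reference,
                      output_dir = file.path(dir, tag))
    suppressMessages(run_batch(cfg, quiet = TRUE))
    readLines(cfg$report_path)
  }
  expect_identical(run_once("a"), run_once("b"))
})

test_that("corrupt frames are skipped, not fatal; all-fail exits nonzero", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(dir, 3)
  bad <- file.path(dir, "corrupt.png")
  writeLines("junk", bad)
  cfg <- run_config(source_paths = c(fx$sources, bad),
                    reference_path = fx$reference,
                    output_dir = file.path(dir, "out"))
  summary <- suppressMessages(run_batch(cfg, quiet = TRUE))
  expect_equal(summary$n_ok, 3L)
  expect_equal(summary$n_failed, 1L)
  expect_identical(summary$failed, bad)
  rep <- read.csv(cfg$report_path, stringsAsFactors = FALSE)
  expect_equal(nrow(rep), 4L)  # 3 frames + MEAN

  cfg2 <- run_config(source_paths = bad, reference_path = fx$reference,
                     output_dir = file.path(dir, "out2"))
  summary2 <- suppressMessages(run_batch(cfg2, quiet = TRUE))
  expect_equal(summary2$status, 2L)
})

test_that("run_config validates its invariants", {
  expect_error(run_config(character(0), reference_path = "r.png"),
               "no source")
  expect_error(run_config("a.png"), "exactly one")
  expect_error(run_config("a.png", reference_path = "r.png",
                          stats_path = "s.json"), "exactly one")
  expect_error(run_config("a.png", reference_path = "r.png",
                          log_floor = 0), "positive")
})

test_that("batch accepts a precomputed stats file as reference", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(dir, 2)
  st <- nbisim:::reference_stats(list(read_image(fx$reference)))
  spath <- file.path(dir, "ref.json")
  write_stats(st, spath)
  cfg <- run_config(source_paths = fx$sources, stats_path = spath,
                    output_dir = file.path(dir, "out"))
  summary <- suppressMessages(run_batch(cfg, quiet = TRUE))
  expect_equal(summary$n_ok, 2L)
})

test_that("cli subcommands cover convert, stats, fixtures, evaluate, batch", {
  dir <- withr::local_tempdir()
  withr::local_dir(dir)
  # fixtures
  code <- suppressMessages(nbi_cli(c("fixtures", "--out-dir", "fx",
                                     "--pairs", "2", "--width", "64",
                                     "--height", "64", "--seed", "5")))
  expect_equal(code, 0L)
  expect_true(file.exists("fx/manifest.json"))
  expect_true(file.exists("fx/wli_002.png"))
  # stats
  code <- suppressMessages(nbi_cli(c("stats", "--reference",
                                     "fx/nbi_ref_001.png",
                                     "--out", "ref.json")))
  expect_equal(code, 0L)
  expect_s3_class(read_stats("ref.json"), "channel_stats")
  # convert with the stats file
  code <- suppressMessages(nbi_cli(c("convert", "--source", "fx/wli_001.png",
                                     "--stats", "ref.json",
                                     "--out", "out/sim.png")))
  expect_equal(code, 0L)
  expect_true(file.exists("out/sim.png"))
  # evaluate
  out <- capture.output(
    code <- suppressMessages(nbi_cli(c("evaluate", "--wli", "fx/wli_001.png",
                                       "--nbi", "out/sim.png"))))
  expect_equal(code, 0L)
  expect_match(out, "ssim_pct=", all = FALSE)
  # batch
  code <- suppressMessages(nbi_cli(c("batch", "--sources",
                                     "fx/wli_001.png,fx/wli_002.png",
                                     "--stats", "ref.json",
                                     "--out-dir", "bout")))
  expect_equal(code, 0L)
  expect_true(file.exists("bout/report.csv"))
  # usage errors exit 1
  expect_equal(suppressMessages(nbi_cli(c("convert"))), 1L)
  expect_equal(suppressMessages(nbi_cli("frobnicate")),
               1L)
})
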