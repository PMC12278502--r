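test_that("the bundled fixture has the published shape and is pinned", {
  c1 <- glyco_fixture(1)
  c2 <- glyco_fixture(2)
  expect_equal(nrow(c1), 55L)
  expect_equal(nrow(c2), 20L)
  expect_equal(c1$ExpNo, 1:55)
  expect_equal(c2$ExpNo, 56:75)
  expect_equal(nrow(glyco_fixture("all")), 75L)
  expect_equal(as.vector(table(c1$Batch)), c(10L, rep(5L, 9)))
  expect_equal(as.vector(table(c2$Batch)), rep(5L, 4))
  # dual campaign: 2 beta-objective + 3 alpha-objective rows per batch
  expect_equal(unname(colSums(table(c2$Objective, c2$Batch))), rep(5L, 4))
  expect_true(all(table(c2$Objective, c2$Batch)["beta", ] == 2))
  # transcription pinned against accidental edits
  sums <- c(YieldPct = sum(c1$YieldPct) + sum(c2$YieldPct),
            BetaPct = sum(c1$BetaPct) + sum(c2$BetaPct))
  expect_equal(unname(sums), c(4887, 4247))
  md5 <- unname(tools::md5sum(vapply(1:2, function(i) {
    system.file("extdata", paste0("campaign", i, ".csv"),
                package = "glycobo")
  }, character(1))))
  expect_equal(md5, c("3fb2269c1ecf8bb3b2e5cfd25eb8561c",
                      "157edd85760bf0cf4ea5a6157a2ef214"))
})

test_that("write/read round-trips campaigns exactly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  res <- small_campaign(n = 20, seed = 15, noise_sd = 5)
  res$Note <- sprintf("run-%d", seq_len(20))  # unknown columns preserved
  write_campaign(res, tmp)
  back <- read_campaign(tmp)
  expect_equal(back[names(res)], res, ignore_attr = TRUE)
})

test_that("schema errors are named and HV columns are never inputs", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  res <- small_campaign(n = 3, seed = 16)
  res$HVContr <- 99  # stale derived column must be dropped on read
  write_campaign(res, tmp)
  expect_false("HVContr" %in% names(read_campaign(tmp)))

  res2 <- res
  res2$ConcM <- NULL
  write_campaign(res2, tmp)
  expect_error(read_campaign(tmp), "ConcM")

  res3 <- small_campaign(n = 3, seed = 16)
  res3$YieldPct <- c("87", "oops", "12")
  write_campaign(res3, tmp)
  expect_error(read_campaign(tmp), "row 2")
})

test_that("campaign analysis recomputes contributions, fronts and totals", {
  an <- analyze_campaign(glyco_fixture(1), "beta_selectivity")
  expect_equal(round_half_up(an$table$HVContr)[1:3], c(60, 12, 8))
  expect_equal(an$total_hv,
               total_hypervolume(glyco_fixture(1)$YieldPct,
                                 glyco_fixture(1)$BetaPct))
  expect_equal(nrow(an$convergence), 10L)
  expect_s3_class(an$front, "glyco_front")
})

test_that("the CLI drives a full loop: init, suggest, simulate, analyze", {
  dir <- withr::local_tempdir()
  cfg <- cli_default_config()
  cfg$init_batch_size <- 6L
  cfg$batch_size <- 3L
  cfg$pool_size <- 80L
  glycobo:::cli_write_config(dir, cfg)

  expect_error(glyco_cli(c("bogus", dir)), "unknown verb")

  suppressMessages(glyco_cli(c("suggest", dir)))
  rows <- read_campaign(file.path(dir, "campaign.csv"))
  expect_equal(nrow(rows), 6L)
  expect_true(all(is.na(rows$YieldPct)))
  expect_true(all(rows$Mode == "random"))

  # the loop refuses to move on while results are missing
  expect_error(suppressMessages(glyco_cli(c("suggest", dir))), "pending")

  suppressMessages(glyco_cli(c("simulate", dir)))
  rows <- read_campaign(file.path(dir, "campaign.csv"))
  expect_false(anyNA(rows$YieldPct))

  suppressMessages(glyco_cli(c("suggest", dir)))
  rows <- read_campaign(file.path(dir, "campaign.csv"))
  expect_equal(nrow(rows), 9L)
  expect_equal(sum(is.na(rows$YieldPct)), 3L)

  # tell with deviating executed conditions updates the stored rows
  pending <- rows[is.na(rows$YieldPct), ]
  executed <- simulate_reaction(lab_scenario(), pending[,
    glycobo:::.campaign_cols], space = the_space, seed = 3)
  executed$LiSaltEq <- pmin(executed$LiSaltEq + 0.1, 5)
  res_file <- file.path(dir, "results.csv")
  write_campaign(executed, res_file)
  suppressMessages(glyco_cli(c("tell", dir, res_file)))
  rows <- read_campaign(file.path(dir, "campaign.csv"))
  expect_false(anyNA(rows$YieldPct))
  expect_equal(rows$LiSaltEq[7:9], executed$LiSaltEq, tolerance = 1e-9)

  suppressMessages(glyco_cli(c("analyze", dir)))
  expect_true(file.exists(file.path(dir, "analysis_beta.csv")))
  expect_true(file.exists(file.path(dir, "convergence_beta.csv")))
  an <- utils::read.csv(file.path(dir, "analysis_beta.csv"))
  expect_equal(an$HVContr, an$YieldPct * an$BetaPct / 100, tolerance = 1e-9)
})
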