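stub_results <- function(corrs) {
  # corrs: settings x subjects matrix
  ns <- nrow(corrs); nsub <- ncol(corrs)
  tibble::tibble(
    setting = rep(seq_len(ns), nsub),
    subject = rep(seq_len(nsub), each = ns),
    algorithm = "GREIT", nf = 0.15, background = "weighted",
    reference = "TD", ts = 0.06, rw = 0.15, prior = NA_character_,
    correlation = as.vector(corrs), achieved_nf = 0.15, lambda = 1,
    error = NA_character_)
}

test_that("rank aggregation follows spreadsheet arithmetic", {
  # 3 subjects x 4 settings with a tie for subject 3
  corrs <- rbind(c(0.9, 0.8, 0.7),
                 c(0.8, 0.9, 0.7),
                 c(0.7, 0.7, 0.9),
                 c(0.6, 0.6, 0.6))
  rk <- rank_settings(stub_results(corrs))
  # hand ranks: s1: 1,2,3,4; s2: 2,1,3,4; s3: 2.5,2.5,1,4
  expected <- c(mean(c(1, 2, 2.5)), mean(c(2, 1, 2.5)),
                mean(c(3, 3, 1)), 4)
  expect_equal(rk$mean_rank[match(1:4, rk$setting)], expected)
  expect_equal(rk$setting[1L], 1L)  # lowest mean rank first

  # a dominant setting ranks first
  dom <- rank_settings(stub_results(rbind(c(0.9, 0.95), c(0.5, 0.6))))
  expect_equal(dom$setting[1L], 1L)

  # ranking is invariant to monotone transformation of the scores
  rk2 <- rank_settings(stub_results(tanh(3 * corrs)))
  expect_equal(rk2$mean_rank, rk$mean_rank)

  # a singleton sweep trivially ranks first
  single <- rank_settings(stub_results(matrix(0.42, 1L, 1L)))
  expect_equal(single$mean_rank, 1)
})

test_that("failed rows rank last and are counted", {
  r <- stub_results(rbind(c(0.9, 0.9), c(0.5, 0.5)))
  r$correlation[r$setting == 2L & r$subject == 1L] <- NA_real_
  r$error[r$setting == 2L & r$subject == 1L] <- "solver error"
  rk <- rank_settings(r)
  expect_equal(rk$n_failed[rk$setting == 2L], 1L)
  expect_equal(rk$setting[1L], 1L)
})

test_that("the default sweep grid enumerates both algorithms", {
  st <- sweep_settings()
  expect_length(st, 24L)
  algos <- vapply(st, function(s) s$algorithm, "")
  expect_equal(sum(algos == "GREIT"), 12L)
  expect_equal(sum(algos == "GN"), 12L)
  nfs <- vapply(st, function(s) s$nf, 0.0)
  expect_setequal(unique(nfs), c(0.15, 0.3, 0.5))
})

test_that("a one-subject one-setting sweep runs end to end", {
  b <- breathing_config(fs = 12, duration = 20, seed = 2L)
  ch <- cohort(n = 1L, seed = 9L, breathing = b, recon_elements = 3000)
  sw <- run_sweep(ch, settings = list(greit_config(nf = 0.3)),
                  target_elements = 3000)
  expect_equal(nrow(sw$results), 1L)
  expect_true(is.na(sw$results$error[1L]))
  expect_gt(sw$results$correlation[1L], 0.5)
  expect_equal(sw$ranking$mean_rank, 1)
})
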