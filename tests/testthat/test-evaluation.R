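# Small synthetic result/truth tables exercise the metric arithmetic
# without any image processing.

make_truth <- function(n_fish = 3, n_frames = 20) {
  do.call(rbind, lapply(seq_len(n_frames), function(f) {
    tibble::tibble(frame = f, id = seq_len(n_fish),
                   nose_x = 100 * seq_len(n_fish) + f,
                   nose_y = 50 + 2 * f)
  }))
}

results_from_truth <- function(truth, jitter = 0.5) {
  tibble::tibble(frame = truth$frame, id = truth$id + 100,
                 N_x = truth$nose_x + jitter, N_y = truth$nose_y,
                 cover_ratio = 0.95)
}

test_that("matching labels correct, missed and spurious fish-frames", {
  truth <- make_truth()
  res <- results_from_truth(truth)
  lab <- match_to_truth(res, truth, tol = 10)
  expect_true(all(lab$correct))
  expect_equal(nrow(lab), nrow(truth))

  # a nose 11 px off is matched to nothing and produces a miss + error
  res2 <- res
  res2$N_x[1] <- res2$N_x[1] + 11
  lab2 <- match_to_truth(res2, truth, tol = 10)
  expect_equal(sum(lab2$type == "miss"), 1L)
  expect_equal(sum(lab2$type == "error"), 1L)

  # a failed cover check invalidates an otherwise matched fish-frame
  res3 <- res
  res3$cover_ratio[5] <- 0.5
  lab3 <- match_to_truth(res3, truth, tol = 10)
  expect_equal(sum(!lab3$correct), 1L)

  # a dropped result row is a miss
  lab4 <- match_to_truth(res[-1, ], truth, tol = 10)
  expect_equal(sum(lab4$type == "miss"), 1L)
})

test_that("miss/error ratio and CTR follow their definitions", {
  truth <- make_truth(5, 100)
  res <- results_from_truth(truth)
  drop <- sample(nrow(res), 10)
  lab <- match_to_truth(res[-drop, ], truth, tol = 10)
  me <- miss_error_ratio(lab, 5, 100)
  expect_equal(me$miss_ratio, 10 / 500)
  expect_equal(me$error_ratio, 0)
  expect_equal(ctr(lab, 5, 100), 490 / 500)

  # all missed
  lab_none <- match_to_truth(res[0, ], truth, tol = 10)
  expect_equal(miss_error_ratio(lab_none, 5, 100)$miss_ratio, 1)
  expect_equal(ctr(lab_none, 5, 100), 0)
  expect_error(miss_error_ratio(lab[0, ], 0, 0), "empty")

  # the printed-precision example: 19834 correct of 10 x 2000
  fake <- tibble::tibble(frame = 1, truth_id = 1, result_id = 1, dist = 0,
                         type = "match",
                         correct = rep(c(TRUE, FALSE), c(19834, 166)))
  expect_equal(ctr(fake, 10, 2000), 0.9917)
})

test_that("fish-frames partition into correct, miss and error", {
  truth <- make_truth(4, 30)
  res <- results_from_truth(truth)
  res$N_x[3] <- res$N_x[3] + 50    # displaced: miss + error
  res <- res[-10, ]                # dropped: miss
  lab <- match_to_truth(res, truth, tol = 10)
  n_match <- sum(lab$type == "match")
  n_miss <- sum(lab$type == "miss")
  n_err <- sum(lab$type == "error")
  expect_equal(n_match + n_miss, nrow(truth))
  expect_equal(n_match + n_err, nrow(res))
})

test_that("interruption rate counts early trajectory endings", {
  truth <- make_truth(2, 100)
  res <- results_from_truth(truth)
  lab <- match_to_truth(res, truth, tol = 10)
  expect_equal(ait(lab, truth, 2, 100), 0)
  # split fish 1's trajectory into two ids at frame 50: one interruption
  res2 <- res
  res2$id[res2$id == 101 & res2$frame > 50] <- 201
  lab2 <- match_to_truth(res2, truth, tol = 10)
  expect_equal(ait(lab2, truth, 2, 100), 1 / (2 * 100 / 100))
  # arithmetic of the published example: 32 interruptions, 10 fish, 2000
  # frames -> 0.16 (checked by construction of the formula inputs)
  expect_equal(32 / (10 * 2000 / 100), 0.16)
})

test_that("identification ratio after occlusions compares identity maps", {
  truth <- make_truth(2, 60)
  res <- results_from_truth(truth)
  events <- tibble::tibble(start_frame = c(20, 40), end_frame = c(22, 42),
                           ids = list(c(1, 2), c(1, 2)))
  lab <- match_to_truth(res, truth, tol = 10)
  expect_equal(cir(lab, events), 1)
  # swap result ids of the two fish after frame 41: the second event fails
  res2 <- res
  swap <- res2$frame > 41
  res2$id[swap] <- ifelse(res2$id[swap] == 101, 102, 101)
  lab2 <- match_to_truth(res2, truth, tol = 10)
  expect_equal(cir(lab2, events), 0.5)
  # ids swapped across the first event only: that event fails, and the
  # second event (consistent on both sides) still counts as correct
  res3 <- res
  s3 <- res3$frame > 21
  res3$id[s3] <- ifelse(res3$id[s3] == 101, 102, 101)
  lab3 <- match_to_truth(res3, truth, tol = 10)
  expect_equal(cir(lab3, events)[1], 0.5)
  expect_true(is.na(cir(lab, events[0, ])))
})

test_that("metrics are invariant to consistent identity relabeling", {
  truth <- make_truth(3, 40)
  res <- results_from_truth(truth)
  res_relab <- res
  res_relab$id <- match(res$id, unique(res$id)) * 7 + 1000
  m1 <- evaluate_tracking(res, truth)
  m2 <- evaluate_tracking(res_relab, truth)
  expect_equal(glance(m1)[, c("miss_ratio", "error_ratio", "ctr", "ait")],
               glance(m2)[, c("miss_ratio", "error_ratio", "ctr", "ait")])
})

test_that("tidy and glance expose the labels and the summary row", {
  truth <- make_truth(2, 10)
  m <- evaluate_tracking(results_from_truth(truth), truth)
  expect_s3_class(tidy(m), "tbl_df")
  g <- glance(m)
  expect_equal(nrow(g), 1L)
  expect_equal(g$ctr, 1)
})
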