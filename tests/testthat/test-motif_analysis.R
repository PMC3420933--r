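# structural motif detection: two-step and pull-push pathways,
# destabilisation, minimal enzymes, usage profile

arr <- standard_arrangement("e-opposite-r-out")

test_that("the consensus circuit has all four standard two-step pathways", {
  std <- count_standard_two_step("00033033", arr)
  expect_equal(nrow(std), 4)
  expect_setequal(paste(std$driver, std$intermediate),
                  c("0 1", "0 2", "3 1", "3 2"))
  expect_true(all(std$destabilized))
  expect_equal(nrow(count_pull_push("00033033", arr)), 0)
})

test_that("the classical circuit has two pathways over one intermediate", {
  std <- count_standard_two_step("x003xx3x", arr)
  expect_equal(nrow(std), 2)
  expect_setequal(std$driver, c(0, 3))
  expect_equal(unique(std$intermediate), arr$R)  # runs over the R state
  expect_true(all(std$over_R))
  expect_true(all(std$destabilized))
})

test_that("the x10320x3 circuit has neither standard two-step nor pull-push", {
  expect_equal(nrow(count_standard_two_step("x10320x3", arr)), 0)
  expect_equal(nrow(count_pull_push("x10320x3", arr)), 0)
})

test_that("0x2131x3 carries one standard two-step pathway and no pull-push", {
  std <- count_standard_two_step("0x2131x3", arr)
  expect_equal(nrow(std), 1)
  expect_equal(std$driver, 3)
  expect_equal(nrow(count_pull_push("0x2131x3", arr)), 0)
})

test_that("pull-push detection distinguishes plain from destabilised", {
  # symmetric double pull-push without destabilisation
  pp <- count_pull_push("x20x3xx1", arr)
  expect_equal(nrow(pp), 2)
  expect_false(any(pp$destabilized))
  # with the attacked E type recruiting the back-reaction
  ppd <- count_pull_push("020x3x31", arr)
  expect_equal(nrow(ppd), 2)
  expect_true(all(ppd$destabilized))
})

test_that("destabilisation excludes driver-recruited loss", {
  # driver-0 pathway over intermediate 2 (slots r3 = 0, r2 = 0); vary the
  # recruiter of the back-reaction 2 -> 3 (slot r7)
  base <- function(r7) paste0("x00xxx", r7, "x")
  expect_false(detect_destabilization(base("x"), arr, 0, 2))
  expect_false(detect_destabilization(base("0"), arr, 0, 2))  # by the driver
  expect_true(detect_destabilization(base("3"), arr, 0, 2))   # by attacked E
  expect_true(detect_destabilization(base("1"), arr, 0, 2))   # by intermediate
  expect_true(detect_destabilization(base("2"), arr, 0, 2))   # by itself
  # restricted scope: only the attacked E type counts
  expect_false(detect_destabilization(base("1"), arr, 0, 2,
                                      destab_scope = "attacked-E"))
  expect_true(detect_destabilization(base("3"), arr, 0, 2,
                                     destab_scope = "attacked-E"))
  expect_error(detect_destabilization("xxxxxxxx", arr, 0, 2),
               "not a standard two-step")
})

test_that("minimal enzyme counting merges position/direction duplicates", {
  expect_equal(minimal_enzymes("00033033"), 4)
  expect_equal(minimal_enzymes("x003xx3x"), 4)
  expect_equal(minimal_enzymes("xxxxxxxx"), 0)
  # r1 (1->0) and r3 (3->2) both remove position 1: one enzyme if same recruiter
  expect_equal(minimal_enzymes("0x0xxxxx"), 1)
  expect_equal(minimal_enzymes("0x1xxxxx"), 2)
})

test_that("minimal enzymes stay within the half-to-full recruited range", {
  for (i in 1:200) {
    cd <- random_code()
    k <- n_recruited(cd)
    m <- minimal_enzymes(cd)
    expect_gte(m, ceiling(k / 2))
    expect_lte(m, k)
  }
})

test_that("usage profile counts toward/away reactions and self-destruction", {
  u <- usage_profile("00033033", arr)
  expect_equal(unname(u$toward), c(4L, 4L))
  expect_equal(unname(u$away), c(0L, 0L))
  expect_false(u$e_self_destruction)
  expect_false(u$intermediate_self_destruction)
  u0 <- usage_profile("xxxxxxxx", arr)
  expect_equal(sum(u0$toward, u0$away), 0)
  # slot r1 = 1: type 1 recruits destruction of its own type (1 -> 0)
  u1 <- usage_profile("1xxxxxxx", arr)
  expect_true(u1$intermediate_self_destruction)
  expect_false(u1$e_self_destruction)
  # slot r4 = 0: E1 recruits a reaction consuming its own type (0 -> 2)
  u2 <- usage_profile("xxx0xxxx", arr)
  expect_true(u2$e_self_destruction)
  expect_equal(unname(u2$away), c(1L, 0L))
})

test_that("motif detectors agree with the brute-force oracle", {
  set.seed(7)
  for (i in 1:1000) {
    cd <- random_code()
    std <- count_standard_two_step(cd, arr)
    ostd <- oracle_std_two_step(cd)
    expect_equal(nrow(std), nrow(ostd))
    expect_equal(sum(std$destabilized), sum(ostd$destabilized))
    pp <- count_pull_push(cd, arr)
    opp <- oracle_pull_push(cd)
    expect_equal(nrow(pp), nrow(opp))
    expect_equal(sum(pp$destabilized), sum(opp$destabilized))
    expect_equal(minimal_enzymes(cd), oracle_min_enzymes(cd))
  }
})

test_that("motif counts are invariant under both twin relabellings", {
  arr_c <- arrangement(0, 3, 1)  # complement twin maps R = 2 onto R = 1
  for (i in 1:300) {
    cd <- random_code()
    tw <- as.character(complement_twin(cd))
    ps <- as.character(position_swap_twin(cd))
    expect_equal(nrow(count_standard_two_step(cd, arr)),
                 nrow(count_standard_two_step(tw, arr_c)))
    expect_equal(sum(count_standard_two_step(cd, arr)$destabilized),
                 sum(count_standard_two_step(tw, arr_c)$destabilized))
    expect_equal(nrow(count_pull_push(cd, arr)),
                 nrow(count_pull_push(tw, arr_c)))
    expect_equal(nrow(count_standard_two_step(cd, arr)),
                 nrow(count_standard_two_step(ps, arr_c)))
    expect_equal(minimal_enzymes(cd), minimal_enzymes(tw))
    expect_equal(minimal_enzymes(cd), minimal_enzymes(ps))
  }
})

test_that("E-adjacent arrangements have no one-step-intermediate pathways", {
  arr_adj <- standard_arrangement("e-adjacent-r-out")
  for (cd in c("00033033", "x003xx3x", "01230123")) {
    expect_equal(nrow(count_standard_two_step(cd, arr_adj)), 0)
    expect_equal(nrow(count_pull_push(cd, arr_adj)), 0)
  }
})

test_that("the generic path finder sees multi-step recruited feedback", {
  # consensus: E1 = 0 drives both two-step routes 3 -> I -> 0
  p <- feedback_paths("00033033", driver = 0, from = 3, to = 0, max_len = 2)
  expect_equal(length(p), 2)
  expect_true(all(vapply(p, function(x) length(x) == 3, logical(1))))
  # classical: single route over the R intermediate
  p2 <- feedback_paths("x003xx3x", driver = 0, from = 3, to = 0, max_len = 2)
  expect_equal(length(p2), 1)
  expect_equal(p2[[1]], c(3, 2, 0))
  expect_equal(length(feedback_paths("xxxxxxxx", 0, 3, 0)), 0)
})

test_that("motif report aggregates all structural columns", {
  mr <- motif_report("00033033", arr)
  expect_equal(mr$n_recruited, 8L)
  expect_equal(mr$min_enzymes, 4)
  expect_equal(mr$n_std_two_step, 4)
  expect_equal(mr$n_std_destabilized, 4)
  expect_equal(mr$n_pull_push, 0)
  expect_output(print(mr), "standard two-step: 4")
})
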