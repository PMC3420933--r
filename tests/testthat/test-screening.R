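# enumeration, per-code seeding, the screen loop and its summary

arr <- standard_arrangement("e-opposite-r-out")

test_that("code enumeration has the right cardinalities", {
  expect_equal(length(enumerate_codes("x***xx*x")), 625)
  expect_equal(enumerate_codes("00033033"), "00033033")
  expect_equal(length(enumerate_codes("0*xxxxxx")), 5)
  all_codes <- enumerate_codes()
  expect_equal(length(all_codes), 390625)
  expect_false(anyDuplicated(all_codes) > 0)
  expect_error(enumerate_codes("****"), "8 characters")
  expect_error(enumerate_codes("*******9"), "position 8")
})

test_that("enumeration round-trips through the parser", {
  sub <- enumerate_codes("12*x**30")
  expect_equal(vapply(sub, function(cd) as.character(parse_code(cd)),
                      character(1), USE.NAMES = FALSE), sub)
  expect_true("x003xx3x" %in% enumerate_codes("x***xx*x"))
  expect_true("xxxxxxxx" %in% enumerate_codes("x***xx*x"))
})

test_that("per-code seeds are deterministic, spread, and order-free", {
  s1 <- code_seed(1, "00033033")
  expect_identical(s1, code_seed(1, "00033033"))
  expect_false(s1 == code_seed(2, "00033033"))
  expect_false(s1 == code_seed(1, "0003303x"))
  seeds <- vapply(enumerate_codes("xx*xx**x"), code_seed,
                  integer(1), master_seed = 7)
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 2))
})

test_that("screen verdicts separate consensus from the all-noise circuit", {
  res <- screen_codes(c("00033033", "xxxxxxxx"), arr,
                      sim_params(gens = 100, repeats = 2), seed = 3)
  expect_true(res$working[res$code == "00033033"])
  expect_false(res$working[res$code == "xxxxxxxx"])
  expect_equal(res$n_std_two_step[res$code == "00033033"], 4L)
  expect_false(any(res$exotic))
})

test_that("screen results do not depend on the order of the code stream", {
  codes <- enumerate_codes("x0*3xx3x")
  p <- sim_params(gens = 50, repeats = 1)
  r1 <- screen_codes(codes, arr, p, seed = 11, motifs = FALSE)
  r2 <- screen_codes(rev(codes), arr, p, seed = 11, motifs = FALSE)
  m <- match(r1$code, r2$code)
  expect_equal(r1$B, r2$B[m])
  expect_equal(r1$working, r2$working[m])
})

test_that("duplicate codes are rejected and checkpoints resume cleanly", {
  expect_error(screen_codes(c("xxxxxxxx", "xxxxxxxx"), arr), "deduplicated")
  codes <- enumerate_codes("x00*xx3x")
  cp <- tempfile(fileext = ".csv")
  p <- sim_params(gens = 30, repeats = 1)
  screen_codes(codes[1:2], arr, p, seed = 4, checkpoint = cp)
  full <- screen_codes(codes, arr, p, seed = 4, checkpoint = cp)
  expect_equal(sort(full$code), sort(codes))
  expect_false(anyDuplicated(full$code) > 0)
  fresh <- screen_codes(codes, arr, p, seed = 4)
  m <- match(fresh$code, full$code)
  expect_equal(full$B[m], fresh$B, tolerance = 1e-12)
})

test_that("early abort never changes a verdict", {
  codes <- enumerate_codes("*x0x3*xx")
  p <- sim_params(gens = 60, repeats = 2)
  r1 <- screen_codes(codes, arr, p, seed = 21, motifs = FALSE)
  r2 <- screen_codes(codes, arr, p, seed = 21, motifs = FALSE,
                     early_abort = TRUE)
  expect_identical(r1$working, r2$working)
  expect_true(any(r2$aborted))
})

test_that("raising the noise level only shrinks the working set", {
  codes <- enumerate_codes("x0*3x*3x")
  low <- screen_codes(codes, arr, sim_params(gens = 100, repeats = 2),
                      seed = 6, motifs = FALSE)
  p_hi <- sim_params(gens = 100, repeats = 2, alpha = 0.05)
  high <- screen_codes(codes, arr, p_hi, seed = 6, motifs = FALSE)
  expect_lte(sum(high$working), sum(low$working))
})

test_that("screen summaries aggregate the motif surfaces", {
  codes <- c("00033033", "x003xx3x", "xxxxxxxx", "x10320x3")
  res <- screen_codes(codes, arr, sim_params(gens = 100, repeats = 2), seed = 9)
  s <- summarize_screen(res, arr)
  expect_equal(s$n_screened, 4)
  expect_equal(s$n_working, sum(res$working))
  expect_equal(sum(s$reaction_usage), 8 * s$n_working)
  expect_equal(sum(s$n_recruited_hist), s$n_working)
  # consensus + classical working: both have standard two-step pathways
  expect_gte(s$n_with_std_two_step, 2 * (s$n_working >= 2))
  expect_warning(empty <- summarize_screen(res[0, ], arr), "empty")
  expect_equal(empty$n_working, 0)
  bare <- screen_codes("xxxxxxxx", arr, sim_params(gens = 10, repeats = 1),
                       seed = 1, motifs = FALSE)
  expect_error(summarize_screen(bare, arr), "motif columns")
})

test_that("twin discordance is measured over within-arrangement twin pairs", {
  # the E-swap twin fixes the R type, so twins face identical dynamics:
  # "0003xx3x" and "x003xx33" are such a pair; consensus and classical are
  # their own twins
  expect_equal(as.character(e_swap_twin("x003xx3x")), "x003xx3x")
  expect_equal(as.character(e_swap_twin("00033033")), "00033033")
  expect_equal(as.character(e_swap_twin("0003xx3x")), "x003xx33")
  codes <- c("00033033", "x003xx3x", "0003xx3x", "x003xx33")
  res <- screen_codes(codes, arr, sim_params(gens = 120, repeats = 2), seed = 12)
  s <- summarize_screen(res, arr)
  expect_equal(s$twin_discordance, 0)
})

test_that("threshold sensitivity re-scores a screen without re-simulating", {
  res <- screen_codes(c("00033033", "x003xx3x", "xxxxxxxx"), arr,
                      sim_params(gens = 100, repeats = 2), seed = 3,
                      motifs = FALSE)
  sens <- working_sensitivity(res)
  expect_equal(nrow(sens), 3)            # tau_max grid {2, 5, 10}
  expect_true(all(diff(sens$n_working) >= 0))  # looser tau never shrinks
  expect_equal(sens$n_working[sens$tau_max == 5], sum(res$working))
  # an impossible balance bound excludes everything
  expect_equal(working_sensitivity(res, B_min = 1.1)$n_working, rep(0, 3))
})

test_that("alpha calibration sweeps report the closest working count", {
  codes <- enumerate_codes("x003xx3*")
  cal <- calibrate_alpha(c(0.004, 0.2), codes, arr,
                         sim_params(gens = 60, repeats = 1),
                         seed = 2, target = length(codes))
  expect_equal(nrow(cal$sweep), 2)
  expect_true(cal$best_alpha %in% c(0.004, 0.2))
  # at the absurdly high alpha nothing can work, so the best match to a
  # positive target is the low-noise screen
  expect_equal(cal$best_alpha, 0.004)
})

test_that("fixtures are deterministic and sized as documented", {
  d <- tempfile()
  f1 <- make_fixture("trajectory", seed = 5, dir = d)
  f2 <- make_fixture("trajectory", seed = 5, dir = tempfile())
  expect_identical(readLines(f1), readLines(f2))
  g <- make_fixture("graph-toy", seed = 1, dir = d)
  expect_equal(nrow(utils::read.table(g, header = TRUE)), 4)  # 5-node chain
  sc <- make_fixture("screen-sample", seed = 1, dir = d)
  expect_equal(nrow(utils::read.csv(sc)), 625)
  expect_error(make_fixture("nope"), "valid kinds")
})
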