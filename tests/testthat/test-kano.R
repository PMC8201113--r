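test_that("pair classification matches the canonical evaluation matrix", {
  # category-defining cells
  expect_equal(classify_pair(1, 5), "O")  # liked present, disliked absent
  expect_equal(classify_pair(3, 3), "I")  # neutral either way
  expect_equal(classify_pair(5, 1), "R")  # disliked present, liked absent
  expect_equal(classify_pair(1, 1), "Q")  # contradictory
  expect_equal(classify_pair(1, 3), "A")
  expect_equal(classify_pair(3, 5), "M")
  # all 25 cells against the literal oracle lookup
  grid <- expand.grid(f = 1:5, d = 1:5)
  expect_equal(classify_pair(grid$f, grid$d),
               unname(oracle_lookup[paste(grid$f, grid$d, sep = ",")]))
  # every category is reachable in the default matrix
  expect_setequal(unique(as.vector(kano_matrix())), kano_categories())
  expect_error(classify_pair(0, 3), "1..5")
  expect_error(classify_pair(1, 6), "1..5")
})

test_that("the bundled evaluation-matrix file equals the built-in default", {
  path <- system.file("extdata", "evaluation_matrix.csv", package = "kanoqual")
  expect_equal(read_kano_matrix(path), kano_matrix())
})

test_that("aggregation tallies valid pairs and handles degenerate tables", {
  instr <- tiny_instrument(1)
  const <- kano_responses(data.frame(
    respondent_id = paste0("p", 1:250),
    age_group = "18-34", gender = "male", hospital = "barton",
    a1_f = 1L, a1_d = 5L), instr)
  counts <- aggregate_counts(const)
  expect_equal(counts$n_O, 250L)
  expect_equal(counts$n_valid, 250L)
  expect_equal(counts$n_A + counts$n_M + counts$n_I + counts$n_R + counts$n_Q, 0L)
  empty <- kano_responses(const[0, ], instr)
  counts0 <- aggregate_counts(empty)
  expect_equal(counts0$n_valid, 0L)
  expect_true(all(counts0[, paste0("n_", kano_categories())] == 0))
})

test_that("modal classification follows counts with configurable tie-break", {
  mk <- function(A = 0, Q = 0, I = 0, R = 0, M = 0, O = 0) {
    data.frame(attr_id = 1, n_A = A, n_Q = Q, n_I = I, n_R = R, n_M = M, n_O = O)
  }
  expect_equal(classify_attribute(mk(A = 2, I = 3, M = 127, O = 118)), "M")
  expect_equal(classify_attribute(mk(A = 2, I = 35, R = 3, M = 104, O = 106)), "O")
  expect_equal(classify_attribute(mk(Q = 1, I = 28, R = 220, M = 1)), "R")
  # default tie order puts must-be before one-dimensional
  expect_equal(classify_attribute(mk(M = 100, O = 100)), "M")
  expect_equal(classify_attribute(mk(M = 100, O = 100),
                                  tie_order = c("O", "M", "A", "I", "R", "Q")), "O")
  expect_error(classify_attribute(mk()), "all-zero")
  expect_error(classify_attribute(mk(M = 1), tie_order = c("M", "O")), "permutation")
})

test_that("CS and DS follow the Berger formulas with Q/R excluded", {
  mk <- function(A = 0, Q = 0, I = 0, R = 0, M = 0, O = 0) {
    data.frame(attr_id = 1, n_A = A, n_Q = Q, n_I = I, n_R = R, n_M = M, n_O = O)
  }
  r1 <- mk(A = 24, I = 21, M = 85, O = 120)
  expect_equal(satisfaction_coefficient(r1), 144 / 250)
  expect_equal(dissatisfaction_coefficient(r1), -205 / 250)
  r31 <- mk(Q = 1, I = 28, R = 220, M = 1)
  expect_equal(satisfaction_coefficient(r31), 0)
  expect_equal(dissatisfaction_coefficient(r31), -1 / 29)
  r11 <- mk(A = 1, I = 6, M = 98, O = 144)
  expect_equal(dissatisfaction_coefficient(r11), -242 / 249)
  expect_equal(round_half_up(dissatisfaction_coefficient(r11)), -0.97)
  # bounds at the extremes
  expect_equal(satisfaction_coefficient(mk(I = 10)), 0)
  expect_equal(satisfaction_coefficient(mk(A = 5, O = 5)), 1)
  expect_equal(dissatisfaction_coefficient(mk(A = 5, I = 5)), 0)
  # all responses reverse/questionable -> undefined, not zero
  und <- mk(R = 3, Q = 2)
  expect_true(is.na(satisfaction_coefficient(und)))
  expect_true(is.na(dissatisfaction_coefficient(und)))
  resu <- analyze_counts(und)
  expect_equal(resu$classification, "R")  # still classified by mode
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_up(0.575), 0.58)
  expect_equal(round_half_up(-0.825), -0.83)
  expect_equal(round_half_up(0.5749), 0.57)
  expect_equal(round_half_up(c(0.005, -0.005), 2), c(0.01, -0.01))
})

test_that("analyze matches the brute-force oracle on random small tables", {
  for (seed in 1:25) {
    tab <- withr::with_seed(seed, random_responses(
      n = sample(1:20, 1), n_attr = sample(1:5, 1), missing_rate = 0.15))
    instr <- attr(tab, "instrument")
    got <- kano_analyze(tab)
    want <- oracle_analyze(tab, instr$attr_id)
    for (col in c("n_A", "n_O", "n_M", "n_I", "n_R", "n_Q")) {
      expect_equal(got[[col]], want[[col]], info = paste("seed", seed, col))
    }
    defined <- got$n_valid > 0
    expect_equal(got$classification[defined],
                 want$classification[defined], info = paste("seed", seed))
    expect_equal(got$cs_exact, want$cs_exact, info = paste("seed", seed))
    expect_equal(got$ds_exact, want$ds_exact, info = paste("seed", seed))
    # conservation and bounds on the same tables
    expect_equal(rowSums(got[, paste0("n_", kano_categories())]),
                 as.double(got$n_valid), ignore_attr = TRUE)
    ok <- !is.na(got$cs_exact)
    expect_true(all(got$cs_exact[ok] >= 0 & got$cs_exact[ok] <= 1))
    expect_true(all(got$ds_exact[ok] >= -1 & got$ds_exact[ok] <= 0))
  }
})

test_that("analysis is invariant under respondent shuffling and Lipschitz in respondents", {
  tab <- withr::with_seed(42, random_responses(n = 15, n_attr = 4, missing_rate = 0.1))
  instr <- attr(tab, "instrument")
  shuffled <- kano_responses(tab[withr::with_seed(7, sample(nrow(tab))), ], instr)
  expect_equal(kano_analyze(tab), kano_analyze(shuffled))
  # adding one respondent moves each category count by at most 1
  c_full <- aggregate_counts(tab)
  c_less <- aggregate_counts(kano_responses(tab[-1, ], instr))
  diffs <- abs(as.matrix(c_full[, paste0("n_", kano_categories())]) -
               as.matrix(c_less[, paste0("n_", kano_categories())]))
  expect_true(all(diffs <= 1))
  # each removed valid pair decrements exactly one category
  expect_equal(rowSums(diffs), as.double(c_full$n_valid - c_less$n_valid),
               ignore_attr = TRUE)
})

test_that("classification tallies are conserved", {
  res <- analyze_counts(hospital_survey_counts())
  tally <- summarize_classifications(res)
  expect_equal(sum(tally$n), nrow(res))
  expect_equal(tally$classification, kano_categories())
  empty <- summarize_classifications(res[0, ])
  expect_equal(empty$n, rep(0L, 6))
})
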